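#' @rdname Trajectory-class
#' @aliases nFrames nAtoms coords atomTable
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname Trajectory-class
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[2])

#' @rdname Trajectory-class
setMethod("coords", "Trajectory", function(x) x@coords)

#' @rdname Trajectory-class
setMethod("atomTable", "Trajectory", function(x) x@atoms)

#' @rdname SegmentEnsemble-class
#' @param x a `SegmentEnsemble`
setMethod("nAtoms", "SegmentEnsemble",
          function(x) nAtoms(x@segments[[1]]))

#' @rdname SegmentEnsemble-class
setMethod("atomTable", "SegmentEnsemble",
          function(x) atomTable(x@segments[[1]]))

#' Segments of an ensemble
#'
#' @param x a [SegmentEnsemble-class]
#' @return list of [Trajectory-class] segments
#' @export
segments <- function(x) {
    stopifnot(is(x, "SegmentEnsemble"))
    x@segments
}

#' @rdname EssentialSpace-class
setMethod("images", "EssentialSpace", function(x) x@images)

#' @rdname EssentialSpace-class
setMethod("essentialCount", "EssentialSpace", function(x) x@m)

#' @rdname EssentialSpace-class
setMethod("varianceFraction", "EssentialSpace",
          function(x) x@varianceFraction)

#' @rdname EssentialSpace-class
setMethod("atomTable", "EssentialSpace", function(x) x@atoms)

#' @rdname CorrelationMap-class
setMethod("mapValues", "CorrelationMap", function(x) x@values)

#' @rdname DomainPartition-class
setMethod("domains", "DomainPartition", function(x) x@domains)

#' Per-atom domain rank labels
#'
#' Returns an integer vector over the analyzed atoms: `k` for members of the
#' k-th largest domain, `NA` for unassigned atoms.
#'
#' @rdname DomainPartition-class
setMethod("domainLabels", "DomainPartition", function(x) {
    lab <- rep(NA_integer_, x@nAtoms)
    for (k in seq_along(x@domains)) lab[x@domains[[k]]] <- k
    lab
})

#' Flexibility profile as a data.frame
#'
#' @param x a [FlexibilityProfile-class] or [BFactorProfile-class]
#' @return data.frame with residue identifiers and values
#' @export
profileTable <- function(x) {
    if (is(x, "FlexibilityProfile")) {
        cbind(x@residues,
              data.frame(mean_flex = x@meanFlex, sd_flex = x@sdFlex))
    } else if (is(x, "BFactorProfile")) {
        cbind(x@residues, data.frame(value = x@value))
    } else stop("unsupported profile object")
}

setMethod("show", "Trajectory", function(object) {
    cat(sprintf("Trajectory: %d frame(s), %d atoms", nFrames(object),
                nAtoms(object)))
    if (!is.na(object@frameInterval))
        cat(sprintf(", %g ps/frame", object@frameInterval))
    ch <- unique(object@atoms$chain)
    cat(sprintf("\n  chains: %s\n", paste(ch, collapse = ", ")))
})

setMethod("show", "AtomSelection", function(object) {
    cat(sprintf("AtomSelection '%s': %d atoms (of %d)\n", object@label,
                length(object@indices), object@nAtomsSource))
})

setMethod("show", "SegmentEnsemble", function(object) {
    cat(sprintf("SegmentEnsemble: %d segments x %d frames, %d atoms\n",
                length(object@segments), object@segmentLength,
                nAtoms(object)))
})

setMethod("show", "EssentialSpace", function(object) {
    cat(sprintf(
        "EssentialSpace: %d atoms, m = %d essential coordinates (%.1f%% of displacement)\n",
        nrow(object@images), object@m, 100 * object@varianceFraction))
})

setMethod("show", "CorrelationMap", function(object) {
    cat(sprintf(
        "CorrelationMap: %d x %d pairs, averaged over %d segment(s)\n  rows: %s\n  cols: %s\n",
        nrow(object@values), ncol(object@values), object@nSegmentsAveraged,
        object@rowLabel, object@colLabel))
})

setMethod("show", "FlexibilityProfile", function(object) {
    cat(sprintf(
        "FlexibilityProfile: %d residues, %d segment(s), mean F in [%.3g, %.3g]\n",
        nrow(object@residues), object@nSegments, min(object@meanFlex),
        max(object@meanFlex)))
})

setMethod("show", "BFactorProfile", function(object) {
    cat(sprintf("BFactorProfile (%s): %d residues, B in [%.3g, %.3g] A^2\n",
                object@aggregation, nrow(object@residues),
                min(object@value), max(object@value)))
})

setMethod("show", "DomainPartition", function(object) {
    sz <- vapply(object@domains, length, integer(1))
    cat(sprintf(
        "DomainPartition at d_c = %g: %d domain(s) of sizes [%s], %d unassigned (largest fraction %.2f)\n",
        object@threshold, length(sz), paste(sz, collapse = ", "),
        length(object@unassigned), object@largestFraction))
})

setMethod("show", "ENMSpec", function(object) {
    cat(sprintf(
        "ENMSpec: %d atoms, %d springs, T = %g K, gamma = %g ps^-1, dt = %g ps, %d frames (stride %d), seed %d\n",
        nrow(object@positions0), nrow(object@springs), object@temperature,
        object@friction, object@dt, object@nFrames, object@stride,
        object@seed))
})
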