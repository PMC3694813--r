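#' Per-residue ECD flexibility profile
#'
#' For each trajectory segment the flexibility of a C-alpha atom is the
#' Euclidean distance, in the m-dimensional essential space, between the
#' atom's image and the centroid (component-wise mean) of all selected
#' C-alpha images; atoms weakly coupled to the collective motion of the
#' molecule sit far from the centroid, so high values mark flexible loops and
#' hinges. `meanFlex` and `sdFlex` are the across-segment mean and standard
#' deviation.
#'
#' @param ensemble a [SegmentEnsemble-class]
#' @param sel [AtomSelection-class] with one C-alpha per residue of interest.
#' @param fraction,fixedM,weighting passed to [essentialSpace()].
#' @param superpose superpose each segment on `sel` first (default TRUE).
#' @return a [FlexibilityProfile-class]
#' @export
flexibilityProfile <- function(ensemble, sel, fraction = 0.90,
                               fixedM = NULL,
                               weighting = c("none", "eigenvalue"),
                               superpose = TRUE) {
    weighting <- match.arg(weighting)
    stopifnot(is(ensemble, "SegmentEnsemble"))
    idx <- .resolveIndices(sel, nAtoms(ensemble))
    segs <- ensemble@segments
    Fmat <- matrix(0, length(segs), length(idx))
    for (s in seq_along(segs)) {
        seg <- segs[[s]]
        if (superpose) seg <- superposeFrames(seg, idx)
        cv <- computeCovariance(seg, idx)
        es <- essentialSpace(cv, fraction = fraction, fixedM = fixedM,
                             weighting = weighting)
        img <- es@images
        centroid <- colMeans(img)
        Fmat[s, ] <- sqrt(rowSums(sweep(img, 2, centroid)^2))
    }
    ns <- length(segs)
    meanF <- colMeans(Fmat)
    if (ns > 1L) {
        sdF <- apply(Fmat, 2, stats::sd)
    } else {
        .logWarn("single segment: across-segment SD reported as 0")
        sdF <- rep(0, length(idx))
    }
    atoms <- atomTable(ensemble)[idx, , drop = FALSE]
    new("FlexibilityProfile",
        residues = data.frame(chain = atoms$chain, resid = atoms$resid,
                              resname = atoms$resname,
                              stringsAsFactors = FALSE),
        meanFlex = meanF, sdFlex = sdF, nSegments = as.integer(ns),
        nCalpha = length(idx))
}

.profileValues <- function(x) {
    if (is(x, "FlexibilityProfile")) x@meanFlex
    else if (is(x, "BFactorProfile")) x@value
    else stop("expected a FlexibilityProfile or BFactorProfile")
}

.profileKeys <- function(x) {
    r <- x@residues
    paste(r$chain, r$resid, sep = ":")
}

#' Normalize a flexibility profile onto a B-factor reference range
#'
#' Affine min-max map of `meanFlex` onto `[min(reference), max(reference)]`
#' over the residues the two profiles share (paired by chain and author
#' residue number); `sdFlex` is scaled by the same factor. Used to over-impose
#' computed flexibility on crystallographic B-factors. `method = "zscore"`
#' instead matches mean and standard deviation to the reference.
#'
#' @param profile a [FlexibilityProfile-class]
#' @param reference a [BFactorProfile-class] (or second flexibility profile).
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return a [FlexibilityProfile-class] restricted to the common residues,
#'   in reference order.
#' @export
normalizeProfile <- function(profile, reference,
                             method = c("minmax", "zscore")) {
    method <- match.arg(method)
    pk <- .profileKeys(profile); rk <- .profileKeys(reference)
    common <- intersect(rk, pk)
    if (length(common) < 3L)
        stop("profiles share fewer than 3 residues")
    pi_ <- match(common, pk); ri_ <- match(common, rk)
    f <- profile@meanFlex[pi_]; s <- profile@sdFlex[pi_]
    ref <- .profileValues(reference)[ri_]
    if (method == "minmax") {
        if (max(f) == min(f))
            stop("constant flexibility profile: min-max normalization undefined")
        scale <- (max(ref) - min(ref)) / (max(f) - min(f))
        out <- min(ref) + (f - min(f)) * scale
    } else {
        if (stats::sd(f) == 0)
            stop("constant flexibility profile: z-score normalization undefined")
        scale <- stats::sd(ref) / stats::sd(f)
        out <- mean(ref) + (f - mean(f)) * scale
    }
    new("FlexibilityProfile",
        residues = profile@residues[pi_, , drop = FALSE],
        meanFlex = out, sdFlex = s * scale,
        nSegments = profile@nSegments, nCalpha = profile@nCalpha)
}

#' Per-residue crystallographic B-factors from a structure
#'
#' @param structure a one-frame [Trajectory-class] whose atom table carries
#'   B-factors (column 61-66 of the PDB).
#' @param aggregation `"CA"` (the C-alpha B-factor, default) or
#'   `"backbone"` (mean over N, CA, C; missing backbone atoms trigger a
#'   warning and the available ones are used).
#' @return a [BFactorProfile-class]
#' @export
extractBFactors <- function(structure, aggregation = c("CA", "backbone")) {
    aggregation <- match.arg(aggregation)
    at <- structure@atoms
    if (all(is.na(at$bfactor)))
        stop("structure carries no B-factor values")
    want <- if (aggregation == "CA") "CA" else c("N", "CA", "C")
    at <- at[at$name %in% want, , drop = FALSE]
    key <- paste(at$chain, at$resid, sep = ":")
    ord <- !duplicated(key)
    res <- at[ord, c("chain", "resid", "resname"), drop = FALSE]
    vals <- numeric(nrow(res))
    ukey <- key[ord]
    for (r in seq_along(ukey)) {
        rows <- which(key == ukey[r])
        b <- at$bfactor[rows]
        if (aggregation == "backbone" && length(rows) < 3L)
            .logWarn("residue %s: only %d backbone atom(s) present; using available",
                     ukey[r], length(rows))
        if (any(is.na(b)))
            stop("missing B-factor for residue ", ukey[r])
        vals[r] <- mean(b)
    }
    rownames(res) <- NULL
    new("BFactorProfile", residues = res, value = vals,
        aggregation = aggregation)
}

#' Quantitative agreement between two per-residue profiles
#'
#' Pearson and Spearman correlations over the residue intersection (paired by
#' chain and author residue number), to put the visual over-imposition of
#' computed flexibility on B-factors on a quantitative footing.
#'
#' @param a,b [FlexibilityProfile-class] or [BFactorProfile-class] objects
#'   sharing >= 3 residues.
#' @return list with `pearson`, `spearman`, `n_common`
#' @export
profileAgreement <- function(a, b) {
    ka <- .profileKeys(a); kb <- .profileKeys(b)
    common <- intersect(ka, kb)
    if (length(common) < 3L)
        stop("profiles share fewer than 3 residues")
    va <- .profileValues(a)[match(common, ka)]
    vb <- .profileValues(b)[match(common, kb)]
    list(pearson = stats::cor(va, vb, method = "pearson"),
         spearman = stats::cor(va, vb, method = "spearman"),
         n_common = length(common))
}

#' Write a per-residue profile as TSV
#'
#' Columns: chain, resid, resname, then `mean_flex`/`sd_flex` (flexibility)
#' or `value` (B-factors).
#'
#' @param x a [FlexibilityProfile-class] or [BFactorProfile-class]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
writeProfile <- function(x, path) {
    utils::write.table(profileTable(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
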