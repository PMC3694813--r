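#' @import methods
NULL

.validAtomTable <- function(atoms) {
    required <- c("chain", "resid", "resname", "name", "elem", "bfactor")
    if (!is.data.frame(atoms))
        return("'atoms' must be a data.frame")
    missing <- setdiff(required, names(atoms))
    if (length(missing))
        return(paste0("atom table lacks column(s): ",
                      paste(missing, collapse = ", ")))
    if (!is.numeric(atoms$resid))
        return("'resid' must be numeric (author numbering)")
    TRUE
}

#' Trajectory: frames of Cartesian coordinates plus an atom table
#'
#' A `Trajectory` holds an `n_frames x n_atoms x 3` coordinate array in
#' angstroms together with a per-atom annotation table (chain, author residue
#' number, residue name, atom name, element, optional crystallographic
#' B-factor). Single structures are one-frame trajectories.
#'
#' @slot coords numeric array, `n_frames x n_atoms x 3`, angstroms.
#' @slot atoms data.frame with columns `chain`, `resid`, `resname`, `name`,
#'   `elem`, `bfactor` (`NA` when unknown); one row per atom.
#' @slot frameInterval numeric(1), time between frames in ps (`NA` if
#'   unknown; metadata only).
#'
#' @seealso [readPDB()], [readTrajectory()], [selectAtoms()],
#'   [superposeFrames()]
#' @exportClass Trajectory
setClass("Trajectory",
    representation(coords = "array", atoms = "data.frame",
                   frameInterval = "numeric"),
    prototype(frameInterval = NA_real_))

setValidity("Trajectory", function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[3] != 3L)
        return("'coords' must be an n_frames x n_atoms x 3 array")
    if (d[1] < 1L)
        return("trajectory must hold at least one frame")
    if (d[2] < 1L)
        return("trajectory must hold at least one atom")
    if (!all(is.finite(object@coords)))
        return("'coords' contains non-finite values")
    ok <- .validAtomTable(object@atoms)
    if (!isTRUE(ok)) return(ok)
    if (nrow(object@atoms) != d[2])
        return(sprintf("atom table has %d rows but coords hold %d atoms",
                       nrow(object@atoms), d[2]))
    TRUE
})

#' AtomSelection: an ordered subset of a trajectory's atoms
#'
#' Indices are 1-based, strictly increasing positions into the atom table of
#' the trajectory the selection was made from. Selections are produced by
#' [selectAtoms()] and consumed by the covariance, flexibility, domain and
#' contact machinery.
#'
#' @slot indices integer vector, strictly increasing, 1-based.
#' @slot label character(1), the selection expression or a free-form label.
#' @slot nAtomsSource integer(1), atom count of the source trajectory (used
#'   to validate the selection when it is applied).
#'
#' @exportClass AtomSelection
setClass("AtomSelection",
    representation(indices = "integer", label = "character",
                   nAtomsSource = "integer"))

setValidity("AtomSelection", function(object) {
    idx <- object@indices
    if (length(idx) == 0L)
        return("empty atom selection")
    if (any(idx < 1L) || any(idx > object@nAtomsSource))
        return("selection indices out of range")
    if (any(diff(idx) <= 0L))
        return("selection indices must be strictly increasing")
    TRUE
})

#' SegmentEnsemble: contiguous equal-length trajectory segments
#'
#' Produced by [segmentTrajectory()]. All segments share one atom table and
#' have the same number of frames; downstream ECD statistics (correlation
#' maps, flexibility profiles) are computed per segment and averaged.
#'
#' @slot segments list of [Trajectory-class] objects.
#' @slot segmentLength integer(1), frames per segment.
#'
#' @exportClass SegmentEnsemble
setClass("SegmentEnsemble",
    representation(segments = "list", segmentLength = "integer"))

setValidity("SegmentEnsemble", function(object) {
    if (length(object@segments) < 1L)
        return("ensemble must hold at least one segment")
    if (!all(vapply(object@segments, is, logical(1), "Trajectory")))
        return("all segments must be Trajectory objects")
    na <- vapply(object@segments, nAtoms, integer(1))
    if (length(unique(na)) != 1L)
        return("segments differ in atom count")
    nf <- vapply(object@segments, nFrames, integer(1))
    if (any(nf < 2L))
        return("each segment needs at least 2 frames")
    if (any(nf != object@segmentLength))
        return("segment frame counts disagree with 'segmentLength'")
    TRUE
})

#' CovarianceResult: Cartesian fluctuation covariance of a segment
#'
#' The `3N x 3N` covariance matrix of atomic displacements about the segment
#' mean, ordered (atom1.x, atom1.y, atom1.z, atom2.x, ...), in angstrom^2.
#'
#' @slot matrix numeric `3N x 3N` symmetric positive semi-definite matrix.
#' @slot meanStructure numeric `N x 3` mean coordinates (angstroms).
#' @slot nFramesUsed integer(1), frames entering the average.
#' @slot divisor character(1), `"population"` (1/n) or `"sample"` (1/(n-1)).
#'
#' @exportClass CovarianceResult
setClass("CovarianceResult",
    representation(matrix = "matrix", meanStructure = "matrix",
                   nFramesUsed = "integer", divisor = "character"))

setValidity("CovarianceResult", function(object) {
    m <- object@matrix
    if (nrow(m) != ncol(m)) return("covariance matrix must be square")
    if (nrow(m) %% 3L != 0L) return("covariance dimension must be 3N")
    if (nrow(object@meanStructure) * 3L != nrow(m))
        return("mean structure size inconsistent with covariance dimension")
    asym <- max(abs(m - t(m)))
    if (asym > 1e-10 * max(1, max(abs(m))))
        return(sprintf("covariance asymmetric (max |C - t(C)| = %g)", asym))
    TRUE
})

#' EssentialSpace: eigen-decomposition and atom images
#'
#' Holds the eigen-decomposition of a fluctuation covariance matrix, the
#' number `m` of retained essential collective coordinates, and the `N x m`
#' matrix of dimensionless atom images. Component `k` of atom `i`'s image is
#' the Euclidean norm of eigenvector `k`'s 3-entry block for atom `i`
#' (optionally eigenvalue-weighted); Euclidean distances between image rows
#' are the ECD pair-correlation descriptors.
#'
#' @slot eigenvalues numeric, length 3N, non-increasing (angstrom^2).
#' @slot eigenvectors numeric `3N x 3N` orthonormal columns.
#' @slot m integer(1), retained essential coordinates.
#' @slot varianceFraction numeric(1) in `[0, 1]`, displacement fraction
#'   sampled by the first `m` eigenvectors.
#' @slot images numeric `N x m` atom-image matrix (dimensionless).
#' @slot weighting character(1), `"none"` or `"eigenvalue"`.
#' @slot atoms data.frame, atom table rows for the analyzed selection.
#'
#' @exportClass EssentialSpace
setClass("EssentialSpace",
    representation(eigenvalues = "numeric", eigenvectors = "matrix",
                   m = "integer", varianceFraction = "numeric",
                   images = "matrix", weighting = "character",
                   atoms = "data.frame"))

setValidity("EssentialSpace", function(object) {
    n3 <- length(object@eigenvalues)
    if (any(diff(object@eigenvalues) > 1e-8 * max(1, abs(object@eigenvalues[1]))))
        return("eigenvalues must be non-increasing")
    if (object@m < 1L || object@m > n3)
        return("'m' out of range")
    if (ncol(object@images) != object@m)
        return("image matrix must have m columns")
    if (nrow(object@images) * 3L != n3)
        return("image matrix must have N rows")
    if (object@varianceFraction < 0 || object@varianceFraction > 1 + 1e-12)
        return("'varianceFraction' outside [0, 1]")
    TRUE
})

#' CorrelationMap: segment-averaged ECD pair-correlation descriptors
#'
#' Matrix of dimensionless distances d_ij between atom images, averaged over
#' trajectory segments. Low values indicate strongly correlated motion.
#'
#' @slot values numeric matrix of segment-averaged d_ij, rows/cols named
#'   `chain:resid:atom`.
#' @slot sdValues numeric matrix, across-segment standard deviation of d_ij.
#' @slot rowAtoms,colAtoms data.frame, atom table rows for the two selections.
#' @slot rowLabel,colLabel character(1), selection labels.
#' @slot nSegmentsAveraged integer(1).
#' @slot mUsed integer, per-segment essential-coordinate counts.
#'
#' @exportClass CorrelationMap
setClass("CorrelationMap",
    representation(values = "matrix", sdValues = "matrix",
                   rowAtoms = "data.frame", colAtoms = "data.frame",
                   rowLabel = "character", colLabel = "character",
                   nSegmentsAveraged = "integer", mUsed = "integer"))

setValidity("CorrelationMap", function(object) {
    if (any(object@values < -1e-12))
        return("correlation descriptors must be non-negative")
    if (!identical(dim(object@values), dim(object@sdValues)))
        return("'values' and 'sdValues' dimensions differ")
    TRUE
})

#' FlexibilityProfile: per-residue ECD flexibility with uncertainties
#'
#' The flexibility descriptor of a C-alpha atom is the distance, in the
#' m-dimensional essential space, between its image and the centroid of all
#' C-alpha images; `meanFlex`/`sdFlex` are its mean and standard deviation
#' across trajectory segments.
#'
#' @slot residues data.frame with columns `chain`, `resid`, `resname`.
#' @slot meanFlex numeric, dimensionless, one per residue.
#' @slot sdFlex numeric, across-segment SD (0 for a single segment).
#' @slot nSegments integer(1).
#' @slot nCalpha integer(1), number of C-alpha atoms entering the centroid.
#'
#' @exportClass FlexibilityProfile
setClass("FlexibilityProfile",
    representation(residues = "data.frame", meanFlex = "numeric",
                   sdFlex = "numeric", nSegments = "integer",
                   nCalpha = "integer"))

setValidity("FlexibilityProfile", function(object) {
    n <- nrow(object@residues)
    if (length(object@meanFlex) != n || length(object@sdFlex) != n)
        return("profile vectors and residue table differ in length")
    if (any(object@meanFlex < -1e-12))
        return("flexibility must be non-negative")
    TRUE
})

#' BFactorProfile: per-residue crystallographic B-factors
#'
#' @slot residues data.frame with columns `chain`, `resid`, `resname`.
#' @slot value numeric, B-factor per residue (angstrom^2).
#' @slot aggregation character(1), `"CA"` or `"backbone"`.
#'
#' @exportClass BFactorProfile
setClass("BFactorProfile",
    representation(residues = "data.frame", value = "numeric",
                   aggregation = "character"))

setValidity("BFactorProfile", function(object) {
    if (length(object@value) != nrow(object@residues))
        return("one B-factor per residue required")
    if (any(object@value < 0, na.rm = TRUE))
        return("B-factors must be non-negative")
    TRUE
})

#' DomainPartition: dynamic domains of correlated motion
#'
#' Disjoint atom clusters obtained by nearest-neighbor (single-linkage)
#' clustering of the protein's image at interdomain distance `threshold`;
#' components below the size floor are reported as `unassigned`.
#'
#' @slot threshold numeric(1), interdomain distance d_c (dimensionless).
#' @slot domains list of integer vectors (1-based indices into the analyzed
#'   atom set), ordered by decreasing size.
#' @slot unassigned integer vector, atoms in components smaller than the
#'   domain-size floor.
#' @slot largestFraction numeric(1), fraction of analyzed atoms in the
#'   largest domain (0 when no domain passes the floor).
#' @slot nAtoms integer(1), number of analyzed atoms.
#'
#' @exportClass DomainPartition
setClass("DomainPartition",
    representation(threshold = "numeric", domains = "list",
                   unassigned = "integer", largestFraction = "numeric",
                   nAtoms = "integer"))

setValidity("DomainPartition", function(object) {
    if (object@threshold <= 0) return("'threshold' must be positive")
    all_idx <- c(unlist(object@domains), object@unassigned)
    if (length(all_idx) != object@nAtoms ||
        !setequal(all_idx, seq_len(object@nAtoms)) ||
        anyDuplicated(all_idx))
        return("domains plus unassigned must partition the atom set")
    sz <- vapply(object@domains, length, integer(1))
    if (length(sz) > 1L && any(diff(sz) > 0L))
        return("domains must be ordered by non-increasing size")
    TRUE
})

#' ENMSpec: elastic-network Langevin simulation specification
#'
#' Defines a harmonic-spring network over `N` atoms together with the
#' overdamped-Langevin integration parameters used by
#' [generateENMTrajectory()]. The equilibrium covariance of the network is
#' known analytically ([analyticCovariance()]), which makes trajectories
#' generated from a spec a ground truth for the analysis pipeline.
#'
#' @slot positions0 numeric `N x 3`, equilibrium coordinates (angstroms).
#' @slot springs data.frame with columns `i`, `j` (1-based atom indices) and
#'   `k` (force constant, kcal mol^-1 A^-2).
#' @slot temperature numeric(1), K.
#' @slot friction numeric(1), ps^-1.
#' @slot dt numeric(1), ps.
#' @slot nFrames integer(1), frames to record.
#' @slot stride integer(1), integration steps between recorded frames.
#' @slot burnIn integer(1), equilibration steps before recording (`NA` =
#'   auto: 10x the slowest relaxation time).
#' @slot seed integer(1), RNG seed (mandatory).
#' @slot blockLabels character, per-atom ground-truth labels (block id,
#'   `"hinge"`, ...).
#' @slot atoms data.frame, synthesized atom table (one CA per "residue") so
#'   generated trajectories run through the full pipeline.
#'
#' @exportClass ENMSpec
setClass("ENMSpec",
    representation(positions0 = "matrix", springs = "data.frame",
                   temperature = "numeric", friction = "numeric",
                   dt = "numeric", nFrames = "integer", stride = "integer",
                   burnIn = "integer", seed = "integer",
                   blockLabels = "character", atoms = "data.frame"))

setValidity("ENMSpec", function(object) {
    n <- nrow(object@positions0)
    if (ncol(object@positions0) != 3L)
        return("'positions0' must be N x 3")
    s <- object@springs
    if (!all(c("i", "j", "k") %in% names(s)))
        return("'springs' needs columns i, j, k")
    if (nrow(s) == 0L) return("spring network is empty")
    if (any(s$i < 1 | s$i > n | s$j < 1 | s$j > n))
        return("spring endpoints reference invalid atoms")
    if (any(s$i == s$j)) return("self-springs are not allowed")
    if (any(s$k <= 0)) return("force constants must be positive")
    if (is.na(object@seed)) return("'seed' is mandatory")
    if (object@temperature < 0) return("'temperature' must be >= 0")
    if (object@friction <= 0 || object@dt <= 0)
        return("'friction' and 'dt' must be positive")
    if (length(object@blockLabels) != n)
        return("one block label per atom required")
    # overdamped Euler stability: dt * lambda_max / gamma < 2, with
    # lambda_max the largest eigenvalue of the spring Laplacian
    L <- matrix(0, n, n)
    for (row in seq_len(nrow(s))) {
        i <- s$i[row]; j <- s$j[row]; k <- s$k[row]
        L[i, j] <- L[i, j] - k; L[j, i] <- L[j, i] - k
        L[i, i] <- L[i, i] + k; L[j, j] <- L[j, j] + k
    }
    lmax <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
    if (object@dt * lmax / object@friction >= 2)
        return(sprintf(
            "unstable integration: dt * lambda_max / friction >= 2 (lambda_max = %g requires dt < %g ps)",
            lmax, 2 * object@friction / lmax))
    TRUE
})
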