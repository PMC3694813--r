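#' Cartesian fluctuation covariance of a trajectory segment
#'
#' Computes `C = <dx dx^T>` over frames, with `dx = x - <x>` the displacement
#' from the segment-mean structure and coordinates ordered
#' (atom1.x, atom1.y, atom1.z, atom2.x, ...). The segment is expected to be
#' superposed already (see [superposeFrames()]); otherwise rigid-body motion
#' dominates the leading eigenvectors.
#'
#' @param segment a [Trajectory-class] with >= 2 frames.
#' @param sel optional [AtomSelection-class] restricting the analysis.
#' @param divisor `"population"` (1/n, default) or `"sample"` (1/(n-1)).
#' @return a [CovarianceResult-class]
#' @export
computeCovariance <- function(segment, sel = NULL,
                              divisor = c("population", "sample")) {
    divisor <- match.arg(divisor)
    nF <- nFrames(segment)
    if (nF < 2L) stop("need at least 2 frames for a covariance")
    idx <- .resolveIndices(sel, nAtoms(segment))
    X <- .xyzFromTrajectory(segment)
    cols <- as.vector(rbind(3L * (idx - 1L) + 1L, 3L * (idx - 1L) + 2L,
                            3L * idx))
    X <- X[, cols, drop = FALSE]
    if (!all(is.finite(X))) stop("non-finite coordinates in segment")
    mu <- colMeans(X)
    D <- sweep(X, 2, mu)
    denom <- if (divisor == "population") nF else nF - 1L
    C <- crossprod(D) / denom
    C <- (C + t(C)) / 2
    new("CovarianceResult", matrix = C,
        meanStructure = matrix(mu, ncol = 3L, byrow = TRUE),
        nFramesUsed = as.integer(nF), divisor = divisor)
}

#' Essential collective coordinates of a fluctuation covariance
#'
#' Diagonalizes the covariance matrix and retains the leading `m`
#' eigenvectors (essential collective coordinates): the smallest `m` whose
#' cumulative eigenvalue fraction reaches `fraction` (default 0.90, the
#' conventional displacement coverage, typically met by 10-30 coordinates
#' for a protein), or a fixed count `fixedM`. Atom images are built from the
#' retained eigenvectors with [buildImages()].
#'
#' @param cov a [CovarianceResult-class] (or a symmetric PSD matrix with an
#'   optional `atoms` attribute).
#' @param fraction target displacement fraction in (0, 1].
#' @param fixedM retain exactly this many coordinates (overrides `fraction`).
#' @param weighting image mode weights: `"none"` (default, unit weights) or
#'   `"eigenvalue"` (`w_k = sqrt(lambda_k / lambda_1)`).
#' @param atoms optional atom table carried into the result.
#' @return an [EssentialSpace-class]
#' @export
essentialSpace <- function(cov, fraction = 0.90, fixedM = NULL,
                           weighting = c("none", "eigenvalue"),
                           atoms = NULL) {
    weighting <- match.arg(weighting)
    if (is(cov, "CovarianceResult")) {
        C <- cov@matrix
    } else {
        C <- as.matrix(cov)
        if (max(abs(C - t(C))) > 1e-10 * max(1, max(abs(C))))
            stop("covariance matrix is not symmetric")
    }
    n3 <- nrow(C)
    if (n3 %% 3L != 0L) stop("covariance dimension must be 3N")
    eg <- eigen(C, symmetric = TRUE)
    ev <- eg$values
    tr <- sum(ev)
    if (tr <= 0) stop("zero total variance: covariance has no fluctuations")
    if (min(ev) < -1e-8 * tr)
        stop(sprintf("covariance is not positive semi-definite (min eigenvalue %g)",
                     min(ev)))
    ev <- pmax(ev, 0)
    if (!is.null(fixedM)) {
        m <- as.integer(fixedM)
        if (m < 1L || m > n3) stop("'fixedM' out of [1, 3N]")
    } else {
        if (!(fraction > 0 && fraction <= 1))
            stop("'fraction' must be in (0, 1]")
        cum <- cumsum(ev) / tr
        m <- which(cum >= fraction - 1e-12)[1]
    }
    w <- if (weighting == "eigenvalue") sqrt(ev[seq_len(m)] / ev[1]) else NULL
    img <- buildImages(eg$vectors, m, weights = w)
    if (is.null(atoms) && is(cov, "CovarianceResult"))
        atoms <- .syntheticAtomTable(n3 %/% 3L)
    if (is.null(atoms)) atoms <- .syntheticAtomTable(n3 %/% 3L)
    new("EssentialSpace", eigenvalues = ev, eigenvectors = eg$vectors,
        m = as.integer(m), varianceFraction = sum(ev[seq_len(m)]) / tr,
        images = img, weighting = weighting, atoms = atoms)
}

#' Atom images in the space of essential collective coordinates
#'
#' Component `k` of atom `i`'s image is the Euclidean norm of eigenvector
#' `k`'s 3-entry block for atom `i` — the magnitude of the atom's direction
#' cosines along that collective coordinate. The construction is invariant to
#' global sign flips of eigenvectors. Atoms whose motions are strongly
#' correlated map to nearby image points.
#'
#' @param eigenvectors `3N x >=m` matrix of orthonormal eigenvector columns.
#' @param m number of essential coordinates to use.
#' @param weights optional length-`m` positive mode weights (default all 1).
#' @return `N x m` image matrix (dimensionless)
#' @export
buildImages <- function(eigenvectors, m, weights = NULL) {
    m <- as.integer(m)
    if (m < 1L || m > ncol(eigenvectors)) stop("'m' out of range")
    n3 <- nrow(eigenvectors)
    if (n3 %% 3L != 0L) stop("eigenvector length must be 3N")
    N <- n3 %/% 3L
    V <- eigenvectors[, seq_len(m), drop = FALSE]
    ix <- 3L * (seq_len(N) - 1L)
    img <- sqrt(V[ix + 1L, , drop = FALSE]^2 + V[ix + 2L, , drop = FALSE]^2 +
                V[ix + 3L, , drop = FALSE]^2)
    if (!is.null(weights)) {
        if (length(weights) != m || any(weights < 0))
            stop("'weights' must be m non-negative values")
        img <- sweep(img, 2, weights, "*")
    }
    img
}

#' Pair-correlation descriptor between two atoms
#'
#' The dimensionless Euclidean distance between the image points of atoms
#' `i` and `j` in the m-dimensional essential space; lower values indicate
#' more strongly correlated motion.
#'
#' @param space an [EssentialSpace-class]
#' @param i,j 1-based atom indices into the analyzed selection.
#' @return non-negative numeric(1)
#' @export
pairDistance <- function(space, i, j) {
    img <- space@images
    n <- nrow(img)
    if (any(c(i, j) < 1L) || any(c(i, j) > n))
        stop("atom index out of range [1, ", n, "]")
    sqrt(sum((img[i, ] - img[j, ])^2))
}

# full rows x cols distance matrix between image rows; self-pairs are
# exactly zero (the quadratic expansion would leave ~1e-8 cancellation noise)
.imageDistances <- function(img, rows = NULL, cols = NULL) {
    if (is.null(rows)) rows <- seq_len(nrow(img))
    if (is.null(cols)) cols <- seq_len(nrow(img))
    A <- img[rows, , drop = FALSE]
    B <- img[cols, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
          outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
    D <- sqrt(pmax(d2, 0))
    same <- which(outer(rows, cols, "==") , arr.ind = TRUE)
    if (nrow(same)) D[same] <- 0
    D
}

#' Segment-averaged ECD correlation map
#'
#' For every segment of the ensemble: superpose on the union of the two
#' selections, compute the fluctuation covariance, build the essential space,
#' and evaluate the pair descriptor d_ij for each (row, col) atom pair. The
#' returned map is the arithmetic mean across segments (with the
#' across-segment SD retained), mirroring the per-segment averaging that
#' gives the descriptors their uncertainties.
#'
#' @param ensemble a [SegmentEnsemble-class]
#' @param selRows,selCols [AtomSelection-class] row/column selections
#'   (typically C-alpha atoms of one or two molecules).
#' @param fraction,fixedM,weighting passed to [essentialSpace()].
#' @param superpose superpose each segment on the union selection first
#'   (default TRUE; disable only for pre-aligned input).
#' @return a [CorrelationMap-class]
#' @export
correlationMap <- function(ensemble, selRows, selCols = selRows,
                           fraction = 0.90, fixedM = NULL,
                           weighting = c("none", "eigenvalue"),
                           superpose = TRUE) {
    weighting <- match.arg(weighting)
    stopifnot(is(ensemble, "SegmentEnsemble"))
    nA <- nAtoms(ensemble)
    ri <- .resolveIndices(selRows, nA)
    ci <- .resolveIndices(selCols, nA)
    uni <- sort(unique(c(ri, ci)))
    rpos <- match(ri, uni); cpos <- match(ci, uni)
    segs <- ensemble@segments
    perSeg <- vector("list", length(segs))
    ms <- integer(length(segs))
    for (s in seq_along(segs)) {
        perSeg[[s]] <- tryCatch({
            seg <- segs[[s]]
            if (superpose) seg <- superposeFrames(seg, uni)
            cv <- computeCovariance(seg, uni)
            es <- essentialSpace(cv, fraction = fraction, fixedM = fixedM,
                                 weighting = weighting)
            ms[s] <- es@m
            .imageDistances(es@images, rpos, cpos)
        }, error = function(e)
            stop("correlationMap failed on segment ", s, ": ",
                 conditionMessage(e)))
    }
    ns <- length(segs)
    mean_d <- Reduce(`+`, perSeg) / ns
    sd_d <- if (ns > 1L) {
        sqrt(Reduce(`+`, lapply(perSeg, function(D) (D - mean_d)^2)) /
             (ns - 1L))
    } else mean_d * 0
    atoms <- atomTable(ensemble)
    rowAtoms <- atoms[ri, , drop = FALSE]
    colAtoms <- atoms[ci, , drop = FALSE]
    dimnames(mean_d) <- dimnames(sd_d) <-
        list(.atomLabels(rowAtoms), .atomLabels(colAtoms))
    if (identical(ri, ci)) {
        diag(mean_d) <- 0
        mean_d <- (mean_d + t(mean_d)) / 2
    }
    rlab <- if (is(selRows, "AtomSelection")) selRows@label else "rows"
    clab <- if (is(selCols, "AtomSelection")) selCols@label else "cols"
    .logInfo("correlation map %d x %d over %d segment(s); m in [%d, %d]",
             length(ri), length(ci), ns, min(ms), max(ms))
    new("CorrelationMap", values = mean_d, sdValues = sd_d,
        rowAtoms = rowAtoms, colAtoms = colAtoms, rowLabel = rlab,
        colLabel = clab, nSegmentsAveraged = as.integer(ns), mUsed = ms)
}

#' Write a correlation map as TSV with a JSON sidecar
#'
#' The TSV holds the segment-averaged d_ij matrix with `chain:resid:atom`
#' row/column headers; the sidecar records the selections, per-segment
#' essential-coordinate counts and segment count.
#'
#' @param map a [CorrelationMap-class]
#' @param path output TSV path (sidecar written as `<path>.json`).
#' @return `path`, invisibly
#' @export
writeCorrelationMap <- function(map, path) {
    df <- as.data.frame(map@values)
    utils::write.table(cbind(atom = rownames(map@values), df), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- list(rows = map@rowLabel, cols = map@colLabel,
                 n_segments = map@nSegmentsAveraged,
                 m_per_segment = map@mUsed)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}
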