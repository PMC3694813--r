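# distance matrix from an EssentialSpace or a precomputed matrix, optionally
# restricted to a selection
.domainDistances <- function(x, sel = NULL) {
    if (is(x, "EssentialSpace")) {
        idx <- .resolveIndices(sel, nrow(x@images))
        .imageDistances(x@images[idx, , drop = FALSE])
    } else if (is(x, "CorrelationMap")) {
        if (!identical(rownames(x@values), colnames(x@values)))
            stop("domain clustering needs a square intra-molecular map")
        D <- x@values
        idx <- .resolveIndices(sel, nrow(D))
        D[idx, idx, drop = FALSE]
    } else {
        D <- as.matrix(x)
        if (nrow(D) != ncol(D)) stop("distance matrix must be square")
        idx <- .resolveIndices(sel, nrow(D))
        D[idx, idx, drop = FALSE]
    }
}

#' Dynamic domains by nearest-neighbor clustering of atom images
#'
#' Atoms are joined whenever their pair descriptor d_ij does not exceed the
#' interdomain distance `threshold`; the connected components of that graph
#' (single-linkage clusters) are the dynamic domains of correlated motion.
#' Components smaller than `minDomainSize` are reported as unassigned.
#'
#' @param x an [EssentialSpace-class], a [CorrelationMap-class] (square,
#'   segment-averaged), or a square distance matrix.
#' @param threshold interdomain distance d_c (> 0, dimensionless); atoms with
#'   `d_ij <= threshold` share a domain.
#' @param minDomainSize smallest atom count accepted as a domain (default 3;
#'   one- or two-atom "domains" are noise).
#' @param sel optional selection restricting the analyzed atoms.
#' @return a [DomainPartition-class]; domains are sorted by decreasing size,
#'   ties broken by smallest member index.
#' @export
clusterDomains <- function(x, threshold, minDomainSize = 3L, sel = NULL) {
    if (threshold <= 0) stop("'threshold' must be positive")
    minDomainSize <- as.integer(minDomainSize)
    if (minDomainSize < 1L) stop("'minDomainSize' must be >= 1")
    D <- .domainDistances(x, sel)
    n <- nrow(D)
    adj <- (D <= threshold)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    groups <- split(seq_len(n), comp)
    sizes <- vapply(groups, length, integer(1))
    firsts <- vapply(groups, min, integer(1))
    ord <- order(-sizes, firsts)
    groups <- groups[ord]; sizes <- sizes[ord]
    keep <- sizes >= minDomainSize
    domains <- unname(lapply(groups[keep], as.integer))
    unassigned <- as.integer(sort(unlist(groups[!keep])))
    lf <- if (length(domains)) length(domains[[1]]) / n else 0
    new("DomainPartition", threshold = threshold, domains = domains,
        unassigned = unassigned, largestFraction = lf,
        nAtoms = as.integer(n))
}

#' Select the interdomain distance over a threshold grid
#'
#' Scans candidate thresholds and, among those whose largest domain holds
#' more than `minLargestFraction` of the atoms, picks the one maximizing the
#' number of domains and then the number of atoms outside the largest domain
#' (total atoms in domains minus largest-domain size); remaining ties go to
#' the smallest threshold. The full diagnostics table is returned so other
#' selection rules can be applied.
#'
#' @param x as in [clusterDomains()].
#' @param grid numeric vector of candidate thresholds (> 0); `NULL`
#'   (default) uses 30 log-spaced values from the 2nd percentile of the
#'   positive pair distances to their maximum.
#' @param minLargestFraction feasibility floor on the largest domain's atom
#'   fraction (default 0.10).
#' @param minDomainSize passed to [clusterDomains()].
#' @param sel optional selection restricting the analyzed atoms.
#' @return list with `threshold` (selected value), `diagnostics` (data.frame
#'   over the grid: n_domains, in_domains, largest, spread = in_domains -
#'   largest, largest_fraction, feasible), and `degenerate` (TRUE when every
#'   grid point yields a single all-atom domain).
#' @export
selectThreshold <- function(x, grid = NULL, minLargestFraction = 0.10,
                            minDomainSize = 3L, sel = NULL) {
    D <- .domainDistances(x, sel)
    if (is.null(grid)) {
        pos <- D[upper.tri(D)]
        pos <- pos[pos > 0]
        if (length(pos) == 0L)
            stop("all pair distances are zero; supply an explicit grid")
        grid <- 10^seq(log10(stats::quantile(pos, 0.02)), log10(max(pos)),
                       length.out = 30)
    }
    grid <- sort(unique(as.numeric(grid)))
    if (length(grid) == 0L || any(grid <= 0))
        stop("'grid' must be non-empty positive thresholds")
    rows <- lapply(grid, function(t) {
        p <- clusterDomains(D, threshold = t, minDomainSize = minDomainSize)
        sizes <- vapply(p@domains, length, integer(1))
        tot <- sum(sizes)
        largest <- if (length(sizes)) sizes[1] else 0L
        data.frame(threshold = t, n_domains = length(sizes),
                   in_domains = tot, largest = largest,
                   spread = tot - largest,
                   largest_fraction = p@largestFraction)
    })
    diag_ <- do.call(rbind, rows)
    diag_$feasible <- diag_$largest_fraction > minLargestFraction
    degenerate <- all(diag_$n_domains == 1L &
                      diag_$largest_fraction >= 1 - 1e-12)
    if (!any(diag_$feasible)) {
        stop("no feasible threshold (largest_fraction <= ",
             minLargestFraction, " everywhere); diagnostics:\n",
             paste(utils::capture.output(print(diag_)), collapse = "\n"))
    }
    feas <- diag_[diag_$feasible, , drop = FALSE]
    best <- feas[order(-feas$n_domains, -feas$spread, feas$threshold), ,
                 drop = FALSE][1, ]
    if (degenerate)
        .logWarn("all images coincident at every grid point; returning smallest threshold")
    .logInfo("selected d_c = %g (%d domains, spread %d, largest fraction %.2f)",
             best$threshold, best$n_domains, best$spread,
             best$largest_fraction)
    list(threshold = best$threshold, diagnostics = diag_,
         degenerate = degenerate)
}

#' Residue-range summary of the largest dynamic domains
#'
#' @param p a [DomainPartition-class]
#' @param atoms atom table aligned with the analyzed atom set (data.frame
#'   with `chain`, `resid`).
#' @param k report at most this many largest domains (default 6).
#' @return data.frame with columns `rank`, `size`, `fraction`, `ranges`
#'   (contiguous author-numbered residue ranges per chain, e.g.
#'   `"A:10-20 (11 residues)"`).
#' @export
domainSummary <- function(p, atoms, k = 6L) {
    stopifnot(is(p, "DomainPartition"))
    if (nrow(atoms) != p@nAtoms)
        stop("atom table does not match the partitioned atom set")
    kk <- min(as.integer(k), length(p@domains))
    out <- vector("list", kk)
    for (r in seq_len(kk)) {
        idx <- p@domains[[r]]
        sub <- atoms[idx, , drop = FALSE]
        parts <- character(0)
        for (ch in unique(sub$chain)) {
            resids <- sort(unique(sub$resid[sub$chain == ch]))
            brk <- c(0L, which(diff(resids) != 1L), length(resids))
            for (b in seq_len(length(brk) - 1L)) {
                lo <- resids[brk[b] + 1L]; hi <- resids[brk[b + 1L]]
                parts <- c(parts, if (lo == hi)
                    sprintf("%s:%d (1 residue)", ch, lo)
                else sprintf("%s:%d-%d (%d residues)", ch, lo, hi,
                             hi - lo + 1L))
            }
        }
        out[[r]] <- data.frame(rank = r, size = length(idx),
                               fraction = length(idx) / p@nAtoms,
                               ranges = paste(parts, collapse = ", "))
    }
    do.call(rbind, out)
}

#' Write a domain partition as TSV (plus JSON summary)
#'
#' One row per analyzed atom: chain, resid, atom name and the rank of its
#' domain (`NA` for unassigned atoms). A JSON summary with threshold and
#' per-domain sizes is written alongside. `writeDomainPDB` stores the domain
#' rank in the B-factor column of a PDB copy for structure-viewer coloring.
#'
#' @param p a [DomainPartition-class]
#' @param atoms atom table aligned with the analyzed atoms.
#' @param path output TSV path (summary at `<path>.json`).
#' @return `path`, invisibly
#' @export
writeDomainPartition <- function(p, atoms, path) {
    lab <- domainLabels(p)
    df <- data.frame(chain = atoms$chain, resid = atoms$resid,
                     atom = atoms$name, domain_rank = lab)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    meta <- list(threshold = p@threshold,
                 sizes = vapply(p@domains, length, integer(1)),
                 unassigned = length(p@unassigned),
                 largest_fraction = p@largestFraction)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeDomainPartition
#' @param structure one-frame [Trajectory-class] whose atoms match the
#'   partitioned set.
#' @export
writeDomainPDB <- function(p, structure, path) {
    if (nAtoms(structure) != p@nAtoms)
        stop("structure does not match the partitioned atom set")
    lab <- domainLabels(p)
    at <- structure@atoms
    at$bfactor <- ifelse(is.na(lab), 0, lab)
    writePDB(initialize(structure, atoms = at), path)
}
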