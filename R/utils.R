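.logInfo <- function(fmt, ...) message(sprintf(paste0("INFO  [ecdyn] ", fmt), ...))
.logWarn <- function(fmt, ...) message(sprintf(paste0("WARN  [ecdyn] ", fmt), ...))

# run expr with a local RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# frame i of a trajectory as an N x 3 matrix
.frame <- function(traj, i) {
    matrix(traj@coords[i, , ], ncol = 3L,
           dimnames = list(NULL, c("x", "y", "z")))
}

.atomLabels <- function(atoms) {
    paste(atoms$chain, atoms$resid, atoms$name, sep = ":")
}

.resolveIndices <- function(sel, n) {
    if (is(sel, "AtomSelection")) {
        if (sel@nAtomsSource != n)
            stop("selection was made on a trajectory with a different atom count")
        sel@indices
    } else if (is.numeric(sel)) {
        idx <- as.integer(sel)
        if (any(idx < 1L | idx > n)) stop("atom indices out of range")
        idx
    } else if (is.null(sel)) {
        seq_len(n)
    } else stop("'sel' must be an AtomSelection, integer indices, or NULL")
}

# synthetic one-CA-per-residue atom table used by text fixtures and the
# elastic-network generator
.syntheticAtomTable <- function(n, chain = "A", resname = "ALA") {
    data.frame(chain = rep(chain, n), resid = seq_len(n),
               resname = rep(resname, n), name = rep("CA", n),
               elem = rep("C", n), bfactor = rep(NA_real_, n),
               stringsAsFactors = FALSE)
}
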