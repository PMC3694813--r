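# ---- text fixture builders -------------------------------------------------

# fixed-column PDB ATOM line
pdbLine <- function(serial, name, resname, chain, resid, x, y, z, b = 0,
                    elem = NULL) {
    if (is.null(elem))
        elem <- toupper(substr(gsub("[0-9]", "", name), 1, 1))
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
            resname, chain, resid, x, y, z, 1.00, b, elem)
}

# write a small multi-model PDB; coords: list of N x 3 matrices (one/model)
writeToyPDB <- function(path, atoms, coords) {
    lines <- character(0)
    for (m in seq_along(coords)) {
        lines <- c(lines, sprintf("MODEL     %4d", m))
        co <- coords[[m]]
        for (i in seq_len(nrow(atoms))) {
            lines <- c(lines, pdbLine(i, atoms$name[i], atoms$resname[i],
                                      atoms$chain[i], atoms$resid[i],
                                      co[i, 1], co[i, 2], co[i, 3],
                                      b = atoms$bfactor[i],
                                      elem = atoms$elem[i]))
        }
        lines <- c(lines, "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
    path
}

# standard 3-residue backbone atom table (N, CA, C per residue)
toyBackboneAtoms <- function(nres = 3, chain = "A", startRes = 1) {
    data.frame(
        chain = chain,
        resid = rep(startRes + seq_len(nres) - 1L, each = 3L),
        resname = "ALA",
        name = rep(c("N", "CA", "C"), nres),
        elem = rep(c("N", "C", "C"), nres),
        bfactor = seq_len(3L * nres),
        stringsAsFactors = FALSE)
}

toyTrajectory <- function(coordsList, atoms = NULL) {
    nA <- nrow(coordsList[[1]])
    if (is.null(atoms)) {
        atoms <- data.frame(chain = "A", resid = seq_len(nA),
                            resname = "ALA", name = "CA", elem = "C",
                            bfactor = NA_real_, stringsAsFactors = FALSE)
    }
    co <- array(0, dim = c(length(coordsList), nA, 3L))
    for (f in seq_along(coordsList)) co[f, , ] <- coordsList[[f]]
    new("Trajectory", coords = co, atoms = atoms)
}

randomRotation <- function() {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
}

# ---- independent oracles ---------------------------------------------------

# cyclic Jacobi eigensolver for symmetric matrices (independent of LAPACK)
jacobiEigen <- function(A, tol = 1e-12, maxSweeps = 100) {
    A <- as.matrix(A)
    n <- nrow(A)
    V <- diag(n)
    for (sweep in seq_len(maxSweeps)) {
        off <- sqrt(sum(A[upper.tri(A)]^2))
        if (off < tol * max(1, sqrt(sum(diag(A)^2)))) break
        for (p in 1:(n - 1)) for (q in (p + 1):n) {
            if (abs(A[p, q]) < 1e-300) next
            theta <- (A[q, q] - A[p, p]) / (2 * A[p, q])
            t <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
            if (theta == 0) t <- 1
            cth <- 1 / sqrt(t^2 + 1); sth <- t * cth
            G <- diag(n); G[p, p] <- cth; G[q, q] <- cth
            G[p, q] <- sth; G[q, p] <- -sth
            A <- t(G) %*% A %*% G
            V <- V %*% G
        }
    }
    ord <- order(diag(A), decreasing = TRUE)
    list(values = diag(A)[ord], vectors = V[, ord, drop = FALSE])
}

# brute-force connected components of d <= threshold (transitive closure)
bruteComponents <- function(D, threshold) {
    n <- nrow(D)
    adj <- D <= threshold
    diag(adj) <- TRUE
    reach <- adj
    repeat {
        nxt <- (reach %*% reach) > 0
        if (identical(nxt, reach)) break
        reach <- nxt
    }
    comp <- integer(n)
    cid <- 0L
    for (i in seq_len(n)) {
        if (comp[i] == 0L) {
            cid <- cid + 1L
            comp[reach[i, ]] <- cid
        }
    }
    comp
}

# brute-force all-pairs contact scan mirroring the classification rules
bruteContacts <- function(structure, ia, ib,
                          cutoffs = c(hbond = 4, polar = 3.5,
                                      nonpolar = 4.5, neighbor = 5)) {
    co <- coords(structure)[1, , ]
    at <- atomTable(structure)
    heavy <- toupper(at$elem) != "H"
    ia <- ia[heavy[ia]]; ib <- ib[heavy[ib]]
    out <- list()
    for (i in ia) for (j in ib) {
        d <- sqrt(sum((co[i, ] - co[j, ])^2))
        if (d > cutoffs[["neighbor"]]) next
        key <- paste(at$chain[i], at$resid[i], at$chain[j], at$resid[j],
                     sep = ":")
        rec <- out[[key]]
        if (is.null(rec))
            rec <- list(min_d = Inf, polar = FALSE, hbond = FALSE,
                        nonpolar = FALSE)
        ei <- toupper(at$elem[i]); ej <- toupper(at$elem[j])
        if (ei %in% c("N", "O", "S") && ej %in% c("N", "O", "S") &&
            d <= cutoffs[["polar"]]) rec$polar <- TRUE
        if (ei %in% c("N", "O") && ej %in% c("N", "O") &&
            d <= cutoffs[["hbond"]]) rec$hbond <- TRUE
        if (ei == "C" && ej == "C" && d <= cutoffs[["nonpolar"]])
            rec$nonpolar <- TRUE
        rec$min_d <- min(rec$min_d, d)
        out[[key]] <- rec
    }
    out
}

# adjusted Rand index between two label vectors (mclust)
ariOf <- function(a, b) mclust::adjustedRandIndex(a, b)

# ---- shared expensive fixtures (built once per test run) -------------------

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
    if (!exists(key, envir = .fixtureCache)) {
        assign(key, builder(), envir = .fixtureCache)
    }
    get(key, envir = .fixtureCache)
}

blockFixture <- function(seed = 1) {
    cached(paste0("block", seed), function() {
        spec <- makeBlockSystem(2, seed = seed)
        traj <- suppressMessages(generateENMTrajectory(spec))
        list(spec = spec, traj = traj)
    })
}
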