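test_that("multi-model PDB files parse into frames with B-factors", {
    at <- toyBackboneAtoms(1)[1:3, ]
    co <- list(matrix(c(0, 0, 0, 1.5, 0, 0, 3, 0, 0), 3, 3, byrow = TRUE),
               matrix(c(0, 1, 0, 1.5, 1, 0, 3, 1, 0), 3, 3, byrow = TRUE))
    f <- withr::local_tempfile(fileext = ".pdb")
    writeToyPDB(f, at, co)
    traj <- suppressMessages(readPDB(f))
    expect_equal(nFrames(traj), 2L)
    expect_equal(nAtoms(traj), 3L)
    expect_equal(atomTable(traj)$bfactor, c(1, 2, 3))
    expect_equal(coords(traj)[1, 2, ], c(1.5, 0, 0), tolerance = 1e-6)

    first <- suppressMessages(readPDB(f, modelPolicy = "first"))
    expect_equal(nFrames(first), 1L)
})

test_that("B-factor column parses at fixed positions", {
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(c(pdbLine(1, "CA", "ALA", "A", 1, 1, 2, 3, b = 12.34), "END"),
               f)
    traj <- suppressMessages(readPDB(f))
    expect_equal(atomTable(traj)$bfactor, 12.34)
})

test_that("malformed ATOM records are reported with their line number", {
    f <- withr::local_tempfile(fileext = ".pdb")
    good <- pdbLine(1, "CA", "ALA", "A", 1, 1, 2, 3)
    bad <- good
    substr(bad, 31, 38) <- "  xx.yyy"
    writeLines(c(good, bad, "END"), f)
    expect_error(readPDB(f), "line 2")
    writeLines(c("REMARK nothing here", "END"), f)
    expect_error(readPDB(f), "no ATOM")
})

test_that("PDB round-trip preserves coordinates to format precision", {
    fix <- blockFixture()
    traj <- fix$traj
    small <- new("Trajectory",
                 coords = traj@coords[1:3, , , drop = FALSE],
                 atoms = traj@atoms)
    f <- withr::local_tempfile(fileext = ".pdb")
    writePDB(small, f)
    back <- suppressMessages(readPDB(f))
    expect_equal(nFrames(back), 3L)
    expect_lt(max(abs(coords(back) - coords(small))), 1e-3)
})

test_that("DCD round-trip through an independent reader is exact to float32", {
    co <- list(matrix(rnorm(30, sd = 5), 10, 3),
               matrix(rnorm(30, sd = 5), 10, 3),
               matrix(rnorm(30, sd = 5), 10, 3),
               matrix(rnorm(30, sd = 5), 10, 3),
               matrix(rnorm(30, sd = 5), 10, 3))
    traj <- toyTrajectory(co)
    fd <- withr::local_tempfile(fileext = ".dcd")
    ft <- withr::local_tempfile(fileext = ".pdb")
    writeDCD(traj, fd)
    writePDB(new("Trajectory", coords = traj@coords[1, , , drop = FALSE],
                 atoms = traj@atoms), ft)
    back <- suppressMessages(readTrajectory(ft, fd))
    expect_equal(nFrames(back), 5L)
    expect_equal(nAtoms(back), 10L)
    # float32 storage: ~7 significant digits
    expect_lt(max(abs(coords(back) - coords(traj))), 1e-4)

    # independent cross-check, bypassing readTrajectory
    xyz <- bio3d::read.dcd(fd, verbose = FALSE)
    expect_equal(dim(xyz), c(5L, 30L))
})

test_that("atom-count mismatches and unsupported formats are explicit errors", {
    co <- list(matrix(rnorm(9), 3, 3))
    traj3 <- toyTrajectory(co)
    traj4 <- toyTrajectory(list(matrix(rnorm(12), 4, 3)))
    ft <- withr::local_tempfile(fileext = ".pdb")
    fd <- withr::local_tempfile(fileext = ".dcd")
    writePDB(traj4, ft)
    writeDCD(traj3, fd)
    expect_error(suppressMessages(readTrajectory(ft, fd)),
                 "atom-count mismatch")
    fx <- withr::local_tempfile(fileext = ".xtc")
    writeLines("x", fx)
    expect_error(suppressMessages(readTrajectory(ft, fx)),
                 "supported formats")
})

test_that("plain-text coordinate fixtures round-trip exactly", {
    traj <- toyTrajectory(list(matrix(rnorm(15), 5, 3),
                               matrix(rnorm(15), 5, 3)))
    f <- withr::local_tempfile(fileext = ".crd")
    writeCoordsText(traj, f)
    back <- readCoordsText(f)
    expect_equal(coords(back), coords(traj), tolerance = 1e-12)
})

test_that("the selection grammar matches a brute-force atom-table filter", {
    at <- rbind(toyBackboneAtoms(5, chain = "A", startRes = 83),
                toyBackboneAtoms(4, chain = "B", startRes = 1))
    traj <- toyTrajectory(list(matrix(rnorm(nrow(at) * 3), nrow(at), 3)), at)

    sel <- selectAtoms(traj, "name CA")
    expect_equal(sel@indices, which(at$name == "CA"))

    sel <- selectAtoms(traj, "name C,CA,N and chain B")
    expect_equal(sel@indices,
                 which(at$name %in% c("C", "CA", "N") & at$chain == "B"))

    # inclusive author-numbered residue range: the PYR1 gate loop
    sel <- selectAtoms(traj, "resid 85-87 and chain A")
    expect_equal(sel@indices,
                 which(at$resid >= 85 & at$resid <= 87 & at$chain == "A"))

    expect_equal(length(selectAtoms(traj, "all")@indices), nrow(at))
    expect_error(selectAtoms(traj, "name XX"), "matches no atoms")
    expect_error(selectAtoms(traj, "resid 1-"), "residue range")
})

test_that("superposition removes exact rigid-body motion", {
    set.seed(7)
    base <- matrix(rnorm(18, sd = 3), 6, 3)
    frames <- list(base)
    for (k in 2:4) {
        R <- randomRotation()
        frames[[k]] <- base %*% R + matrix(rep(rnorm(3, sd = 10), each = 6),
                                           6, 3)
    }
    traj <- toyTrajectory(frames)
    fit <- superposeFrames(traj, seq_len(6), reference = "first")
    for (f in 2:4)
        expect_lt(rmsd(coords(fit)[1, , ], coords(fit)[f, , ]), 1e-8)
})

test_that("superposition is idempotent on aligned input", {
    set.seed(8)
    frames <- lapply(1:3, function(i) matrix(rnorm(18, sd = 2), 6, 3))
    traj <- toyTrajectory(frames)
    once <- superposeFrames(traj, seq_len(6))
    twice <- superposeFrames(once, seq_len(6))
    expect_lt(max(abs(coords(twice) - coords(once))), 1e-10)
})

test_that("Kabsch fit attains the rotation-grid optimum", {
    set.seed(9)
    A <- matrix(rnorm(18, sd = 2), 6, 3)
    B <- matrix(rnorm(18, sd = 2), 6, 3)
    fitted <- rmsd(A, B, superpose = TRUE)
    # brute force: coarse-to-fine search over Euler angles
    best <- Inf
    Rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0,
                               -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    center <- c(0, 0, 0); width <- pi
    for (level in 1:6) {
        grid <- lapply(1:3, function(i)
            seq(center[i] - width, center[i] + width, length.out = 9))
        for (a in grid[[1]]) for (b in grid[[2]]) for (g in grid[[3]]) {
            R <- Rz(a) %*% Ry(b) %*% Rz(g)
            v <- sqrt(mean(rowSums((Ac %*% R - Bc)^2)))
            if (v < best) { best <- v; center <- c(a, b, g) }
        }
        width <- width / 4
    }
    expect_lt(abs(fitted - best), 1e-3)
    expect_lte(fitted, best + 1e-9)
})

test_that("superposition never increases the fitted RMSD of any frame", {
    fix <- blockFixture()
    traj <- new("Trajectory",
                coords = fix$traj@coords[1:10, , , drop = FALSE],
                atoms = fix$traj@atoms)
    idx <- seq_len(nAtoms(traj))
    fit <- superposeFrames(traj, idx, reference = "first")
    ref <- coords(traj)[1, , ]
    for (f in 2:10) {
        expect_lte(rmsd(coords(fit)[f, , ], coords(fit)[1, , ]),
                   rmsd(coords(traj)[f, , ], ref) + 1e-9)
    }
})

test_that("rmsd satisfies its defining identities", {
    A <- matrix(rnorm(12), 4, 3)
    expect_equal(rmsd(A, A), 0)
    B <- sweep(A, 2, c(3, 4, 0), "+")
    expect_equal(rmsd(A, B), 5, tolerance = 1e-12)
    expect_equal(rmsd(A, B), rmsd(B, A))
    # direct formula oracle
    C <- matrix(rnorm(12), 4, 3)
    expect_equal(rmsd(A, C), sqrt(sum((A - C)^2) / 4), tolerance = 1e-6)
    # invariance under simultaneous rigid motion when superposing
    R <- randomRotation()
    expect_equal(rmsd(A %*% R + 5, C %*% R + 5, superpose = TRUE),
                 rmsd(A, C, superpose = TRUE), tolerance = 1e-8)
    expect_error(rmsd(A, matrix(0, 3, 3)), "shapes differ")
})

test_that("segmenting slices contiguous, disjoint, covering segments", {
    traj <- toyTrajectory(lapply(1:25, function(f)
        matrix(f + 0 * seq_len(9), 3, 3)))
    ens <- suppressMessages(segmentTrajectory(traj, 4, 5, take = "tail"))
    expect_equal(length(segments(ens)), 4L)
    # take = tail: frames 6..25; segment 0 starts at the first sliced frame
    got <- unlist(lapply(segments(ens), function(s) coords(s)[, 1, 1]))
    expect_equal(got, 6:25)

    one <- suppressMessages(segmentTrajectory(traj, 1, 25, take = "all"))
    expect_equal(coords(segments(one)[[1]]), coords(traj))

    head_ <- suppressMessages(segmentTrajectory(traj, 2, 10, take = "head"))
    expect_equal(unlist(lapply(segments(head_), function(s)
        coords(s)[, 1, 1])), 1:20)

    expect_error(suppressMessages(segmentTrajectory(traj, 10, 5)),
                 "insufficient frames")
})
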