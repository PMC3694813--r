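test_that("covariance matches hand-computed values on trivial segments", {
    # identical frames: zero fluctuation
    same <- toyTrajectory(list(matrix(1:9, 3, 3), matrix(1:9, 3, 3)))
    cv <- computeCovariance(same)
    expect_equal(max(abs(cv@matrix)), 0)

    # one atom, two frames along x: population variance 1
    two <- toyTrajectory(list(matrix(c(0, 0, 0), 1, 3),
                              matrix(c(2, 0, 0), 1, 3)))
    cv <- computeCovariance(two)
    expect_equal(cv@matrix[1, 1], 1.0)
    expect_equal(sum(abs(cv@matrix)) - abs(cv@matrix[1, 1]), 0)
    expect_equal(cv@meanStructure[1, ], c(1, 0, 0))

    cvs <- computeCovariance(two, divisor = "sample")
    expect_equal(cvs@matrix[1, 1], 2.0)

    expect_error(computeCovariance(toyTrajectory(list(matrix(0, 1, 3)))),
                 "2 frames")
})

test_that("sample covariance of exact equilibrium draws matches the analytic
           covariance within 5 standard errors", {
    spec <- makeBlockSystem(1, atomsPerBlock = 3, hingeAtoms = 0, seed = 3)
    Ct <- analyticCovariance(spec)
    traj <- sampleEquilibrium(spec, 5000, seed = 11)
    cv <- computeCovariance(traj)
    n <- cv@nFramesUsed
    se <- sqrt((outer(diag(Ct), diag(Ct)) + Ct^2) / n)
    z <- abs(cv@matrix - Ct) / se
    expect_lt(max(z), 5)
})

test_that("essential-coordinate count follows the displacement fraction", {
    # all modes equal: cumulative fraction k/3N, so fraction 0.9 on 3N = 30
    # is reached exactly at m = 27
    C <- diag(30) * 0.5
    es <- essentialSpace(C, fraction = 0.9)
    expect_equal(es@m, 27L)
    # one dominant mode
    ev <- c(95, rep(5 / 8, 8))
    V <- jacobiEigen(diag(ev))$vectors
    C2 <- V %*% diag(ev) %*% t(V)
    es2 <- essentialSpace((C2 + t(C2)) / 2, fraction = 0.90)
    expect_equal(es2@m, 1L)
    expect_equal(es2@varianceFraction, 0.95, tolerance = 1e-10)
    # fraction 1 keeps the full rank
    es3 <- essentialSpace(C, fraction = 1.0)
    expect_equal(es3@m, 30L)
    expect_error(essentialSpace(C, fraction = 0))
    expect_error(essentialSpace(matrix(0, 6, 6)), "zero total variance")
})

test_that("eigen-pairs agree with an independent Jacobi eigensolver", {
    set.seed(21)
    for (rep in 1:3) {
        A <- matrix(rnorm(144), 12, 12)
        C <- crossprod(A) / 12
        es <- essentialSpace(C, fraction = 1.0)
        jac <- jacobiEigen(C)
        expect_equal(es@eigenvalues, jac$values, tolerance = 1e-8)
        # eigenvectors up to sign
        dots <- abs(colSums(es@eigenvectors * jac$vectors))
        expect_equal(dots, rep(1, 12), tolerance = 1e-8)
    }
})

test_that("images are unsigned block norms of the eigenvectors", {
    # single atom, eigenvector block (1,0,0)
    V <- diag(3)
    expect_equal(buildImages(V, 1)[1, 1], 1.0)

    # two atoms moving identically: coincident images, d = 0
    v <- c(1, 0, 0, 1, 0, 0) / sqrt(2)
    V2 <- cbind(v, diag(6)[, 2:6])
    img <- buildImages(V2, 1)
    expect_equal(img[1, 1], img[2, 1])

    # toy covariance: images equal block norms of independent eigenvectors
    set.seed(4)
    A <- matrix(rnorm(81), 9, 9)
    C <- crossprod(A) / 9
    es <- essentialSpace(C, fixedM = 4)
    jac <- jacobiEigen(C)
    for (k in 1:4) {
        expected <- sqrt(vapply(1:3, function(i)
            sum(jac$vectors[3 * (i - 1) + 1:3, k]^2), numeric(1)))
        expect_equal(es@images[, k], expected, tolerance = 1e-8)
    }

    # invariance to global sign flips
    expect_equal(buildImages(-jac$vectors, 4), buildImages(jac$vectors, 4))

    # eigenvalue weighting scales columns
    w <- sqrt(jac$values[1:4] / jac$values[1])
    expect_equal(buildImages(jac$vectors, 4, weights = w),
                 sweep(buildImages(jac$vectors, 4), 2, w, "*"))
})

test_that("pair distances form a metric on atom images", {
    set.seed(5)
    A <- matrix(rnorm(81), 9, 9)
    es <- essentialSpace(crossprod(A) / 9, fixedM = 2)
    es@images <- matrix(c(0.3, 0.4, 0, 0, 1, 1), 3, 2, byrow = TRUE)
    expect_equal(pairDistance(es, 1, 1), 0)
    expect_equal(pairDistance(es, 1, 2), 0.5)   # 3-4-5 triangle
    expect_equal(pairDistance(es, 1, 2), pairDistance(es, 2, 1))
    expect_error(pairDistance(es, 1, 99), "out of range")

    # brute-force double loop on random images; symmetry + triangle inequality
    img <- matrix(runif(60), 12, 5)
    es2 <- essentialSpace(diag(36), fixedM = 5)
    es2@images <- img
    D <- outer(seq_len(12), seq_len(12),
               Vectorize(function(i, j) pairDistance(es2, i, j)))
    for (i in 1:12) for (j in 1:12) {
        expect_equal(D[i, j], sqrt(sum((img[i, ] - img[j, ])^2)),
                     tolerance = 1e-12)
    }
    for (i in 1:12) for (j in 1:12) for (k in 1:12)
        expect_lte(D[i, k], D[i, j] + D[j, k] + 1e-12)
})

test_that("correlation maps average per-segment descriptors", {
    set.seed(6)
    frames <- lapply(1:8, function(f) matrix(rnorm(15, sd = 2), 5, 3))
    traj <- toyTrajectory(frames)
    sel <- selectAtoms(traj, "all")

    # identical-dynamics segments: mean equals the single-segment map, SD = 0
    rep2 <- new("Trajectory", coords = coords(traj)[c(1:8, 1:8), , ],
                atoms = traj@atoms)
    ensRep <- suppressMessages(segmentTrajectory(rep2, 2, 8))
    ensOne <- suppressMessages(segmentTrajectory(traj, 1, 8))
    mapRep <- suppressMessages(correlationMap(ensRep, sel))
    mapOne <- suppressMessages(correlationMap(ensOne, sel))
    expect_equal(mapValues(mapRep), mapValues(mapOne), tolerance = 1e-10)
    expect_lt(max(mapRep@sdValues), 1e-10)
    expect_equal(mapRep@nSegmentsAveraged, 2L)

    # intra map: symmetric with zero diagonal
    expect_equal(unname(diag(mapValues(mapOne))), rep(0, 5))
    expect_equal(mapValues(mapOne), t(mapValues(mapOne)))
    expect_true(all(mapValues(mapOne) >= 0))
})

test_that("correlated blocks sit closer in image space than uncorrelated ones", {
    fix <- blockFixture()
    lab <- fix$spec@blockLabels
    traj <- fix$traj
    sel <- selectAtoms(traj, "all")
    ens <- suppressMessages(segmentTrajectory(traj, 10, 100, take = "tail"))
    map <- suppressMessages(correlationMap(ens, sel))
    D <- mapValues(map)
    within1 <- mean(D[lab == "block1", lab == "block1"])
    within2 <- mean(D[lab == "block2", lab == "block2"])
    between <- mean(D[lab == "block1", lab == "block2"])
    expect_lt(within1, between)
    expect_lt(within2, between)

    # d_ij anticorrelates with the analytic normalized cross-correlation
    Ct <- analyticCovariance(fix$spec)
    n <- nAtoms(traj)
    cc <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
        ii <- 3 * (i - 1) + 1:3; jj <- 3 * (j - 1) + 1:3
        cc[i, j] <- sum(diag(Ct[ii, jj])) /
            sqrt(sum(diag(Ct[ii, ii])) * sum(diag(Ct[jj, jj])))
    }
    ut <- upper.tri(D)
    expect_lt(cor(D[ut], cc[ut], method = "spearman"), 0)
})

test_that("correlation map serialization writes TSV plus JSON sidecar", {
    frames <- lapply(1:4, function(f) matrix(rnorm(9), 3, 3))
    traj <- toyTrajectory(frames)
    ens <- suppressMessages(segmentTrajectory(traj, 2, 2))
    map <- suppressMessages(correlationMap(ens, selectAtoms(traj, "all")))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeCorrelationMap(map, f)
    back <- read.delim(f, check.names = FALSE)
    expect_equal(nrow(back), 3L)
    meta <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
    expect_equal(meta$n_segments, 2L)
})
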