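twoAtomSpec <- function(k = 2, seed = 9, ...) {
    enmSpec(matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE),
            data.frame(i = 1L, j = 2L, k = k), seed = seed, ...)
}

test_that("zero temperature freezes the trajectory at equilibrium", {
    spec <- twoAtomSpec(temperature = 0, nFrames = 20L, burnIn = 50L)
    traj <- suppressMessages(generateENMTrajectory(spec, removeCOM = FALSE))
    expect_lt(max(abs(sweep(coords(traj), c(2, 3), spec@positions0))), 1e-12)
})

test_that("trajectories are bit-identical for equal seeds", {
    spec <- makeBlockSystem(1, atomsPerBlock = 6, hingeAtoms = 0, seed = 5,
                            nFrames = 30L, burnIn = 100L)
    t1 <- suppressMessages(generateENMTrajectory(spec))
    t2 <- suppressMessages(generateENMTrajectory(spec))
    expect_identical(coords(t1), coords(t2))

    spec2 <- makeBlockSystem(1, atomsPerBlock = 6, hingeAtoms = 0, seed = 6,
                             nFrames = 30L, burnIn = 100L)
    t3 <- suppressMessages(generateENMTrajectory(spec2))
    expect_gt(max(abs(coords(t3) - coords(t1))), 0)
})

test_that("the generator leaves the caller's RNG state untouched", {
    set.seed(123)
    before <- .Random.seed
    invisible(suppressMessages(generateENMTrajectory(
        twoAtomSpec(nFrames = 5L, burnIn = 10L))))
    expect_identical(.Random.seed, before)
})

test_that("relative-coordinate variance satisfies equipartition", {
    k <- 2
    spec <- twoAtomSpec(k = k, seed = 10, nFrames = 4000L, stride = 50L)
    traj <- suppressMessages(generateENMTrajectory(spec))
    # bond-vector fluctuation along each axis: var = kB T / k per coordinate
    rel <- coords(traj)[, 2, ] - coords(traj)[, 1, ]
    kT <- 0.0019872 * 300
    target <- kT / k
    # relaxation time gamma/(2k) = 1.25 ps vs 0.5 ps sampling: AR(1) with
    # rho ~ 0.67, effective sample size ~ n (1-rho)/(1+rho) ~ 800
    nEff <- 800
    for (ax in 1:3) {
        v <- var(rel[, ax])
        se <- target * sqrt(2 / nEff)
        expect_lt(abs(v - target), 5 * se)
    }
})

test_that("unstable time steps are rejected with the dt bound", {
    # lambda_max = 2k = 400; dt lambda_max / gamma = 8 >= 2
    expect_error(twoAtomSpec(k = 200, dt = 0.1, friction = 5), "unstable")
    expect_error(twoAtomSpec(k = 200, dt = 0.1, friction = 5),
                 "dt < 0.025")
})

test_that("analytic covariance is exact for a single spring", {
    k <- 1.7
    spec <- twoAtomSpec(k = k)
    C <- analyticCovariance(spec)
    kT <- 0.0019872 * 300
    # relative coordinate along any axis: var = kT/k = C11 + C44 - 2*C14
    for (ax in 1:3) {
        i <- ax; j <- 3 + ax
        expect_equal(C[i, i] + C[j, j] - 2 * C[i, j], kT / k,
                     tolerance = 1e-10)
    }
    # pure function: identical on repeated evaluation
    expect_identical(C, analyticCovariance(spec))
})

test_that("a 3-atom chain's analytic covariance matches a long simulation", {
    spec <- enmSpec(matrix(c(0, 0, 0, 3, 0, 0, 6, 0, 0), 3, 3, byrow = TRUE),
                    data.frame(i = c(1, 2), j = c(2, 3), k = 1),
                    seed = 12, nFrames = 6000L, stride = 10L, dt = 0.01,
                    friction = 5)
    traj <- suppressMessages(generateENMTrajectory(spec))
    Chat <- computeCovariance(traj)@matrix
    Ct <- analyticCovariance(spec)
    # slowest relaxation 5 ps vs 600 ps of data: entrywise Monte-Carlo error
    # is well under half the leading variance
    expect_lt(max(abs(Chat - Ct)), 0.5 * max(diag(Ct)))
    expect_gt(cor(as.vector(Chat), as.vector(Ct)), 0.95)
})

test_that("anisotropic Hessian has six rigid-body modes and matches kT H+", {
    set.seed(13)
    pos <- matrix(rnorm(15, sd = 4), 5, 3)
    pr <- t(combn(5, 2))
    spec <- enmSpec(pos, data.frame(i = pr[, 1], j = pr[, 2], k = 1),
                    seed = 14)
    C <- analyticCovariance(spec, form = "anisotropic")
    expect_equal(dim(C), c(15L, 15L))
    expect_equal(max(abs(C - t(C))), 0, tolerance = 1e-12)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    # pseudo-inverse removed 6 rigid modes: rank 15 - 6 = 9
    expect_equal(sum(ev > 1e-12 * max(ev)), 9L)
})

test_that("disconnected networks are rejected for covariance requests", {
    spec <- enmSpec(matrix(rnorm(12), 4, 3),
                    data.frame(i = c(1, 3), j = c(2, 4), k = 1), seed = 15)
    expect_error(analyticCovariance(spec), "disconnected")
})

test_that("block systems assemble the advertised composition", {
    spec <- makeBlockSystem(2, atomsPerBlock = 20, hingeAtoms = 4, seed = 7)
    expect_equal(nrow(spec@positions0), 44L)
    expect_equal(sum(spec@blockLabels == "block1"), 20L)
    expect_equal(sum(spec@blockLabels == "block2"), 20L)
    expect_equal(sum(spec@blockLabels == "hinge"), 4L)
    expect_equal(nrow(spec@atoms), 44L)
    expect_equal(unique(spec@atoms$name), "CA")

    # default grading
    d3 <- makeBlockSystem(3, seed = 7)
    expect_equal(as.vector(table(factor(d3@blockLabels,
        levels = c("block1", "block2", "block3", "hinge")))),
        c(15L, 40L, 109L, 12L))
})

test_that("hinge atoms carry the largest analytic fluctuations", {
    spec <- makeBlockSystem(2, seed = 8)
    msf <- analyticMSF(spec)
    lab <- spec@blockLabels
    expect_gt(min(msf[lab == "hinge"]), max(msf[lab == "block2"]))
    expect_gt(mean(msf[lab == "hinge"]), max(msf[lab != "hinge"]))
})

test_that("sample covariance converges to the analytic law with length", {
    spec <- makeBlockSystem(1, atomsPerBlock = 5, hingeAtoms = 0, seed = 16,
                            stride = 10L)
    Ct <- analyticCovariance(spec)
    err <- vapply(c(400L, 6000L), function(nf) {
        traj <- suppressMessages(generateENMTrajectory(spec, nFrames = nf))
        norm(computeCovariance(traj)@matrix - Ct, "F") / norm(Ct, "F")
    }, numeric(1))
    expect_lt(err[2], err[1])
    expect_lt(err[2], 0.2)
})

test_that("core-arm systems grade fluctuations monotonically along arms", {
    spec <- makeCoreArmSystem(seed = 17)
    msf <- analyticMSF(spec)
    lab <- spec@blockLabels
    expect_gt(min(msf[lab == "arm1"]), max(msf[lab == "core"]))
    arm1 <- msf[lab == "arm1"]
    expect_true(all(diff(arm1) > 0))
})

test_that("ENM specs round-trip through JSON", {
    spec <- makeBlockSystem(2, atomsPerBlock = 8, hingeAtoms = 2, seed = 18,
                            nFrames = 50L)
    f <- withr::local_tempfile(fileext = ".json")
    writeENMSpec(spec, f)
    back <- readENMSpec(f)
    expect_equal(back@positions0, spec@positions0, tolerance = 1e-12)
    expect_equal(back@springs$k, spec@springs$k)
    expect_equal(back@seed, spec@seed)
    expect_equal(back@blockLabels, spec@blockLabels)
    t1 <- suppressMessages(generateENMTrajectory(spec))
    t2 <- suppressMessages(generateENMTrajectory(back))
    # JSON text serialization reproduces positions to parsing precision
    expect_equal(coords(t1), coords(t2), tolerance = 1e-9)

    f2 <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(positions0 = matrix(0, 2, 3)), f2)
    expect_error(readENMSpec(f2), "springs")
})

test_that("rigid-body tumbling does not defeat block recovery", {
    fix <- blockFixture()
    lab <- fix$spec@blockLabels
    co <- coords(fix$traj)
    set.seed(19)
    for (f in seq_len(dim(co)[1])) {
        R <- randomRotation()
        co[f, , ] <- co[f, , ] %*% R +
            matrix(rep(rnorm(3, sd = 8), each = dim(co)[2]), dim(co)[2], 3)
    }
    tumbled <- new("Trajectory", coords = co, atoms = fix$traj@atoms)
    sel <- selectAtoms(tumbled, "all")
    ens <- suppressMessages(segmentTrajectory(tumbled, 20, 100,
                                              take = "tail"))
    map <- suppressMessages(correlationMap(ens, sel))
    D <- mapValues(map)
    grid <- 10^seq(log10(quantile(D[upper.tri(D)], 0.02)), log10(max(D)),
                   length.out = 30)
    thr <- suppressMessages(selectThreshold(map, grid))
    p <- clusterDomains(map, thr$threshold)
    pl <- domainLabels(p); pl[is.na(pl)] <- 0L
    blk <- lab != "hinge"
    expect_gte(ariOf(pl[blk], lab[blk]), 0.9)
})
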