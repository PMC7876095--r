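randomTrace <- function(seed, n = 40, mask = NULL) {
    set.seed(seed)
    grid <- BinGrid("chr_test", 0, n * 300, 300)
    ud <- matrix(runif(2 * n), n, 2,
                 dimnames = list(NULL, c("Watson", "Crick")))
    if (is.null(mask))
        mask <- matrix(FALSE, n, 2,
                       dimnames = list(NULL, c("Watson", "Crick")))
    ud[mask] <- NA
    new("PuSeqTrace", grid = grid, usageDelta = ud, usageEpsilon = 1 - ud,
        alphaOverlay = matrix(NA_real_, n, 2,
                              dimnames = list(NULL, c("Watson", "Crick"))),
        mask = mask)
}

test_that("the objective is the Euclidean norm over unmasked ROI bins", {
    a <- idealTrace(40)
    expect_equal(modelError(a, a), 0)
    b <- a
    b@usageDelta <- a@usageDelta + 0.1
    b@usageEpsilon <- 1 - b@usageDelta
    # constant difference c over m points on 2 channels -> c * sqrt(2m)
    expect_equal(modelError(b, a), 0.1 * sqrt(2 * 40), tolerance = 1e-12)
    # single bin, one channel
    expect_equal(modelError(b, a, roi = c(0, 300),
                            channels = "delta:Watson"), 0.1,
                 tolerance = 1e-12)
    # masked bins drop out
    c <- a
    c@mask[1:39, ] <- TRUE
    c@usageDelta[c@mask] <- NA
    c@usageEpsilon[c@mask] <- NA
    expect_equal(modelError(b, c), 0.1 * sqrt(2), tolerance = 1e-12)
    c@mask[] <- TRUE
    expect_error(modelError(b, c), "no unmasked bins")
    # grid mismatch is an input error
    expect_error(modelError(idealTrace(30), a), "different grids")
})

test_that("the objective is a metric on unmasked trace vectors", {
    for (s in 1:5) {
        # share one mask so the same coordinates enter each norm
        set.seed(s)
        m <- matrix(runif(80) < 0.1, 40, 2,
                    dimnames = list(NULL, c("Watson", "Crick")))
        x <- randomTrace(s, mask = m)
        y <- randomTrace(s + 100, mask = m)
        z <- randomTrace(s + 200, mask = m)
        dxy <- modelError(x, y)
        expect_equal(dxy, modelError(y, x), tolerance = 1e-12)
        expect_equal(modelError(x, x), 0)
        expect_gt(dxy, 0)
        expect_lte(modelError(x, z), dxy + modelError(y, z) + 1e-12)
    }
})

test_that("candidate parameter values modify the right barrier field", {
    cfg <- presetLocus("tandem_rts1")
    spec <- FitSpec("restart_offset", c(0, 100), c(11000, 18000),
                    targetBarrier = 1L)
    mod <- replifork:::.applyFitValue(cfg, spec, 100)
    expect_equal(barriers(mod)$restartOffset[1], -100)

    spec2 <- FitSpec("second_barrier_delay", c(0, 5), c(11000, 45000),
                     targetBarrier = 2L)
    mod2 <- replifork:::.applyFitValue(cfg, spec2, 5)
    extra <- barriers(mod2)[nrow(barriers(mod2)), ]
    expect_equal(extra$position, barriers(cfg)$position[2])
    expect_equal(extra$kind, "pause")
    expect_equal(extra$appliesTo, "restarted")
    expect_equal(extra$delay, 5)

    spec3 <- FitSpec("arrest_probability", c(0.1, 0.2), c(11000, 45000),
                     targetBarrier = 9L)
    expect_error(replifork:::.applyFitValue(cfg, spec3, 0.1),
                 "target barrier")
})

test_that("a flat objective returns the smallest grid value with the tie
           flagged", {
    # with arrest probability 0 the delay never acts: common random
    # numbers make every grid point identical
    cfg <- twoOriginConfig(p = 0, D = 0)
    obs <- profileToTrace(simulateEnsemble(cfg,
        SimulationParams(nCells = 30, masterSeed = 3)))
    spec <- FitSpec("delay", c(0, 5, 10), c(1000, 29000),
                    targetBarrier = 1L, nCells = 30,
                    validationNCells = 30, masterSeed = 8)
    fit <- lineSearch(spec, cfg, SimulationParams(), obs)
    expect_true(fit@tie)
    expect_equal(bestValue(fit), 0)
    expect_equal(length(unique(fit@objectives)), 1L)
})

test_that("the line-search objective is unimodal in the restart delay
           under common random numbers", {
    sc <- scenarioObserved("rts1_rrfb_wt", seed = 510, nCells = 800)
    spec <- FitSpec("delay", seq(1, 21, by = 2), c(11000, 45000),
                    targetBarrier = 1L, nCells = 2000,
                    validationNCells = 2000, masterSeed = 17)
    fit <- lineSearch(spec, presetLocus("rts1_rrfb"), SimulationParams(),
                      sc$obs)
    o <- fit@objectives
    k <- which.min(o)
    expect_true(all(diff(o[seq_len(k)]) <= 1e-9))
    expect_true(all(diff(o[k:length(o)]) >= -1e-9))
})

test_that("line search recovers generating parameters across replicate
           datasets", {
    errD <- errP <- numeric(0)
    cfg <- presetLocus("rts1_rrfb")
    for (r in 1:8) {
        sc <- scenarioObserved("rts1_rrfb_wt", seed = 3000 + r,
                               nCells = 600)
        fD <- lineSearch(FitSpec("delay", 5:17, c(11000, 45000),
                                 targetBarrier = 1L, nCells = 600,
                                 validationNCells = 600,
                                 masterSeed = 50 + r),
                         cfg, SimulationParams(), sc$obs)
        fP <- lineSearch(FitSpec("arrest_probability",
                                 seq(0.4, 0.95, 0.05), c(11000, 45000),
                                 targetBarrier = 1L, nCells = 600,
                                 validationNCells = 600,
                                 masterSeed = 50 + r),
                         cfg, SimulationParams(), sc$obs)
        errD <- c(errD, abs(bestValue(fD) - 11))
        errP <- c(errP, abs(bestValue(fP) - 0.7))
    }
    expect_lte(median(errD), 1)
    expect_lte(median(errP), 0.05)
})

test_that("scenario fits reject a mismatched observed grid", {
    wrong <- idealTrace(40)
    expect_error(scenarioFits("rts1_delay", wrong), "does not match")
})
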