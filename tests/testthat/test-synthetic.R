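test_that("count generation follows the Poisson noise model", {
    n <- 1000
    grid <- BinGrid("chr_test", 0, n * 300, 300)
    dn <- list(NULL, c("Watson", "Crick"))
    tr <- new("PuSeqTrace", grid = grid,
              usageDelta = matrix(1, n, 2, dimnames = dn),
              usageEpsilon = matrix(0, n, 2, dimnames = dn),
              alphaOverlay = matrix(NA_real_, n, 2, dimnames = dn),
              mask = matrix(FALSE, n, 2, dimnames = dn))
    cts <- generateCounts(tr, NoiseModel(depth = 100, background = 0,
                                         seed = 5))
    mat <- SummarizedExperiment::assay(cts, "counts")
    # usage 0 with no background: identically zero counts
    expect_true(all(mat[, "pol_epsilon:Watson"] == 0))
    # usage 1 at depth 100: sample mean within 3 standard errors
    expect_lt(abs(mean(mat[, "pol_delta:Watson"]) - 100),
              3 * sqrt(100 / n))
    # determinism in the noise seed
    cts2 <- generateCounts(tr, NoiseModel(depth = 100, background = 0,
                                          seed = 5))
    expect_identical(mat, SummarizedExperiment::assay(cts2, "counts"))
    # masked traces are rejected
    trM <- tr
    trM@mask[1, 1] <- TRUE
    trM@usageDelta[1, 1] <- NA
    trM@usageEpsilon[1, 1] <- NA
    expect_error(generateCounts(trM, NoiseModel()), "unmasked")
    expect_error(NoiseModel(depth = -5), "depth")
})

test_that("scenario datasets record the generating truth and regenerate
           bit-exactly", {
    d <- withr::local_tempdir()
    ds <- makeScenarioDataset("rts1_rrfb_wt", d, depth = 50, nCells = 40,
                              seed = 31)
    truth <- jsonlite::read_json(file.path(d, "truth.json"),
                                 simplifyVector = TRUE)
    b <- truth$barriers
    expect_equal(b$delay[b$kind == "restart"], 11)
    expect_equal(b$arrestProbability[b$kind == "restart"], 0.7)
    expect_equal(truth$params$master_seed, 31)

    adh <- makeScenarioDataset("rts1_rrfb_adh", withr::local_tempdir(),
                               depth = 50, nCells = 10, seed = 31)
    tAdh <- jsonlite::read_json(adh$truthFile, simplifyVector = TRUE)
    expect_equal(
        tAdh$barriers$arrestProbability[tAdh$barriers$kind == "restart"],
        0.9)

    # rebuild everything from the truth file alone
    re <- readTruth(file.path(d, "truth.json"))
    prof <- simulateEnsemble(re$config, re$params)
    regen <- generateCounts(profileToTrace(prof), re$noise)
    expect_identical(SummarizedExperiment::assay(regen, "counts"),
                     SummarizedExperiment::assay(ds$counts, "counts"))

    # written files carry the same counts and the normalisation sidecar
    back <- readCounts(puseqFileSet(d), binGrid(ds$config),
                       readLibraryTotals(d))
    expect_equal(unname(SummarizedExperiment::assay(back, "counts")),
                 unname(SummarizedExperiment::assay(ds$counts, "counts")))
    expect_equal(SummarizedExperiment::colData(back)$libraryTotal,
                 SummarizedExperiment::colData(ds$counts)$libraryTotal)
})

test_that("the barrier-off scenario shows no delta/delta region", {
    d <- withr::local_tempdir()
    ds <- makeScenarioDataset("barrier_off", d, depth = 200,
                              nCells = 300, seed = 77)
    expect_true(all(barriers(ds$config)$arrestProbability == 0))
    obs <- computeUsage(readCounts(puseqFileSet(d), binGrid(ds$config),
                                   readLibraryTotals(d)))
    m <- binMidpoints(binGrid(obs))
    # on the Watson strand, epsilon stays high from the early origin to
    # well past RTS1: no switch to delta/delta synthesis
    reg <- m > 11000 & m < 20000 & !traceMask(obs)[, "Watson"]
    expect_gt(min(usageEpsilon(obs)[reg, "Watson"]), 0.6)
    expect_error(makeScenarioDataset("no_such_scenario",
                                     withr::local_tempdir()))
})

test_that("usage recovered from generated counts converges to the trace
           as depth grows", {
    cfg <- presetLocus("rts1_rrfb")
    prof <- simulateEnsemble(cfg, SimulationParams(nCells = 400,
                                                   masterSeed = 5))
    tr <- profileToTrace(prof)
    dev <- vapply(c(100, 1000, 10000), function(lam) {
        cts <- generateCounts(tr, NoiseModel(depth = lam, background = 1,
                                             seed = 70 + lam))
        u <- computeUsage(cts, minDepth = 0)
        max(abs(usageDelta(u) - usageDelta(tr)), na.rm = TRUE)
    }, numeric(1))
    expect_true(all(diff(dev) < 0))
    expect_lte(dev[3], 0.02)
})
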