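# Shared fixtures: all inputs are built in code at test time.

# two origins firing deterministically at t = 0 with an optional barrier
# between them; the closed-form scenario used throughout
twoOriginConfig <- function(p = 1, D = 11, offset = 0, kind = "restart",
                            barrierAt = 3000, domain = 30000,
                            binSize = 300) {
    barriers <- if (is.na(p)) Barrier(numeric(0), character(0))
        else Barrier(barrierAt, "rightward", kind = kind,
                     arrestProbability = p, delay = D,
                     restartOffset = offset)
    LocusConfig("two_origin", BinGrid("chr_test", 0, domain, binSize),
                origins = Origin(c(0, domain)), barriers = barriers)
}

# deterministic random small locus for engine cross-checks
randomSmallConfig <- function(seed) {
    set.seed(seed)
    domain <- 9000
    nOri <- sample(2:3, 1)
    ori <- Origin(sort(sample(seq(0, domain, by = 300), nOri)),
                  efficiency = runif(nOri, 0.5, 1),
                  meanFiringTime = runif(nOri, 0, 6),
                  firingTimeSD = runif(nOri, 0, 2))
    nBar <- sample(0:2, 1)
    bar <- if (nBar > 0) {
        kinds <- sample(c("restart", "pause"), nBar, replace = TRUE,
                        prob = c(0.7, 0.3))
        Barrier(sample(seq(300, domain - 300, by = 300), nBar),
                sample(c("rightward", "leftward"), nBar, replace = TRUE),
                kind = kinds,
                arrestProbability = sample(c(0, 0.5, 1), nBar,
                                           replace = TRUE),
                delay = round(runif(nBar, 0, 6), 1),
                restartOffset = ifelse(kinds == "restart",
                                       sample(c(0, -300), nBar,
                                              replace = TRUE), 0))
    } else Barrier(numeric(0), character(0))
    LocusConfig("random_small", BinGrid("chr_test", 0, domain, 300), ori,
                bar)
}

# generate a scenario dataset in a temp dir and return its observed trace
scenarioObserved <- function(scenario, seed, depth = 100, nCells = 1000,
                             overrides = list(), binSize = 300,
                             minDepth = 10) {
    dir <- withr::local_tempdir(.local_envir = parent.frame())
    ds <- makeScenarioDataset(scenario, dir, depth = depth,
                              nCells = nCells, seed = seed,
                              overrides = overrides, binSize = binSize)
    counts <- readCounts(puseqFileSet(dir), binGrid(ds$config),
                         readLibraryTotals(dir))
    list(obs = computeUsage(counts, minDepth), dir = dir, truth = ds)
}

# flat ideal trace on a small grid, optionally with a usage step
idealTrace <- function(n = 60, binSize = 300, stepAt = NULL, low = 0.3) {
    grid <- BinGrid("chr_test", 0, n * binSize, binSize)
    ue <- matrix(1, n, 2, dimnames = list(NULL, c("Watson", "Crick")))
    if (!is.null(stepAt)) {
        k <- (binMidpoints(grid) > stepAt)
        ue[k, ] <- low
    }
    new("PuSeqTrace", grid = grid, usageDelta = 1 - ue, usageEpsilon = ue,
        alphaOverlay = matrix(NA_real_, n, 2,
                              dimnames = list(NULL, c("Watson", "Crick"))),
        mask = matrix(FALSE, n, 2,
                      dimnames = list(NULL, c("Watson", "Crick"))))
}
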