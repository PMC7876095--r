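test_that("a single fork replicates at the configured velocity", {
    cfg <- LocusConfig("one", BinGrid("chr_test", 0, 20000, 200),
                       origins = Origin(10000))
    cell <- simulateCell(cfg, SimulationParams(), cellSeed = 1)
    m <- binMidpoints(binGrid(cell))
    k <- which(m > 19000)[1]
    # 9 kb at 1.8 kb/min = 5 min (up to half a bin of midpoint offset)
    expect_equal(replicationTime(cell)[k], 5,
                 tolerance = 0.001 + 200 / 2 / 1800 / 5)
    expect_equal(forkDirection(cell)[k], "rightward")
    expect_equal(forkType(cell)[k], "canonical")
    # leftward mirror
    k2 <- which(m < 1000)[1]
    expect_equal(forkDirection(cell)[k2], "leftward")
})

test_that("an arrested-and-restarted fork meets the converging fork at the
           closed-form position", {
    # right fork waits 11 min at 3 kb; solve 3 + 1.8(t - 12.67) = 30 - 1.8t
    cfg <- twoOriginConfig(p = 1, D = 11)
    cell <- simulateCell(cfg, SimulationParams(), cellSeed = 7)
    m <- binMidpoints(binGrid(cell))
    meetBin <- which(m > 5100)[1] - 1L
    expect_equal(forkDirection(cell)[meetBin], "rightward")
    expect_equal(forkType(cell)[meetBin], "restarted")
    expect_equal(forkDirection(cell)[meetBin + 1L], "leftward")
    expect_equal(max(replicationTime(cell)), 83 / 6 - 150 / 1800,
                 tolerance = 1e-6)

    prof <- simulateEnsemble(cfg, SimulationParams(nCells = 10,
                                                   masterSeed = 1))
    expect_equal(terminationMidpoint(prof), 5100, tolerance = 300 / 5100)
})

test_that("a barrier with zero arrest probability leaves the cell
           untouched under a shared seed", {
    free <- twoOriginConfig(p = NA)
    off <- twoOriginConfig(p = 0, D = 11)
    a <- simulateCell(free, SimulationParams(), cellSeed = 5)
    b <- simulateCell(off, SimulationParams(), cellSeed = 5)
    expect_identical(replicationTime(a), replicationTime(b))
    expect_identical(forkDirection(a), forkDirection(b))
    expect_identical(forkType(a), forkType(b))
    # and at ensemble level, bit-exactly
    pa <- simulateEnsemble(free, SimulationParams(nCells = 50,
                                                  masterSeed = 9))
    pb <- simulateEnsemble(off, SimulationParams(nCells = 50,
                                                 masterSeed = 9))
    expect_identical(pa@usage, pb@usage)
    expect_identical(fracRightward(pa), fracRightward(pb))

    # a zero-delay pause with no offset is also a no-op
    pause0 <- twoOriginConfig(p = 1, D = 0, kind = "pause")
    c <- simulateCell(pause0, SimulationParams(), cellSeed = 5)
    expect_identical(replicationTime(a), replicationTime(c))
    expect_identical(forkType(a), forkType(c))
})

test_that("ensembles are deterministic in the master seed", {
    cfg <- presetLocus("rts1_rrfb")
    p1 <- simulateEnsemble(cfg, SimulationParams(nCells = 40,
                                                 masterSeed = 11))
    p2 <- simulateEnsemble(cfg, SimulationParams(nCells = 40,
                                                 masterSeed = 11))
    p3 <- simulateEnsemble(cfg, SimulationParams(nCells = 40,
                                                 masterSeed = 12))
    expect_identical(p1@usage, p2@usage)
    expect_identical(p1@meanReplicationTime, p2@meanReplicationTime)
    expect_false(identical(p1@usage, p3@usage))
})

test_that("ensemble fractions and usage close to 1 at every bin", {
    cfg <- presetLocus("tandem_rts1")
    prof <- simulateEnsemble(cfg, SimulationParams(nCells = 100,
                                                   masterSeed = 2))
    for (s in c("Watson", "Crick")) {
        tot <- polUsage(prof, s, "epsilon") + polUsage(prof, s, "delta") +
            polUsage(prof, s, "alpha")
        expect_equal(tot, rep(1, nBins(binGrid(prof))), tolerance = 1e-12)
    }
    expect_true(all(fracRightward(prof) >= 0 & fracRightward(prof) <= 1))
    expect_true(all(fracRestarted(prof) >= 0 & fracRestarted(prof) <= 1))
})

test_that("polymerase usage mapping follows the fork type and direction", {
    # all cells replicate a left-end bin with canonical rightward forks
    cfg <- LocusConfig("map", BinGrid("chr_test", 0, 12000, 300),
                       origins = Origin(0))
    a <- 0.1
    prof <- simulateEnsemble(cfg, SimulationParams(nCells = 20,
                                                   masterSeed = 3,
                                                   alphaFraction = a))
    expect_equal(polUsage(prof, "Watson", "epsilon")[5], 1)
    expect_equal(polUsage(prof, "Crick", "delta")[5], 1 - a)
    expect_equal(polUsage(prof, "Crick", "alpha")[5], a)

    # downstream of a fully penetrant restart barrier: delta on both strands
    cfg2 <- LocusConfig("map2", BinGrid("chr_test", 0, 12000, 300),
                        origins = Origin(0),
                        barriers = Barrier(3000, "rightward",
                                           kind = "restart",
                                           arrestProbability = 1,
                                           delay = 2))
    prof2 <- simulateEnsemble(cfg2, SimulationParams(nCells = 20,
                                                     masterSeed = 3,
                                                     alphaFraction = a))
    m <- binMidpoints(binGrid(prof2))
    k <- which(m > 6000)[1]
    expect_equal(polUsage(prof2, "Watson", "delta")[k], 1)
    expect_equal(polUsage(prof2, "Crick", "delta")[k], 1)
    expect_equal(polUsage(prof2, "Crick", "alpha")[k], 0)
    expect_equal(fracRestarted(prof2)[k], 1)
})

test_that("strand bookkeeping is exactly symmetric without barriers and
           without Pol alpha", {
    cfg <- LocusConfig("sym", BinGrid("chr_test", 0, 30000, 300),
                       origins = Origin(c(4800, 15000, 25200),
                                        efficiency = c(0.8, 0.9, 0.7),
                                        meanFiringTime = c(4, 6, 8),
                                        firingTimeSD = 2))
    prof <- simulateEnsemble(cfg, SimulationParams(nCells = 200,
                                                   masterSeed = 21,
                                                   alphaFraction = 0))
    expect_identical(polUsage(prof, "Watson", "epsilon"),
                     polUsage(prof, "Crick", "delta"))
    expect_identical(polUsage(prof, "Crick", "epsilon"),
                     polUsage(prof, "Watson", "delta"))
})

test_that("restarted forks cross a canonical-only barrier with zero
           transit delay", {
    # fork restarts at the first RTS1, then crosses a second copy 1.8 kb
    # downstream: transit time across it must be exactly distance/velocity
    cfg <- LocusConfig("imm", BinGrid("chr_test", 0, 12000, 300),
                       origins = Origin(0),
                       barriers = Barrier(c(3000, 4800), "rightward",
                                          kind = "restart",
                                          arrestProbability = 1,
                                          delay = c(5, 5),
                                          canonicalOnly = TRUE))
    cell <- simulateCell(cfg, SimulationParams(), cellSeed = 13)
    m <- binMidpoints(binGrid(cell))
    t1 <- replicationTime(cell)[which(m > 3600)[1]]
    t2 <- replicationTime(cell)[which(m > 6600)[1]]
    expect_equal(t2 - t1, 3000 / 1800, tolerance = 1e-9)
    expect_true(all(forkType(cell)[m > 3000] == "restarted"))
})

test_that("termination midpoint interpolates the 0.5 crossing and errors
           without one", {
    sym <- LocusConfig("sym2", BinGrid("chr_test", 0, 30000, 300),
                       origins = Origin(c(0, 30000)))
    prof <- simulateEnsemble(sym, SimulationParams(nCells = 5,
                                                   masterSeed = 1))
    expect_equal(terminationMidpoint(prof), 15000, tolerance = 300 / 15000)
    one <- LocusConfig("mono", BinGrid("chr_test", 0, 12000, 300),
                       origins = Origin(0))
    profMono <- simulateEnsemble(one, SimulationParams(nCells = 5,
                                                       masterSeed = 1))
    expect_error(terminationMidpoint(profMono), "not found")
})

test_that("a restart offset re-replicates the offset window", {
    cfg <- LocusConfig("off", BinGrid("chr_test", 0, 12000, 300),
                       origins = Origin(0),
                       barriers = Barrier(3000, "rightward",
                                          kind = "restart",
                                          arrestProbability = 1, delay = 5,
                                          restartOffset = -900))
    cell <- simulateCell(cfg, SimulationParams(), cellSeed = 2)
    m <- binMidpoints(binGrid(cell))
    redo <- m > 2100 & m < 3000
    expect_true(all(forkType(cell)[redo] == "restarted"))
    # re-replication happens after the delay, not at first passage
    expect_true(all(replicationTime(cell)[redo] >
                    3000 / 1800 + 5 - 900 / 1800))
})

test_that("simulation errors name the failing cell", {
    allSuppressed <- LocusConfig("bad", BinGrid("chr_test", 0, 6000, 300),
                                 origins = Origin(3000, suppressed = TRUE))
    expect_error(
        simulateEnsemble(allSuppressed, SimulationParams(nCells = 2,
                                                         masterSeed = 1)),
        "cell 1")
})
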