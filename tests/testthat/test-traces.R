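writeBedGraph <- function(path, chrom, starts, ends, values) {
    write.table(data.frame(chrom, starts, ends, values), path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    path
}

test_that("count tracks are read against the grid with strict tiling", {
    grid <- BinGrid("chr_test", 0, 900, 300)
    d <- withr::local_tempdir()
    ok <- writeBedGraph(file.path(d, "a.bedgraph"), "chr_test",
                        c(0, 300, 600), c(300, 600, 900), c(5, 7, 9))
    paths <- c("pol_delta:Watson" = ok)
    counts <- readCounts(paths, grid)
    expect_equal(as.vector(SummarizedExperiment::assay(counts, "counts")),
                 c(5, 7, 9))
    expect_equal(unname(SummarizedExperiment::colData(counts)$libraryTotal),
                 21)

    bad <- writeBedGraph(file.path(d, "b.bedgraph"), "chr_test",
                         c(0, 300), c(300, 550), c(5, 7))
    expect_error(readCounts(c("pol_delta:Watson" = bad), grid),
                 "format error.*line 2")
    wrongChrom <- writeBedGraph(file.path(d, "c.bedgraph"), "chrX",
                                0, 300, 5)
    expect_error(readCounts(c("pol_delta:Watson" = wrongChrom), grid),
                 "chrom mismatch")

    empty <- file.path(d, "empty.bedgraph")
    file.create(empty)
    expect_warning(
        cEmpty <- readCounts(c("pol_delta:Watson" = empty), grid),
        "empty")
    expect_true(all(SummarizedExperiment::assay(cEmpty, "counts") == 0))

    partial <- writeBedGraph(file.path(d, "p.bedgraph"), "chr_test",
                             0, 300, 4)
    expect_warning(readCounts(c("pol_delta:Watson" = partial), grid),
                   "2 bin")
})

test_that("usage ratios, masking and the alpha overlay follow the count
           model", {
    grid <- BinGrid("chr_test", 0, 900, 300)
    mat <- cbind("pol_delta:Watson" = c(30, 20, 0),
                 "pol_epsilon:Watson" = c(10, 0, 0),
                 "pol_delta:Crick" = c(15, 15, 15),
                 "pol_epsilon:Crick" = c(45, 15, 15))
    d <- withr::local_tempdir()
    paths <- vapply(colnames(mat), function(k) {
        f <- file.path(d, paste0(gsub(":", "_", k), ".bedgraph"))
        writeBedGraph(f, "chr_test", c(0, 300, 600), c(300, 600, 900),
                      mat[, k])
    }, character(1))
    counts <- readCounts(paths, grid,
                         libraryTotals = c("pol_delta:Watson" = 100,
                                           "pol_epsilon:Watson" = 100,
                                           "pol_delta:Crick" = 100,
                                           "pol_epsilon:Crick" = 100))
    tr <- computeUsage(counts, minDepth = 10)
    expect_equal(unname(usageDelta(tr)[1, "Watson"]), 0.75)      # 30 / 40
    expect_equal(unname(usageDelta(tr)[2, "Watson"]), 1.0)       # epsilon = 0
    expect_true(traceMask(tr)[3, "Watson"])              # 0 + 0 < 10
    expect_equal(unname(usageDelta(tr)[1, "Crick"]), 0.25)
    ok <- !traceMask(tr)
    expect_equal((usageDelta(tr) + usageEpsilon(tr))[ok],
                 rep(1, sum(ok)), tolerance = 1e-12)

    expect_error(computeUsage(readCounts(paths[1:2], grid)),
                 "input error")
})

test_that("usage is invariant to rescaling one strain's counts", {
    grid <- BinGrid("chr_test", 0, 3000, 300)
    set.seed(8)
    base <- matrix(rpois(40, 200), 10, 4,
                   dimnames = list(NULL, c("pol_delta:Watson",
                                           "pol_epsilon:Watson",
                                           "pol_delta:Crick",
                                           "pol_epsilon:Crick")))
    mk <- function(mat) {
        d <- withr::local_tempdir(.local_envir = parent.frame())
        paths <- vapply(colnames(mat), function(k) {
            f <- file.path(d, paste0(gsub(":", "_", k), ".bedgraph"))
            writeBedGraph(f, "chr_test", seq(0, 2700, 300),
                          seq(300, 3000, 300), mat[, k])
        }, character(1))
        computeUsage(readCounts(paths, grid), minDepth = 10)
    }
    scaled <- base
    scaled[, c("pol_delta:Watson", "pol_delta:Crick")] <-
        3 * scaled[, c("pol_delta:Watson", "pol_delta:Crick")]
    expect_equal(usageDelta(mk(base)), usageDelta(mk(scaled)),
                 tolerance = 1e-12)
})

test_that("Savitzky-Golay smoothing is exact on low-order polynomials and
           validates its window", {
    x <- seq_len(50)
    cubic <- 2 + 0.5 * x - 0.01 * x^2 + 0.0004 * x^3
    expect_equal(smoothTrace(cubic, window = 9, polyorder = 3), cubic,
                 tolerance = 1e-8)
    expect_equal(smoothTrace(rep(0.4, 30), 9, 3), rep(0.4, 30),
                 tolerance = 1e-12)
    expect_error(smoothTrace(cubic, window = 4, polyorder = 3),
                 "parameter error")
    expect_error(smoothTrace(cubic, window = 3, polyorder = 3),
                 "parameter error")
    # masked values are interpolated for the fit and restored afterwards
    withNA <- cubic
    withNA[c(10, 25)] <- NA
    sm <- smoothTrace(withNA, 9, 3)
    expect_true(all(is.na(sm[c(10, 25)])))
    # away from the interpolated gaps the fit is still exact
    far <- setdiff(seq_along(cubic), c(6:14, 21:29))
    expect_equal(sm[far], cubic[far], tolerance = 1e-6)
})

test_that("profiles map onto trace space with alpha folded into delta", {
    cfg <- LocusConfig("map", BinGrid("chr_test", 0, 12000, 300),
                       origins = Origin(0),
                       barriers = Barrier(6000, "rightward",
                                          kind = "restart",
                                          arrestProbability = 1,
                                          delay = 3))
    prof <- simulateEnsemble(cfg, SimulationParams(nCells = 10,
                                                   masterSeed = 4,
                                                   alphaFraction = 0.1))
    tr <- profileToTrace(prof)
    m <- binMidpoints(binGrid(tr))
    up <- which(m < 6000)[2]
    down <- which(m > 8000)[1]
    expect_equal(unname(usageEpsilon(tr)[up, "Watson"]), 1)
    expect_equal(unname(usageDelta(tr)[up, "Crick"]), 1)  # 0.9 d + 0.1 a
    expect_equal(unname(alphaOverlay(tr)[up, "Crick"]), 1)  # 10 x 0.1
    expect_equal(unname(usageDelta(tr)[down, "Watson"]), 1)  # delta/delta
    expect_equal(unname(usageDelta(tr)[down, "Crick"]), 1)
    expect_equal(unname(alphaOverlay(tr)[down, "Crick"]), 0)
    expect_false(any(traceMask(tr)))
    # closure survives the mapping
    expect_equal(usageDelta(tr) + usageEpsilon(tr),
                 matrix(1, nBins(binGrid(tr)), 2,
                        dimnames = dimnames(usageDelta(tr))),
                 tolerance = 1e-12)
})

test_that("transition positions are located by the midpoint crossing", {
    tr <- idealTrace(60, stepAt = 9000, low = 0.3)
    est <- estimateTransitionPosition(tr, "Watson", c(3000, 15000))
    expect_lt(abs(est - 9000), 300 + 1e-9)
    flat <- idealTrace(60)
    expect_error(estimateTransitionPosition(flat, "Watson"), "flat")
})

test_that("trace files round-trip including the mask", {
    cfg <- twoOriginConfig(p = 0.7, D = 11)
    prof <- simulateEnsemble(cfg, SimulationParams(nCells = 30,
                                                   masterSeed = 6))
    tr <- profileToTrace(prof)
    counts <- generateCounts(tr, NoiseModel(depth = 30, background = 0,
                                            seed = 2))
    masked <- computeUsage(counts, minDepth = 20)
    expect_gt(sum(traceMask(masked)), 0)

    d <- withr::local_tempdir()
    writeTrace(masked, d)
    back <- readTrace(d)
    expect_equal(binGrid(back), binGrid(masked))
    expect_identical(traceMask(back), traceMask(masked))
    expect_equal(usageDelta(back), usageDelta(masked), tolerance = 1e-12)
    expect_equal(alphaOverlay(back), alphaOverlay(masked),
                 tolerance = 1e-12)
})
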