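#' @include AllClasses.R AllGenerics.R simulate.R traces.R
NULL

## strains actually emitted for a trace (alpha only when an overlay exists)
.traceStrains <- function(trace) {
    s <- c("pol_delta", "pol_epsilon")
    if (!all(is.na(trace@alphaOverlay))) s <- c(s, "pol_alpha")
    s
}

#' Generate Pu-seq-like counts from a usage trace
#'
#' Emulates sequencing of the three polymerase-mutant strains: for each
#' strain, strand and bin, a count is drawn independently from
#' \code{Poisson(depth * u + background)} where \code{u} is the strain's
#' usage channel on that strand (delta strain: \code{usageDelta}; epsilon
#' strain: \code{usageEpsilon}; alpha strain: the un-scaled alpha fraction
#' \code{alphaOverlay / 10}). Library totals are the realised column sums.
#'
#' @param trace an unmasked \code{\link{PuSeqTrace}} (typically from
#'   \code{\link{profileToTrace}}).
#' @param noise a \code{\link{NoiseModel}}.
#' @return a \code{\link{PuSeqCounts}}.
#' @examples
#' prof <- simulateEnsemble(presetLocus("rts1_rrfb"),
#'                          SimulationParams(nCells = 50))
#' generateCounts(profileToTrace(prof), NoiseModel(depth = 100, seed = 1))
#' @export
generateCounts <- function(trace, noise = NoiseModel()) {
    stopifnot(is(trace, "PuSeqTrace"), is(noise, "NoiseModel"))
    validObject(noise)
    if (any(trace@mask))
        stop("trace must be unmasked to generate counts", call. = FALSE)
    grid <- trace@grid
    n <- nBins(grid)
    strains <- .traceStrains(trace)
    keys <- as.vector(outer(strains, .STRANDS, paste, sep = ":"))
    counts <- matrix(0L, n, length(keys), dimnames = list(NULL, keys))
    .withSeed(noise@seed, {
        for (s in strains) for (st in .STRANDS) {
            u <- switch(s,
                pol_delta = trace@usageDelta[, st],
                pol_epsilon = trace@usageEpsilon[, st],
                pol_alpha = trace@alphaOverlay[, st] / 10)
            lambda <- noise@depth * u + noise@background
            counts[, paste(s, st, sep = ":")] <- rpois(n, lambda)
        }
    })
    parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
    ## Library totals are the *design* totals of a depth-matched,
    ## genome-scale experiment (n bins at the average usage of 1/2 plus
    ## background), identical across strains, not the realised sums over
    ## this window: the locus is a window of a genome-wide library, and
    ## normalising by window sums would skew the delta/epsilon ratio
    ## wherever delta/delta restart synthesis makes the strains' local
    ## shares unequal.
    designTotal <- n * (noise@depth / 2 + noise@background)
    cd <- S4Vectors::DataFrame(strain = parts[, 1], strand = parts[, 2],
                               libraryTotal = rep(designTotal, length(keys)),
                               row.names = keys)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowRanges = binRanges(grid),
        colData = cd)
    new("PuSeqCounts", se)
}

#' Write count tracks as bedGraph files
#'
#' One bedGraph per strain x strand with the standard names read back by
#' \code{\link{puseqFileSet}} / \code{\link{readCounts}}, plus a
#' \code{<prefix>_library_totals.json} sidecar recording the library
#' totals (bedGraph windows cannot carry the genome-wide normalisation
#' constants; see \code{\link{readLibraryTotals}}).
#'
#' @param counts a \code{\link{PuSeqCounts}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default \code{"counts"}).
#' @return named vector of written paths, invisibly.
#' @export
writeCounts <- function(counts, dir, prefix = "counts") {
    stopifnot(is(counts, "PuSeqCounts"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cd <- SummarizedExperiment::colData(counts)
    mat <- SummarizedExperiment::assay(counts, "counts")
    rr <- SummarizedExperiment::rowRanges(counts)
    paths <- character(0)
    for (i in seq_len(ncol(mat))) {
        gr <- rr
        GenomicRanges::score(gr) <- as.numeric(mat[, i])
        f <- file.path(dir, paste0(prefix, "_",
                                   sub("pol_", "", cd$strain[i]), "_",
                                   tolower(cd$strand[i]), ".bedgraph"))
        rtracklayer::export(gr, f, format = "bedGraph")
        paths[paste(cd$strain[i], cd$strand[i], sep = ":")] <- f
    }
    totals <- as.list(stats::setNames(cd$libraryTotal, rownames(cd)))
    jsonlite::write_json(totals,
                         file.path(dir, paste0(prefix,
                                               "_library_totals.json")),
                         auto_unbox = TRUE, digits = NA)
    invisible(paths)
}

#' Read a library-totals sidecar
#'
#' Returns the named vector of library totals written next to a count
#' dataset by \code{\link{writeCounts}}, or \code{NULL} when no sidecar
#' exists (in which case \code{\link{readCounts}} falls back to the file
#' sums).
#'
#' @param dir dataset directory.
#' @param prefix file-name prefix (default \code{"counts"}).
#' @return named numeric vector or \code{NULL}.
#' @export
readLibraryTotals <- function(dir, prefix = "counts") {
    f <- file.path(dir, paste0(prefix, "_library_totals.json"))
    if (!file.exists(f)) return(NULL)
    unlist(jsonlite::read_json(f, simplifyVector = TRUE))
}

## generating parameters for each scenario dataset: the RTS1 arrest
## probability and restart delay defaults are the fitted values of the
## matching experiment (wild type 0.7 / 11 min; adh-driven Rtf1 0.9;
## pku70 deletion 14 min)
.DATASETS <- list(
    rts1_rrfb_wt     = list(preset = "rts1_rrfb", p = 0.7, delay = 11),
    rts1_rrfb_adh    = list(preset = "rts1_rrfb", p = 0.9, delay = 11),
    rts1_rrfb_pku70d = list(preset = "rts1_rrfb", p = 0.7, delay = 14),
    inverted         = list(preset = "inverted_rts1", p = 0.9, delay = 11),
    tandem           = list(preset = "tandem_rts1", p = 0.7, delay = 11),
    barrier_off      = list(preset = "rts1_rrfb", p = 0, delay = 11),
    rrfb_calibration = list(preset = "rrfb_only", p = 1, delay = 6,
                            kind = "pause"))

#' Build a synthetic Pu-seq scenario dataset
#'
#' Simulates the matching preset locus with the scenario's generating
#' parameters, converts the ensemble profile to trace space, draws Poisson
#' counts and writes bedGraph count files plus a \code{truth.json}
#' recording every generating parameter and seed, so the dataset can be
#' regenerated bit-exactly (see \code{\link{readTruth}}).
#'
#' Scenarios: \code{rts1_rrfb_wt} (arrest probability 0.7, restart delay
#' 11 min), \code{rts1_rrfb_adh} (0.9, 11 min), \code{rts1_rrfb_pku70d}
#' (0.7, 14 min), \code{inverted}, \code{tandem} and \code{barrier_off}
#' (all arrest probabilities 0).
#'
#' @param scenario scenario name.
#' @param dir output directory.
#' @param depth expected counts per bin per strand at usage 1.
#' @param nCells ensemble size.
#' @param seed master seed (drives both the simulation and the Poisson
#'   noise).
#' @param overrides named list applied to the restart barriers before
#'   simulation: any of \code{delay}, \code{arrestProbability},
#'   \code{restartOffset}, \code{restartVelocity}.
#' @param binSize analysis window in bp (see \code{\link{presetLocus}}).
#' @param params base \code{\link{SimulationParams}}.
#' @return invisibly, a list with \code{dir}, \code{paths},
#'   \code{truthFile}, \code{counts} and the generating \code{config}.
#' @export
makeScenarioDataset <- function(scenario = names(.DATASETS), dir,
                                depth = 100, nCells = 1000L, seed = 1L,
                                overrides = list(), binSize = 300,
                                params = SimulationParams()) {
    scenario <- match.arg(scenario)
    ds <- .DATASETS[[scenario]]
    config <- presetLocus(ds$preset, binSize = binSize)
    b <- config@barriers
    restart <- b$kind == if (is.null(ds$kind)) "restart" else ds$kind
    b$arrestProbability[restart] <- ds$p
    b$delay[restart] <- ds$delay
    for (nm in names(overrides)) {
        if (!nm %in% c("delay", "arrestProbability", "restartOffset",
                       "restartVelocity"))
            stop("unknown override: ", nm, call. = FALSE)
        b[[nm]][restart] <- overrides[[nm]]
    }
    if (scenario == "barrier_off") b$arrestProbability[] <- 0
    config <- initialize(config, barriers = b,
                         name = paste0(ds$preset, ":", scenario))
    params <- initialize(params, nCells = as.integer(nCells),
                         masterSeed = as.integer(seed))
    noise <- NoiseModel(depth = depth, background = 1,
                        seed = .cellSeed(seed, 424243L))
    prof <- simulateEnsemble(config, params)
    counts <- generateCounts(profileToTrace(prof), noise)
    paths <- writeCounts(counts, dir)
    truth <- list(
        scenario = scenario,
        preset = ds$preset,
        grid = list(chrom = config@grid@chrom, start = config@grid@start,
                    end = config@grid@end, bin_size = config@grid@binSize),
        origins = as.data.frame(config@origins),
        barriers = as.data.frame(config@barriers),
        params = list(fork_velocity = params@forkVelocity,
                      n_cells = params@nCells,
                      master_seed = params@masterSeed,
                      alpha_fraction = params@alphaFraction),
        noise = list(depth = noise@depth, background = noise@background,
                     seed = noise@seed))
    truthFile <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, truthFile, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(list(dir = dir, paths = paths, truthFile = truthFile,
                   counts = counts, config = config, params = params,
                   noise = noise))
}

#' Read a scenario truth file
#'
#' Reconstructs the generating objects recorded by
#' \code{\link{makeScenarioDataset}}; regenerating with them reproduces
#' the dataset bit-exactly.
#'
#' @param path path to a \code{truth.json}.
#' @return list with \code{scenario}, \code{config}, \code{params} and
#'   \code{noise}.
#' @export
readTruth <- function(path) {
    tr <- jsonlite::read_json(path, simplifyVector = TRUE)
    g <- tr$grid
    grid <- BinGrid(g$chrom, g$start, g$end, g$bin_size)
    o <- tr$origins
    origins <- Origin(o$position, o$efficiency, o$meanFiringTime,
                      o$firingTimeSD, o$suppressed)
    b <- tr$barriers
    barriers <- if (is.null(b) || !length(b)) Barrier(numeric(0), character(0))
        else Barrier(b$position, b$blocksDirection, b$kind,
                     b$arrestProbability, b$delay, b$restartOffset,
                     restartVelocity = if (is.null(b$restartVelocity))
                         NA_real_ else b$restartVelocity,
                     appliesTo = b$appliesTo)
    list(scenario = tr$scenario,
         config = LocusConfig(paste0(tr$preset, ":", tr$scenario), grid,
                              origins, barriers),
         params = SimulationParams(tr$params$fork_velocity,
                                   tr$params$n_cells,
                                   tr$params$master_seed,
                                   tr$params$alpha_fraction),
         noise = NoiseModel(tr$noise$depth, tr$noise$background,
                            tr$noise$seed))
}
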