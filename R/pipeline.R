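#' @include AllClasses.R AllGenerics.R simulate.R traces.R fitting.R synthetic.R
#' @importFrom tools md5sum
NULL

## every pipeline run writes one manifest.json describing how to redo it
.writeManifest <- function(outDir, command, args, seeds, outputs) {
    configHash <- if (!is.null(args$config) && file.exists(args$config))
        unname(tools::md5sum(args$config)) else NA_character_
    manifest <- list(command = command, arguments = args,
                     config_md5 = configHash, seeds = seeds,
                     package = "replifork",
                     version = as.character(utils::packageVersion("replifork")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     outputs = outputs)
    path <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

.resolveConfig <- function(preset = NULL, config = NULL) {
    if (!is.null(config)) {
        loaded <- loadConfig(config)
        list(config = loaded$config, params = loaded$params,
             source = config)
    } else if (!is.null(preset)) {
        list(config = presetLocus(preset), params = SimulationParams(),
             source = preset)
    } else stop("either 'preset' or 'config' must be given", call. = FALSE)
}

#' Run the simulation pipeline stage
#'
#' Simulates an ensemble at a preset or configured locus and writes the
#' replication profile (\code{profile.tsv}), the usage trace channel
#' files and a run manifest into \code{outDir}. Reruns with identical
#' arguments produce identical files (the manifest's timestamp aside).
#'
#' @param outDir output directory.
#' @param preset preset name (see \code{\link{presetLocus}}).
#' @param config path to a YAML config (overrides \code{preset}).
#' @param nCells ensemble size.
#' @param seed master seed.
#' @return invisibly, a list with the profile, trace and written paths.
#' @export
runSimulate <- function(outDir, preset = NULL, config = NULL,
                        nCells = 1000L, seed = 1L) {
    rc <- .resolveConfig(preset, config)
    params <- initialize(rc$params, nCells = as.integer(nCells),
                         masterSeed = as.integer(seed))
    prof <- simulateEnsemble(rc$config, params)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    grid <- prof@grid
    s <- binStarts(grid)
    df <- data.frame(chrom = grid@chrom, start = s, end = s + grid@binSize,
                     frac_rightward = prof@fracRightward,
                     frac_restarted = prof@fracRestarted,
                     mean_time = prof@meanReplicationTime)
    for (st in c("Watson", "Crick"))
        for (p in c("epsilon", "delta", "alpha"))
            df[[paste0("usage_", p, "_", tolower(st))]] <- prof@usage[, st, p]
    profilePath <- file.path(outDir, "profile.tsv")
    write.table(df, profilePath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    trace <- profileToTrace(prof)
    writeTrace(trace, outDir)
    .writeManifest(outDir, "simulate",
                   list(preset = preset, config = config, n_cells = nCells),
                   seeds = list(master_seed = seed),
                   outputs = list(profile = profilePath, trace_dir = outDir))
    invisible(list(profile = prof, trace = trace, profilePath = profilePath,
                   dir = outDir))
}

#' Compute usage traces from count files
#'
#' Reads the count tracks under \code{countsDir}, computes the usage
#' trace and writes the trace channel files plus a manifest to
#' \code{outDir}.
#'
#' @param countsDir directory holding count bedGraphs (see
#'   \code{\link{puseqFileSet}}).
#' @param outDir output directory.
#' @param grid the \code{\link{BinGrid}} of the counts.
#' @param minDepth minimum raw delta + epsilon count per bin.
#' @return invisibly, the \code{\link{PuSeqTrace}}.
#' @export
runTraces <- function(countsDir, outDir, grid, minDepth = 10) {
    counts <- readCounts(puseqFileSet(countsDir), grid,
                         libraryTotals = readLibraryTotals(countsDir))
    trace <- computeUsage(counts, minDepth)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTrace(trace, outDir)
    .writeManifest(outDir, "traces",
                   list(counts_dir = countsDir, min_depth = minDepth),
                   seeds = list(), outputs = list(trace_dir = outDir))
    invisible(trace)
}

#' Overlay several trace sets for plotting
#'
#' Combines two or more trace sets sharing one grid into a long-format
#' TSV (bin_start, channel, strand, dataset, value), the shape expected
#' by plotting front ends for overlays of e.g. barrier-on versus
#' barrier-off traces.
#'
#' @param traceDirs named character vector of directories previously
#'   written by \code{\link{writeTrace}}; names label the datasets.
#' @param outFile output TSV path.
#' @return invisibly, the combined data frame.
#' @export
runOverlay <- function(traceDirs, outFile) {
    if (length(traceDirs) < 2)
        stop("at least two trace sets are required", call. = FALSE)
    if (is.null(names(traceDirs)) || any(!nzchar(names(traceDirs))))
        names(traceDirs) <- paste0("dataset", seq_along(traceDirs))
    traces <- lapply(traceDirs, readTrace)
    g0 <- traces[[1]]@grid
    for (tr in traces[-1]) {
        g <- tr@grid
        if (g@start != g0@start || g@end != g0@end ||
            g@binSize != g0@binSize)
            stop("grid mismatch between trace sets", call. = FALSE)
    }
    rows <- list()
    for (nm in names(traces)) {
        tr <- traces[[nm]]
        chans <- list(usage_delta = tr@usageDelta,
                      usage_epsilon = tr@usageEpsilon,
                      alpha_overlay = tr@alphaOverlay)
        for (ch in names(chans)) for (st in .STRANDS) {
            v <- chans[[ch]][, st]
            if (all(is.na(v))) next
            rows[[length(rows) + 1L]] <- data.frame(
                bin_start = binStarts(g0), channel = ch,
                strand = st, dataset = nm, value = v)
        }
    }
    out <- do.call(rbind, rows)
    dir.create(dirname(outFile), showWarnings = FALSE, recursive = TRUE)
    write.table(out, outFile, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(out)
}

#' Run a fitting scenario from count files
#'
#' Reads observed counts, computes the usage trace and runs the
#' pre-registered \code{\link{scenarioFits}} line search, writing the full
#' grid/objective table as JSON.
#'
#' @param scenario scenario name (see \code{\link{scenarioFits}}).
#' @param observedDir directory with observed count bedGraphs.
#' @param outFile output JSON path.
#' @param nCells,validationNCells,seed search parameters.
#' @param minDepth masking threshold for the observed counts.
#' @return invisibly, the \code{\link{FitResult}}.
#' @export
runFit <- function(scenario, observedDir, outFile, nCells = 1000L,
                   validationNCells = 10000L, seed = 1L, minDepth = 10) {
    sc <- .SCENARIOS[[match.arg(scenario, names(.SCENARIOS))]]
    grid <- presetLocus(sc$preset)@grid
    counts <- readCounts(puseqFileSet(observedDir), grid,
                         libraryTotals = readLibraryTotals(observedDir))
    observed <- computeUsage(counts, minDepth)
    fit <- scenarioFits(scenario, observed, nCells = nCells,
                        validationNCells = validationNCells,
                        masterSeed = seed)
    out <- list(scenario = scenario, parameter = fit@spec@parameter,
                grid = fit@grid, objectives = fit@objectives,
                best_value = fit@bestValue,
                best_objective = fit@bestObjective,
                validation_objective = fit@validationObjective,
                tie = fit@tie, seed = fit@seed,
                n_cells = fit@spec@nCells,
                validation_n_cells = fit@spec@validationNCells,
                roi = fit@spec@roi, channels = fit@spec@channels,
                smoothing = fit@spec@smoothing)
    dir.create(dirname(outFile), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(out, outFile, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    .writeManifest(dirname(outFile), "fit",
                   list(scenario = scenario, observed_dir = observedDir,
                        n_cells = nCells,
                        validation_n_cells = validationNCells),
                   seeds = list(master_seed = seed),
                   outputs = list(fit = outFile))
    invisible(fit)
}

#' Generate a synthetic scenario dataset (pipeline stage)
#'
#' Thin wrapper over \code{\link{makeScenarioDataset}} that also writes a
#' run manifest.
#'
#' @param scenario dataset scenario name.
#' @param outDir output directory.
#' @param depth,nCells,seed generator settings.
#' @return invisibly, the \code{\link{makeScenarioDataset}} result.
#' @export
runSynth <- function(scenario, outDir, depth = 100, nCells = 1000L,
                     seed = 1L) {
    res <- makeScenarioDataset(scenario, outDir, depth = depth,
                               nCells = nCells, seed = seed)
    .writeManifest(outDir, "synth",
                   list(scenario = scenario, depth = depth,
                        n_cells = nCells),
                   seeds = list(master_seed = seed),
                   outputs = list(counts_dir = outDir,
                                  truth = res$truthFile))
    invisible(res)
}
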