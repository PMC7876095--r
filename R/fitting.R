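#' @include AllClasses.R AllGenerics.R simulate.R traces.R
NULL

.channelMatrix <- function(trace, channel) {
    parts <- strsplit(channel, ":", fixed = TRUE)[[1]]
    stopifnot(parts[1] == "delta")
    trace@usageDelta[, parts[2]]
}

#' Model-data discrepancy (Euclidean norm)
#'
#' The Euclidean norm of the difference between a predicted and an
#' observed trace over the region of interest: the square root of the sum
#' of squared per-bin differences across the selected channels. Bins
#' masked in the observed trace are excluded from both vectors.
#'
#' @param predicted,observed \code{\link{PuSeqTrace}} objects on the same
#'   grid.
#' @param roi bp interval \code{c(lo, hi)}.
#' @param channels usage channels entering the norm (default Pol delta on
#'   both strands; epsilon is redundant given the closure).
#' @return a non-negative scalar.
#' @examples
#' # identical traces give 0 by construction
#' @export
modelError <- function(predicted, observed, roi = NULL,
                       channels = c("delta:Watson", "delta:Crick")) {
    stopifnot(is(predicted, "PuSeqTrace"), is(observed, "PuSeqTrace"))
    gp <- predicted@grid; go <- observed@grid
    if (gp@start != go@start || gp@end != go@end ||
        gp@binSize != go@binSize)
        stop("input error: predicted and observed traces are on ",
             "different grids", call. = FALSE)
    if (is.null(roi)) roi <- c(gp@start, gp@end)
    m <- binMidpoints(gp)
    inRoi <- m >= roi[1] & m <= roi[2]
    ss <- 0
    nUsed <- 0L
    for (ch in channels) {
        st <- strsplit(ch, ":", fixed = TRUE)[[1]][2]
        keep <- inRoi & !observed@mask[, st] & !predicted@mask[, st]
        nUsed <- nUsed + sum(keep)
        d <- .channelMatrix(predicted, ch)[keep] -
             .channelMatrix(observed, ch)[keep]
        ss <- ss + sum(d^2)
    }
    if (nUsed == 0L)
        stop("input error: no unmasked bins in the region of interest",
             call. = FALSE)
    sqrt(ss)
}

## build the config variant for one candidate parameter value
.applyFitValue <- function(config, spec, value) {
    b <- config@barriers
    j <- spec@targetBarrier
    if (j < 1L || j > nrow(b))
        stop("input error: target barrier ", j, " not present",
             call. = FALSE)
    switch(spec@parameter,
        delay = ,
        pause_delay = { b$delay[j] <- value },
        arrest_probability = { b$arrestProbability[j] <- value },
        restart_velocity = { b$restartVelocity[j] <- value },
        restart_offset = { b$restartOffset[j] <- -abs(value) },
        second_barrier_delay = {
            extra <- Barrier(b$position[j], b$blocksDirection[j],
                             kind = "pause", arrestProbability = 1,
                             delay = value, appliesTo = "restarted")
            b <- rbind(b, extra)
        })
    initialize(config, barriers = b)
}

#' Line search of a single barrier parameter
#'
#' For each candidate value on the grid, the modified locus is simulated
#' (\code{\link{simulateEnsemble}} with common random numbers: the same
#' master seed at every grid point, so the objective differences reflect
#' the parameter and not Monte Carlo noise), converted to trace space,
#' smoothed identically to the observed trace, and scored with
#' \code{\link{modelError}}. The arg-min is returned together with a
#' validation rerun of the best value at \code{validationNCells} cells and
#' a fresh seed. Ties are broken toward the smallest grid value and
#' flagged.
#'
#' @param spec a \code{\link{FitSpec}}.
#' @param config the base \code{\link{LocusConfig}}.
#' @param params base \code{\link{SimulationParams}} (cell counts and seed
#'   are taken from \code{spec}).
#' @param observed the observed \code{\link{PuSeqTrace}}.
#' @return a \code{\link{FitResult}}.
#' @export
lineSearch <- function(spec, config, params = SimulationParams(), observed) {
    stopifnot(is(spec, "FitSpec"), is(config, "LocusConfig"),
              is(observed, "PuSeqTrace"))
    validObject(spec)
    smooth <- all(is.finite(spec@smoothing))
    obsS <- if (smooth)
        smoothTrace(observed, spec@smoothing[1], spec@smoothing[2])
    else observed
    runOne <- function(value, nCells, seed) {
        cfg <- .applyFitValue(config, spec, value)
        p <- initialize(params, nCells = as.integer(nCells),
                        masterSeed = as.integer(seed))
        prof <- tryCatch(simulateEnsemble(cfg, p), error = function(e)
            stop("simulation failed at ", spec@parameter, " = ", value,
                 ": ", conditionMessage(e), call. = FALSE))
        tr <- profileToTrace(prof)
        if (smooth) tr <- smoothTrace(tr, spec@smoothing[1], spec@smoothing[2])
        modelError(tr, obsS, spec@roi, spec@channels)
    }
    obj <- vapply(spec@grid, runOne, numeric(1), nCells = spec@nCells,
                  seed = spec@masterSeed)
    k <- which.min(obj)
    validationSeed <- .cellSeed(spec@masterSeed, 104729L)
    vObj <- runOne(spec@grid[k], spec@validationNCells, validationSeed)
    new("FitResult", spec = spec, grid = spec@grid, objectives = obj,
        bestValue = spec@grid[k], bestObjective = obj[k],
        validationObjective = vObj, tie = sum(obj == obj[k]) > 1L,
        seed = spec@masterSeed)
}

## pre-registered fitting scenarios: preset locus, target barrier,
## parameter, candidate grid and region of interest for each analysis
.SCENARIOS <- list(
    rrfb_delay = list(preset = "rrfb_only", parameter = "pause_delay",
                      target = 1L, grid = 0:15, roi = c(14000, 45000)),
    rts1_delay = list(preset = "rts1_rrfb", parameter = "delay",
                      target = 1L, grid = 0:20, roi = c(11000, 45000)),
    rts1_efficiency = list(preset = "rts1_rrfb",
                           parameter = "arrest_probability", target = 1L,
                           grid = seq(0, 1, by = 0.05),
                           roi = c(11000, 45000)),
    second_barrier_delay = list(preset = "tandem_rts1",
                                parameter = "second_barrier_delay",
                                target = 2L, grid = 0:30,
                                roi = c(11000, 45000)),
    pku70_delay = list(preset = "rts1_rrfb", parameter = "delay",
                       target = 1L, grid = 0:25, roi = c(11000, 45000)),
    restart_offset = list(preset = "rts1_rrfb",
                          parameter = "restart_offset", target = 1L,
                          grid = seq(0, 1000, by = 50),
                          roi = c(11000, 18000)))

#' Pre-registered fitting scenarios
#'
#' Runs \code{\link{lineSearch}} with the pre-registered specification of
#' one of the standard analyses: the rRFB pause delay
#' (\code{"rrfb_delay"}, grid 0-15 min), the RTS1 restart delay
#' (\code{"rts1_delay"}, 0-20 min), the RTS1 arrest efficiency
#' (\code{"rts1_efficiency"}, 0-1 by 0.05), the hypothetical delay of
#' HR-restarted forks at a second RTS1 copy
#' (\code{"second_barrier_delay"}, 0-30 min on the tandem locus), the
#' restart delay in a pku70 deletion background (\code{"pku70_delay"},
#' 0-25 min) and the upstream shift of the restart position
#' (\code{"restart_offset"}, 0-1000 bp by 50).
#'
#' @param scenario scenario name (see above).
#' @param observed observed \code{\link{PuSeqTrace}} for the matching
#'   preset locus.
#' @param nCells,validationNCells,masterSeed forwarded into the
#'   \code{\link{FitSpec}}.
#' @param params base \code{\link{SimulationParams}}.
#' @return a \code{\link{FitResult}}.
#' @export
scenarioFits <- function(scenario = names(.SCENARIOS), observed,
                         nCells = 1000L, validationNCells = 10000L,
                         masterSeed = 1L, params = SimulationParams()) {
    scenario <- match.arg(scenario)
    sc <- .SCENARIOS[[scenario]]
    config <- presetLocus(sc$preset)
    g <- config@grid; go <- observed@grid
    if (g@start != go@start || g@end != go@end || g@binSize != go@binSize)
        stop("input error: observed trace grid does not match the '",
             sc$preset, "' preset locus", call. = FALSE)
    spec <- FitSpec(parameter = sc$parameter, grid = sc$grid, roi = sc$roi,
                    targetBarrier = sc$target, nCells = nCells,
                    validationNCells = validationNCells,
                    masterSeed = masterSeed)
    lineSearch(spec, config, params, observed)
}
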