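#' @include AllClasses.R AllGenerics.R
#' @useDynLib replifork, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif qnorm pnorm rpois setNames
NULL

## snap a bp position to the nearest bin boundary of the grid
.snap <- function(pos, grid) {
    p <- grid@start + round((pos - grid@start) / grid@binSize) * grid@binSize
    pmin(pmax(p, grid@start), grid@end)
}

## run `code` with the RNG seeded to `seed`, restoring global RNG state
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

## derive the seed of cell i from the master seed (order-independent streams)
.cellSeed <- function(master, i) {
    m <- as.numeric(master) %% 2147483647
    as.integer((m * 48271 + as.numeric(i) * 1664525 + 1013904223) %%
               2147483647)
}

## Pre-draw every stochastic quantity a cell needs:
##  - one competence uniform per origin (redrawn wholesale until some origin
##    is competent; the redraw count is returned),
##  - one truncated-normal firing time per competent origin,
##  - one arrest uniform per origin lineage x barrier.
.drawCell <- function(origins, nBarriers, seed, maxResample = 1000L) {
    .withSeed(seed, {
        nO <- nrow(origins)
        resamples <- 0L
        repeat {
            competent <- runif(nO) < origins$efficiency & !origins$suppressed
            if (any(competent)) break
            resamples <- resamples + 1L
            if (resamples >= maxResample)
                stop("simulation error: no origin competent after ",
                     maxResample, " redraws", call. = FALSE)
        }
        m <- origins$meanFiringTime[competent]
        s <- origins$firingTimeSD[competent]
        u <- runif(sum(competent))
        fire <- ifelse(s > 0,
                       qnorm(pnorm(0, m, s) + u * (1 - pnorm(0, m, s)), m, s),
                       m)
        U <- matrix(runif(nO * nBarriers), nrow = nO, ncol = nBarriers)
        list(competent = competent, fire = fire, U = U,
             resamples = resamples)
    })
}

## common geometry/parameter preparation shared by both engines
.prepSim <- function(config, params) {
    grid <- config@grid
    o <- as.data.frame(config@origins)
    b <- as.data.frame(config@barriers)
    o$position <- .snap(o$position, grid)
    b$position <- if (nrow(b)) .snap(b$position, grid) else numeric(0)
    list(grid = grid, origins = o, barriers = b,
         v = params@forkVelocity * 1000,
         barVel = b$restartVelocity * 1000,
         barDir = ifelse(b$blocksDirection == "rightward", 1L, -1L),
         barKind = ifelse(b$kind == "restart", 1L, 0L),
         barApplies = match(b$appliesTo,
                            c("canonical", "restarted", "both")) - 1L)
}

#' Simulate replication of one cell
#'
#' Event-driven, continuous-time Monte Carlo simulation of a single cell's
#' S phase at the configured locus: competent origins fire unless passively
#' replicated first, forks progress at the canonical velocity, arrest at
#' susceptible barriers, pause or HR-restart after the barrier delay, are
#' rescued by converging forks, and terminate where converging
#' trajectories meet. See \code{\link{Barrier}} for the barrier semantics.
#'
#' @param config a \code{\link{LocusConfig}}.
#' @param params a \code{\link{SimulationParams}}.
#' @param cellSeed integer seed for this cell's random draws.
#' @return a \code{\link{CellOutcome}}.
#' @examples
#' cfg <- LocusConfig("toy", BinGrid("chr", 0, 20000, 300),
#'                    origins = Origin(10000))
#' simulateCell(cfg, SimulationParams(), cellSeed = 1)
#' @seealso \code{\link{simulateEnsemble}},
#'   \code{\link{simulateCellFixedStep}} (independent fixed-step engine)
#' @export
simulateCell <- function(config, params = SimulationParams(), cellSeed = 1L) {
    stopifnot(is(config, "LocusConfig"), is(params, "SimulationParams"))
    validObject(config)
    validObject(params)
    pp <- .prepSim(config, params)
    draws <- .drawCell(pp$origins, nrow(pp$barriers), cellSeed)
    .runCellEvent(pp, draws, config@grid)
}

.runCellEvent <- function(pp, draws, grid) {
    comp <- which(draws$competent)
    out <- .simCellEvent(grid@start, grid@binSize, nBins(grid), pp$v,
                         pp$origins$position[comp], draws$fire,
                         comp - 1L,
                         pp$barriers$position, pp$barDir, pp$barKind,
                         pp$barriers$arrestProbability,
                         pp$barriers$delay, pp$barriers$restartOffset,
                         pp$barApplies, pp$barVel, draws$U)
    new("CellOutcome", grid = grid, replicationTime = out$time,
        direction = out$dir, forkType = out$type,
        resamples = draws$resamples)
}

#' Simulate a cell ensemble and aggregate polymerase usage
#'
#' Runs \code{\link{simulateCell}} for \code{nCells} independent cells
#' (per-cell seeds derived deterministically from the master seed, so
#' ensembles are reproducible and order-independent) and aggregates
#' per-bin fractions. Polymerase usage is mapped per cell and bin:
#' a canonical rightward fork puts Pol epsilon on the Watson strand
#' (leading) and Pol delta on the Crick strand (lagging, of which a
#' fraction \code{alphaFraction} is attributed to Pol alpha); a canonical
#' leftward fork is the mirror image; an HR-restarted fork puts Pol delta
#' on both strands with no Pol alpha.
#'
#' @inheritParams simulateCell
#' @return a \code{\link{ReplicationProfile}}.
#' @examples
#' prof <- simulateEnsemble(presetLocus("rts1_rrfb"),
#'                          SimulationParams(nCells = 50, masterSeed = 7))
#' max(fracRestarted(prof))
#' @export
simulateEnsemble <- function(config, params = SimulationParams()) {
    stopifnot(is(config, "LocusConfig"), is(params, "SimulationParams"))
    validObject(config)
    validObject(params)
    pp <- .prepSim(config, params)
    grid <- config@grid
    n <- nBins(grid)
    nc <- params@nCells
    canR <- canL <- resR <- resL <- numeric(n)
    sumT <- numeric(n)
    resampled <- 0L
    for (i in seq_len(nc)) {
        draws <- tryCatch(
            .drawCell(pp$origins, nrow(pp$barriers),
                      .cellSeed(params@masterSeed, i)),
            error = function(e)
                stop("cell ", i, ": ", conditionMessage(e), call. = FALSE))
        cell <- tryCatch(.runCellEvent(pp, draws, grid),
            error = function(e)
                stop("cell ", i, ": ", conditionMessage(e), call. = FALSE))
        resampled <- resampled + cell@resamples
        right <- cell@direction > 0L
        restarted <- cell@forkType > 0L
        canR <- canR + (right & !restarted)
        canL <- canL + (!right & !restarted)
        resR <- resR + (right & restarted)
        resL <- resL + (!right & restarted)
        sumT <- sumT + cell@replicationTime
    }
    a <- params@alphaFraction
    res <- resR + resL
    usage <- array(0, dim = c(n, 2L, 3L),
                   dimnames = list(NULL, c("Watson", "Crick"),
                                   c("epsilon", "delta", "alpha")))
    usage[, "Watson", "epsilon"] <- canR / nc
    usage[, "Watson", "delta"]   <- (canL * (1 - a) + res) / nc
    usage[, "Watson", "alpha"]   <- canL * a / nc
    usage[, "Crick", "epsilon"]  <- canL / nc
    usage[, "Crick", "delta"]    <- (canR * (1 - a) + res) / nc
    usage[, "Crick", "alpha"]    <- canR * a / nc
    new("ReplicationProfile", grid = grid,
        fracRightward = (canR + resR) / nc, fracRestarted = res / nc,
        meanReplicationTime = sumT / nc, usage = usage,
        nCells = as.integer(nc), seed = params@masterSeed,
        resampledCells = as.integer(resampled))
}

#' Termination midpoint of converging forks
#'
#' The ensemble-average position of fork-merger (termination) events,
#' estimated as the linearly interpolated position at which the fraction
#' of rightward-moving forks crosses 0.5 within a window.
#'
#' @param profile a \code{\link{ReplicationProfile}}.
#' @param window bp interval \code{c(lo, hi)} to search; defaults to the
#'   whole grid.
#' @return interpolated bp position of the 0.5 crossing (the first one if
#'   several occur in the window).
#' @export
terminationMidpoint <- function(profile, window = NULL) {
    stopifnot(is(profile, "ReplicationProfile"))
    grid <- profile@grid
    if (is.null(window)) window <- c(grid@start, grid@end)
    m <- binMidpoints(grid)
    keep <- m >= window[1] & m <= window[2]
    if (sum(keep) < 2)
        stop("window contains fewer than two bins", call. = FALSE)
    .interpCrossing(m[keep], profile@fracRightward[keep], 0.5,
                    what = "termination midpoint")
}

## first interpolated crossing of `values` through `level` along `x`
.interpCrossing <- function(x, values, level, what = "crossing") {
    d <- values - level
    hit <- which(d == 0)
    cross <- which(d[-length(d)] * d[-1] < 0)
    if (length(hit) && (!length(cross) || hit[1] <= cross[1]))
        return(x[hit[1]])
    if (!length(cross))
        stop(what, " not found: no crossing of ", level,
             " in the window", call. = FALSE)
    k <- cross[1]
    x[k] + (level - values[k]) * (x[k + 1] - x[k]) /
        (values[k + 1] - values[k])
}
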