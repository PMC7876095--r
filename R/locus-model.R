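#' @include AllClasses.R AllGenerics.R
NULL

## config file schema: snake_case keys, one YAML mapping per file.
## top level: name, grid, origins, barriers, params
.CONFIG_KEYS <- list(
    top = c("name", "grid", "origins", "barriers", "params"),
    grid = c("chrom", "start", "end", "bin_size"),
    origin = c("position", "efficiency", "mean_firing_time",
               "firing_time_sd", "suppressed"),
    barrier = c("position", "blocks_direction", "kind", "arrest_probability",
                "delay", "restart_offset", "canonical_only",
                "restart_velocity", "applies_to"),
    params = c("fork_velocity", "n_cells", "master_seed", "alpha_fraction"))

.checkKeys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
        stop("config validation: unknown key(s) in ", where, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
}

.getOr <- function(x, key, default) if (!is.null(x[[key]])) x[[key]] else default

#' Load a locus configuration file
#'
#' Reads a YAML locus description (grid, origins, barriers, simulation
#' parameters) and returns fully validated objects, with documented
#' defaults applied for omitted optional fields (fork velocity 1.8 kb/min,
#' 1000 cells, Pol alpha fraction 0.1, bin size 300 bp). The schema keys
#' are the snake_case field names documented in \code{\link{Origin}},
#' \code{\link{Barrier}}, \code{\link{BinGrid-class}} and
#' \code{\link{SimulationParams-class}}; unknown or out-of-range values
#' raise a validation error naming the offending keys.
#'
#' @param path path to a YAML config file.
#' @return a list with elements \code{config} (a \code{\link{LocusConfig}})
#'   and \code{params} (a \code{\link{SimulationParams}}).
#' @seealso \code{\link{writeConfig}}, \code{\link{presetLocus}}
#' @export
loadConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path, call. = FALSE)
    raw <- yaml::read_yaml(path)
    .checkKeys(raw, .CONFIG_KEYS$top, "top level")
    g <- .getOr(raw, "grid", list())
    .checkKeys(g, .CONFIG_KEYS$grid, "grid")
    if (is.null(g$start) || is.null(g$end))
        stop("config validation: grid requires keys 'start' and 'end'",
             call. = FALSE)
    grid <- BinGrid(chrom = .getOr(g, "chrom", "locus"), start = g$start,
                    end = g$end, binSize = .getOr(g, "bin_size", 300))

    oList <- .getOr(raw, "origins", list())
    origins <- if (length(oList)) {
        rows <- lapply(seq_along(oList), function(i) {
            o <- oList[[i]]
            .checkKeys(o, .CONFIG_KEYS$origin, paste0("origins[", i, "]"))
            if (is.null(o$position))
                stop("config validation: origins[", i, "] missing 'position'",
                     call. = FALSE)
            Origin(position = o$position,
                   efficiency = .getOr(o, "efficiency", 1),
                   meanFiringTime = .getOr(o, "mean_firing_time", 0),
                   firingTimeSD = .getOr(o, "firing_time_sd", 0),
                   suppressed = .getOr(o, "suppressed", FALSE))
        })
        do.call(rbind, rows)
    } else Origin(numeric(0))

    bList <- .getOr(raw, "barriers", list())
    barriers <- if (length(bList)) {
        rows <- lapply(seq_along(bList), function(i) {
            b <- bList[[i]]
            .checkKeys(b, .CONFIG_KEYS$barrier, paste0("barriers[", i, "]"))
            if (is.null(b$position) || is.null(b$blocks_direction))
                stop("config validation: barriers[", i,
                     "] requires 'position' and 'blocks_direction'",
                     call. = FALSE)
            rv <- .getOr(b, "restart_velocity", "inherit")
            rv <- if (identical(rv, "inherit")) NA_real_ else as.numeric(rv)
            Barrier(position = b$position,
                    blocksDirection = b$blocks_direction,
                    kind = .getOr(b, "kind", "restart"),
                    arrestProbability = .getOr(b, "arrest_probability", 1),
                    delay = .getOr(b, "delay", 0),
                    restartOffset = .getOr(b, "restart_offset", 0),
                    canonicalOnly = b$canonical_only,
                    restartVelocity = rv,
                    appliesTo = b$applies_to)
        })
        do.call(rbind, rows)
    } else Barrier(numeric(0), character(0))

    p <- .getOr(raw, "params", list())
    .checkKeys(p, .CONFIG_KEYS$params, "params")
    params <- SimulationParams(
        forkVelocity = .getOr(p, "fork_velocity", 1.8),
        nCells = .getOr(p, "n_cells", 1000L),
        masterSeed = .getOr(p, "master_seed", 1L),
        alphaFraction = .getOr(p, "alpha_fraction", 0.1))

    config <- LocusConfig(name = .getOr(raw, "name", "locus"), grid = grid,
                          origins = origins, barriers = barriers)
    list(config = config, params = params)
}

#' Write a locus configuration file
#'
#' Serialises a \code{\link{LocusConfig}} (and optionally
#' \code{\link{SimulationParams}}) to the YAML schema read by
#' \code{\link{loadConfig}}; the two round-trip to equal objects.
#'
#' @param config a \code{\link{LocusConfig}}.
#' @param path output file path.
#' @param params optional \code{\link{SimulationParams}}.
#' @return \code{path}, invisibly.
#' @export
writeConfig <- function(config, path, params = NULL) {
    stopifnot(is(config, "LocusConfig"))
    g <- config@grid
    o <- as.data.frame(config@origins)
    b <- as.data.frame(config@barriers)
    out <- list(
        name = config@name,
        grid = list(chrom = g@chrom, start = g@start, end = g@end,
                    bin_size = g@binSize),
        origins = lapply(seq_len(nrow(o)), function(i) list(
            position = o$position[i], efficiency = o$efficiency[i],
            mean_firing_time = o$meanFiringTime[i],
            firing_time_sd = o$firingTimeSD[i],
            suppressed = o$suppressed[i])),
        barriers = lapply(seq_len(nrow(b)), function(i) list(
            position = b$position[i],
            blocks_direction = b$blocksDirection[i],
            kind = b$kind[i],
            arrest_probability = b$arrestProbability[i],
            delay = b$delay[i],
            restart_offset = b$restartOffset[i],
            applies_to = b$appliesTo[i],
            restart_velocity = if (is.na(b$restartVelocity[i])) "inherit"
                               else b$restartVelocity[i])))
    if (!is.null(params))
        out$params <- list(fork_velocity = params@forkVelocity,
                           n_cells = params@nCells,
                           master_seed = params@masterSeed,
                           alpha_fraction = params@alphaFraction)
    yaml::write_yaml(out, path)
    invisible(path)
}

#' Preset locus configurations
#'
#' Fixture geometries approximating the engineered constructs analysed by
#' this package. Positions are synthetic coordinates on \code{"chrII_sim"}
#' (the real constructs sit on S. pombe chromosome II; only the relative
#' distances matter to the model):
#' \describe{
#'   \item{\code{rts1_rrfb}}{an efficient early origin; the RTS1 barrier
#'     (blocks rightward forks, restart kind, arrest probability 0.7,
#'     delay 11 min) 3 kb downstream; the rRFB pause barrier (blocks
#'     leftward forks, delay 6 min) 12 kb beyond RTS1; a late origin 30 kb
#'     from the early origin; flanking origins outside the region of
#'     interest.}
#'   \item{\code{rts1_only}}{as above without the rRFB.}
#'   \item{\code{tandem_rts1}}{as \code{rts1_rrfb} plus a second RTS1 copy
#'     in the same orientation 1.8 kb downstream of the first.}
#'   \item{\code{inverted_rts1}}{two RTS1 copies in opposing orientations
#'     30 kb apart with no origin in between, isolating an origin-free
#'     region replicated only by HR-restarted forks.}
#'   \item{\code{rrfb_only}}{the rRFB calibration construct: the pause
#'     barrier alone, oriented against the forks emerging from a strong
#'     early origin, used to estimate the pause delay from the shift of
#'     the termination zone.}
#' }
#'
#' @param name one of \code{"rts1_rrfb"}, \code{"rts1_only"},
#'   \code{"tandem_rts1"}, \code{"inverted_rts1"}.
#' @param binSize analysis window in bp (default 300; use finer windows,
#'   e.g. 100, to resolve sub-window shifts of the restart position).
#' @return a \code{\link{LocusConfig}}.
#' @examples
#' presetLocus("rts1_rrfb")
#' @export
presetLocus <- function(name = c("rts1_rrfb", "rts1_only", "tandem_rts1",
                                 "inverted_rts1", "rrfb_only"),
                        binSize = 300) {
    name <- match.arg(name)
    grid <- BinGrid("chrII_sim", 0, 60000, binSize)
    flanks <- Origin(position = c(1800, 57900), efficiency = c(0.5, 0.6),
                     meanFiringTime = c(10, 12), firingTimeSD = 3)
    rts1 <- function(pos, p = 0.7, dir = "rightward")
        Barrier(pos, dir, kind = "restart", arrestProbability = p,
                delay = 11, restartOffset = 0, canonicalOnly = TRUE)
    rrfb <- Barrier(25200, "leftward", kind = "pause",
                    arrestProbability = 1, delay = 6)
    switch(name,
        rts1_rrfb = LocusConfig("rts1_rrfb", grid,
            origins = rbind(flanks,
                Origin(10200, 0.9, 5, 2), Origin(40200, 0.8, 18, 3)),
            barriers = rbind(rts1(13200), rrfb)),
        rts1_only = LocusConfig("rts1_only", grid,
            origins = rbind(flanks,
                Origin(10200, 0.9, 5, 2), Origin(40200, 0.8, 18, 3)),
            barriers = rts1(13200)),
        tandem_rts1 = LocusConfig("tandem_rts1", grid,
            origins = rbind(flanks,
                Origin(10200, 0.9, 5, 2), Origin(40200, 0.8, 18, 3)),
            barriers = rbind(rts1(13200), rts1(15000), rrfb)),
        inverted_rts1 = LocusConfig("inverted_rts1", grid,
            origins = rbind(flanks,
                Origin(8100, 0.9, 5, 2), Origin(45900, 0.9, 12, 3)),
            barriers = rbind(rts1(12000, p = 0.9),
                             rts1(42000, p = 0.9, dir = "leftward"))),
        rrfb_only = LocusConfig("rrfb_only", grid,
            origins = rbind(flanks,
                Origin(10200, 0.9, 5, 2), Origin(40200, 0.8, 18, 3)),
            barriers = Barrier(16200, "rightward", kind = "pause",
                               arrestProbability = 1, delay = 6)))
}
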