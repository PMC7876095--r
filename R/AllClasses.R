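#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowRanges
NULL

#' BinGrid: the binned coordinate system of a locus
#'
#' A \code{BinGrid} describes the genomic window being modelled and its
#' division into fixed-width bins. Bins are 0-based and half-open:
#' bin \eqn{k} covers \eqn{[start + k \cdot binSize, start + (k+1) \cdot binSize)}.
#' All tracks (counts, usage traces, replication profiles) in this package
#' live on a \code{BinGrid}.
#'
#' @slot chrom single chromosome / sequence name used in track files.
#' @slot start,end domain extent in bp; \code{end - start} must be a
#'   multiple of \code{binSize}.
#' @slot binSize bin width in bp (default 300).
#'
#' @export
setClass("BinGrid",
    representation(chrom = "character", start = "numeric",
                   end = "numeric", binSize = "numeric"))

setValidity("BinGrid", function(object) {
    msg <- character()
    if (length(object@chrom) != 1L || is.na(object@chrom) || !nzchar(object@chrom))
        msg <- c(msg, "'chrom' must be a single non-empty string")
    if (length(object@start) != 1L || length(object@end) != 1L ||
        length(object@binSize) != 1L)
        msg <- c(msg, "'start', 'end', 'binSize' must be scalars")
    else {
        if (!is.finite(object@binSize) || object@binSize <= 0)
            msg <- c(msg, "'bin_size' must be > 0")
        if (!is.finite(object@start) || !is.finite(object@end) ||
            object@end <= object@start)
            msg <- c(msg, "'end' must be greater than 'start'")
        else if (is.finite(object@binSize) && object@binSize > 0 &&
                 abs(((object@end - object@start) / object@binSize) %% 1) > 1e-8)
            msg <- c(msg, "'end' - 'start' must be a whole number of bins")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname BinGrid-class
#' @param chrom,start,end,binSize see slots.
#' @return a validated \code{BinGrid}.
#' @examples
#' BinGrid("chrII_sim", 0, 60000, 300)
#' @export
BinGrid <- function(chrom = "locus", start = 0, end = 60000, binSize = 300) {
    new("BinGrid", chrom = as.character(chrom), start = as.numeric(start),
        end = as.numeric(end), binSize = as.numeric(binSize))
}

#' LocusConfig: origins, barriers and extent of the simulated locus
#'
#' Bundles the simulated world: a \code{\link{BinGrid}}, a table of
#' replication origins (see \code{\link{Origin}}) and a table of programmed
#' fork barriers (see \code{\link{Barrier}}).
#'
#' @slot name label of the construct (e.g. \code{"rts1_rrfb"}).
#' @slot grid a \code{\link{BinGrid}}.
#' @slot origins a \code{DataFrame} as built by \code{\link{Origin}}.
#' @slot barriers a \code{DataFrame} as built by \code{\link{Barrier}}.
#'
#' @export
setClass("LocusConfig",
    representation(name = "character", grid = "BinGrid",
                   origins = "DataFrame", barriers = "DataFrame"))

.validOrigins <- function(o, grid) {
    msg <- character()
    need <- c("position", "efficiency", "meanFiringTime", "firingTimeSD",
              "suppressed")
    miss <- setdiff(need, colnames(o))
    if (length(miss))
        return(paste("origins: missing columns:", paste(miss, collapse = ", ")))
    if (nrow(o)) {
        if (any(o$efficiency < 0 | o$efficiency > 1, na.rm = TRUE))
            msg <- c(msg, "origins: 'efficiency' must be in [0, 1]")
        if (any(o$meanFiringTime < 0 | o$firingTimeSD < 0, na.rm = TRUE))
            msg <- c(msg, "origins: firing time mean and sd must be >= 0")
        if (any(o$position < grid@start | o$position > grid@end))
            msg <- c(msg, "origins: 'position' outside [start, end]")
    }
    msg
}

.validBarriers <- function(b, grid) {
    msg <- character()
    need <- c("position", "blocksDirection", "kind", "arrestProbability",
              "delay", "restartOffset", "appliesTo", "restartVelocity")
    miss <- setdiff(need, colnames(b))
    if (length(miss))
        return(paste("barriers: missing columns:", paste(miss, collapse = ", ")))
    if (nrow(b)) {
        if (!all(b$blocksDirection %in% c("rightward", "leftward")))
            msg <- c(msg, "barriers: 'blocks_direction' must be rightward/leftward")
        if (!all(b$kind %in% c("restart", "pause")))
            msg <- c(msg, "barriers: 'kind' must be restart/pause")
        if (!all(b$appliesTo %in% c("canonical", "restarted", "both")))
            msg <- c(msg, "barriers: 'appliesTo' must be canonical/restarted/both")
        if (any(b$arrestProbability < 0 | b$arrestProbability > 1, na.rm = TRUE))
            msg <- c(msg, "barriers: 'arrest_probability' must be in [0, 1]")
        if (any(b$delay < 0, na.rm = TRUE))
            msg <- c(msg, "barriers: 'delay' must be >= 0")
        if (any(b$restartOffset > 0, na.rm = TRUE))
            msg <- c(msg, "barriers: 'restart_offset' must be <= 0")
        if (any(b$kind == "pause" & b$restartOffset != 0))
            msg <- c(msg, "barriers: pause barriers must have restart_offset = 0")
        if (any(b$position < grid@start | b$position > grid@end))
            msg <- c(msg, "barriers: 'position' outside [start, end]")
        if (any(!is.na(b$restartVelocity) & b$restartVelocity <= 0))
            msg <- c(msg, "barriers: 'restart_velocity' must be > 0 or \"inherit\"")
        key <- paste(b$position, b$blocksDirection, b$kind, b$appliesTo)
        if (anyDuplicated(key))
            msg <- c(msg, "barriers: duplicated position/direction/kind/appliesTo")
    }
    msg
}

setValidity("LocusConfig", function(object) {
    msg <- character()
    if (length(object@name) != 1L)
        msg <- c(msg, "'name' must be a single string")
    msg <- c(msg, .validOrigins(object@origins, object@grid))
    msg <- c(msg, .validBarriers(object@barriers, object@grid))
    if (length(msg)) msg else TRUE
})

#' Construct an origin table
#'
#' Vectorised constructor for the origin table of a \code{\link{LocusConfig}}.
#' Per cell, an unsuppressed origin is competent with probability
#' \code{efficiency}; competent origins draw a firing time from a Normal
#' distribution (mean \code{meanFiringTime}, sd \code{firingTimeSD})
#' truncated at 0 min. An origin whose position is passively replicated
#' before its firing time never fires; suppressed origins never fire.
#'
#' @param position bp coordinate (snapped to the nearest bin boundary at
#'   simulation time).
#' @param efficiency firing probability in [0, 1].
#' @param meanFiringTime,firingTimeSD minutes (>= 0).
#' @param suppressed logical; suppressed origins never fire.
#' @return a \code{DataFrame} with one row per origin.
#' @examples
#' Origin(position = c(10000, 40000), efficiency = c(0.9, 0.8),
#'        meanFiringTime = c(5, 18), firingTimeSD = c(2, 3))
#' @export
Origin <- function(position, efficiency = 1, meanFiringTime = 0,
                   firingTimeSD = 0, suppressed = FALSE) {
    n <- length(position)
    DataFrame(position = as.numeric(position),
              efficiency = rep_len(as.numeric(efficiency), n),
              meanFiringTime = rep_len(as.numeric(meanFiringTime), n),
              firingTimeSD = rep_len(as.numeric(firingTimeSD), n),
              suppressed = rep_len(as.logical(suppressed), n))
}

#' Construct a barrier table
#'
#' Vectorised constructor for the barrier table of a
#' \code{\link{LocusConfig}}. A barrier blocks forks travelling in
#' \code{blocksDirection} only; on each encounter a susceptible fork
#' arrests with probability \code{arrestProbability} (one independent draw
#' per fork lineage per barrier). \code{kind = "pause"} holds the fork for
#' \code{delay} minutes and releases it unchanged (e.g. the rRFB).
#' \code{kind = "restart"} holds it for \code{delay} minutes and releases
#' it as an HR-restarted fork at \code{position + restartOffset}
#' (\code{restartOffset <= 0}), re-replicating the offset window; the
#' restarted fork synthesises both strands with Pol delta and, when
#' \code{canonicalOnly} is \code{TRUE} (the RTS1 behaviour), is immune to
#' the barrier thereafter.
#'
#' @param position bp coordinate.
#' @param blocksDirection \code{"rightward"} or \code{"leftward"}: the fork
#'   travel direction that is blocked.
#' @param kind \code{"restart"} (RTS1-like) or \code{"pause"} (rRFB-like).
#' @param arrestProbability probability in [0, 1] that a susceptible fork
#'   arrests on encounter.
#' @param delay minutes the arrested fork is held.
#' @param restartOffset bp (<= 0); restart barriers only. 0 restarts at the
#'   barrier itself.
#' @param canonicalOnly logical; if \code{TRUE} only canonical forks are
#'   susceptible (restarted forks pass freely). Defaults to \code{TRUE} for
#'   restart barriers and \code{FALSE} for pause barriers.
#' @param restartVelocity kb/min for the restarted fork, or \code{NA}
#'   (\code{"inherit"} in config files) to keep the canonical velocity.
#' @param appliesTo advanced override of \code{canonicalOnly}:
#'   \code{"canonical"}, \code{"restarted"} or \code{"both"}. A
#'   restarted-only pause barrier is how a hypothetical delay of
#'   HR-restarted forks at a second RTS1 copy is modelled.
#' @return a \code{DataFrame} with one row per barrier.
#' @examples
#' Barrier(13000, "rightward", kind = "restart",
#'         arrestProbability = 0.7, delay = 11)
#' @export
Barrier <- function(position, blocksDirection, kind = "restart",
                    arrestProbability = 1, delay = 0, restartOffset = 0,
                    canonicalOnly = NULL, restartVelocity = NA_real_,
                    appliesTo = NULL) {
    n <- length(position)
    kind <- rep_len(as.character(kind), n)
    if (is.null(appliesTo)) {
        if (is.null(canonicalOnly))
            canonicalOnly <- kind == "restart"
        canonicalOnly <- rep_len(as.logical(canonicalOnly), n)
        appliesTo <- ifelse(canonicalOnly, "canonical", "both")
    }
    DataFrame(position = as.numeric(position),
              blocksDirection = rep_len(as.character(blocksDirection), n),
              kind = kind,
              arrestProbability = rep_len(as.numeric(arrestProbability), n),
              delay = rep_len(as.numeric(delay), n),
              restartOffset = rep_len(as.numeric(restartOffset), n),
              appliesTo = rep_len(as.character(appliesTo), n),
              restartVelocity = rep_len(as.numeric(restartVelocity), n))
}

#' @rdname LocusConfig-class
#' @param name,grid,origins,barriers see slots.
#' @return a validated \code{LocusConfig}.
#' @export
LocusConfig <- function(name, grid, origins = Origin(numeric(0)),
                        barriers = Barrier(numeric(0), character(0))) {
    new("LocusConfig", name = as.character(name), grid = grid,
        origins = origins, barriers = barriers)
}

#' SimulationParams: global parameters of the replication simulation
#'
#' @slot forkVelocity canonical fork velocity in kb/min (default 1.8).
#' @slot nCells ensemble size (default 1000; 10000 for validation runs).
#' @slot masterSeed integer seed from which per-cell substreams are derived.
#' @slot alphaFraction fraction of canonical lagging-strand synthesis
#'   attributed to Pol alpha (default 0.1); HR-restarted forks use none.
#'
#' @export
setClass("SimulationParams",
    representation(forkVelocity = "numeric", nCells = "integer",
                   masterSeed = "integer", alphaFraction = "numeric"))

setValidity("SimulationParams", function(object) {
    msg <- character()
    if (!is.finite(object@forkVelocity) || object@forkVelocity <= 0)
        msg <- c(msg, "'fork_velocity' must be > 0")
    if (is.na(object@nCells) || object@nCells < 1L)
        msg <- c(msg, "'n_cells' must be >= 1")
    if (is.na(object@alphaFraction) || object@alphaFraction < 0 ||
        object@alphaFraction > 1)
        msg <- c(msg, "'alpha_fraction' must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname SimulationParams-class
#' @param forkVelocity,nCells,masterSeed,alphaFraction see slots.
#' @export
SimulationParams <- function(forkVelocity = 1.8, nCells = 1000L,
                             masterSeed = 1L, alphaFraction = 0.1) {
    new("SimulationParams", forkVelocity = as.numeric(forkVelocity),
        nCells = as.integer(nCells), masterSeed = as.integer(masterSeed),
        alphaFraction = as.numeric(alphaFraction))
}

#' CellOutcome: one cell's per-bin replication record
#'
#' For every bin of the grid: the time (minutes) the bin was last
#' synthesised, the travel direction of the synthesising fork, and whether
#' that fork was canonical or HR-restarted.
#'
#' @slot grid the \code{\link{BinGrid}}.
#' @slot replicationTime numeric, minutes per bin.
#' @slot direction integer per bin: \code{+1} rightward, \code{-1} leftward.
#' @slot forkType integer per bin: \code{0} canonical, \code{1} restarted.
#' @slot resamples number of whole-cell redraws needed before at least one
#'   origin was competent.
#'
#' @export
setClass("CellOutcome",
    representation(grid = "BinGrid", replicationTime = "numeric",
                   direction = "integer", forkType = "integer",
                   resamples = "integer"))

setValidity("CellOutcome", function(object) {
    n <- nBins(object@grid)
    msg <- character()
    if (length(object@replicationTime) != n ||
        length(object@direction) != n || length(object@forkType) != n)
        msg <- c(msg, "per-bin vectors must have one entry per bin")
    else if (any(!is.finite(object@replicationTime)))
        msg <- c(msg, "all bins must carry a finite replication time")
    if (length(msg)) msg else TRUE
})

#' ReplicationProfile: ensemble-averaged replication statistics
#'
#' Per-bin fractions over an ensemble of simulated cells: fraction of cells
#' in which the bin was replicated by a rightward-moving fork, by an
#' HR-restarted fork, the mean replication time, and the polymerase usage
#' of each strand (epsilon / delta / alpha summing to 1 per strand).
#'
#' @slot grid the \code{\link{BinGrid}}.
#' @slot fracRightward,fracRestarted,meanReplicationTime numeric per bin.
#' @slot usage 3-d array \code{[bin, strand, polymerase]} with strands
#'   \code{Watson}/\code{Crick} and polymerases
#'   \code{epsilon}/\code{delta}/\code{alpha}.
#' @slot nCells,seed ensemble size and master seed used.
#' @slot resampledCells total whole-cell redraws across the ensemble.
#'
#' @export
setClass("ReplicationProfile",
    representation(grid = "BinGrid", fracRightward = "numeric",
                   fracRestarted = "numeric",
                   meanReplicationTime = "numeric", usage = "array",
                   nCells = "integer", seed = "integer",
                   resampledCells = "integer"))

setValidity("ReplicationProfile", function(object) {
    n <- nBins(object@grid)
    msg <- character()
    if (length(object@fracRightward) != n || length(object@fracRestarted) != n ||
        length(object@meanReplicationTime) != n)
        msg <- c(msg, "per-bin vectors must have one entry per bin")
    if (!identical(dim(object@usage), c(n, 2L, 3L)))
        msg <- c(msg, "'usage' must be a [bins x 2 strands x 3 polymerases] array")
    else {
        s <- apply(object@usage, c(1, 2), sum)
        if (any(abs(s - 1) > 1e-6))
            msg <- c(msg, "per-strand polymerase usage must sum to 1 at every bin")
    }
    if (any(object@fracRightward < -1e-9 | object@fracRightward > 1 + 1e-9))
        msg <- c(msg, "'fracRightward' must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' PuSeqCounts: binned strand-specific ribonucleotide counts
#'
#' A \code{RangedSummarizedExperiment} whose rows are the bins of a
#' \code{\link{BinGrid}} and whose columns are strain x strand libraries
#' (strains \code{pol_delta}, \code{pol_epsilon} and optionally
#' \code{pol_alpha}; strands \code{Watson}/\code{Crick}). The single assay
#' \code{"counts"} holds non-negative integers; \code{colData} carries
#' \code{strain}, \code{strand} and \code{libraryTotal}.
#'
#' @export
setClass("PuSeqCounts", contains = "RangedSummarizedExperiment")

setValidity("PuSeqCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    cd <- SummarizedExperiment::colData(object)
    need <- c("strain", "strand", "libraryTotal")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("colData: missing", paste(miss, collapse = ", ")))
    else {
        if (!all(cd$strain %in% c("pol_delta", "pol_epsilon", "pol_alpha")))
            msg <- c(msg, "strains must be pol_delta/pol_epsilon/pol_alpha")
        if (!all(cd$strand %in% c("Watson", "Crick")))
            msg <- c(msg, "strands must be Watson/Crick")
    }
    if ("counts" %in% SummarizedExperiment::assayNames(object) &&
        any(SummarizedExperiment::assay(object, "counts") < 0, na.rm = TRUE))
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' PuSeqTrace: per-strand polymerase-usage fractions
#'
#' Per bin and strand, the fraction of synthesis performed by Pol delta and
#' Pol epsilon (closing to 1 on unmasked bins), a not-to-scale Pol alpha
#' overlay (the alpha fraction multiplied by 10, following the display
#' convention for Pu-seq figures), and a mask of bins with insufficient
#' counts.
#'
#' @slot grid the \code{\link{BinGrid}}.
#' @slot usageDelta,usageEpsilon numeric matrices \code{[bin, strand]} with
#'   columns \code{Watson}, \code{Crick}.
#' @slot alphaOverlay matrix \code{[bin, strand]}, 10 x the alpha fraction
#'   (all \code{NA} when no Pol alpha data is available).
#' @slot mask logical matrix \code{[bin, strand]}; \code{TRUE} = masked.
#'
#' @export
setClass("PuSeqTrace",
    representation(grid = "BinGrid", usageDelta = "matrix",
                   usageEpsilon = "matrix", alphaOverlay = "matrix",
                   mask = "matrix"))

setValidity("PuSeqTrace", function(object) {
    n <- nBins(object@grid)
    msg <- character()
    dims <- list(object@usageDelta, object@usageEpsilon, object@alphaOverlay,
                 object@mask)
    if (!all(vapply(dims, function(m) identical(dim(m), c(n, 2L)), logical(1))))
        msg <- c(msg, "all matrices must be [bins x 2 strands]")
    else {
        ok <- !object@mask
        s <- object@usageDelta + object@usageEpsilon
        if (any(abs(s[ok] - 1) > 1e-6, na.rm = TRUE))
            msg <- c(msg, "usage_delta + usage_epsilon must equal 1 on unmasked bins")
        if (any(is.na(s[ok])))
            msg <- c(msg, "unmasked bins must not contain NA usage")
    }
    if (length(msg)) msg else TRUE
})

#' NoiseModel: sequencing-depth model for synthetic Pu-seq counts
#'
#' Counts for each strain x strand x bin are drawn independently as
#' \code{Poisson(depth * usage + background)}, where \code{usage} is the
#' strain's usage channel on that strand (the alpha strain uses the
#' un-scaled alpha fraction, i.e. \code{alphaOverlay / 10}).
#'
#' @slot depth expected counts per bin per strand at usage 1 (default 100).
#' @slot background expected stray counts per bin (default 1).
#' @slot seed integer seed.
#'
#' @export
setClass("NoiseModel",
    representation(depth = "numeric", background = "numeric",
                   seed = "integer"))

setValidity("NoiseModel", function(object) {
    msg <- character()
    if (!is.finite(object@depth) || object@depth <= 0)
        msg <- c(msg, "'depth' must be > 0")
    if (!is.finite(object@background) || object@background < 0)
        msg <- c(msg, "'background' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname NoiseModel-class
#' @param depth,background,seed see slots.
#' @export
NoiseModel <- function(depth = 100, background = 1, seed = 1L) {
    new("NoiseModel", depth = as.numeric(depth),
        background = as.numeric(background), seed = as.integer(seed))
}

#' FitSpec: a single-parameter line search specification
#'
#' @slot parameter one of \code{"delay"}, \code{"arrest_probability"},
#'   \code{"restart_velocity"}, \code{"restart_offset"},
#'   \code{"pause_delay"}, \code{"second_barrier_delay"}.
#' @slot targetBarrier 1-based index into the config's barrier table.
#' @slot grid strictly increasing candidate values. For
#'   \code{"restart_offset"} the grid is the upstream shift in bp
#'   (non-negative; applied as \code{restartOffset = -value}).
#' @slot roi bp interval \code{c(lo, hi)} entering the objective.
#' @slot channels subset of \code{"delta:Watson"}, \code{"delta:Crick"}.
#' @slot nCells,validationNCells ensemble sizes for the search and the
#'   validation rerun.
#' @slot masterSeed integer; shared across grid points (common random
#'   numbers).
#' @slot smoothing numeric \code{c(window, polyorder)} applied identically
#'   to predicted and observed channels, or \code{c(NA, NA)} for off.
#'
#' @export
setClass("FitSpec",
    representation(parameter = "character", targetBarrier = "integer",
                   grid = "numeric", roi = "numeric", channels = "character",
                   nCells = "integer", validationNCells = "integer",
                   masterSeed = "integer", smoothing = "numeric"))

setValidity("FitSpec", function(object) {
    msg <- character()
    pars <- c("delay", "arrest_probability", "restart_velocity",
              "restart_offset", "pause_delay", "second_barrier_delay")
    if (length(object@parameter) != 1L || !object@parameter %in% pars)
        msg <- c(msg, paste("'parameter' must be one of:",
                            paste(pars, collapse = ", ")))
    if (length(object@grid) < 1L || is.unsorted(object@grid, strictly = TRUE))
        msg <- c(msg, "'grid' must be non-empty and strictly increasing")
    if (length(object@roi) != 2L || object@roi[1] >= object@roi[2])
        msg <- c(msg, "'roi' must be an increasing bp interval")
    if (!all(object@channels %in% c("delta:Watson", "delta:Crick")) ||
        !length(object@channels))
        msg <- c(msg, "'channels' must be a subset of delta:Watson, delta:Crick")
    if (length(msg)) msg else TRUE
})

#' @rdname FitSpec-class
#' @param parameter,targetBarrier,grid,roi,channels,nCells,validationNCells,masterSeed,smoothing
#'   see slots.
#' @export
FitSpec <- function(parameter, grid, roi, targetBarrier = 1L,
                    channels = c("delta:Watson", "delta:Crick"),
                    nCells = 1000L, validationNCells = 10000L,
                    masterSeed = 1L, smoothing = c(9, 3)) {
    new("FitSpec", parameter = as.character(parameter),
        targetBarrier = as.integer(targetBarrier), grid = as.numeric(grid),
        roi = as.numeric(roi), channels = as.character(channels),
        nCells = as.integer(nCells),
        validationNCells = as.integer(validationNCells),
        masterSeed = as.integer(masterSeed),
        smoothing = as.numeric(smoothing))
}

#' FitResult: outcome of a line search
#'
#' @slot spec the \code{\link{FitSpec}} that was run.
#' @slot grid,objectives candidate values and their Euclidean-norm
#'   objectives.
#' @slot bestValue arg-min of the objective (ties broken toward the
#'   smallest grid value).
#' @slot bestObjective,validationObjective minimum objective at search
#'   \code{nCells} and at the validation rerun with
#'   \code{validationNCells} and a fresh seed.
#' @slot tie \code{TRUE} if the minimum was attained at more than one grid
#'   value.
#' @slot seed master seed used for the search ensembles.
#'
#' @export
setClass("FitResult",
    representation(spec = "FitSpec", grid = "numeric",
                   objectives = "numeric", bestValue = "numeric",
                   bestObjective = "numeric",
                   validationObjective = "numeric", tie = "logical",
                   seed = "integer"))
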