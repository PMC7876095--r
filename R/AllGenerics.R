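#' @include AllClasses.R
NULL

#' Accessors for grid-based objects
#'
#' @param x a \code{\link{BinGrid}} or an object carrying one.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("binGrid", function(x) standardGeneric("binGrid"))
#' @rdname grid-accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname grid-accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname grid-accessors
#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))
#' @rdname grid-accessors
#' @export
setGeneric("binMidpoints", function(x) standardGeneric("binMidpoints"))
#' @rdname grid-accessors
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' @rdname grid-accessors
setMethod("binGrid", "BinGrid", function(x) x)
#' @rdname grid-accessors
setMethod("nBins", "BinGrid", function(x)
    as.integer(round((x@end - x@start) / x@binSize)))
#' @rdname grid-accessors
setMethod("binSize", "BinGrid", function(x) x@binSize)
#' @rdname grid-accessors
setMethod("binStarts", "BinGrid", function(x)
    x@start + (seq_len(nBins(x)) - 1) * x@binSize)
#' @rdname grid-accessors
setMethod("binMidpoints", "BinGrid", function(x) binStarts(x) + x@binSize / 2)

#' @rdname grid-accessors
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
setMethod("binRanges", "BinGrid", function(x) {
    s <- binStarts(x)
    GenomicRanges::GRanges(x@chrom,
        IRanges::IRanges(start = s + 1, width = x@binSize))
})

setMethod("show", "BinGrid", function(object) {
    cat("BinGrid on ", object@chrom, ": [", object@start, ", ", object@end,
        ") bp, ", nBins(object), " bins of ", object@binSize, " bp\n",
        sep = "")
})

for (cls in c("LocusConfig", "CellOutcome", "ReplicationProfile",
              "PuSeqTrace"))
    setMethod("binGrid", cls, function(x) x@grid)
setMethod("binGrid", "PuSeqCounts", function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    w <- unique(GenomicRanges::width(rr))
    BinGrid(as.character(GenomicRanges::seqnames(rr)[1]),
            min(GenomicRanges::start(rr)) - 1, max(GenomicRanges::end(rr)), w)
})

#' Accessors for \code{LocusConfig}
#'
#' @param x a \code{\link{LocusConfig}}.
#' @name config-accessors
NULL

#' @rdname config-accessors
#' @export
setGeneric("origins", function(x) standardGeneric("origins"))
#' @rdname config-accessors
#' @export
setGeneric("barriers", function(x) standardGeneric("barriers"))
#' @rdname config-accessors
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))

#' @rdname config-accessors
setMethod("origins", "LocusConfig", function(x) x@origins)
#' @rdname config-accessors
setMethod("barriers", "LocusConfig", function(x) x@barriers)
#' @rdname config-accessors
setMethod("locusName", "LocusConfig", function(x) x@name)

setMethod("show", "LocusConfig", function(object) {
    cat("LocusConfig \"", object@name, "\"\n", sep = "")
    show(object@grid)
    cat(nrow(object@origins), " origins, ", nrow(object@barriers),
        " barriers\n", sep = "")
})

#' Accessors for simulation outputs
#'
#' @param x a \code{\link{CellOutcome}} or \code{\link{ReplicationProfile}}.
#' @param strand \code{"Watson"} or \code{"Crick"}.
#' @param polymerase \code{"epsilon"}, \code{"delta"} or \code{"alpha"}.
#' @name profile-accessors
NULL

#' @rdname profile-accessors
#' @export
setGeneric("replicationTime", function(x) standardGeneric("replicationTime"))
#' @rdname profile-accessors
#' @export
setGeneric("forkDirection", function(x) standardGeneric("forkDirection"))
#' @rdname profile-accessors
#' @export
setGeneric("forkType", function(x) standardGeneric("forkType"))
#' @rdname profile-accessors
#' @export
setGeneric("fracRightward", function(x) standardGeneric("fracRightward"))
#' @rdname profile-accessors
#' @export
setGeneric("fracRestarted", function(x) standardGeneric("fracRestarted"))
#' @rdname profile-accessors
#' @export
setGeneric("polUsage", function(x, strand, polymerase)
    standardGeneric("polUsage"))

#' @rdname profile-accessors
setMethod("replicationTime", "CellOutcome", function(x) x@replicationTime)
#' @rdname profile-accessors
setMethod("forkDirection", "CellOutcome", function(x)
    ifelse(x@direction > 0, "rightward", "leftward"))
#' @rdname profile-accessors
setMethod("forkType", "CellOutcome", function(x)
    ifelse(x@forkType > 0, "restarted", "canonical"))
#' @rdname profile-accessors
setMethod("replicationTime", "ReplicationProfile",
    function(x) x@meanReplicationTime)
#' @rdname profile-accessors
setMethod("fracRightward", "ReplicationProfile", function(x) x@fracRightward)
#' @rdname profile-accessors
setMethod("fracRestarted", "ReplicationProfile", function(x) x@fracRestarted)
#' @rdname profile-accessors
setMethod("polUsage", "ReplicationProfile", function(x, strand, polymerase)
    x@usage[, strand, polymerase])

setMethod("show", "CellOutcome", function(object) {
    cat("CellOutcome over ", nBins(object@grid), " bins; S phase span ",
        round(max(object@replicationTime), 2), " min; ",
        sum(object@forkType > 0), " bins by HR-restarted forks\n", sep = "")
})

setMethod("show", "ReplicationProfile", function(object) {
    cat("ReplicationProfile: ", object@nCells, " cells (seed ", object@seed,
        ") over ", nBins(object@grid), " bins\n", sep = "")
    cat("  restarted-fork fraction: max ",
        round(max(object@fracRestarted), 3), "\n", sep = "")
})

#' Accessors for \code{PuSeqTrace}
#'
#' @param x a \code{\link{PuSeqTrace}}.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
setGeneric("usageDelta", function(x) standardGeneric("usageDelta"))
#' @rdname trace-accessors
#' @export
setGeneric("usageEpsilon", function(x) standardGeneric("usageEpsilon"))
#' @rdname trace-accessors
#' @export
setGeneric("alphaOverlay", function(x) standardGeneric("alphaOverlay"))
#' @rdname trace-accessors
#' @export
setGeneric("traceMask", function(x) standardGeneric("traceMask"))

#' @rdname trace-accessors
setMethod("usageDelta", "PuSeqTrace", function(x) x@usageDelta)
#' @rdname trace-accessors
setMethod("usageEpsilon", "PuSeqTrace", function(x) x@usageEpsilon)
#' @rdname trace-accessors
setMethod("alphaOverlay", "PuSeqTrace", function(x) x@alphaOverlay)
#' @rdname trace-accessors
setMethod("traceMask", "PuSeqTrace", function(x) x@mask)

setMethod("show", "PuSeqTrace", function(object) {
    cat("PuSeqTrace over ", nBins(object@grid), " bins; ",
        sum(object@mask), " strand-bins masked; Pol alpha overlay ",
        if (all(is.na(object@alphaOverlay))) "absent" else "present",
        "\n", sep = "")
})

#' Accessors for \code{FitResult}
#'
#' @param x a \code{\link{FitResult}}.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("bestValue", function(x) standardGeneric("bestValue"))
#' @rdname fit-accessors
#' @export
setGeneric("objectives", function(x) standardGeneric("objectives"))

#' @rdname fit-accessors
setMethod("bestValue", "FitResult", function(x) x@bestValue)
#' @rdname fit-accessors
setMethod("objectives", "FitResult", function(x)
    stats::setNames(x@objectives, x@grid))

setMethod("show", "FitResult", function(object) {
    cat("FitResult: line search of '", object@spec@parameter, "' over ",
        length(object@grid), " values\n", sep = "")
    cat("  best value ", object@bestValue, " (objective ",
        signif(object@bestObjective, 4), "; validation ",
        signif(object@validationObjective, 4), ")",
        if (object@tie) " [tie]", "\n", sep = "")
})
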