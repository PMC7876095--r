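#' @include AllClasses.R AllGenerics.R
#' @importFrom utils read.table write.table
NULL

.STRAINS <- c("pol_delta", "pol_epsilon", "pol_alpha")
.STRANDS <- c("Watson", "Crick")

#' Standard file names for a Pu-seq count/trace dataset
#'
#' Count files are named \code{<prefix>_<strain>_<strand>.bedgraph} with
#' strain in \code{delta}, \code{epsilon}, \code{alpha} and strand in
#' \code{watson}, \code{crick}; only existing files are returned.
#'
#' @param dir directory to scan.
#' @param prefix file-name prefix (default \code{"counts"}).
#' @return named character vector of paths; names are
#'   \code{"<strain>:<strand>"} keys such as \code{"pol_delta:Watson"}.
#' @export
puseqFileSet <- function(dir, prefix = "counts") {
    keys <- as.vector(outer(.STRAINS, .STRANDS, paste, sep = ":"))
    paths <- vapply(keys, function(k) {
        parts <- strsplit(k, ":", fixed = TRUE)[[1]]
        file.path(dir, paste0(prefix, "_", sub("pol_", "", parts[1]), "_",
                              tolower(parts[2]), ".bedgraph"))
    }, character(1))
    paths[file.exists(paths)]
}

#' Read binned strand-specific count tracks
#'
#' Reads one bedGraph file per strain x strand library, checks that the
#' intervals tile the target \code{\link{BinGrid}} without overlaps or
#' mis-sized bins, and assembles a \code{\link{PuSeqCounts}} object.
#' Bins absent from a file are set to 0 (the number of such bins is
#' reported in a warning).
#'
#' @param paths named character vector of bedGraph paths; names are
#'   \code{"<strain>:<strand>"} keys (see \code{\link{puseqFileSet}}).
#' @param grid the target \code{\link{BinGrid}}.
#' @param libraryTotals optional named numeric vector (same keys) of
#'   library totals to use for normalisation, e.g. genome-wide totals
#'   when the tracks are a window of a larger experiment (see
#'   \code{\link{readLibraryTotals}}); defaults to the per-file sums.
#' @return a \code{\link{PuSeqCounts}}.
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @export
readCounts <- function(paths, grid, libraryTotals = NULL) {
    stopifnot(is(grid, "BinGrid"))
    keys <- names(paths)
    if (is.null(keys) || !all(grepl(":", keys, fixed = TRUE)))
        stop("'paths' must be named \"<strain>:<strand>\"", call. = FALSE)
    n <- nBins(grid)
    starts <- binStarts(grid)
    counts <- matrix(0, nrow = n, ncol = length(paths),
                     dimnames = list(NULL, keys))
    for (i in seq_along(paths)) {
        gr <- rtracklayer::import(paths[[i]], format = "bedGraph")
        if (length(gr) == 0) {
            warning("empty count file: ", paths[[i]], "; all bins set to 0",
                    call. = FALSE)
            next
        }
        chr <- as.character(GenomicRanges::seqnames(gr))
        if (any(chr != grid@chrom))
            stop("chrom mismatch in ", paths[[i]], ": expected '",
                 grid@chrom, "', found '", setdiff(chr, grid@chrom)[1], "'",
                 call. = FALSE)
        s0 <- GenomicRanges::start(gr) - 1  # back to 0-based
        w <- GenomicRanges::width(gr)
        bad <- which(w != grid@binSize |
                     (s0 - grid@start) %% grid@binSize != 0)
        if (length(bad))
            stop("format error in ", paths[[i]], ", line ", bad[1],
                 ": interval [", s0[bad[1]], ", ", s0[bad[1]] + w[bad[1]],
                 ") does not match the ", grid@binSize, " bp grid",
                 call. = FALSE)
        idx <- (s0 - grid@start) / grid@binSize + 1
        if (anyDuplicated(idx))
            stop("format error in ", paths[[i]], ", line ",
                 which(duplicated(idx))[1], ": overlapping intervals",
                 call. = FALSE)
        inside <- idx >= 1 & idx <= n
        counts[idx[inside], i] <- GenomicRanges::score(gr)[inside]
        nmiss <- n - sum(inside)
        if (nmiss > 0)
            warning(nmiss, " bin(s) missing from ", paths[[i]],
                    "; set to 0", call. = FALSE)
    }
    if (any(counts < 0))
        stop("negative counts encountered", call. = FALSE)
    totals <- colSums(counts)
    if (!is.null(libraryTotals)) {
        miss <- setdiff(keys, names(libraryTotals))
        if (length(miss))
            stop("libraryTotals missing entries for: ",
                 paste(miss, collapse = ", "), call. = FALSE)
        totals <- as.numeric(libraryTotals[keys])
    }
    parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
    cd <- S4Vectors::DataFrame(strain = parts[, 1], strand = parts[, 2],
                               libraryTotal = totals,
                               row.names = keys)
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = binRanges(grid), colData = cd)
    new("PuSeqCounts", se)
}

.pickChannel <- function(counts, strain, strand) {
    cd <- SummarizedExperiment::colData(counts)
    i <- which(cd$strain == strain & cd$strand == strand)
    if (length(i) != 1L) return(NULL)
    list(raw = SummarizedExperiment::assay(counts, "counts")[, i],
         total = cd$libraryTotal[i])
}

#' Compute polymerase usage from count tracks
#'
#' Per strand, counts from the Pol delta and Pol epsilon mutant strains
#' are library-size normalised (divided by their library totals) and the
#' Pol delta usage at each bin is the normalised delta density divided by
#' the summed normalised delta and epsilon densities, with
#' \code{usage_epsilon = 1 - usage_delta}. Bins whose raw delta + epsilon
#' count is below \code{minDepth} are masked. When a Pol alpha strain is
#' present, its normalised density relative to delta + epsilon is exported
#' times 10 as a not-to-scale overlay (no assumption is made about the
#' relative ribonucleotide incorporation rates of the three polymerases,
#' so the alpha track is never folded into the delta/epsilon closure).
#'
#' @param counts a \code{\link{PuSeqCounts}} with at least the
#'   \code{pol_delta} and \code{pol_epsilon} strains.
#' @param minDepth minimum raw delta + epsilon count per bin (default 10).
#' @return a \code{\link{PuSeqTrace}}.
#' @export
computeUsage <- function(counts, minDepth = 10) {
    stopifnot(is(counts, "PuSeqCounts"))
    grid <- binGrid(counts)
    n <- nBins(grid)
    ud <- ue <- ao <- matrix(NA_real_, n, 2, dimnames = list(NULL, .STRANDS))
    mask <- matrix(TRUE, n, 2, dimnames = list(NULL, .STRANDS))
    for (s in .STRANDS) {
        d <- .pickChannel(counts, "pol_delta", s)
        e <- .pickChannel(counts, "pol_epsilon", s)
        if (is.null(d) || is.null(e))
            stop("input error: strains pol_delta and pol_epsilon are ",
                 "required on both strands", call. = FALSE)
        dn <- d$raw / max(d$total, 1)
        en <- e$raw / max(e$total, 1)
        m <- (d$raw + e$raw) < minDepth
        frac <- ifelse(dn + en > 0, dn / (dn + en), NA_real_)
        ud[, s] <- ifelse(m, NA_real_, frac)
        ue[, s] <- 1 - ud[, s]
        mask[, s] <- m | is.na(ud[, s])
        a <- .pickChannel(counts, "pol_alpha", s)
        if (!is.null(a)) {
            an <- a$raw / max(a$total, 1)
            ao[, s] <- ifelse(mask[, s], NA_real_,
                              10 * an / (dn + en))
        }
    }
    new("PuSeqTrace", grid = grid, usageDelta = ud, usageEpsilon = ue,
        alphaOverlay = ao, mask = mask)
}

#' Savitzky-Golay smoothing of a track
#'
#' Applies a Savitzky-Golay filter with mirrored edge handling. For a
#' numeric vector, \code{NA} values are linearly interpolated before
#' smoothing and restored to \code{NA} afterwards. For a
#' \code{\link{PuSeqTrace}}, the Pol delta usage of each strand is
#' smoothed (epsilon follows as its complement, preserving the closure)
#' along with the alpha overlay, and the mask is re-applied.
#'
#' @param x numeric vector or \code{\link{PuSeqTrace}}.
#' @param window odd number of bins (default 9); must exceed
#'   \code{polyorder}.
#' @param polyorder polynomial order (default 3).
#' @return same shape as the input.
#' @examples
#' smoothTrace(sin(seq(0, 3, length.out = 50)), window = 9, polyorder = 3)
#' @export
smoothTrace <- function(x, window = 9, polyorder = 3) {
    if (window %% 2 != 1 || window <= polyorder)
        stop("parameter error: 'window' must be odd and greater than ",
             "'polyorder'", call. = FALSE)
    if (is(x, "PuSeqTrace")) {
        ud <- x@usageDelta
        ao <- x@alphaOverlay
        for (s in seq_len(ncol(ud))) {
            ud[, s] <- smoothTrace(ud[, s], window, polyorder)
            if (!all(is.na(ao[, s])))
                ao[, s] <- smoothTrace(ao[, s], window, polyorder)
        }
        ud[x@mask] <- NA_real_
        ao[x@mask] <- NA_real_
        return(new("PuSeqTrace", grid = x@grid, usageDelta = ud,
                   usageEpsilon = 1 - ud, alphaOverlay = ao,
                   mask = x@mask))
    }
    v <- as.numeric(x)
    if (length(v) < window)
        stop("parameter error: series shorter than 'window'", call. = FALSE)
    nas <- is.na(v)
    if (all(nas)) return(v)
    if (any(nas)) {
        idx <- seq_along(v)
        v <- stats::approx(idx[!nas], v[!nas], xout = idx, rule = 2)$y
    }
    # sgolayfilt fits full polynomials to the first and last half-windows,
    # so the filter is exact on polynomials of degree <= polyorder
    # including the edges
    out <- signal::sgolayfilt(v, p = polyorder, n = window)
    out[nas] <- NA_real_
    out
}

#' Convert a simulated profile to Pu-seq trace space
#'
#' Maps a \code{\link{ReplicationProfile}} onto the quantities a Pu-seq
#' experiment measures. The small Pol alpha contribution is folded into
#' the Pol delta channel for the delta/epsilon closure (the two strains'
#' tracks are indistinguishable there) and additionally exported as the
#' not-to-scale x10 overlay. No bins are masked.
#'
#' @param profile a \code{\link{ReplicationProfile}}.
#' @return a \code{\link{PuSeqTrace}}.
#' @export
profileToTrace <- function(profile) {
    stopifnot(is(profile, "ReplicationProfile"))
    u <- profile@usage
    ud <- u[, , "delta"] + u[, , "alpha"]
    ue <- u[, , "epsilon"]
    ao <- 10 * u[, , "alpha"]
    n <- nBins(profile@grid)
    dim(ud) <- dim(ue) <- dim(ao) <- c(n, 2L)
    dimnames(ud) <- dimnames(ue) <- dimnames(ao) <- list(NULL, .STRANDS)
    new("PuSeqTrace", grid = profile@grid, usageDelta = ud,
        usageEpsilon = ue, alphaOverlay = ao,
        mask = matrix(FALSE, n, 2, dimnames = list(NULL, .STRANDS)))
}

#' Estimate a polymerase-switch position
#'
#' Locates the epsilon-to-delta transition that marks the position of fork
#' arrest / HR restart: within the window, the Pol epsilon usage on the
#' chosen strand is scanned for the (first) crossing of the midpoint of
#' its local range, and the crossing position is linearly interpolated.
#'
#' @param trace a \code{\link{PuSeqTrace}}.
#' @param strand \code{"Watson"} or \code{"Crick"}.
#' @param window bp interval \code{c(lo, hi)}; defaults to the whole grid.
#' @return interpolated bp position of the transition.
#' @export
estimateTransitionPosition <- function(trace, strand = "Watson",
                                       window = NULL) {
    stopifnot(is(trace, "PuSeqTrace"), strand %in% .STRANDS)
    grid <- trace@grid
    if (is.null(window)) window <- c(grid@start, grid@end)
    m <- binMidpoints(grid)
    v <- trace@usageEpsilon[, strand]
    keep <- m >= window[1] & m <= window[2] & !trace@mask[, strand] &
        !is.na(v)
    if (sum(keep) < 2)
        stop("not found: fewer than two unmasked bins in the window",
             call. = FALSE)
    vv <- v[keep]
    rng <- range(vv)
    if (diff(rng) < 1e-3)
        stop("not found: trace is flat in the window", call. = FALSE)
    .interpCrossing(m[keep], vv, mean(rng), what = "transition")
}

.TRACE_CHANNELS <- c("usage_delta", "usage_epsilon", "alpha_overlay")

#' Write / read trace channel files
#'
#' One 4-column bedGraph-style file (chrom, start, end, value; no header)
#' per channel x strand, named
#' \code{<prefix>_<channel>_<strand>.bedgraph}; masked bins are written as
#' \code{NA}. \code{readTrace} reconstructs the \code{\link{PuSeqTrace}},
#' recovering the mask from the \code{NA} bins; the pair round-trips.
#'
#' @param trace a \code{\link{PuSeqTrace}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default \code{"trace"}).
#' @return \code{writeTrace}: the directory, invisibly;
#'   \code{readTrace}: a \code{\link{PuSeqTrace}}.
#' @export
writeTrace <- function(trace, dir, prefix = "trace") {
    stopifnot(is(trace, "PuSeqTrace"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    grid <- trace@grid
    s <- binStarts(grid)
    chans <- list(usage_delta = trace@usageDelta,
                  usage_epsilon = trace@usageEpsilon,
                  alpha_overlay = trace@alphaOverlay)
    for (ch in names(chans)) for (st in .STRANDS) {
        v <- chans[[ch]][, st]
        if (ch == "alpha_overlay" && all(is.na(v))) next
        v[trace@mask[, st]] <- NA_real_
        df <- data.frame(chrom = grid@chrom, start = s,
                         end = s + grid@binSize, value = v)
        write.table(df, .traceFile(dir, prefix, ch, st), sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    invisible(dir)
}

.traceFile <- function(dir, prefix, channel, strand)
    file.path(dir, paste0(prefix, "_", channel, "_", tolower(strand),
                          ".bedgraph"))

#' @rdname writeTrace
#' @export
readTrace <- function(dir, prefix = "trace") {
    readChan <- function(ch, st) {
        f <- .traceFile(dir, prefix, ch, st)
        if (!file.exists(f)) return(NULL)
        read.table(f, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   na.strings = "NA")
    }
    dw <- readChan("usage_delta", "Watson")
    if (is.null(dw))
        stop("no usage_delta files found under ", dir, call. = FALSE)
    grid <- BinGrid(dw$chrom[1], min(dw$start), max(dw$end),
                    dw$end[1] - dw$start[1])
    n <- nBins(grid)
    ud <- ue <- ao <- matrix(NA_real_, n, 2, dimnames = list(NULL, .STRANDS))
    for (st in .STRANDS) {
        for (ch in .TRACE_CHANNELS) {
            df <- readChan(ch, st)
            if (is.null(df)) next
            idx <- (df$start - grid@start) / grid@binSize + 1
            val <- df$value
            if (ch == "usage_delta") ud[idx, st] <- val
            else if (ch == "usage_epsilon") ue[idx, st] <- val
            else ao[idx, st] <- val
        }
    }
    mask <- is.na(ud) | is.na(ue)
    new("PuSeqTrace", grid = grid, usageDelta = ud, usageEpsilon = ue,
        alphaOverlay = ao, mask = mask)
}
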