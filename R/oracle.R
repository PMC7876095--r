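#' @include AllClasses.R AllGenerics.R simulate.R
NULL

#' Simulate one cell by explicit time stepping
#'
#' A deliberately simple fixed-step replication engine with the same
#' semantics as the event-driven \code{\link{simulateCell}}: the state is
#' advanced in increments of \code{dt} minutes and fork events (barrier
#' encounters, meetings, rescues, edge arrivals) are detected within each
#' step and resolved at their exact interpolated times. It consumes the
#' same pre-drawn randomness as \code{simulateCell} for a given
#' \code{cellSeed}, so the two engines can be compared cell by cell; this
#' function exists as an independent cross-check of the event engine and
#' is far slower.
#'
#' @inheritParams simulateCell
#' @param dt time step in minutes (> 0). A step so large that a fork would
#'   cross the whole domain within it is rejected.
#' @return a \code{\link{CellOutcome}}.
#' @export
simulateCellFixedStep <- function(config, params = SimulationParams(),
                                  dt = 0.001, cellSeed = 1L) {
    stopifnot(is(config, "LocusConfig"), is(params, "SimulationParams"))
    validObject(config)
    validObject(params)
    if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
        stop("'dt' must be a single positive number", call. = FALSE)
    pp <- .prepSim(config, params)
    grid <- config@grid
    vmax <- max(pp$v, pp$barVel, na.rm = TRUE)
    if (vmax * dt >= grid@end - grid@start)
        stop("'dt' too large: a fork would cross the whole domain in one step",
             call. = FALSE)
    draws <- .drawCell(pp$origins, nrow(pp$barriers), cellSeed)

    gs <- grid@start
    ge <- grid@end
    bs <- grid@binSize
    nb <- nBins(grid)
    tol <- 1e-7
    repTime <- rep(NA_real_, nb)
    outDir <- rep(NA_integer_, nb)
    outType <- rep(NA_integer_, nb)
    assignSeg <- function(from, to, tFrom, vel, dir, type) {
        lo <- min(from, to); hi <- max(from, to)
        kmin <- max(0L, as.integer(ceiling((lo - gs) / bs - 0.5 - 1e-9)))
        kmax <- min(nb - 1L, as.integer(floor((hi - gs) / bs - 0.5 + 1e-9)))
        if (kmax < kmin) return(invisible())
        ks <- kmin:kmax
        m <- gs + (ks + 0.5) * bs
        keep <- m >= lo - tol & m <= hi + tol
        if (!any(keep)) return(invisible())
        idx <- ks[keep] + 1L
        repTime[idx] <<- tFrom + abs(m[keep] - from) / vel
        outDir[idx] <<- dir
        outType[idx] <<- type
        invisible()
    }

    b <- pp$barriers
    nBar <- nrow(b)
    comp <- which(draws$competent)
    pend <- data.frame(pos = pp$origins$position[comp], fire = draws$fire,
                       row = comp, done = FALSE)

    forks <- list()
    newFork <- function(p, t0, dir)
        list(anchorPos = p, anchorT = t0, pos = p, dir = dir, vel = pp$v,
             type = 0L, status = "moving", resumeT = NA_real_,
             arrestBarrier = NA_integer_, decided = rep(FALSE, nBar),
             origin = NA_integer_, coverLo = p, coverHi = p)
    susceptible <- function(f, j) {
        if (f$decided[j] || pp$barDir[j] != f$dir) return(FALSE)
        ap <- pp$barApplies[j]
        !((ap == 0L && f$type != 0L) || (ap == 1L && f$type != 1L))
    }
    posAt <- function(f, tt) {
        if (f$status != "moving") return(f$pos)
        f$anchorPos + f$dir * f$vel * (max(tt, f$anchorT) - f$anchorT)
    }
    ## earliest exact meeting/rescue time involving fork i, from anchors
    earliestContact <- function(i) {
        f <- forks[[i]]
        best <- Inf
        for (j in seq_along(forks)) {
            if (j == i) next
            g <- forks[[j]]
            if (g$status == "done") next
            if (g$status == "arrested") {
                d <- (g$pos - f$anchorPos) * f$dir
                if (d > tol) best <- min(best, f$anchorT + d / f$vel)
            } else if (g$dir != f$dir) {
                r <- if (f$dir > 0) f else g
                l <- if (f$dir > 0) g else f
                if (l$anchorPos - r$anchorPos > tol) {
                    tm <- (l$anchorPos + l$vel * l$anchorT - r$anchorPos +
                           r$vel * r$anchorT) / (r$vel + l$vel)
                    best <- min(best, tm)
                }
            }
        }
        best
    }

    t <- 0
    repeat {
        movingOrArrested <- any(vapply(forks, function(f)
            f$status != "done", logical(1)))
        if (!movingOrArrested && all(pend$done)) break
        if (t > 1e5)
            stop("simulation error: fixed-step run failed to terminate",
                 call. = FALSE)
        t2 <- t + dt

        ## resume arrested forks due this step (unless a rescuer arrives first)
        for (i in seq_along(forks)) {
            f <- forks[[i]]
            if (f$status != "arrested" || f$resumeT > t2) next
            rescuerAt <- Inf
            for (j in seq_along(forks)) {
                if (j == i) next
                g <- forks[[j]]
                if (g$status != "moving") next
                d <- (f$pos - g$anchorPos) * g$dir
                if (d > tol) rescuerAt <- min(rescuerAt, g$anchorT + d / g$vel)
            }
            if (rescuerAt < f$resumeT) next
            j <- f$arrestBarrier
            f$anchorT <- f$resumeT
            if (pp$barKind[j] == 1L) { # restart
                # restart point is |offset| bp behind the fork, in its wake
                newPos <- min(ge, max(gs, f$pos + f$dir * b$restartOffset[j]))
                f$pos <- f$anchorPos <- newPos
                f$coverLo <- min(f$coverLo, newPos)
                f$coverHi <- max(f$coverHi, newPos)
                f$type <- 1L
                if (is.finite(pp$barVel[j])) f$vel <- pp$barVel[j]
            } else {
                f$anchorPos <- f$pos
            }
            f$status <- "moving"
            f$resumeT <- NA_real_
            f$arrestBarrier <- NA_integer_
            forks[[i]] <- f
        }

        ## fire pending origins due this step, unless passively replicated
        due <- which(!pend$done & pend$fire <= t2)
        for (k in due) {
            pend$done[k] <- TRUE
            p <- pend$pos[k]
            tf <- pend$fire[k]
            covered <- FALSE
            for (g in forks) {
                pg <- posAt(g, tf)
                lo <- min(g$coverLo, pg); hi <- max(g$coverHi, pg)
                if (lo < p - 1e-9 && hi > p + 1e-9) { covered <- TRUE; break }
                # boundary contact counts as replicated unless it is a
                # moving fork arriving exactly at the firing instant
                if (lo <= p + 1e-9 && hi >= p - 1e-9) {
                    arrivingNow <- g$status == "moving" &&
                        abs(pg - p) <= 1e-9 &&
                        abs(g$coverLo - p) > 1e-9 && abs(g$coverHi - p) > 1e-9
                    if (!arrivingNow) { covered <- TRUE; break }
                }
            }
            if (covered) next
            for (dir in c(-1L, 1L)) {
                f <- newFork(p, tf, dir)
                f$origin <- pend$row[k]
                forks[[length(forks) + 1L]] <- f
            }
        }

        ## advance moving forks to t2, handling barrier encounters en route
        for (i in seq_along(forks)) {
            f <- forks[[i]]
            if (f$status != "moving") next
            repeat {
                pos2 <- f$anchorPos + f$dir * f$vel * (t2 - f$anchorT)
                ahead <- vapply(seq_len(nBar), function(j)
                    susceptible(f, j) &&
                    (b$position[j] - f$anchorPos) * f$dir > tol &&
                    (pos2 - b$position[j]) * f$dir >= 0, logical(1))
                if (nBar == 0L || !any(ahead)) { f$pos <- pos2; break }
                j <- which(ahead)[which.min(
                    (b$position[which(ahead)] - f$anchorPos) * f$dir)]
                tCross <- f$anchorT +
                    (b$position[j] - f$anchorPos) * f$dir / f$vel
                forks[[i]] <- f
                if (earliestContact(i) < tCross - 1e-12) {
                    f$pos <- pos2
                    break # a meeting pre-empts this barrier
                }
                f$decided[j] <- TRUE
                nullPause <- pp$barKind[j] == 0L && b$delay[j] <= 0
                if (draws$U[f$origin, j] < b$arrestProbability[j] &&
                    !nullPause) {
                    assignSeg(f$anchorPos, b$position[j], f$anchorT, f$vel,
                              f$dir, f$type)
                    f$pos <- b$position[j]
                    f$coverLo <- min(f$coverLo, f$pos)
                    f$coverHi <- max(f$coverHi, f$pos)
                    f$status <- "arrested"
                    f$resumeT <- tCross + b$delay[j]
                    f$arrestBarrier <- j
                    break
                }
            }
            forks[[i]] <- f
        }

        ## resolve meetings and rescues in exact chronological order
        repeat {
            bestT <- Inf; bestPair <- NULL; bestKind <- ""
            for (i in seq_along(forks)) {
                f <- forks[[i]]
                if (f$status != "moving") next
                for (j in seq_along(forks)) {
                    if (j == i) next
                    g <- forks[[j]]
                    if (g$status == "arrested") {
                        d <- (g$pos - f$anchorPos) * f$dir
                        if (d <= tol) next
                        ta <- f$anchorT + d / f$vel
                        if (ta <= t2 + 1e-12 && ta < g$resumeT &&
                            ta < bestT) {
                            bestT <- ta; bestPair <- c(i, j)
                            bestKind <- "rescue"
                        }
                    } else if (g$status == "moving" && j > i &&
                               g$dir != f$dir) {
                        r <- if (f$dir > 0) f else g
                        l <- if (f$dir > 0) g else f
                        if (l$anchorPos - r$anchorPos <= tol) next
                        tm <- (l$anchorPos + l$vel * l$anchorT - r$anchorPos +
                               r$vel * r$anchorT) / (r$vel + l$vel)
                        if (tm <= t2 + 1e-12 &&
                            tm >= max(f$anchorT, g$anchorT) - 1e-12 &&
                            tm < bestT) {
                            bestT <- tm; bestPair <- c(i, j)
                            bestKind <- "meet"
                        }
                    }
                }
            }
            if (is.null(bestPair)) break
            f <- forks[[bestPair[1]]]
            g <- forks[[bestPair[2]]]
            if (bestKind == "rescue") {
                assignSeg(f$anchorPos, g$pos, f$anchorT, f$vel, f$dir,
                          f$type)
                f$pos <- g$pos
                f$coverLo <- min(f$coverLo, f$pos)
                f$coverHi <- max(f$coverHi, f$pos)
                f$status <- "done"
                g$status <- "done"
            } else {
                r <- if (f$dir > 0) f else g
                l <- if (f$dir > 0) g else f
                x <- r$anchorPos + r$vel * (bestT - r$anchorT)
                assignSeg(l$anchorPos, x, l$anchorT, l$vel, -1L, l$type)
                assignSeg(r$anchorPos, x, r$anchorT, r$vel, 1L, r$type)
                l$pos <- x; l$status <- "done"
                l$coverLo <- min(l$coverLo, x)
                r$pos <- x; r$status <- "done"
                r$coverHi <- max(r$coverHi, x)
                if (f$dir > 0) { f <- r; g <- l } else { f <- l; g <- r }
            }
            forks[[bestPair[1]]] <- f
            forks[[bestPair[2]]] <- g
        }

        ## domain edges
        for (i in seq_along(forks)) {
            f <- forks[[i]]
            if (f$status != "moving") next
            target <- if (f$dir > 0) ge else gs
            if ((f$pos - target) * f$dir >= -tol) {
                assignSeg(f$anchorPos, target, f$anchorT, f$vel, f$dir,
                          f$type)
                f$pos <- target
                f$status <- "done"
                f$coverLo <- min(f$coverLo, f$pos)
                f$coverHi <- max(f$coverHi, f$pos)
                forks[[i]] <- f
            }
        }

        ## assign this step's plain movement: left-movers first so a
        ## rightward fork wins an exact midpoint tie
        ord <- order(vapply(forks, function(f) f$dir, integer(1)))
        for (i in ord) {
            f <- forks[[i]]
            if (f$status != "moving") next
            assignSeg(f$anchorPos, f$pos, f$anchorT, f$vel, f$dir, f$type)
            f$anchorPos <- f$pos
            f$anchorT <- t2
            f$coverLo <- min(f$coverLo, f$pos)
            f$coverHi <- max(f$coverHi, f$pos)
            forks[[i]] <- f
        }

        t <- t2
    }

    if (anyNA(repTime)) {
        gap <- which(is.na(repTime))[1]
        stop("simulation error: unreplicated gap at bin ", gap,
             call. = FALSE)
    }
    new("CellOutcome", grid = grid, replicationTime = repTime,
        direction = outDir, forkType = outType,
        resamples = draws$resamples)
}
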