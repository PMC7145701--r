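## Event analysis: time zero, change-point step calling, first-arrival and
## dwell extraction, binding-count time courses, SNBR, survival curves.

#' Robust trace noise estimate
#'
#' Noise sd from first differences, `mad(diff(x)) / sqrt(2)`; steps are
#' sparse in the differences so they barely bias the MAD.
#'
#' @param x numeric intensity vector.
#' @return estimated noise sd.
#' @export
noiseSdEstimate <- function(x) mad(diff(x)) / sqrt(2)

#' Detect time zero of the translation reaction
#'
#' The reagent-exchange baseline rise marks delivery; its completion sets
#' time 0 for all kinetics. The rise is located as the strongest sustained
#' increase of the smoothed trace inside `searchWindow`; the post-delivery
#' plateau is the median of a window shortly after the rise; `t0` is the
#' first time the trace reaches 90% of the plateau (relative to the
#' pre-delivery level). For a field, apply to every trace and take the
#' median ([fieldTimeZero()]) since reagent exchange is simultaneous across
#' the field of view.
#'
#' @param trace a [Trace-class] including pre-delivery frames.
#' @param searchWindow time window searched for the rise, s.
#' @param plateauWindow `(from, to)` offsets after the rise midpoint over
#'   which the plateau median is taken, s.
#' @return `t0` on the acquisition clock, s.
#' @export
detectTimeZero <- function(trace, searchWindow = 60,
                           plateauWindow = c(5, 25)) {
    tt <- trace@times
    v <- trace@intensities
    if (length(v) < 5L) stop("trace too short")
    sm <- stats::runmed(v, 3L)
    ns <- noiseSdEstimate(v)
    inWin <- which(tt <= tt[1L] + searchWindow)
    d <- diff(sm[inWin])
    ## sustained rise: rolling sum of differences over ~deadTime
    w <- max(2L, min(5L, length(d)))
    roll <- stats::filter(d, rep(1, w), sides = 1)
    roll[is.na(roll)] <- -Inf
    peak <- max(roll)
    if (peak < max(5 * ns, .Machine$double.eps))
        stop("no reagent delivery found")
    riseEnd <- inWin[which.max(roll) + 1L]
    pre <- median(v[seq_len(max(1L, riseEnd - w - 1L))])
    platIdx <- which(tt >= tt[riseEnd] + plateauWindow[1L] &
                     tt <= tt[riseEnd] + plateauWindow[2L])
    if (!length(platIdx)) platIdx <- seq(riseEnd, min(riseEnd + 5L, length(v)))
    plateau <- median(v[platIdx])
    if (plateau - pre < 5 * ns) stop("no reagent delivery found")
    hit <- which(sm >= pre + 0.9 * (plateau - pre) & seq_along(v) <= max(platIdx))
    tt[hit[1L]]
}

#' Field-wide time zero
#'
#' @param x a [TraceSet-class] or list of [Trace-class] objects.
#' @param ... passed to [detectTimeZero()].
#' @return median `t0` across traces, s.
#' @export
fieldTimeZero <- function(x, ...) {
    trs <- if (is(x, "TraceSet")) x@traces else x
    t0s <- vapply(trs, function(tr)
        tryCatch(detectTimeZero(tr, ...), error = function(e) NA_real_),
        numeric(1L))
    if (all(is.na(t0s))) stop("no reagent delivery found")
    median(t0s, na.rm = TRUE)
}

## ---- change-point step detection ------------------------------------------

## binary segmentation for piecewise-constant mean: returns interior
## change-point indices (last index of the left segment)
.binSeg <- function(x, penalty) {
    n <- length(x)
    cps <- integer()
    segs <- list(c(1L, n))
    cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
    segCost <- function(i, j) {
        s <- cs[j + 1L] - cs[i]
        (cs2[j + 1L] - cs2[i]) - s^2 / (j - i + 1L)
    }
    while (length(segs)) {
        seg <- segs[[1L]]; segs <- segs[-1L]
        i <- seg[1L]; j <- seg[2L]
        if (j - i < 1L) next
        whole <- segCost(i, j)
        ks <- i:(j - 1L)
        sL <- cs[ks + 1L] - cs[i]
        nL <- ks - i + 1L
        costL <- (cs2[ks + 1L] - cs2[i]) - sL^2 / nL
        sR <- cs[j + 1L] - cs[ks + 1L]
        nR <- j - ks
        costR <- (cs2[j + 1L] - cs2[ks + 1L]) - sR^2 / nR
        gain <- whole - (costL + costR)
        kbest <- which.max(gain)
        if (gain[kbest] > penalty) {
            k <- ks[kbest]
            cps <- c(cps, k)
            segs <- c(segs, list(c(i, k)), list(c(k + 1L, j)))
        }
    }
    sort(cps)
}

#' Detect binding/dissociation steps in a trace segment
#'
#' Penalized least-squares change-point segmentation of the
#' baseline-subtracted signal into piecewise-constant levels (binary
#' segmentation, penalty `penaltyFactor * log(n) * noiseSd^2` per change),
#' followed by amplitude filtering: boundaries whose level change is below
#' `minAmplitudeSigma * noiseSd` are merged away (smallest first), so only
#' genuine antibody arrivals/departures remain. Robust to the 2-7 dye
#' amplitude heterogeneity because no single step height is assumed.
#'
#' @param x baseline-subtracted intensity vector.
#' @param times frame times for `x`, s.
#' @param minAmplitudeSigma minimum step amplitude in noise-sd units.
#' @param noiseSd noise sd; estimated from `x` when `NULL`.
#' @param penaltyFactor multiplier of the `log(n) * noiseSd^2` penalty.
#' @return data.frame `(time, direction, amplitude)`: `time` is the first
#'   frame at the new level; `amplitude` the level difference (positive).
#' @export
detectSteps <- function(x, times, minAmplitudeSigma = 5, noiseSd = NULL,
                        penaltyFactor = 3) {
    stopifnot(length(x) == length(times))
    n <- length(x)
    empty <- data.frame(time = numeric(), direction = character(),
                        amplitude = numeric())
    if (n < 3L) return(empty)
    if (is.null(noiseSd)) noiseSd <- noiseSdEstimate(x)
    noiseSd <- max(noiseSd, .Machine$double.eps)
    pen <- penaltyFactor * log(n) * noiseSd^2
    cps <- .binSeg(x, pen)
    if (!length(cps)) return(empty)
    ## merge boundaries with sub-threshold level changes
    minAmp <- minAmplitudeSigma * noiseSd
    repeat {
        bounds <- c(0L, cps, n)
        means <- vapply(seq_len(length(bounds) - 1L), function(i)
            mean(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1L))
        dAmp <- abs(diff(means))
        if (!length(dAmp) || all(dAmp >= minAmp)) break
        cps <- cps[-which.min(dAmp)]
        if (!length(cps)) return(empty)
    }
    bounds <- c(0L, cps, n)
    means <- vapply(seq_len(length(bounds) - 1L), function(i)
        mean(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1L))
    delta <- diff(means)
    data.frame(time = times[cps + 1L],
               direction = ifelse(delta > 0, "up", "down"),
               amplitude = abs(delta))
}

## pair ups with downs and derive dwells; events relative to t0
.pairDwells <- function(ev, censorTime, ampTol = 0.5) {
    dwells <- data.frame(start = numeric(), duration = numeric(),
                         amplitude = numeric(), censored = logical(),
                         monosome = logical())
    if (!nrow(ev)) return(dwells)
    open <- list()   # each: list(time, amplitude)
    rows <- list()
    for (i in seq_len(nrow(ev))) {
        if (ev$direction[i] == "up") {
            open[[length(open) + 1L]] <- list(time = ev$time[i],
                                              amp = ev$amplitude[i])
        } else if (length(open)) {
            amps <- vapply(open, `[[`, numeric(1L), "amp")
            rel <- abs(amps - ev$amplitude[i]) / pmax(amps, ev$amplitude[i])
            ok <- which(rel <= ampTol)
            if (length(ok)) {
                j <- ok[which.min(rel[ok])]
                rows[[length(rows) + 1L]] <-
                    data.frame(start = open[[j]]$time,
                               duration = ev$time[i] - open[[j]]$time,
                               amplitude = open[[j]]$amp,
                               censored = FALSE, monosome = NA)
                open[[j]] <- NULL
            }
            ## down without a compatible open up: orphan, ignored
        }
    }
    for (j in seq_along(open))
        rows[[length(rows) + 1L]] <-
            data.frame(start = open[[j]]$time,
                       duration = censorTime - open[[j]]$time,
                       amplitude = open[[j]]$amp,
                       censored = TRUE, monosome = NA)
    if (!length(rows)) return(dwells)
    dwells <- do.call(rbind, rows)
    dwells <- dwells[order(dwells$start), , drop = FALSE]
    ## monosome flag: no other antibody bound at any point during the dwell
    nOpen <- cumsum(ifelse(ev$direction == "up", 1L, -1L))
    for (i in seq_len(nrow(dwells))) {
        s <- dwells$start[i]; e <- s + dwells$duration[i]
        inside <- ev$time >= s & ev$time < e
        dwells$monosome[i] <- all(nOpen[inside] <= 1L)
    }
    rownames(dwells) <- NULL
    dwells
}

#' Extract kinetic observables from one trace
#'
#' Runs the full per-trace event analysis: time zero (detected or
#' supplied), baseline subtraction, change-point step calling, first
#' arrival (censored when no binding occurs within the window), and dwell
#' pairing. Each up event is paired with the next down event of compatible
#' amplitude (within 50% relative tolerance); unpaired ups are censored at
#' the movie end; a dwell is flagged `monosome` when no second antibody is
#' bound at any time during it. A binding step before `t0` marks the trace
#' invalid (surface artifact) and excludes it from kinetic analysis.
#'
#' @param trace a [Trace-class].
#' @param t0 time zero on the acquisition clock, s; detected per trace when
#'   `NULL`. Pass the field median for field data.
#' @param minAmplitudeSigma step threshold in noise-sd units.
#' @param ampTol relative amplitude tolerance for up/down pairing.
#' @param penaltyFactor change-point penalty multiplier.
#' @param riseGuard seconds before `t0` excluded from the pre-delivery
#'   artifact check (the reagent-exchange rise itself lives there).
#' @return An [EventSeries-class]; event times are seconds since `t0`.
#' @examples
#' p <- SimParams(seed = 5L)
#' tr <- synthesizeTrace(simulateTimeline(p, 1L), p)
#' traceEvents(tr, t0 = tr@t0Truth)
#' @export
traceEvents <- function(trace, t0 = NULL, minAmplitudeSigma = 5,
                        ampTol = 0.5, penaltyFactor = 3, riseGuard = 10) {
    stopifnot(is(trace, "Trace"))
    if (is.null(t0)) t0 <- detectTimeZero(trace)
    tt <- trace@times
    v <- trace@intensities
    post <- tt >= t0
    ns <- noiseSdEstimate(v[post])
    ## plateau of the diffusing-antibody baseline, from early post-t0 frames
    early <- post & tt <= t0 + 10 * trace@frameInterval
    plateau <- median(v[early])
    x <- v[post] - plateau
    ev <- detectSteps(x, tt[post] - t0, minAmplitudeSigma, noiseSd = ns,
                      penaltyFactor = penaltyFactor)
    ## pre-delivery binding artifact check (before the rise, so baseline 0)
    preIdx <- tt < max(t0 - riseGuard, tt[1L])
    valid <- TRUE
    if (sum(preIdx) >= 3L) {
        evPre <- detectSteps(v[preIdx] - median(v[preIdx]), tt[preIdx],
                             minAmplitudeSigma, noiseSd = ns,
                             penaltyFactor = penaltyFactor)
        if (any(evPre$direction == "up")) valid <- FALSE
    }
    censorTime <- max(tt) - t0
    ups <- ev$time[ev$direction == "up"]
    fa <- if (length(ups)) ups[1L] else NA_real_
    new("EventSeries", traceId = trace@traceId, t0 = t0, events = ev,
        firstArrival = fa, firstArrivalCensored = !length(ups),
        censorTime = censorTime,
        dwells = .pairDwells(ev, censorTime, ampTol), valid = valid,
        noiseSd = ns)
}

#' First-arrival times of a set of event series
#'
#' The first arrival `t1` is the lag from completion of reagent exchange to
#' the first antibody binding on an mRNA. Censored molecules (no binding
#' within the window) are reported with their censoring time; invalid
#' traces (pre-delivery binding) are dropped.
#'
#' @param seriesList list of [EventSeries-class] objects.
#' @return data.frame `(traceId, t1, censored, censorTime)`.
#' @export
firstArrivals <- function(seriesList) {
    seriesList <- seriesList[vapply(seriesList, slot, logical(1L), "valid")]
    data.frame(
        traceId = vapply(seriesList, slot, character(1L), "traceId"),
        t1 = vapply(seriesList, slot, numeric(1L), "firstArrival"),
        censored = vapply(seriesList, slot, logical(1L),
                          "firstArrivalCensored"),
        censorTime = vapply(seriesList, slot, numeric(1L), "censorTime"))
}

#' Dwell times of a set of event series
#'
#' @param seriesList list of [EventSeries-class] objects.
#' @param monosomeOnly keep only uncensored single-ribosome dwells, the
#'   convention for elongation kinetics (overlapping antibodies make
#'   per-ribosome assignment ambiguous).
#' @return data.frame `(traceId, start, duration, amplitude, censored,
#'   monosome)`.
#' @export
dwellTimes <- function(seriesList, monosomeOnly = TRUE) {
    seriesList <- seriesList[vapply(seriesList, slot, logical(1L), "valid")]
    rows <- lapply(seriesList, function(s) {
        d <- s@dwells
        if (!nrow(d)) return(NULL)
        cbind(traceId = s@traceId, d)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(traceId = character(), start = numeric(),
                          duration = numeric(), amplitude = numeric(),
                          censored = logical(), monosome = logical())
    if (monosomeOnly) out <- out[!out$censored & out$monosome, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Binding-count time course
#'
#' Number of concurrently bound antibodies per frame, summed over a field.
#' For detected events the count is cumulative ups minus cumulative downs;
#' for a nonspecific arrival log (never released) it is the cumulative
#' arrival count.
#'
#' @param x list of [EventSeries-class] objects, a [TraceSet-class] (uses
#'   ground truth), or a nonspecific log data.frame with a `time` column.
#' @param times evaluation grid, s (kinetics clock). Defaults to the frame
#'   grid of the first series/trace.
#' @return data.frame `(time, count)`.
#' @export
bindingCountTimecourse <- function(x, times = NULL) {
    if (is(x, "TraceSet")) {
        p <- x@params
        if (is.null(times)) times <- seq(0, p@movieLength, by = p@frameInterval)
        count <- integer(length(times))
        for (tr in x@traces) {
            tl <- tr@truth
            if (is.null(tl) || !length(tl@bindings)) next
            count <- count + vapply(times, function(t)
                sum(tl@bindings <= t & tl@departures > t), integer(1L))
        }
        return(data.frame(time = times, count = count))
    }
    if (is.data.frame(x)) {
        if (is.null(times)) times <- seq(0, max(x$time, 0), length.out = 200L)
        return(data.frame(time = times, count = vapply(times, function(t)
            sum(x$time <= t), integer(1L))))
    }
    stopifnot(is.list(x), length(x) >= 1L)
    if (is.null(times)) {
        ct <- max(vapply(x, slot, numeric(1L), "censorTime"))
        times <- seq(0, ct, length.out = 400L)
    }
    count <- integer(length(times))
    for (s in x) {
        if (!s@valid || !nrow(s@events)) next
        ev <- s@events
        count <- count + vapply(times, function(t)
            sum(ev$time <= t & ev$direction == "up") -
            sum(ev$time <= t & ev$direction == "down"), integer(1L))
    }
    data.frame(time = times, count = count)
}

#' Specific vs. nonspecific binding ratio (SNBR)
#'
#' Ratio of the specific binding level at its plateau to the nonspecific
#' level over the same window, with the nonspecific channel rescaled by
#' `mrnaDensityRatio` to correct for unequal immobilized-mRNA density
#' between the two channels. The plateau window is the final
#' `plateauFraction` of the specific time course.
#'
#' @param specific,nonspecific data.frames `(time, count)`.
#' @param mrnaDensityRatio nonspecific-channel mRNA density relative to the
#'   specific channel.
#' @param plateauFraction final fraction of the acquisition used as the
#'   plateau window.
#' @return the SNBR (`Inf`, with a message, when the nonspecific plateau is
#'   zero).
#' @export
computeSNBR <- function(specific, nonspecific, mrnaDensityRatio = 1,
                        plateauFraction = 0.1) {
    tEnd <- max(specific$time)
    t0w <- tEnd - plateauFraction * (tEnd - min(specific$time))
    sp <- mean(specific$count[specific$time >= t0w])
    np <- mean(nonspecific$count[nonspecific$time >= t0w]) / mrnaDensityRatio
    if (np == 0) {
        message("nonspecific plateau is zero; SNBR reported as Inf")
        return(Inf)
    }
    sp / np
}

#' Kaplan-Meier survival of bound fluorescent spots
#'
#' Survival of a cohort of bound antibodies against fluorescence loss,
#' right-censored at the movie end.
#'
#' @param durations time from cohort start to loss (or censoring), s.
#' @param lost logical: `TRUE` when the spot was lost, `FALSE` when
#'   censored.
#' @return data.frame `(time, survival, nAtRisk)`; survival starts at 1 and
#'   is non-increasing.
#' @export
survivalCurve <- function(durations, lost = rep(TRUE, length(durations))) {
    if (!length(durations)) stop("empty cohort")
    sf <- survival::survfit(survival::Surv(durations, lost) ~ 1)
    data.frame(time = c(0, sf$time), survival = c(1, sf$surv),
               nAtRisk = c(length(durations), sf$n.risk))
}
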