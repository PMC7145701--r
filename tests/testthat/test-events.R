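# Time zero, step calling, first arrivals, dwells, counting, SNBR, survival.

# a hand-built trace: baseline 0 until `riseStart`, linear rise of
# `riseLen`, plateau `level`, plus optional steps (list of c(t_on, t_off,
# amp)) and noise
rampTrace <- function(riseStart = 10, riseLen = 4, level = 5, total = 600,
                      frameInterval = 1, steps = list(), noise = 0) {
    times <- seq(0, total, by = frameInterval)
    v <- level * pmin(pmax((times - riseStart) / riseLen, 0), 1)
    for (s in steps) v <- v + s[3L] * (times >= s[1L] & times < s[2L])
    if (noise > 0) v <- v + rnorm(length(v), sd = noise)
    new("Trace", traceId = "manual", times = times, intensities = v,
        frameInterval = frameInterval, truth = NULL,
        truthAmplitudes = numeric(), t0Truth = riseStart + riseLen)
}

test_that("time zero is found at the end of the reagent-exchange rise", {
    set.seed(61)
    tr <- rampTrace(riseStart = 10, riseLen = 4, noise = 0.15)
    expect_lt(abs(detectTimeZero(tr) - 14), 1 + 1e-9)
    ## zero noise: exact to one frame
    tr0 <- rampTrace(riseStart = 10, riseLen = 4, noise = 0)
    expect_lt(abs(detectTimeZero(tr0) - 14), 1 + 1e-9)
    ## a trace already at plateau has no detectable delivery
    flat <- rampTrace(riseStart = -20, riseLen = 1, noise = 0.1)
    expect_error(detectTimeZero(flat), "no reagent delivery")
    ## field median
    set.seed(62)
    trs <- replicate(9, rampTrace(noise = 0.2), simplify = FALSE)
    expect_lt(abs(fieldTimeZero(trs) - 14), 1 + 1e-9)
})

test_that("a noiseless 10-sigma step is called exactly once at its frame", {
    tr <- rampTrace(steps = list(c(200, 400, 3)), noise = 0)
    x <- tr@intensities[tr@times >= 14] - 5
    ev <- detectSteps(x, tr@times[tr@times >= 14] - 14, noiseSd = 0.3)
    expect_identical(nrow(ev), 2L)
    expect_identical(ev$direction, c("up", "down"))
    expect_equal(ev$time, c(200, 400) - 14)
    expect_equal(ev$amplitude, c(3, 3), tolerance = 1e-6)
})

test_that("flat noise traces yield no events at a 5-sigma threshold", {
    set.seed(63)
    falsePos <- vapply(1:500, function(k) {
        x <- rnorm(300, sd = 0.3)
        nrow(detectSteps(x, seq_along(x), minAmplitudeSigma = 5)) > 0L
    }, logical(1L))
    expect_gte(mean(!falsePos), 0.99)
})

test_that("steps in simulated traces are recovered at default SNR", {
    p <- SimParams(seed = 71L, reinitMean = 120,
                   firstInit = c(x0 = 60, mu = log(120), sigma = 0.5),
                   movieLength = 1200)
    nTrue <- nRec <- nFalse <- 0L
    for (i in 1:60) {
        tr <- synthesizeTrace(simulateTimeline(p, i), p)
        s <- traceEvents(tr, t0 = tr@t0Truth)
        tl <- tr@truth
        keep <- tl@bindings <= p@movieLength
        tru <- c(tl@bindings[keep],
                 tl@departures[keep][tl@departures[keep] <= p@movieLength])
        det <- s@events$time
        nTrue <- nTrue + length(tru)
        nRec <- nRec + sum(vapply(tru, function(tb)
            any(abs(det - tb) <= p@frameInterval + 1e-9), logical(1L)))
        nFalse <- nFalse + sum(vapply(det, function(td)
            !any(abs(tru - td) <= p@frameInterval + 1e-9), logical(1L)))
    }
    expect_gte(nTrue, 50L)
    expect_gte(nRec / nTrue, 0.95)   # within one frame
    expect_lte(nFalse / nTrue, 0.05)
})

test_that("first arrival is the first up event relative to time zero", {
    tr <- rampTrace(steps = list(c(134, 368, 4)), noise = 0)
    s <- traceEvents(tr, t0 = 14)
    expect_false(s@firstArrivalCensored)
    expect_equal(s@firstArrival, 120)
    ## censored: no event by movie end
    tr0 <- rampTrace(noise = 0)
    s0 <- traceEvents(tr0, t0 = 14)
    expect_true(s0@firstArrivalCensored)
    expect_equal(s0@censorTime, 600 - 14)
    fa <- firstArrivals(list(s, s0))
    expect_equal(fa$t1, c(120, NA))
    expect_equal(fa$censored, c(FALSE, TRUE))
})

test_that("a pre-delivery binding invalidates the trace", {
    tr <- rampTrace(riseStart = 60, riseLen = 4, total = 600,
                    steps = list(c(20, 300, 4)), noise = 0)
    s <- traceEvents(tr, t0 = 64)
    expect_false(s@valid)
    expect_identical(nrow(firstArrivals(list(s))), 0L)
})

test_that("detected first arrivals match the generating distribution", {
    p <- SimParams(seed = 72L, firstInit = c(x0 = 30, mu = log(60),
                                             sigma = 0.5), movieLength = 600)
    det <- c(); tru <- c()
    for (i in 1:300) {
        tl <- simulateTimeline(p, i)
        tr <- synthesizeTrace(tl, p)
        s <- traceEvents(tr, t0 = tr@t0Truth)
        if (!s@firstArrivalCensored) det <- c(det, s@firstArrival)
        if (length(tl@bindings) && tl@bindings[1L] <= p@movieLength)
            tru <- c(tru, tl@bindings[1L])
    }
    expect_gte(length(det), 280L)
    ks <- suppressWarnings(ks.test(det, tru))
    expect_gt(ks$p.value, 0.01)
})

test_that("dwells pair ups with downs and flag polysome overlap", {
    ## up at 100 s, down at 334 s
    tr <- rampTrace(steps = list(c(114, 348, 4)), noise = 0)
    s <- traceEvents(tr, t0 = 14)
    expect_identical(nrow(s@dwells), 1L)
    expect_equal(s@dwells$duration, 234)
    expect_false(s@dwells$censored)
    expect_true(s@dwells$monosome)
    ## two overlapping bindings: both dwells flagged non-monosome
    tr2 <- rampTrace(steps = list(c(114, 348, 4), c(214, 448, 6)),
                     noise = 0)
    s2 <- traceEvents(tr2, t0 = 14)
    expect_identical(nrow(s2@dwells), 2L)
    expect_false(any(s2@dwells$monosome))
    ## unpaired up at movie end is censored
    tr3 <- rampTrace(steps = list(c(314, 1000, 4)), noise = 0)
    s3 <- traceEvents(tr3, t0 = 14)
    expect_true(s3@dwells$censored)
    expect_equal(s3@dwells$duration, 600 - 314)
})

test_that("monosome dwells estimate the total decoding time", {
    p <- monosomeDwellParams(seed = 73L)
    dur <- c()
    for (i in 1:80) {
        tr <- synthesizeTrace(simulateTimeline(p, i), p)
        d <- traceEvents(tr, t0 = tr@t0Truth)@dwells
        dur <- c(dur, d$duration[!d$censored & d$monosome])
    }
    ## dwell is deterministic here (zero recognition delay, no bleaching):
    ## binding -> release = nCodons / rate, frame-quantized
    expect_gte(length(dur), 60L)
    expect_lt(abs(mean(dur) - 574 / 2.5), 2 * p@frameInterval)
})

test_that("event pairing conserves counts per trace", {
    p <- SimParams(seed = 74L, reinitMean = 90, movieLength = 1500)
    for (i in 1:25) {
        tr <- synthesizeTrace(simulateTimeline(p, i), p)
        s <- traceEvents(tr, t0 = tr@t0Truth)
        ups <- sum(s@events$direction == "up")
        downs <- sum(s@events$direction == "down")
        openCensored <- sum(s@dwells$censored)
        ## every up is either matched to a down or censored-open; with no
        ## orphan downs the balance closes exactly
        expect_identical(ups - downs - openCensored, 0L)
        expect_identical(nrow(s@dwells), ups)
    }
})

test_that("binding-count time course equals cumulative ups minus downs", {
    p <- SimParams(seed = 75L, reinitMean = 80, noiseSigma = 0,
                   movieLength = 1500)
    fld <- simulateField(p, 10L)
    times <- seq(0, p@movieLength, by = p@frameInterval)
    truthCount <- bindingCountTimecourse(fld, times = times)
    ## event series built from the ground-truth event log: exact identity
    truthSeries <- lapply(fld@traces, function(tr) {
        tl <- tr@truth
        ev <- rbind(data.frame(time = tl@bindings, direction = "up",
                               amplitude = 1),
                    data.frame(time = tl@departures, direction = "down",
                               amplitude = 1))
        ev <- ev[ev$time <= p@movieLength, , drop = FALSE]
        ev <- ev[order(ev$time), ]
        new("EventSeries", traceId = tr@traceId, t0 = tr@t0Truth,
            events = ev, firstArrival = NA_real_,
            firstArrivalCensored = TRUE, censorTime = p@movieLength,
            dwells = data.frame(), valid = TRUE, noiseSd = 0)
    })
    fromEvents <- bindingCountTimecourse(truthSeries, times = times)
    expect_identical(fromEvents$count, truthCount$count)
    ## detected events track the same curve (bindings that share a frame
    ## merge into one step, so the identity is only approximate)
    series <- lapply(fld@traces, function(tr)
        traceEvents(tr, t0 = tr@t0Truth))
    detCount <- bindingCountTimecourse(series, times = times)
    expect_gte(cor(truthCount$count, detCount$count), 0.98)
    expect_lte(max(abs(truthCount$count - detCount$count)), 3L)
    ## no events -> all zeros
    empty <- bindingCountTimecourse(simulateField(
        SimParams(seed = 1L, nonspecificRate = 0), 0L)@nonspecific,
        times = times)
    expect_true(all(empty$count == 0L))
})

test_that("nonspecific count slope matches the arrival rate", {
    slopes <- vapply(1:20, function(s) {
        p <- SimParams(seed = s, nonspecificRate = 0.02, movieLength = 1800)
        ns <- simulateField(p, 0L)@nonspecific
        ct <- bindingCountTimecourse(ns, times = seq(0, 1800, by = 30))
        coef(lm(count ~ time, ct))[["time"]]
    }, numeric(1L))
    expect_lt(abs(mean(slopes) - 0.02) / 0.02, 0.1)
})

test_that("SNBR is computed over the plateau window with density rescaling", {
    tt <- seq(0, 1800, by = 10)
    cs <- data.frame(time = tt, count = 50L)
    expect_equal(computeSNBR(cs, cs, mrnaDensityRatio = 1), 1)
    ## known plateau ratio 25 with Poisson sampling noise
    set.seed(81)
    snbrs <- vapply(1:20, function(k) {
        spec <- data.frame(time = tt, count = rpois(length(tt), 250))
        ns <- data.frame(time = tt, count = rpois(length(tt), 23))
        computeSNBR(spec, ns, mrnaDensityRatio = 2.3)
    }, numeric(1L))
    expect_lt(abs(mean(snbrs) - 25), 1)
    ## zero nonspecific plateau
    zero <- data.frame(time = tt, count = 0L)
    expect_message(r <- computeSNBR(cs, zero), "Inf")
    expect_identical(r, Inf)
})

test_that("a default-like field reaches at least a 20-fold SNBR", {
    p <- SimParams(seed = 82L, reinitMean = 60)
    fld <- simulateField(p, 100L)
    spec <- bindingCountTimecourse(fld)
    ns <- bindingCountTimecourse(fld@nonspecific, times = spec$time)
    expect_gte(computeSNBR(spec, ns), 20)
})

test_that("survival analysis reproduces the exponential loss law", {
    expect_error(survivalCurve(numeric()), "empty")
    ## no losses
    sv0 <- survivalCurve(rep(100, 20), lost = rep(FALSE, 20))
    expect_true(all(sv0$survival == 1))
    ## exponential loss at known rate, within a pointwise binomial band
    lam <- 1 / 600
    p <- stalledParams(seed = 83L, bleachRate = lam, movieLength = 1e9)
    dur <- vapply(1:1500, function(i) {
        tl <- simulateTimeline(p, i)
        tl@departures[1L] - tl@bindings[1L]
    }, numeric(1L))
    sv <- survivalCurve(dur)
    for (tq in c(300, 600, 1200)) {
        shat <- sv$survival[findInterval(tq, sv$time)]
        s0 <- exp(-lam * tq)
        expect_lt(abs(shat - s0), 3 * sqrt(s0 * (1 - s0) / 1500))
    }
})

test_that("stalled-translation survival at 30 minutes is about 90%", {
    fx <- generateFixtures("stalled_survival", seed = 84L, nMrna = 800L)
    dep <- vapply(fx$field@traces, function(tr) tr@truth@departures[1L],
                  numeric(1L))
    sv <- survivalCurve(pmin(dep, 1800), lost = dep <= 1800)
    s30 <- sv$survival[findInterval(1800, sv$time)]
    expect_lt(abs(s30 - 0.9), 3 * sqrt(0.9 * 0.1 / 800))
})

test_that("detected survival is stable under frame-interval refinement", {
    getSurv <- function(fi, seed) {
        ## binding at 30 s so the up step is observable after t0
        p <- stalledParams(seed = seed, frameInterval = fi,
                           movieLength = 1800,
                           firstInit = c(x0 = 30, mu = -Inf, sigma = 0),
                           dyeCountRange = c(4L, 7L))
        dur <- c(); lost <- c()
        for (i in 1:60) {
            tr <- synthesizeTrace(simulateTimeline(p, i), p)
            d <- traceEvents(tr, t0 = tr@t0Truth)@dwells
            if (!nrow(d)) next
            dur <- c(dur, d$duration[1L]); lost <- c(lost, !d$censored[1L])
        }
        survivalCurve(dur, lost)
    }
    svA <- getSurv(2, 85L); svB <- getSurv(0.5, 85L)
    for (tq in c(450, 900, 1500)) {
        sA <- svA$survival[findInterval(tq, svA$time)]
        sB <- svB$survival[findInterval(tq, svB$time)]
        expect_lt(abs(sA - sB), 3 * sqrt(0.25 * (2 / 60)))
    }
})
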