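# Registration, background, detection, localization and photometry are all
# validated against the simulator's ground truth.

gaussFrame <- function(W, H, spots, sigma = 1.2, bg = 0) {
    f <- matrix(bg, H, W)
    xs <- 0:(W - 1); ys <- 0:(H - 1)
    for (i in seq_len(nrow(spots)))
        f <- f + spots[i, 3L] * outer(exp(-(ys - spots[i, 2L])^2 / (2 * sigma^2)),
                                      exp(-(xs - spots[i, 1L])^2 / (2 * sigma^2)))
    f
}

staticMovie <- function(seed = 3L, dim = c(64L, 64L), drift = NULL,
                        readNoiseSd = 0.3, movieLength = 200) {
    p <- staticSpotParams(seed = seed, movieLength = movieLength)
    fld <- simulateField(p, 8L, fieldSize = dim)
    mv <- renderMovie(fld@traces, fld@positions, p, dim = dim,
                      drift = drift, readNoiseSd = readNoiseSd)
    list(p = p, fld = fld, mv = mv)
}

test_that("zero applied drift is recovered as zero", {
    s <- staticMovie(seed = 3L)
    est <- estimateDrift(s$mv)
    expect_lt(max(abs(est)), 0.05)
})

test_that("linear drift is recovered and correction is idempotent", {
    s <- staticMovie(seed = 3L)
    nf <- dim(s$mv@frames)[3L]
    drift <- cbind(0.02 * (0:(nf - 1L)), 0.01 * (0:(nf - 1L)))
    mv <- renderMovie(s$fld@traces, s$fld@positions, s$p, dim = c(64L, 64L),
                      drift = drift, readNoiseSd = 0.3)
    est <- estimateDrift(mv)
    slope <- coef(lm(est[, 1L] ~ seq_len(nf)))[2L]
    expect_lt(abs(slope - 0.02) / 0.02, 0.1)
    ## residual drift of the corrected movie is below a tenth of a pixel
    res <- estimateDrift(correctDrift(mv, est))
    expect_lt(max(abs(res)), 0.1)
})

test_that("featureless movies warn and return zero displacement", {
    arr <- array(5, c(16L, 16L, 4L))
    mv <- new("MovieStack", frames = arr, frameInterval = 1,
              positions = matrix(numeric(), 0L, 2L), psfSigma = 1.2,
              background = 5, driftPath = matrix(0, 4L, 2L), truth = list(),
              truthAmplitudes = list(), t0Truth = 0)
    expect_warning(est <- estimateDrift(mv), "featureless")
    expect_true(all(est == 0))
})

test_that("background subtraction zeroes a flat movie and keeps spot flux", {
    set.seed(21)
    arr <- array(20 + rnorm(32 * 32 * 3, sd = 0.2), c(32L, 32L, 3L))
    mv <- new("MovieStack", frames = arr, frameInterval = 1,
              positions = matrix(numeric(), 0L, 2L), psfSigma = 1.2,
              background = 20, driftPath = matrix(0, 3L, 2L), truth = list(),
              truthAmplitudes = list(), t0Truth = 0)
    out <- subtractBackground(mv)
    expect_lt(max(abs(out@frames)), 1.5)          # within noise
    expect_lt(abs(median(out@frames)), 0.05)
    ## spot flux preserved within 5%
    f <- gaussFrame(48L, 48L, cbind(24.4, 22.7, 8), bg = 15)
    mv2 <- new("MovieStack", frames = array(f, c(48L, 48L, 1L)),
               frameInterval = 1, positions = matrix(numeric(), 0L, 2L),
               psfSigma = 1.2, background = 15,
               driftPath = matrix(0, 1L, 2L), truth = list(),
               truthAmplitudes = list(), t0Truth = 0)
    out2 <- subtractBackground(mv2)
    flux0 <- 8 * 2 * pi * 1.2^2
    expect_lt(abs(sum(out2@frames) - flux0) / flux0, 0.05)
})

test_that("a ramp background is estimated correctly at the spot", {
    W <- H <- 48L
    ramp <- matrix(rep(seq(10, 20, length.out = W), each = H), H, W)
    f <- ramp + gaussFrame(W, H, cbind(24.3, 23.6, 8))
    mv <- new("MovieStack", frames = array(f, c(H, W, 1L)),
              frameInterval = 1, positions = matrix(numeric(), 0L, 2L),
              psfSigma = 1.2, background = 0, driftPath = matrix(0, 1L, 2L),
              truth = list(), truthAmplitudes = list(), t0Truth = 0)
    out <- subtractBackground(mv)
    ## residual at the spot = spot only: local background estimate matched
    ## the ramp value within 5%
    est <- f - out@frames[, , 1L]
    rampAtSpot <- ramp[24L, 25L]
    expect_lt(abs(est[24L, 25L] - rampAtSpot) / rampAtSpot, 0.05)
    ## background estimate tracks the ramp everywhere in the interior
    expect_lt(max(abs((est - ramp)[13:36, 13:36])) / rampAtSpot, 0.05)
})

test_that("spot detection controls false positives on pure noise", {
    set.seed(31)
    fp <- 0L
    for (k in 1:5) {
        fr <- matrix(rnorm(128 * 128), 128L, 128L)
        fp <- fp + nrow(detectSpots(fr, thresholdSigma = 5))
    }
    expect_lt(fp / (5 * 128 * 128), 0.001)
    ## empty frame of zeros
    expect_identical(nrow(detectSpots(matrix(0, 32L, 32L), 5)), 0L)
})

test_that("spot detection finds a dense field at SNR 10 without duplicates", {
    set.seed(32)
    gx <- rep(seq(10, 118, length.out = 8), times = 7)[1:50]
    gy <- rep(seq(10, 110, length.out = 7), each = 8)[1:50]
    pos <- cbind(gx + runif(50, -1, 1), gy + runif(50, -1, 1))
    fr <- gaussFrame(128L, 128L, cbind(pos, 10)) +
        matrix(rnorm(128 * 128), 128L, 128L)
    det <- detectSpots(fr, thresholdSigma = 5)
    matched <- vapply(seq_len(nrow(pos)), function(i)
        any((det$x - pos[i, 1L])^2 + (det$y - pos[i, 2L])^2 <= 2^2),
        logical(1L))
    expect_gte(sum(matched), 49L)
    ## no two detections share a true spot (no duplicates)
    nearest <- vapply(seq_len(nrow(det)), function(j)
        which.min((det$x[j] - pos[, 1L])^2 + (det$y[j] - pos[, 2L])^2),
        integer(1L))
    expect_identical(anyDuplicated(nearest), 0L)
})

test_that("sub-pixel localization is exact on noiseless spots", {
    fr <- gaussFrame(32L, 32L, cbind(16, 12, 5), bg = 2)
    s <- localizeSpot(fr, c(16, 12))
    expect_true(s$success)
    expect_lt(abs(s$centerX - 16), 1e-3)
    expect_lt(abs(s$centerY - 12), 1e-3)
    expect_lt(abs(s$amplitude - 5) / 5, 1e-3)
    expect_lt(abs(s$backgroundLocal - 2), 1e-3)
})

test_that("localization reaches a tenth of a pixel at SNR 10", {
    set.seed(41)
    errs <- vapply(1:50, function(k) {
        fr <- gaussFrame(24L, 24L, cbind(10.30, 7.60, 10)) +
            matrix(rnorm(24 * 24), 24L, 24L)
        s <- localizeSpot(fr, c(10, 8))
        if (!s$success) return(NA_real_)
        sqrt((s$centerX - 10.30)^2 + (s$centerY - 7.60)^2)
    }, numeric(1L))
    expect_lt(median(errs, na.rm = TRUE), 0.1)
})

test_that("degenerate windows fail gracefully", {
    expect_false(localizeSpot(matrix(1, 20L, 20L), c(10, 10))$success)
    ## window clipped by the frame edge
    fr <- gaussFrame(20L, 20L, cbind(2, 10, 5))
    expect_false(localizeSpot(fr, c(2, 10))$success)
})

test_that("localization error decreases monotonically with SNR", {
    pos <- cbind(rep(c(8.3, 16.7, 25.2), 3),
                 rep(c(8.6, 17.1, 24.8), each = 3))
    rmse <- vapply(c(3, 10, 40), function(snr) {
        set.seed(51)
        e2 <- c()
        for (rep in 1:5) {
            fr <- gaussFrame(33L, 33L, cbind(pos, snr)) +
                matrix(rnorm(33 * 33), 33L, 33L)
            for (i in seq_len(nrow(pos))) {
                s <- localizeSpot(fr, round(pos[i, ]))
                if (s$success)
                    e2 <- c(e2, (s$centerX - pos[i, 1L])^2 +
                                (s$centerY - pos[i, 2L])^2)
            }
        }
        sqrt(mean(e2))
    }, numeric(1L))
    expect_true(all(diff(rmse) < 0))
})

test_that("aperture photometry recovers step amplitudes and isolates spots", {
    ## deterministic binding at 30 s so early frames are spot-free
    p <- SimParams(seed = 6L, movieLength = 120, deliveryStart = 0,
                   deadTime = 1, firstInit = c(x0 = 30, mu = -Inf, sigma = 0),
                   tagExposureAa = 0L,
                   recognition = c(tauFast = 0, tauSlow = 0,
                                   fastFraction = 1),
                   bleachRate = 0, elongationRate = 0.01,
                   nCodons = 100000L, dyeCountRange = c(10L, 10L))
    ## two molecules far apart (> 4 sigma)
    pos <- cbind(c(15.2, 33.7), c(14.8, 32.3))
    trs <- lapply(1:2, function(i)
        synthesizeTrace(simulateTimeline(p, i), p))
    mv <- renderMovie(trs, pos, p, dim = c(48L, 48L), noise = "none",
                      baselineScale = 0, background = 4)
    mvb <- subtractBackground(mv)
    out <- extractTraces(mvb)
    expect_length(out, 2L)
    for (i in 1:2) {
        amp <- trs[[i]]@truthAmplitudes[1L]
        lvl <- mean(tail(out[[i]]@intensities, 10L))
        expect_lt(abs(lvl - amp) / amp, 0.1)
        ## before the binding the trace is flat at zero
        expect_lt(max(abs(out[[i]]@intensities[1:2])), 0.05 * amp)
    }
    ## cross-talk: molecule 2's trace before its own binding sees < 2% of
    ## molecule 1's amplitude (both bind at the same time here, so check a
    ## movie where only molecule 1 exists)
    mv1 <- renderMovie(trs[1], pos[1, , drop = FALSE], p, dim = c(48L, 48L),
                       noise = "none", baselineScale = 0, background = 4)
    tr2 <- extractTraces(subtractBackground(mv1),
                         positions = pos[2L, , drop = FALSE])
    expect_lt(max(abs(tr2[[1L]]@intensities)),
              0.02 * trs[[1L]]@truthAmplitudes[1L])
})

test_that("edge and overlap flags are raised and flagged traces dropped", {
    p <- staticSpotParams(seed = 7L, movieLength = 20)
    pos <- cbind(c(2, 20, 22), c(10, 20, 21.5))  # edge; overlapping pair
    trs <- lapply(1:3, function(i) synthesizeTrace(simulateTimeline(p, i), p))
    mv <- renderMovie(trs, pos, p, dim = c(40L, 40L), noise = "none")
    expect_warning(out <- extractTraces(mv), "flagged")
    expect_length(out, 0L)
})

test_that("the movie pipeline recovers binding events end to end", {
    p <- SimParams(seed = 21L, movieLength = 1200,
                   firstInit = c(x0 = 60, mu = log(120), sigma = 0.5),
                   reinitMean = 300)
    fld <- simulateField(p, 8L, fieldSize = c(64L, 64L), margin = 8)
    mv <- renderMovie(fld@traces, fld@positions, p, dim = c(64L, 64L),
                      readNoiseSd = 0.5)
    trs <- suppressWarnings(extractTraces(subtractBackground(
        correctDrift(mv))))
    expect_gte(length(trs), 5L)
    nTrue <- nRec <- nFalse <- 0L
    tol <- 2 * p@frameInterval + 1
    for (tr in trs) {
        s <- traceEvents(tr, t0 = tr@t0Truth)
        tru <- tr@truth@bindings[tr@truth@bindings <= p@movieLength]
        det <- s@events$time[s@events$direction == "up"]
        nTrue <- nTrue + length(tru)
        nRec <- nRec + sum(vapply(tru, function(tb)
            any(abs(det - tb) <= tol), logical(1L)))
        nFalse <- nFalse + sum(vapply(det, function(td)
            !any(abs(tru - td) <= tol), logical(1L)))
    }
    expect_gte(nTrue, 15L)
    expect_gte(nRec / nTrue, 0.9)
    expect_lte(nFalse / max(nRec, 1L), 0.05)
})
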