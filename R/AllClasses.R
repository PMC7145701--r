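#' @import methods
#' @importFrom stats rexp rlnorm rnorm rpois runif mad median quantile sd
#'   optim integrate dlnorm qlnorm ks.test lm coef complete.cases fft
#'   setNames qpois pnorm dist IQR
NULL

#' Simulation parameters for the single-molecule translation assay
#'
#' `SimParams` bundles every tunable of the ground-truth simulator: the
#' first-round initiation law (a shifted log-normal on the seconds scale),
#' peptide chain elongation, epitope exposure, the two-component exponential
#' antibody-recognition mixture, re-initiation, nonspecific surface binding,
#' translation-irrelevant fluorescence loss (antibody dissociation from the
#' intact nascent chain plus photobleaching, lumped into one exponential
#' clock), the reagent-exchange baseline rise, and acquisition settings.
#'
#' @slot firstInit named numeric `(x0, mu, sigma)` of the shifted log-normal
#'   first-initiation law, seconds. `sigma = 0` gives a point mass at
#'   `x0 + exp(mu)`.
#' @slot elongationRate amino acids per second.
#' @slot nCodons coding length in codons.
#' @slot tagExposureAa amino acids translated before the epitope clears the
#'   ribosome exit tunnel (tag length + tunnel-protected length).
#' @slot recognition named numeric `(tauFast, tauSlow, fastFraction)` of the
#'   double-exponential antibody recognition delay, seconds.
#' @slot reinitMean mean inter-initiation waiting time, seconds; `Inf`
#'   disables re-initiation (monosome-only).
#' @slot clearanceAa codons the leading ribosome must translate before a new
#'   initiation may occur (5' end occupancy rule).
#' @slot nonspecificRate nonspecific antibody arrivals per field per second.
#' @slot bleachRate per-bound-antibody translation-irrelevant loss rate, 1/s.
#' @slot deadTime reagent-exchange baseline rise duration, seconds.
#' @slot deliveryStart acquisition time at which reagent delivery begins, s.
#' @slot baselineLevel plateau of the diffusing-antibody baseline, intensity
#'   units.
#' @slot unitBrightness intensity per dye.
#' @slot frameInterval seconds per frame.
#' @slot movieLength length of the kinetic observation window (measured from
#'   completion of the baseline rise), seconds.
#' @slot noiseSigma additive Gaussian trace noise sd, intensity units.
#' @slot dyeCountRange integer `(min, max)` dyes per antibody.
#' @slot seed integer master seed.
#' @export
setClass("SimParams", representation(
    firstInit = "numeric", elongationRate = "numeric", nCodons = "integer",
    tagExposureAa = "integer", recognition = "numeric", reinitMean = "numeric",
    clearanceAa = "integer", nonspecificRate = "numeric", bleachRate = "numeric",
    deadTime = "numeric", deliveryStart = "numeric", baselineLevel = "numeric",
    unitBrightness = "numeric", frameInterval = "numeric", movieLength = "numeric",
    noiseSigma = "numeric", dyeCountRange = "integer", seed = "integer"))

setValidity("SimParams", function(object) {
    msg <- character()
    fi <- object@firstInit
    if (length(fi) != 3L || !all(c("x0", "mu", "sigma") %in% names(fi)))
        msg <- c(msg, "firstInit must be named (x0, mu, sigma)")
    else {
        if (fi[["x0"]] < 0) msg <- c(msg, "firstInit x0 must be >= 0")
        if (fi[["sigma"]] < 0) msg <- c(msg, "firstInit sigma must be >= 0")
    }
    rc <- object@recognition
    if (length(rc) != 3L || !all(c("tauFast", "tauSlow", "fastFraction") %in% names(rc)))
        msg <- c(msg, "recognition must be named (tauFast, tauSlow, fastFraction)")
    else {
        if (any(rc[c("tauFast", "tauSlow")] < 0))
            msg <- c(msg, "recognition time constants must be >= 0")
        if (rc[["fastFraction"]] < 0 || rc[["fastFraction"]] > 1)
            msg <- c(msg, "fastFraction must lie in [0, 1]")
    }
    if (object@elongationRate <= 0) msg <- c(msg, "elongationRate must be > 0")
    if (object@nCodons <= 0L) msg <- c(msg, "nCodons must be > 0")
    if (object@tagExposureAa < 0L) msg <- c(msg, "tagExposureAa must be >= 0")
    if (object@tagExposureAa >= object@nCodons)
        msg <- c(msg, "epitope exposure length must be shorter than the coding region (tagExposureAa < nCodons)")
    if (object@reinitMean <= 0) msg <- c(msg, "reinitMean must be > 0 (use Inf for monosome-only)")
    for (s in c("clearanceAa", "nonspecificRate", "bleachRate", "deadTime",
                "deliveryStart", "noiseSigma"))
        if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be >= 0"))
    if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
    if (object@movieLength <= 0) msg <- c(msg, "movieLength must be > 0")
    dr <- object@dyeCountRange
    if (length(dr) != 2L || dr[1L] < 1L || dr[2L] < dr[1L])
        msg <- c(msg, "dyeCountRange must be an increasing pair of positive integers")
    if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' Defaults describe a budding-yeast-extract-like experiment: a first-round
#' initiation distribution spanning roughly 2-30 minutes with a minutes-scale
#' mode, fast double-exponential antibody recognition (3.9 s / 38 s, 13:1
#' amplitude ratio), 2.5 aa/s elongation over 574 codons, epitope exposure
#' after 57 aa (22 aa 3xFLAG tag + 35 aa tunnel-protected), a 3.5 s
#' reagent-exchange rise, ~10% translation-irrelevant loss per 30 min, 2 s
#' frames and 2-7 dyes per antibody.
#'
#' @param firstInit named numeric `(x0, mu, sigma)`, seconds.
#' @param elongationRate aa/s.
#' @param nCodons coding length, codons.
#' @param tagExposureAa aa before epitope exposure.
#' @param recognition named numeric `(tauFast, tauSlow, fastFraction)`.
#' @param reinitMean mean inter-initiation time, s (`Inf` = monosome-only).
#' @param clearanceAa 5' clearance length, codons.
#' @param nonspecificRate nonspecific arrivals per field per second.
#' @param bleachRate translation-irrelevant loss rate, 1/s.
#' @param deadTime reagent-exchange rise duration, s.
#' @param deliveryStart delivery start on the acquisition clock, s.
#' @param baselineLevel diffusing-antibody baseline plateau.
#' @param unitBrightness intensity per dye.
#' @param frameInterval s/frame.
#' @param movieLength kinetic window length, s.
#' @param noiseSigma trace noise sd.
#' @param dyeCountRange integer pair, dyes per antibody.
#' @param seed integer master seed.
#' @return A [SimParams-class] object.
#' @examples
#' p <- SimParams(seed = 7L)
#' p
#' @export
SimParams <- function(firstInit = c(x0 = 120, mu = log(240), sigma = 0.8),
                      elongationRate = 2.5, nCodons = 574L, tagExposureAa = 57L,
                      recognition = c(tauFast = 3.9, tauSlow = 38,
                                      fastFraction = 13 / 14),
                      reinitMean = Inf, clearanceAa = 35L,
                      nonspecificRate = 0.005,
                      bleachRate = -log(0.9) / 1800, deadTime = 3.5,
                      deliveryStart = 10, baselineLevel = 5,
                      unitBrightness = 1, frameInterval = 2,
                      movieLength = 1800, noiseSigma = 0.3,
                      dyeCountRange = c(2L, 7L), seed = 1L) {
    new("SimParams", firstInit = firstInit, elongationRate = elongationRate,
        nCodons = as.integer(nCodons), tagExposureAa = as.integer(tagExposureAa),
        recognition = recognition, reinitMean = reinitMean,
        clearanceAa = as.integer(clearanceAa), nonspecificRate = nonspecificRate,
        bleachRate = bleachRate, deadTime = deadTime,
        deliveryStart = deliveryStart, baselineLevel = baselineLevel,
        unitBrightness = unitBrightness, frameInterval = frameInterval,
        movieLength = movieLength, noiseSigma = noiseSigma,
        dyeCountRange = as.integer(dyeCountRange), seed = as.integer(seed))
}

#' Ground-truth molecular event timeline of one mRNA
#'
#' Times are on the kinetics clock: seconds since completion of the
#' reagent-exchange baseline rise (time 0 of the translation reaction).
#' One row of the binding bookkeeping exists per *observed* antibody binding;
#' a round whose recognition delay would outlast peptide release produces no
#' binding (the event is unobservable).
#'
#' @slot mrnaId character identifier.
#' @slot initiations ascending initiation times, s (all rounds).
#' @slot exposures epitope exposure times per round, s.
#' @slot bindings observed antibody binding times, s.
#' @slot bindingRound initiation round index of each binding.
#' @slot releases scheduled peptide release (termination) per binding, s.
#' @slot bleaches translation-irrelevant loss time per binding, s (`Inf` if
#'   the antibody outlives its ribosome).
#' @slot departures `pmin(releases, bleaches)`: when fluorescence is lost.
#' @slot censored logical per binding: departure (or the binding itself)
#'   falls beyond the observation window.
#' @slot movieLength observation window length, s.
#' @export
setClass("EventTimeline", representation(
    mrnaId = "character", initiations = "numeric", exposures = "numeric",
    bindings = "numeric", bindingRound = "integer", releases = "numeric",
    bleaches = "numeric", departures = "numeric", censored = "logical",
    movieLength = "numeric"))

setValidity("EventTimeline", function(object) {
    msg <- character()
    nb <- length(object@bindings)
    if (length(object@releases) != nb || length(object@bleaches) != nb ||
        length(object@departures) != nb || length(object@censored) != nb ||
        length(object@bindingRound) != nb)
        msg <- c(msg, "binding bookkeeping vectors must have equal length")
    if (is.unsorted(object@initiations, strictly = FALSE))
        msg <- c(msg, "initiations must be ascending")
    if (length(object@exposures) != length(object@initiations))
        msg <- c(msg, "one exposure per initiation required")
    if (length(object@initiations) &&
        any(object@exposures < object@initiations))
        msg <- c(msg, "exposure must follow initiation")
    if (nb) {
        ex <- object@exposures[object@bindingRound]
        if (any(object@bindings < ex - 1e-9))
            msg <- c(msg, "binding cannot precede epitope exposure")
        if (any(object@bindings >= object@releases))
            msg <- c(msg, "binding must precede release")
        if (is.unsorted(object@bindings))
            msg <- c(msg, "bindings must be time-ordered")
    }
    if (length(msg)) msg else TRUE
})

#' Single-molecule fluorescence trace
#'
#' @slot traceId character identifier.
#' @slot times acquisition-clock frame times, s (uniform spacing).
#' @slot intensities intensity per frame, arbitrary units.
#' @slot frameInterval s/frame.
#' @slot truth the generating [EventTimeline-class], or `NULL`.
#' @slot truthAmplitudes per-binding step amplitude (dye count x unit
#'   brightness) aligned with `truth@bindings`; empty when no truth.
#' @slot t0Truth true kinetics time zero on the acquisition clock, s;
#'   `NA` when unknown.
#' @export
setClass("Trace", representation(
    traceId = "character", times = "numeric", intensities = "numeric",
    frameInterval = "numeric", truth = "ANY", truthAmplitudes = "numeric",
    t0Truth = "numeric"))

setValidity("Trace", function(object) {
    msg <- character()
    if (length(object@times) != length(object@intensities))
        msg <- c(msg, "times and intensities must have equal length")
    if (length(object@times) > 1L) {
        dt <- diff(object@times)
        if (any(dt <= 0)) msg <- c(msg, "times must be strictly increasing")
        if (max(abs(dt - object@frameInterval)) > 1e-6 * object@frameInterval)
            msg <- c(msg, "times must be uniformly spaced at frameInterval")
    }
    if (length(msg)) msg else TRUE
})

#' A simulated field of view: traces plus the nonspecific event log
#'
#' @slot traces list of [Trace-class] objects (specific channel).
#' @slot positions numeric matrix (n x 2) of molecule positions, 0-based
#'   pixel units (pixel centers at integers).
#' @slot nonspecific data.frame of nonspecific arrivals: `time` (kinetics
#'   clock, s), `x`, `y`, `amplitude`. Nonspecific binders are never
#'   released, so their count accumulates linearly.
#' @slot params the generating [SimParams-class].
#' @export
setClass("TraceSet", representation(
    traces = "list", positions = "matrix", nonspecific = "data.frame",
    params = "SimParams"))

setValidity("TraceSet", function(object) {
    if (length(object@traces) &&
        (!is.numeric(object@positions) || ncol(object@positions) != 2L ||
         nrow(object@positions) != length(object@traces)))
        return("positions must be an (n traces) x 2 numeric matrix")
    TRUE
})

#' TIRF-like movie stack with ground-truth registry
#'
#' Frames are indexed `[y + 1, x + 1, frame + 1]` for 0-based coordinates
#' `(x, y)` with pixel centers at integers; the time of frame `k` (0-based)
#' is `k * frameInterval` on the acquisition clock.
#'
#' @slot frames numeric array, height x width x frames.
#' @slot frameInterval s/frame.
#' @slot positions molecule positions (n x 2, columns x, y), 0-based
#'   continuous pixel units.
#' @slot psfSigma point-spread-function width, px.
#' @slot background constant background level.
#' @slot driftPath applied per-frame rigid drift (frames x 2, columns dx,
#'   dy), px relative to frame 0; all zero when none applied.
#' @slot truth list of [EventTimeline-class] (may be empty), one per
#'   position.
#' @slot truthAmplitudes list of per-binding amplitudes, parallel to truth.
#' @slot t0Truth true kinetics time zero on the acquisition clock, s.
#' @export
setClass("MovieStack", representation(
    frames = "array", frameInterval = "numeric", positions = "matrix",
    psfSigma = "numeric", background = "numeric", driftPath = "matrix",
    truth = "list", truthAmplitudes = "list", t0Truth = "numeric"))

setValidity("MovieStack", function(object) {
    msg <- character()
    d <- dim(object@frames)
    if (length(d) != 3L) msg <- c(msg, "frames must be a 3D array")
    if (any(!is.finite(object@frames)) || any(object@frames < -1e-9))
        msg <- c(msg, "frame intensities must be finite and >= 0")
    if (nrow(object@positions)) {
        if (ncol(object@positions) != 2L)
            msg <- c(msg, "positions must have 2 columns (x, y)")
        else if (any(object@positions[, 1L] < 0) ||
                 any(object@positions[, 1L] > d[2L] - 1L) ||
                 any(object@positions[, 2L] < 0) ||
                 any(object@positions[, 2L] > d[1L] - 1L))
            msg <- c(msg, "positions must lie within frame bounds")
    }
    if (object@psfSigma <= 0) msg <- c(msg, "psfSigma must be > 0")
    if (nrow(object@driftPath) != d[3L] || ncol(object@driftPath) != 2L)
        msg <- c(msg, "driftPath must be (n frames) x 2")
    else if (any(object@driftPath[1L, ] != 0))
        msg <- c(msg, "driftPath must be relative to frame 0 (first row zero)")
    if (length(msg)) msg else TRUE
})

#' Detected step events and kinetic observables of one trace
#'
#' @slot traceId character identifier.
#' @slot t0 kinetics time zero on the acquisition clock, s.
#' @slot events data.frame `(time, direction, amplitude)`: step time in
#'   seconds since `t0`, direction `"up"`/`"down"`, amplitude in trace units.
#' @slot firstArrival first up-event time since `t0`, s; `NA` when censored.
#' @slot firstArrivalCensored logical.
#' @slot censorTime observation window since `t0`, s.
#' @slot dwells data.frame `(start, duration, amplitude, censored,
#'   monosome)`: paired binding dwells; `censored` marks open dwells at the
#'   movie end, `monosome` marks dwells with no concurrent second antibody.
#' @slot valid `FALSE` when the trace shows a pre-delivery binding artifact
#'   and must be excluded from kinetic analysis.
#' @slot noiseSd estimated trace noise sd.
#' @export
setClass("EventSeries", representation(
    traceId = "character", t0 = "numeric", events = "data.frame",
    firstArrival = "numeric", firstArrivalCensored = "logical",
    censorTime = "numeric", dwells = "data.frame", valid = "logical",
    noiseSd = "numeric"))

setValidity("EventSeries", function(object) {
    ev <- object@events
    if (nrow(ev)) {
        if (!all(c("time", "direction", "amplitude") %in% names(ev)))
            return("events needs columns time, direction, amplitude")
        if (is.unsorted(ev$time)) return("events must be time-ordered")
        if (!all(ev$direction %in% c("up", "down")))
            return("direction must be 'up' or 'down'")
    }
    TRUE
})

## ---- fit result classes ---------------------------------------------------

#' Double-exponential recognition-delay fit
#'
#' Mixture density `f(t) = p/tau1 exp(-t/tau1) + (1-p)/tau2 exp(-t/tau2)`
#' with `tau1 <= tau2` by convention; `ampRatio = p/(1-p)` is the fast/slow
#' amplitude ratio and `fastFraction = ampRatio/(1+ampRatio) = p`.
#'
#' @slot tau1,tau2 time constants, s.
#' @slot ampRatio fast/slow amplitude ratio.
#' @slot fastFraction fraction of events in the fast component.
#' @slot se named bootstrap standard errors (`tau1`, `tau2`, `ampRatio`,
#'   `fastFraction`).
#' @slot n sample size.
#' @slot loglik maximized log-likelihood (MLE mode) or `NA` (binned mode).
#' @slot degenerate `TRUE` when the two components collapse.
#' @slot method `"mle"` or `"binned"`.
#' @export
setClass("DoubleExpFit", representation(
    tau1 = "numeric", tau2 = "numeric", ampRatio = "numeric",
    fastFraction = "numeric", se = "numeric", n = "integer",
    loglik = "numeric", degenerate = "logical", method = "character"))

#' Shifted (3-parameter) log-normal first-arrival fit
#'
#' Histogram model `y = y0` for `x <= x0` and
#' `y = y0 + A / (sqrt(2 pi) sigma (x - x0)) exp(-(ln(x - x0) - mu)^2 /
#' (2 sigma^2))` for `x > x0`; the additive floor `y0` absorbs nonspecific
#' binding.
#'
#' @slot y0 nonspecific floor, counts/bin.
#' @slot A area, counts x bin width.
#' @slot mu,sigma log-normal parameters.
#' @slot x0 location shift, s.
#' @slot se named bootstrap standard errors of the five parameters.
#' @slot mean derived distribution mean `x0 + exp(mu + sigma^2/2)`, s.
#' @slot peak derived mode `x0 + exp(mu - sigma^2)`, s.
#' @slot seMean,sePeak bootstrap standard errors of mean and peak.
#' @slot n sample size.
#' @slot binEdges histogram bin edges used for the fit.
#' @export
setClass("ShiftedLogNormalFit", representation(
    y0 = "numeric", A = "numeric", mu = "numeric", sigma = "numeric",
    x0 = "numeric", se = "numeric", mean = "numeric", peak = "numeric",
    seMean = "numeric", sePeak = "numeric", n = "integer",
    binEdges = "numeric"))

setValidity("ShiftedLogNormalFit", function(object) {
    msg <- character()
    if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
    if (object@A <= 0) msg <- c(msg, "A must be > 0")
    if (!(object@mean > object@peak && object@peak > object@x0))
        msg <- c(msg, "expected mean > peak > x0")
    if (length(msg)) msg else TRUE
})

#' Log-normal dwell-time fit
#'
#' @slot mu,sigma log-scale parameters (MLE).
#' @slot mean distribution mean `exp(mu + sigma^2/2)`, input time units.
#' @slot seMean bootstrap standard error of the mean.
#' @slot n sample size.
#' @export
setClass("LogNormalFit", representation(
    mu = "numeric", sigma = "numeric", mean = "numeric", seMean = "numeric",
    n = "integer"))

#' Translational asynchrony profile
#'
#' Fractions of molecules whose first arrival falls in consecutive windows
#' of one mean peptide-elongation time; molecules in one interval lead the
#' next interval by a full round of peptide synthesis.
#'
#' @slot intervalWidth window width (mean elongation time), s.
#' @slot nIntervals number of windows.
#' @slot fractions fraction of molecules per window.
#' @slot remainder fraction arriving after the last window.
#' @slot n sample size.
#' @export
setClass("AsynchronyProfile", representation(
    intervalWidth = "numeric", nIntervals = "integer", fractions = "numeric",
    remainder = "numeric", n = "integer"))

setValidity("AsynchronyProfile", function(object) {
    if (any(object@fractions < 0) || object@remainder < -1e-12)
        return("fractions must be nonnegative")
    if (abs(sum(object@fractions) + object@remainder - 1) > 1e-9)
        return("fractions and remainder must sum to 1")
    TRUE
})
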