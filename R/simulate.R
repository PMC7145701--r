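## Ground-truth simulator: per-mRNA molecular event timelines, fluorescence
## traces, fields of view, and TIRF-like movie stacks.

## deterministic per-molecule sub-seed so each molecule's history is
## reproducible in isolation and fields regenerate bit-identically
.moleculeSeed <- function(seed, id) {
    (as.double(seed) * 48271 + as.double(id) * 1009) %% 2147483647
}

#' Simulate the molecular event timeline of one mRNA
#'
#' Draws the first-round initiation time from the shifted log-normal law,
#' then (when re-initiation is enabled) subsequent initiations with
#' exponential waiting times subject to a 5' clearance rule: a new
#' initiation is blocked until the previous ribosome has translated
#' `clearanceAa` codons. Each initiation exposes the epitope after
#' `tagExposureAa / elongationRate` seconds and terminates (releasing the
#' antibody with the peptide) after `nCodons / elongationRate` seconds. The
#' antibody recognition delay is drawn from the double-exponential mixture;
#' a binding whose recognition delay would outlast release is discarded as
#' unobservable. Each bound antibody carries an independent exponential
#' translation-irrelevant loss clock (`bleachRate`). Events extending past
#' the observation window are flagged censored.
#'
#' All times are on the kinetics clock (seconds since completion of the
#' reagent-exchange baseline rise).
#'
#' @param params a [SimParams-class] object.
#' @param mrnaId integer molecule index; with `params@seed` it determines
#'   the molecule's private random stream.
#' @return An [EventTimeline-class] object.
#' @examples
#' tl <- simulateTimeline(SimParams(seed = 3L), mrnaId = 1L)
#' tl
#' @export
simulateTimeline <- function(params, mrnaId = 1L) {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    set.seed(.moleculeSeed(params@seed, mrnaId))
    rate <- params@elongationRate
    tExpose <- params@tagExposureAa / rate
    tTotal <- params@nCodons / rate
    TL <- params@movieLength

    inits <- rFirstInit(1L, params)
    if (is.finite(params@reinitMean)) {
        tClear <- params@clearanceAa / rate
        cur <- inits
        repeat {
            nxt <- max(cur + rexp(1L) * params@reinitMean, cur + tClear)
            if (nxt > TL) break
            inits <- c(inits, nxt)
            cur <- nxt
        }
    }
    exposures <- inits + tExpose
    releases0 <- inits + tTotal
    delays <- rRecognitionDelay(length(inits), params)
    observed <- delays < (tTotal - tExpose)
    bindings <- exposures[observed] + delays[observed]
    rounds <- which(observed)
    releases <- releases0[observed]
    ## a slow recognition can bind after a later round's fast one
    ord <- order(bindings)
    bindings <- bindings[ord]; rounds <- rounds[ord]
    releases <- releases[ord]
    bleachDelay <- if (params@bleachRate > 0)
        rexp(length(bindings)) / params@bleachRate else rep(Inf, length(bindings))
    bleaches <- bindings + bleachDelay
    departures <- pmin(releases, bleaches)
    censored <- bindings > TL | departures > TL

    new("EventTimeline", mrnaId = as.character(mrnaId),
        initiations = inits, exposures = exposures, bindings = bindings,
        bindingRound = as.integer(rounds), releases = releases,
        bleaches = bleaches, departures = departures, censored = censored,
        movieLength = TL)
}

#' Synthesize a fluorescence trace from an event timeline
#'
#' Intensity is the sum of (i) the diffusing-antibody baseline: zero before
#' reagent delivery, a linear rise of duration `deadTime` starting at
#' `deliveryStart`, then a plateau at `baselineLevel`; (ii) one step of
#' per-antibody amplitude (dye count drawn uniformly on `dyeCountRange`
#' times `unitBrightness`) for every currently bound antibody; and (iii)
#' additive Gaussian noise of sd `noiseSigma`. Frame `k` (0-based) sits at
#' `k * frameInterval` on the acquisition clock; kinetic event times are
#' offset by `t0 = deliveryStart + deadTime`.
#'
#' @param timeline an [EventTimeline-class].
#' @param params the [SimParams-class] used to generate it.
#' @param traceId identifier stored in the trace.
#' @return A [Trace-class] with `truth`, `truthAmplitudes` and `t0Truth`
#'   attached.
#' @export
synthesizeTrace <- function(timeline, params, traceId = timeline@mrnaId) {
    stopifnot(is(timeline, "EventTimeline"), is(params, "SimParams"))
    t0 <- params@deliveryStart + params@deadTime
    total <- t0 + params@movieLength
    times <- seq(0, total, by = params@frameInterval)
    base <- baselineProfile(times, params)
    nb <- length(timeline@bindings)
    amps <- rDyeAmplitude(nb, params)
    sig <- base
    if (nb) {
        on <- t0 + timeline@bindings
        off <- t0 + timeline@departures
        for (j in seq_len(nb))
            sig <- sig + amps[j] * (times >= on[j] & times < off[j])
    }
    if (params@noiseSigma > 0)
        sig <- sig + rnorm(length(times), sd = params@noiseSigma)
    new("Trace", traceId = as.character(traceId), times = times,
        intensities = sig, frameInterval = params@frameInterval,
        truth = timeline, truthAmplitudes = amps, t0Truth = t0)
}

#' Diffusing-antibody baseline profile
#'
#' @param times acquisition-clock times, s.
#' @param params a [SimParams-class].
#' @return baseline intensity at `times`.
#' @export
baselineProfile <- function(times, params) {
    t0 <- params@deliveryStart
    ramp <- (times - t0) / params@deadTime
    params@baselineLevel * pmin(pmax(ramp, 0), 1)
}

#' Simulate a field of view
#'
#' Generates `nMrna` specific traces (each molecule on its own seeded
#' stream) at random positions, plus nonspecific antibody arrivals as a
#' homogeneous Poisson process of rate `nonspecificRate` over the kinetic
#' window, placed uniformly in the field and never released, so their count
#' accumulates approximately linearly.
#'
#' @param params a [SimParams-class].
#' @param nMrna number of tethered mRNA molecules (>= 0).
#' @param fieldSize integer `(width, height)` of the field, px.
#' @param margin minimum distance of molecule positions from the field
#'   border, px.
#' @return A [TraceSet-class].
#' @examples
#' fld <- simulateField(SimParams(seed = 11L, reinitMean = 60), nMrna = 5)
#' fld
#' @export
simulateField <- function(params, nMrna, fieldSize = c(64L, 64L),
                          margin = 5) {
    stopifnot(is(params, "SimParams"), nMrna >= 0)
    ## trace synthesis continues each molecule's private seeded stream, so
    ## molecule i is identical whatever nMrna is
    trs <- vector("list", nMrna)
    for (i in seq_len(nMrna))
        trs[[i]] <- synthesizeTrace(simulateTimeline(params, mrnaId = i),
                                    params)

    set.seed(.moleculeSeed(params@seed, 0L))
    pos <- cbind(x = runif(nMrna, margin, fieldSize[1L] - 1 - margin),
                 y = runif(nMrna, margin, fieldSize[2L] - 1 - margin))
    nNs <- rpois(1L, params@nonspecificRate * params@movieLength)
    nsTimes <- sort(runif(nNs, 0, params@movieLength))
    ns <- data.frame(time = nsTimes,
                     x = runif(nNs, 0, fieldSize[1L] - 1),
                     y = runif(nNs, 0, fieldSize[2L] - 1),
                     amplitude = rDyeAmplitude(nNs, params))
    new("TraceSet", traces = trs, positions = pos, nonspecific = ns,
        params = params)
}

## evaluate a symmetric 2D Gaussian (peak amplitude A) on a pixel window
.addSpot <- function(frame, x, y, A, sigma) {
    H <- nrow(frame); W <- ncol(frame)
    r <- ceiling(5 * sigma)
    cx <- seq(max(0, floor(x) - r), min(W - 1, ceiling(x) + r))
    cy <- seq(max(0, floor(y) - r), min(H - 1, ceiling(y) + r))
    if (!length(cx) || !length(cy)) return(frame)
    gx <- exp(-(cx - x)^2 / (2 * sigma^2))
    gy <- exp(-(cy - y)^2 / (2 * sigma^2))
    frame[cy + 1, cx + 1] <- frame[cy + 1, cx + 1] + A * outer(gy, gx)
    frame
}

#' Render a TIRF-like movie stack from simulated traces
#'
#' Each bound antibody is rendered as a symmetric 2D Gaussian of width
#' `psfSigma` (peak height = the antibody's step amplitude, so the
#' integrated spot intensity is `amplitude * 2 * pi * psfSigma^2`) at its
#' molecule's position, on a constant background, with optional rigid
#' per-frame drift and per-pixel noise. The diffusing-antibody baseline is
#' rendered as a field-wide uniform level following the same ramp as the
#' traces (scaled per pixel by `baselineScale`).
#'
#' @param traces list of [Trace-class] objects with ground truth attached
#'   (e.g. from [simulateField()]).
#' @param positions matrix (n x 2) of molecule positions, 0-based pixel
#'   units.
#' @param params the generating [SimParams-class].
#' @param dim integer `(width, height)` in px.
#' @param psfSigma PSF width, px.
#' @param background constant background level, counts.
#' @param drift `NULL`, or an (n frames) x 2 matrix of rigid displacements
#'   (applied to all spot positions) relative to frame 0.
#' @param noise `"gaussian"`, `"poisson"` or `"none"`.
#' @param readNoiseSd sd of Gaussian pixel noise (ignored otherwise).
#' @param baselineScale per-pixel intensity of the diffusing-antibody
#'   baseline at plateau.
#' @param nonspecific optional nonspecific arrival log (data.frame with
#'   `time`, `x`, `y`, `amplitude`) rendered as never-released spots.
#' @return A [MovieStack-class] with the ground-truth registry and the
#'   applied drift path recorded.
#' @export
renderMovie <- function(traces, positions, params, dim = c(64L, 64L),
                        psfSigma = 1.2, background = 10, drift = NULL,
                        noise = c("gaussian", "poisson", "none"),
                        readNoiseSd = 0.5, baselineScale = 0.02,
                        nonspecific = NULL) {
    noise <- match.arg(noise)
    W <- as.integer(dim[1L]); H <- as.integer(dim[2L])
    stopifnot(length(traces) == 0L || nrow(positions) == length(traces))
    if (length(traces) && (any(positions[, 1L] < 0) ||
        any(positions[, 1L] > W - 1) || any(positions[, 2L] < 0) ||
        any(positions[, 2L] > H - 1)))
        stop("positions outside frame")
    tRef <- if (length(traces)) traces[[1L]] else NULL
    fi <- params@frameInterval
    times <- if (is.null(tRef))
        seq(0, params@deliveryStart + params@deadTime + params@movieLength,
            by = fi) else tRef@times
    nf <- length(times)
    if (is.null(drift)) drift <- matrix(0, nf, 2L)
    stopifnot(nrow(drift) == nf, ncol(drift) == 2L)
    t0 <- params@deliveryStart + params@deadTime
    base <- baselineProfile(times, params) / params@baselineLevel *
        baselineScale

    ## per-frame bound amplitude per molecule from ground truth
    arr <- array(0, c(H, W, nf))
    set.seed(.moleculeSeed(params@seed, -1L))
    for (k in seq_len(nf)) {
        fr <- matrix(background + base[k], H, W)
        tk <- times[k]
        for (i in seq_along(traces)) {
            tl <- traces[[i]]@truth
            if (is.null(tl) || !length(tl@bindings)) next
            on <- tk >= t0 + tl@bindings & tk < t0 + tl@departures
            if (!any(on)) next
            A <- sum(traces[[i]]@truthAmplitudes[on])
            fr <- .addSpot(fr, positions[i, 1L] + drift[k, 1L],
                           positions[i, 2L] + drift[k, 2L], A, psfSigma)
        }
        if (!is.null(nonspecific) && nrow(nonspecific)) {
            on <- which(tk >= t0 + nonspecific$time)
            for (j in on)
                fr <- .addSpot(fr, nonspecific$x[j] + drift[k, 1L],
                               nonspecific$y[j] + drift[k, 2L],
                               nonspecific$amplitude[j], psfSigma)
        }
        arr[, , k] <- fr
    }
    if (noise == "gaussian" && readNoiseSd > 0)
        arr <- arr + array(rnorm(length(arr), sd = readNoiseSd), dim(arr))
    else if (noise == "poisson")
        arr <- array(rpois(length(arr), lambda = pmax(arr, 0)), dim(arr))
    arr <- pmax(arr, 0)
    new("MovieStack", frames = arr, frameInterval = fi,
        positions = if (length(traces)) positions else
            matrix(numeric(), 0L, 2L),
        psfSigma = psfSigma, background = background, driftPath = drift,
        truth = lapply(traces, function(tr) tr@truth),
        truthAmplitudes = lapply(traces, function(tr) tr@truthAmplitudes),
        t0Truth = t0)
}
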