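## Imaging pipeline: drift estimation/correction, background subtraction,
## spot detection, sub-pixel 2D Gaussian localization, aperture photometry.

## 3-point sub-sample interpolation of a correlation peak. Log-parabolic
## (exact for a Gaussian-shaped peak, which spot-image correlations are)
## when all three samples are positive, plain parabolic otherwise.
.parabolic <- function(m1, p0, p1) {
    if (is.finite(m1) && is.finite(p1) && m1 > 0 && p1 > 0 && p0 > 0) {
        m1 <- log(m1); p0 <- log(p0); p1 <- log(p1)
    }
    den <- m1 + p1 - 2 * p0
    if (!is.finite(den) || den >= 0) return(0)
    d <- 0.5 * (m1 - p1) / den
    max(min(d, 0.5), -0.5)
}

## cross-correlation displacement of `img` relative to `ref` via FFT,
## sub-pixel by quadratic interpolation around the correlation peak.
## Returns c(dx, dy, quality) with quality = normalized correlation height.
.xcorrShift <- function(ref, img, refFft = NULL) {
    H <- nrow(ref); W <- ncol(ref)
    a <- ref - mean(ref); b <- img - mean(img)
    sa <- sd(a); sb <- sd(b)
    if (sa < .Machine$double.eps || sb < .Machine$double.eps)
        return(c(NA_real_, NA_real_, 0))
    if (is.null(refFft)) refFft <- Conj(fft(a))
    cc <- Re(fft(refFft * fft(b), inverse = TRUE)) / (H * W)
    quality <- max(cc) / (sa * sb * H * W)
    pk <- arrayInd(which.max(cc), dim(cc))
    iy <- pk[1L]; ix <- pk[2L]
    wrap <- function(i, n) ((i - 1L) %% n) + 1L
    dy <- .parabolic(cc[wrap(iy - 1L, H), ix], cc[iy, ix],
                     cc[wrap(iy + 1L, H), ix])
    dx <- .parabolic(cc[iy, wrap(ix - 1L, W)], cc[iy, ix],
                     cc[iy, wrap(ix + 1L, W)])
    sx <- ix - 1L; sy <- iy - 1L
    if (sx > W / 2) sx <- sx - W
    if (sy > H / 2) sy <- sy - H
    c(sx + dx, sy + dy, quality)
}

#' Estimate rigid drift of a movie
#'
#' Per-frame rigid displacement relative to frame 0, estimated by Fourier
#' cross-correlation of each frame against the reference, with sub-pixel
#' refinement by quadratic interpolation of the correlation peak.
#'
#' @param movie a [MovieStack-class] with at least 2 frames.
#' @param reference `"mean"` (average of `refFrames` frames evenly spaced
#'   over the movie; robust when early frames precede reagent delivery and
#'   carry no spots) or `"first"` (frame 0).
#' @param refFrames frames averaged for the `"mean"` reference.
#' @param minQuality minimum normalized correlation height; frames below
#'   it (featureless, e.g. before any antibody binds) get their
#'   displacement interpolated from neighboring well-correlated frames.
#' @param maxShift largest physically plausible displacement, px; larger
#'   estimates are spurious constellation matches (a lone spot aligned
#'   onto a different molecule) and are interpolated over instead.
#' @param smoothWindow odd running-median window (frames) applied to the
#'   path; stage drift is slow and smooth, so this suppresses single-frame
#'   outliers without biasing a linear drift. `1` disables smoothing.
#' @param refine run a second pass against a drift-compensated reference
#'   (sharper than the raw frame average when drift is appreciable).
#' @return An (n frames) x 2 matrix (`dx`, `dy`) in px; row 1 is `(0, 0)`.
#'   An entirely featureless movie yields all zeros with a warning.
#' @export
estimateDrift <- function(movie, reference = c("mean", "first"),
                          refFrames = 20L, minQuality = 0.2, maxShift = 5,
                          smoothWindow = 9L, refine = TRUE) {
    stopifnot(is(movie, "MovieStack"))
    reference <- match.arg(reference)
    fr <- movie@frames
    nf <- dim(fr)[3L]
    stopifnot(nf >= 2L)
    idx <- unique(round(seq(1L, nf, length.out = min(refFrames, nf))))
    ref <- if (reference == "first") fr[, , 1L] else
        apply(fr[, , idx, drop = FALSE], c(1, 2), mean)
    path <- .driftPass(fr, ref, minQuality, maxShift, smoothWindow)
    if (is.null(path)) {
        warning("featureless movie: zero displacement assumed")
        path <- matrix(0, nf, 2L, dimnames = list(NULL, c("dx", "dy")))
        return(path)
    }
    if (refine && reference == "mean" && any(path != 0)) {
        ## average drift-compensated frames into a sharper reference
        acc <- 0
        for (k in idx)
            acc <- acc + .shiftFrame(fr[, , k], path[k, 1L], path[k, 2L])
        p2 <- .driftPass(fr, acc / length(idx), minQuality, maxShift,
                         smoothWindow)
        if (!is.null(p2)) path <- p2
    }
    sweep(path, 2L, path[1L, ])
}

## one estimation pass: returns filled, smoothed path (not re-referenced),
## or NULL when no frame correlates acceptably
.driftPass <- function(fr, ref, minQuality, maxShift, smoothWindow) {
    nf <- dim(fr)[3L]
    refFft <- Conj(fft(ref - mean(ref)))
    path <- matrix(NA_real_, nf, 2L, dimnames = list(NULL, c("dx", "dy")))
    for (k in seq_len(nf)) {
        s <- .xcorrShift(ref, fr[, , k], refFft)
        if (!anyNA(s) && s[3L] >= minQuality &&
            max(abs(s[1:2])) <= maxShift) path[k, ] <- s[1:2]
    }
    ok <- complete.cases(path)
    if (!any(ok)) return(NULL)
    if (sum(ok) == 1L) {
        path[!ok, 1L] <- path[ok, 1L][1L]
        path[!ok, 2L] <- path[ok, 2L][1L]
    } else if (!all(ok)) {  # fill poorly correlated frames from neighbors
        idx <- seq_len(nf)
        for (j in 1:2)
            path[!ok, j] <- stats::approx(idx[ok], path[ok, j], idx[!ok],
                                          rule = 2)$y
    }
    k <- min(as.integer(smoothWindow), nf)
    if (k %% 2L == 0L) k <- k - 1L
    if (k >= 3L)
        for (j in 1:2) path[, j] <- stats::runmed(path[, j], k)
    path
}

## shift a frame by (-dx, -dy) with bilinear interpolation, edge clamp
.shiftFrame <- function(fr, dx, dy) {
    H <- nrow(fr); W <- ncol(fr)
    xs <- pmin(pmax(seq_len(W) + dx, 1), W)
    ys <- pmin(pmax(seq_len(H) + dy, 1), H)
    x0 <- pmin(floor(xs), W - 1L); y0 <- pmin(floor(ys), H - 1L)
    fx <- xs - x0; fy <- ys - y0
    f00 <- fr[y0, x0]; f01 <- fr[y0, x0 + 1L]
    f10 <- fr[y0 + 1L, x0]; f11 <- fr[y0 + 1L, x0 + 1L]
    wfy <- matrix(fy, H, W); wfx <- matrix(fx, H, W, byrow = TRUE)
    f00 * (1 - wfy) * (1 - wfx) + f01 * (1 - wfy) * wfx +
        f10 * wfy * (1 - wfx) + f11 * wfy * wfx
}

#' Correct a movie for rigid drift
#'
#' Resamples every frame by the negated drift path (bilinear interpolation,
#' edge clamp) so all frames align with frame 0.
#'
#' @param movie a [MovieStack-class].
#' @param path drift path from [estimateDrift()] (defaults to estimating
#'   it).
#' @return A drift-corrected [MovieStack-class]; its `driftPath` records
#'   the residual (all zeros by construction).
#' @export
correctDrift <- function(movie, path = estimateDrift(movie)) {
    fr <- movie@frames
    nf <- dim(fr)[3L]
    out <- fr
    for (k in seq_len(nf))
        if (any(path[k, ] != 0))
            out[, , k] <- .shiftFrame(fr[, , k], path[k, 1L], path[k, 2L])
    initialize(movie, frames = out, driftPath = matrix(0, nf, 2L))
}

#' Subtract the slowly varying background of every frame
#'
#' Per-frame background is estimated by a median filter whose radius is
#' much larger than the PSF (default `10 * psfSigma`) and subtracted.
#' Residuals are left signed so that downstream aperture photometry is
#' unbiased; clip only for image output.
#'
#' @param movie a [MovieStack-class].
#' @param radius median-filter radius, px.
#' @param clip clip negative residuals at zero (for display/export only).
#' @return A background-corrected [MovieStack-class] (`background` slot set
#'   to 0).
#' @export
subtractBackground <- function(movie, radius = ceiling(10 * movie@psfSigma),
                               clip = FALSE) {
    stopifnot(is(movie, "MovieStack"))
    fr <- movie@frames
    out <- fr
    for (k in seq_len(dim(fr)[3L])) {
        f <- fr[, , k]
        lo <- min(f); hi <- max(f)
        bg <- if (hi - lo < .Machine$double.eps) f else {
            norm <- (f - lo) / (hi - lo)
            EBImage::medianFilter(norm, size = radius) * (hi - lo) + lo
        }
        out[, , k] <- f - bg
    }
    if (clip) out <- pmax(out, 0)
    res <- movie
    res@frames <- out
    res@background <- 0
    res
}

#' Detect candidate spots in one frame
#'
#' Local maxima exceeding `thresholdSigma` times the robust noise sd
#' (median absolute deviation) of the background-corrected frame, with
#' non-maximum suppression within `2 * psfSigma`.
#'
#' @param frame numeric matrix (background-corrected).
#' @param thresholdSigma detection threshold in noise-sd units (> 0).
#' @param psfSigma PSF width, px.
#' @return data.frame `(x, y, intensity)` of integer-pixel candidates,
#'   0-based coordinates, strongest first.
#' @export
detectSpots <- function(frame, thresholdSigma = 5, psfSigma = 1.2) {
    stopifnot(thresholdSigma > 0)
    H <- nrow(frame); W <- ncol(frame)
    noiseSd <- mad(frame, center = median(frame))
    thr <- median(frame) + thresholdSigma * noiseSd
    if (H < 3L || W < 3L) return(data.frame(x = integer(), y = integer(),
                                            intensity = numeric()))
    ctr <- frame[2:(H - 1), 2:(W - 1)]
    isMax <- ctr > thr
    for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0) next
        isMax <- isMax & ctr >= frame[2:(H - 1) + dy, 2:(W - 1) + dx]
    }
    idx <- which(isMax, arr.ind = TRUE)
    if (!nrow(idx)) return(data.frame(x = integer(), y = integer(),
                                      intensity = numeric()))
    cand <- data.frame(x = idx[, 2L], y = idx[, 1L],  # 0-based: (+1 pad -1)
                       intensity = ctr[idx])
    cand <- cand[order(-cand$intensity), ]
    ## non-maximum suppression
    keep <- logical(nrow(cand))
    minD2 <- (2 * psfSigma)^2
    for (i in seq_len(nrow(cand))) {
        ok <- TRUE
        if (any(keep)) {
            d2 <- (cand$x[keep] - cand$x[i])^2 + (cand$y[keep] - cand$y[i])^2
            ok <- all(d2 > minD2)
        }
        keep[i] <- ok
    }
    out <- cand[keep, ]
    rownames(out) <- NULL
    out
}

#' Localize one spot with sub-pixel resolution
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt) of a symmetric 2D
#' Gaussian plus constant offset on a window of half-width
#' `ceiling(3 * psfSigma)` around the candidate.
#'
#' @param frame numeric matrix.
#' @param candidate numeric `(x, y)` integer-pixel candidate, 0-based.
#' @param psfSigma PSF width, px.
#' @param windowHalf fit window half-width, px.
#' @return One-row data.frame: `centerX`, `centerY` (0-based sub-pixel),
#'   `amplitude`, `sigma`, `backgroundLocal`, `residualRms`, `success`.
#'   `success` is `FALSE` when the window is clipped by the frame edge, the
#'   fit diverges, the center leaves the window, or `sigma` falls outside
#'   `[0.5, 3] * psfSigma`.
#' @export
localizeSpot <- function(frame, candidate, psfSigma = 1.2,
                         windowHalf = ceiling(3 * psfSigma)) {
    H <- nrow(frame); W <- ncol(frame)
    cx <- round(candidate[[1L]]); cy <- round(candidate[[2L]])
    fail <- data.frame(centerX = NA_real_, centerY = NA_real_,
                       amplitude = NA_real_, sigma = NA_real_,
                       backgroundLocal = NA_real_, residualRms = NA_real_,
                       success = FALSE)
    if (cx - windowHalf < 0 || cx + windowHalf > W - 1 ||
        cy - windowHalf < 0 || cy + windowHalf > H - 1)
        return(fail)
    xs <- (cx - windowHalf):(cx + windowHalf)
    ys <- (cy - windowHalf):(cy + windowHalf)
    z <- frame[ys + 1L, xs + 1L]
    gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    gy <- matrix(ys, length(ys), length(xs))
    b0 <- median(z); a0 <- max(z) - b0
    if (a0 <= 0 || sd(as.vector(z)) < .Machine$double.eps) return(fail)
    resid <- function(p)
        as.vector(z - (p[5L] + p[3L] *
            exp(-((gx - p[1L])^2 + (gy - p[2L])^2) / (2 * p[4L]^2))))
    fit <- try(minpack.lm::nls.lm(
        par = c(cx, cy, a0, psfSigma, b0), fn = resid,
        control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (inherits(fit, "try-error")) return(fail)
    p <- fit$par
    sig <- abs(p[4L])
    ok <- is.finite(sum(p)) && p[3L] > 0 &&
        sig >= 0.5 * psfSigma && sig <= 3 * psfSigma &&
        p[1L] >= min(xs) && p[1L] <= max(xs) &&
        p[2L] >= min(ys) && p[2L] <= max(ys)
    data.frame(centerX = p[1L], centerY = p[2L], amplitude = p[3L],
               sigma = sig, backgroundLocal = p[5L],
               residualRms = sqrt(mean(resid(p)^2)), success = ok)
}

#' Localize all spots of a frame
#'
#' Convenience wrapper: [detectSpots()] then [localizeSpot()] per
#' candidate.
#'
#' @inheritParams detectSpots
#' @return data.frame of [localizeSpot()] rows plus candidate columns.
#' @export
localizeFrame <- function(frame, thresholdSigma = 5, psfSigma = 1.2) {
    cand <- detectSpots(frame, thresholdSigma, psfSigma)
    if (!nrow(cand))
        return(cbind(cand, localizeSpot(matrix(0, 1, 1), c(0, 0))[0, ]))
    fits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
        localizeSpot(frame, c(cand$x[i], cand$y[i]), psfSigma)))
    cbind(cand, fits)
}

#' Extract intensity traces by fixed-aperture photometry
#'
#' Per frame and molecule position, sums the (drift- and
#' background-corrected) movie over a circular aperture of radius
#' `apertureRadius` and converts the sum to PSF peak-amplitude units by
#' dividing by `2 pi sigma^2 (1 - exp(-r^2 / (2 sigma^2)))`, the fraction
#' of a unit-peak Gaussian inside the aperture. Photometry uses the fixed
#' mRNA map positions (not per-frame re-detection) so that intensity is
#' measured before any antibody binds.
#'
#' @param movie a drift- and background-corrected [MovieStack-class].
#' @param positions matrix (n x 2) of molecule positions, 0-based px;
#'   defaults to the movie's ground-truth registry.
#' @param apertureRadius aperture radius, px.
#' @param edgeMargin positions closer than this to the border are flagged
#'   and dropped.
#' @param keepFlagged keep traces flagged for edge proximity or aperture
#'   overlap.
#' @return list of [Trace-class] objects (ground truth attached when the
#'   movie carries a registry); attribute `"flags"` is a data.frame of
#'   per-position `edge`/`overlap` flags.
#' @export
extractTraces <- function(movie, positions = movie@positions,
                          apertureRadius = 2 * movie@psfSigma,
                          edgeMargin = 3 * movie@psfSigma,
                          keepFlagged = FALSE) {
    stopifnot(is(movie, "MovieStack"), nrow(positions) >= 1L)
    fr <- movie@frames
    H <- dim(fr)[1L]; W <- dim(fr)[2L]; nf <- dim(fr)[3L]
    n <- nrow(positions)
    edge <- positions[, 1L] < edgeMargin | positions[, 1L] > W - 1 - edgeMargin |
        positions[, 2L] < edgeMargin | positions[, 2L] > H - 1 - edgeMargin
    overlap <- logical(n)
    if (n > 1L) {
        d <- as.matrix(dist(positions))
        diag(d) <- Inf
        overlap <- apply(d < 2 * apertureRadius, 1L, any)
    }
    flags <- data.frame(edge = edge, overlap = overlap)
    if (any(edge | overlap))
        warning(sum(edge), " edge-flagged and ", sum(overlap),
                " overlap-flagged position(s)")
    s2 <- movie@psfSigma^2
    calib <- 2 * pi * s2 * (1 - exp(-apertureRadius^2 / (2 * s2)))
    flat <- matrix(fr, H * W, nf)
    times <- (seq_len(nf) - 1L) * movie@frameInterval
    out <- vector("list", n)
    for (i in seq_len(n)) {
        if (!keepFlagged && (edge[i] || overlap[i])) next
        xs <- pmax(0, floor(positions[i, 1L] - apertureRadius)):
            pmin(W - 1, ceiling(positions[i, 1L] + apertureRadius))
        ys <- pmax(0, floor(positions[i, 2L] - apertureRadius)):
            pmin(H - 1, ceiling(positions[i, 2L] + apertureRadius))
        g <- expand.grid(y = ys, x = xs)
        inAp <- (g$x - positions[i, 1L])^2 + (g$y - positions[i, 2L])^2 <=
            apertureRadius^2
        lin <- g$y[inAp] + 1L + g$x[inAp] * H
        vals <- colSums(flat[lin, , drop = FALSE]) / calib
        out[[i]] <- new("Trace", traceId = as.character(i), times = times,
                        intensities = vals,
                        frameInterval = movie@frameInterval,
                        truth = if (length(movie@truth) >= i)
                            movie@truth[[i]] else NULL,
                        truthAmplitudes = if (length(movie@truthAmplitudes) >= i)
                            movie@truthAmplitudes[[i]] else numeric(),
                        t0Truth = movie@t0Truth)
    }
    keep <- !vapply(out, is.null, logical(1L))
    res <- out[keep]
    attr(res, "flags") <- flags
    res
}
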