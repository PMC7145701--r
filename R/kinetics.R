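## Kinetic model fitting: double-exponential recognition, shifted
## (3-parameter) log-normal first arrival, log-normal dwell, and derived
## initiation/elongation quantities.

.logit <- function(p) log(p / (1 - p))
.invlogit <- function(z) 1 / (1 + exp(-z))

## negative log-likelihood of the two-exponential mixture
.dexpMixNll <- function(theta, x) {
    t1 <- exp(theta[1L]); t2 <- exp(theta[2L]); p <- .invlogit(theta[3L])
    f <- p / t1 * exp(-x / t1) + (1 - p) / t2 * exp(-x / t2)
    -sum(log(pmax(f, 1e-300)))
}

.fitDexpMle <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.9))
    starts <- list(c(log(max(q[[1L]], 1e-6)), log(max(q[[3L]], 1e-5)), .logit(0.7)),
                   c(log(max(mean(x) / 3, 1e-6)), log(mean(x) * 2), 0))
    best <- NULL
    for (s in starts) {
        ft <- try(optim(s, .dexpMixNll, x = x, method = "Nelder-Mead",
                        control = list(maxit = 2000)), silent = TRUE)
        if (inherits(ft, "try-error")) next
        if (is.null(best) || ft$value < best$value) best <- ft
    }
    if (is.null(best)) stop("double-exponential fit did not converge")
    t1 <- exp(best$par[1L]); t2 <- exp(best$par[2L])
    p <- .invlogit(best$par[3L])
    if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp; p <- 1 - p }
    list(tau1 = t1, tau2 = t2, p = p, loglik = -best$value)
}

.fdBreaks <- function(x) {
    h <- 2 * stats::IQR(x) / length(x)^(1 / 3)
    if (h <= 0) h <- diff(range(x)) / 30
    nb <- max(10L, ceiling(diff(range(x)) / h))
    seq(min(x), max(x), length.out = nb + 1L)
}

## binned least-squares fit of y = A1/t1 e^{-t/t1} + A2/t2 e^{-t/t2}
.fitDexpBinned <- function(x, breaks) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    mids <- h$mids; counts <- h$counts
    bw <- diff(h$breaks)
    st <- .fitDexpMle(x[seq_len(min(length(x), 2000L))])
    n <- length(x)
    df <- data.frame(t = mids, y = counts, bw = bw)
    ft <- minpack.lm::nlsLM(
        y ~ bw * (exp(lA1) / exp(lt1) * exp(-t / exp(lt1)) +
                  exp(lA2) / exp(lt2) * exp(-t / exp(lt2))),
        data = df,
        start = list(lt1 = log(st$tau1), lt2 = log(st$tau2),
                     lA1 = log(max(n * st$p, 1e-6)),
                     lA2 = log(max(n * (1 - st$p), 1e-6))),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(ft)
    t1 <- exp(cf[["lt1"]]); t2 <- exp(cf[["lt2"]])
    A1 <- exp(cf[["lA1"]]); A2 <- exp(cf[["lA2"]])
    if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp
                   tmp <- A1; A1 <- A2; A2 <- tmp }
    list(tau1 = t1, tau2 = t2, p = A1 / (A1 + A2), loglik = NA_real_)
}

#' Fit a double-exponential distribution to first-arrival samples
#'
#' Maximum-likelihood fit of the two-component exponential mixture
#' `f(t) = p/tau1 exp(-t/tau1) + (1-p)/tau2 exp(-t/tau2)` to raw samples
#' (default), or a binned least-squares fit of
#' `y = A1/tau1 exp(-t/tau1) + A2/tau2 exp(-t/tau2)` to histogram counts.
#' Standard errors are the sd over `nBoot` nonparametric resamples with a
#' fixed seed. The fast/slow amplitude ratio is `A1/A2 = p/(1-p)` and the
#' fast fraction `p` is the share of events with the fast time constant.
#'
#' @param samples positive recognition/arrival delays (uncensored), s.
#' @param nBoot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @param method `"mle"` (raw samples) or `"binned"` (histogram
#'   least-squares, mirroring histogram-based fitting).
#' @param breaks histogram breaks for the binned mode (Freedman-Diaconis
#'   when `NULL`).
#' @return A [DoubleExpFit-class]; `degenerate` is `TRUE` when the two
#'   time constants collapse (ratio < 1.5) or the mixture weight is at a
#'   boundary.
#' @examples
#' x <- rDoubleExp(2000, 3.9, 38, 13 / 14)
#' fitDoubleExponential(x, nBoot = 50, seed = 1)
#' @export
fitDoubleExponential <- function(samples, nBoot = 200L, seed = 1L,
                                 method = c("mle", "binned"),
                                 breaks = NULL) {
    method <- match.arg(method)
    samples <- as.numeric(samples)
    if (length(samples) < 50L) stop("need at least 50 uncensored samples")
    if (any(samples <= 0)) stop("all samples must be positive")
    if (is.null(breaks) && method == "binned") breaks <- .fdBreaks(samples)
    fitOne <- function(x) if (method == "mle") .fitDexpMle(x) else
        .fitDexpBinned(x, breaks)
    pt <- fitOne(samples)
    set.seed(seed)
    boots <- matrix(NA_real_, nBoot, 4L,
                    dimnames = list(NULL, c("tau1", "tau2", "ampRatio",
                                            "fastFraction")))
    for (b in seq_len(nBoot)) {
        bs <- try(fitOne(sample(samples, replace = TRUE)), silent = TRUE)
        if (inherits(bs, "try-error")) next
        boots[b, ] <- c(bs$tau1, bs$tau2, bs$p / (1 - bs$p), bs$p)
    }
    se <- apply(boots, 2L, sd, na.rm = TRUE)
    degenerate <- pt$tau2 / pt$tau1 < 1.5 || pt$p > 0.995 || pt$p < 0.005
    new("DoubleExpFit", tau1 = pt$tau1, tau2 = pt$tau2,
        ampRatio = pt$p / (1 - pt$p), fastFraction = pt$p, se = se,
        n = length(samples), loglik = pt$loglik, degenerate = degenerate,
        method = method)
}

## shifted log-normal histogram model (the y0 floor absorbs nonspecific
## binding); vectorized over x
.slnModel <- function(x, y0, A, mu, sigma, x0) {
    out <- rep(y0, length(x))
    pos <- x > x0
    d <- x[pos] - x0
    out[pos] <- y0 + A / (sqrt(2 * pi) * sigma * d) *
        exp(-(log(d) - mu)^2 / (2 * sigma^2))
    out
}

.fitSlnOnce <- function(samples, breaks, fitY0, start = NULL) {
    h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
    df <- data.frame(x = h$mids, y = h$counts)
    bw <- mean(diff(h$breaks))
    if (is.null(start)) {
        x0s <- max(0, min(samples) * 0.98)
        lx <- log(pmax(samples - x0s, .Machine$double.eps))
        start <- list(y0 = 0, A = length(samples) * bw, mu = mean(lx),
                      sigma = max(sd(lx), 0.05), x0 = x0s)
    }
    lower <- c(y0 = 0, A = 1e-12, mu = -Inf, sigma = 1e-3, x0 = 0)
    upper <- c(y0 = Inf, A = Inf, mu = Inf, sigma = Inf,
               x0 = max(min(samples) - 1e-9, 0))
    start$x0 <- min(max(start$x0, lower[["x0"]]), upper[["x0"]])
    ft <- if (fitY0)
        minpack.lm::nlsLM(y ~ .slnModel(x, y0, A, mu, sigma, x0),
                          data = df, start = start,
                          lower = lower, upper = upper,
                          control = minpack.lm::nls.lm.control(maxiter = 300))
    else
        minpack.lm::nlsLM(y ~ .slnModel(x, 0, A, mu, sigma, x0),
                          data = df, start = start[-1L],
                          lower = lower[-1L], upper = upper[-1L],
                          control = minpack.lm::nls.lm.control(maxiter = 300))
    cf <- as.list(coef(ft))
    if (!fitY0) cf$y0 <- 0
    cf$mean <- cf$x0 + exp(cf$mu + cf$sigma^2 / 2)
    cf$peak <- cf$x0 + exp(cf$mu - cf$sigma^2)
    cf
}

#' Fit the shifted (3-parameter) log-normal to first-arrival times
#'
#' Least-squares fit of the shifted log-normal histogram model (with an
#' additive floor `y0` absorbing nonspecific binding) to binned
#' first-arrival counts. Censored arrivals must be excluded beforehand
#' (fits are to observed-arrival histograms). Parameter standard errors,
#' and errors of the derived mean `x0 + exp(mu + sigma^2/2)` and peak
#' (mode) `x0 + exp(mu - sigma^2)`, come from a nonparametric bootstrap
#' over trajectories re-binned on the same edges.
#'
#' @param t1Samples uncensored first-arrival times, s (>= 100 recommended).
#' @param nBoot bootstrap replicates.
#' @param seed integer bootstrap seed.
#' @param breaks histogram breaks (Freedman-Diaconis when `NULL`).
#' @param fitY0 fit the nonspecific floor (`TRUE`) or pin it at 0.
#' @return A [ShiftedLogNormalFit-class].
#' @examples
#' t1 <- rShiftedLogNormal(1500, 120, log(240), 0.6)
#' fitShiftedLogNormal(t1, nBoot = 50, seed = 1)
#' @export
fitShiftedLogNormal <- function(t1Samples, nBoot = 200L, seed = 1L,
                                breaks = NULL, fitY0 = TRUE) {
    t1Samples <- as.numeric(t1Samples)
    if (length(t1Samples) < 100L)
        stop("need at least 100 uncensored samples")
    if (is.null(breaks)) breaks <- .fdBreaks(t1Samples)
    pt <- .fitSlnOnce(t1Samples, breaks, fitY0)
    set.seed(seed)
    cols <- c("y0", "A", "mu", "sigma", "x0", "mean", "peak")
    boots <- matrix(NA_real_, nBoot, length(cols),
                    dimnames = list(NULL, cols))
    st <- pt[c("y0", "A", "mu", "sigma", "x0")]
    for (b in seq_len(nBoot)) {
        bs <- try(.fitSlnOnce(sample(t1Samples, replace = TRUE), breaks,
                              fitY0, start = st), silent = TRUE)
        if (inherits(bs, "try-error")) next
        boots[b, ] <- unlist(bs[cols])
    }
    se <- apply(boots, 2L, sd, na.rm = TRUE)
    new("ShiftedLogNormalFit", y0 = pt$y0, A = pt$A, mu = pt$mu,
        sigma = pt$sigma, x0 = pt$x0, se = se[c("y0", "A", "mu", "sigma", "x0")],
        mean = pt$mean, peak = pt$peak, seMean = se[["mean"]],
        sePeak = se[["peak"]], n = length(t1Samples), binEdges = breaks)
}

#' Fit a log-normal distribution to monosome dwell times
#'
#' Maximum-likelihood log-normal fit (closed form on log dwell times); the
#' reported mean `exp(mu + sigma^2/2)` estimates the average total decoding
#' time, with a bootstrap standard error.
#'
#' @param dwells uncensored monosome dwell times (> 0), any time unit
#'   (>= 50 recommended).
#' @param nBoot bootstrap replicates.
#' @param seed integer bootstrap seed.
#' @return A [LogNormalFit-class] (mean in the input units).
#' @examples
#' d <- rLogNormalByMean(515, 3.9, 0.4)  # minutes
#' fitLognormalDwell(d, nBoot = 50, seed = 1)
#' @export
fitLognormalDwell <- function(dwells, nBoot = 200L, seed = 1L) {
    dwells <- as.numeric(dwells)
    if (!length(dwells)) stop("no dwells supplied")
    if (any(dwells <= 0)) stop("all dwell times must be positive")
    mleLn <- function(x) {
        l <- log(x)
        mu <- mean(l)
        sig <- sqrt(mean((l - mu)^2))
        c(mu = mu, sigma = sig, mean = exp(mu + sig^2 / 2))
    }
    pt <- mleLn(dwells)
    set.seed(seed)
    bm <- vapply(seq_len(nBoot), function(b)
        mleLn(sample(dwells, replace = TRUE))[["mean"]], numeric(1L))
    new("LogNormalFit", mu = pt[["mu"]], sigma = pt[["sigma"]],
        mean = pt[["mean"]], seMean = sd(bm), n = length(dwells))
}

#' Peptide chain elongation rate from the mean dwell time
#'
#' The antibody dwell time measures the total decoding time of the coding
#' region, so the elongation rate is `nCodons / meanDwellS`.
#'
#' @param meanDwellS mean dwell time, seconds.
#' @param nCodons coding length, codons.
#' @return named numeric: `raw` (aa/s) and `rounded` (one decimal).
#' @examples
#' elongationRate(3.9 * 60, 574)  # ~2.5 aa/s
#' @export
elongationRate <- function(meanDwellS, nCodons) {
    stopifnot(meanDwellS > 0, nCodons > 0)
    r <- nCodons / meanDwellS
    c(raw = r, rounded = round(r, 1L))
}

#' The 3xFLAG insert nucleotide sequence
#'
#' The 66-nt triple-FLAG epitope coding sequence inserted immediately after
#' the start codon of the luciferase reporter.
#' @export
flag3xSequence <- paste0("GACTACAAAGACCATGACGGTGATTATAAAGATCATGATATC",
                         "GATTACAAGGATGACGATGACAAG")

#' Coding length of a tagged reporter in codons
#'
#' @param codingNt base coding-region length, nt.
#' @param insert inserted tag: either a nucleotide string (whitespace
#'   ignored) or an insert length in nt. Defaults to the 3xFLAG insert.
#' @return integer codon count `(codingNt + insertNt) / 3`; errors when the
#'   total is not a multiple of 3.
#' @examples
#' codingLength(1656)  # 574 codons for the 3xFLAG-tagged reporter
#' @export
codingLength <- function(codingNt, insert = flag3xSequence) {
    insertNt <- if (is.character(insert))
        nchar(gsub("\\s", "", insert)) else as.numeric(insert)
    total <- codingNt + insertNt
    if (total %% 3 != 0)
        stop("coding length plus insert is not a multiple of 3")
    as.integer(total / 3)
}

#' Mean first-round initiation time from the mean first arrival
#'
#' The first arrival decomposes as `t1 = t1_tag + t1_I`: time to translate
#' the tag plus the tunnel-protected stretch, then antibody binding.
#' Subtracting the tag term recovers the mean initiation time:
#' `<t1_I> = <t1> - (tagAa + tunnelAa) / rate`. Because the
#' tunnel-protected length is only known to lie in ~30-40 aa, a sensitivity
#' band over that range is reported alongside.
#'
#' @param meanT1 mean first-arrival time, s.
#' @param rate elongation rate, aa/s.
#' @param tagAa epitope tag length, aa.
#' @param tunnelAa assumed tunnel-protected length, aa.
#' @param tunnelRange uncertainty range of the tunnel-protected length, aa.
#' @return list: `t1I` (s), `band` (t1I at the range extremes, s),
#'   `bandWidth` (s).
#' @examples
#' meanInitiationTime(450, 2.45)
#' @export
meanInitiationTime <- function(meanT1, rate, tagAa = 22L, tunnelAa = 35L,
                               tunnelRange = c(30L, 40L)) {
    stopifnot(rate > 0)
    t1I <- meanT1 - (tagAa + tunnelAa) / rate
    if (t1I < 0)
        stop("mean first arrival shorter than the tag translation time")
    band <- meanT1 - (tagAa + rev(tunnelRange)) / rate
    names(band) <- paste0("tunnel", rev(tunnelRange))
    list(t1I = t1I, band = band,
         bandWidth = diff(range(tunnelRange)) / rate)
}

#' Translational asynchrony profile of first-arrival times
#'
#' Divides the observed first-arrival distribution into consecutive
#' intervals of one mean peptide-elongation time, starting at the earliest
#' arrival: molecules in interval k lead those in interval k+1 by a full
#' round of peptide synthesis on average. Reports the fraction per interval
#' and the remainder arriving later.
#'
#' @param t1Samples uncensored first-arrival times, s.
#' @param meanElongationS mean peptide elongation time (interval width), s.
#' @param nIntervals number of intervals.
#' @return An [AsynchronyProfile-class].
#' @export
asynchronyProfile <- function(t1Samples, meanElongationS, nIntervals = 14L) {
    stopifnot(meanElongationS > 0, nIntervals >= 1L, length(t1Samples) >= 1L)
    start <- min(t1Samples)
    edges <- start + seq(0L, nIntervals) * meanElongationS
    k <- findInterval(t1Samples, edges, rightmost.closed = FALSE)
    fr <- vapply(seq_len(nIntervals), function(i)
        sum(k == i) / length(t1Samples), numeric(1L))
    new("AsynchronyProfile", intervalWidth = meanElongationS,
        nIntervals = as.integer(nIntervals), fractions = fr,
        remainder = 1 - sum(fr), n = length(t1Samples))
}

#' Numerical first moment of a fitted shifted log-normal
#'
#' Quadrature check of the closed-form mean: integrates `x f(x)` for the
#' normalized shifted log-normal density (floor excluded).
#'
#' @param fit a [ShiftedLogNormalFit-class].
#' @return numeric mean, s.
#' @export
slnNumericMean <- function(fit) {
    f <- function(x) x * dlnorm(x - fit@x0, fit@mu, fit@sigma)
    up <- fit@x0 + qlnorm(1 - 1e-12, fit@mu, fit@sigma)
    integrate(f, fit@x0, up, rel.tol = 1e-9)$value
}
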