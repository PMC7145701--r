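## Elementary random samplers used by the simulator. Exposed so that the
## distributional laws the analysis fits can be sampled directly (e.g. for
## parameter-recovery experiments at the sample sizes of a real dataset).

#' Sample from a shifted log-normal distribution
#'
#' The law of the first-round initiation time: `x0 + exp(N(mu, sigma^2))`.
#' `sigma = 0` collapses to a point mass at `x0 + exp(mu)` (with
#' `mu = -Inf` giving exactly `x0`).
#'
#' @param n sample size.
#' @param x0 location shift (>= 0).
#' @param mu,sigma log-scale mean and sd (`sigma >= 0`).
#' @return numeric vector of length `n`.
#' @examples
#' mean(rShiftedLogNormal(1e4, 120, log(240), 0.8))  # ~ 120 + 240*exp(0.32)
#' @export
rShiftedLogNormal <- function(n, x0, mu, sigma) {
    stopifnot(n >= 0, x0 >= 0, sigma >= 0)
    if (sigma == 0) return(rep(x0 + exp(mu), n))
    x0 + rlnorm(n, meanlog = mu, sdlog = sigma)
}

#' Sample from a two-component exponential mixture
#'
#' The antibody recognition-delay law: with probability `fastFraction` an
#' exponential of mean `tauFast`, otherwise of mean `tauSlow`. A zero time
#' constant contributes exact zeros.
#'
#' @param n sample size.
#' @param tauFast,tauSlow component means, same units.
#' @param fastFraction mixture weight of the fast component, in `[0, 1]`.
#'   Equivalently `A1/A2 / (1 + A1/A2)` for amplitude ratio `A1/A2`.
#' @return numeric vector of length `n`.
#' @examples
#' d <- rDoubleExp(1e4, 3.9, 38, 13 / 14)
#' mean(d)  # ~ (13 * 3.9 + 38) / 14
#' @export
rDoubleExp <- function(n, tauFast, tauSlow, fastFraction) {
    stopifnot(n >= 0, tauFast >= 0, tauSlow >= 0,
              fastFraction >= 0, fastFraction <= 1)
    fast <- runif(n) < fastFraction
    tau <- ifelse(fast, tauFast, tauSlow)
    ifelse(tau == 0, 0, rexp(n) * tau)
}

#' Sample log-normal variates with a prescribed distribution mean
#'
#' Convenience parameterization for dwell times reported as a mean: solves
#' `mu = log(meanValue) - sigma^2 / 2` so `E[X] = meanValue` exactly.
#'
#' @param n sample size.
#' @param meanValue target distribution mean (> 0).
#' @param sigma log-scale sd (>= 0).
#' @return numeric vector of length `n`.
#' @export
rLogNormalByMean <- function(n, meanValue, sigma) {
    stopifnot(meanValue > 0, sigma >= 0)
    mu <- log(meanValue) - sigma^2 / 2
    if (sigma == 0) return(rep(meanValue, n))
    rlnorm(n, meanlog = mu, sdlog = sigma)
}

#' Sample per-antibody step amplitudes
#'
#' Discrete-uniform dye count on `dyeCountRange` times the unit brightness;
#' no per-dye photophysics (the labeled antibodies show no blinking at
#' seconds-scale acquisition).
#'
#' @param n sample size.
#' @param params a [SimParams-class] object.
#' @return numeric amplitudes.
#' @export
rDyeAmplitude <- function(n, params = SimParams()) {
    dr <- params@dyeCountRange
    sample(seq.int(dr[1L], dr[2L]), n, replace = TRUE) * params@unitBrightness
}

## internal: draws tied to a SimParams
rFirstInit <- function(n, params) {
    fi <- params@firstInit
    rShiftedLogNormal(n, fi[["x0"]], fi[["mu"]], fi[["sigma"]])
}

rRecognitionDelay <- function(n, params) {
    rc <- params@recognition
    rDoubleExp(n, rc[["tauFast"]], rc[["tauSlow"]], rc[["fastFraction"]])
}
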