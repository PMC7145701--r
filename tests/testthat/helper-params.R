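# Shared parameter builders for the test suite.

# all randomness removed: point-mass initiation, zero recognition delay
deterministicParams <- function(...) {
    SimParams(firstInit = c(x0 = 100, mu = -Inf, sigma = 0),
              recognition = c(tauFast = 0, tauSlow = 0, fastFraction = 1),
              elongationRate = 2.5, tagExposureAa = 57L, nCodons = 574L,
              bleachRate = 0, noiseSigma = 0, reinitMean = Inf, ...)
}

# monosome configuration whose dwell equals nCodons/elongationRate exactly
monosomeDwellParams <- function(seed = 1L) {
    SimParams(seed = seed, firstInit = c(x0 = 60, mu = log(120), sigma = 0.5),
              tagExposureAa = 0L,
              recognition = c(tauFast = 0, tauSlow = 0, fastFraction = 1),
              bleachRate = 0, movieLength = 1200)
}

# pre-bound, stalled-elongation configuration: loss only via the bleach clock
stalledParams <- function(seed = 1L,
                          firstInit = c(x0 = 0, mu = -Inf, sigma = 0),
                          ...) {
    SimParams(seed = seed, firstInit = firstInit,
              tagExposureAa = 0L,
              recognition = c(tauFast = 0, tauSlow = 0, fastFraction = 1),
              elongationRate = 0.01, nCodons = 100000L, ...)
}

# bright static-spot movie for registration tests: spots present from frame 0
staticSpotParams <- function(seed = 3L, movieLength = 200) {
    SimParams(seed = seed, movieLength = movieLength, deliveryStart = 0,
              deadTime = 1, firstInit = c(x0 = 0, mu = -Inf, sigma = 0),
              tagExposureAa = 0L,
              recognition = c(tauFast = 0, tauSlow = 0, fastFraction = 1),
              bleachRate = 0, elongationRate = 0.01, nCodons = 100000L,
              dyeCountRange = c(10L, 10L))
}

firstInitMean <- function(p) {
    fi <- p@firstInit
    fi[["x0"]] + exp(fi[["mu"]] + fi[["sigma"]]^2 / 2)
}

recognitionMean <- function(p) {
    rc <- p@recognition
    rc[["fastFraction"]] * rc[["tauFast"]] +
        (1 - rc[["fastFraction"]]) * rc[["tauSlow"]]
}
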