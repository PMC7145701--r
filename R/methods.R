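## Accessors and show methods.

#' @describeIn Trace-class frame times, s
#' @param object,x a package object
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @export
setMethod("traceTimes", "Trace", function(x) x@times)

#' @describeIn Trace-class intensity vector
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @export
setMethod("intensities", "Trace", function(x) x@intensities)

#' @describeIn Trace-class generating ground-truth timeline (or `NULL`)
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @export
setMethod("truth", "Trace", function(x) x@truth)

#' @describeIn TraceSet-class list of traces
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))
#' @export
setMethod("traces", "TraceSet", function(x) x@traces)

#' @describeIn TraceSet-class nonspecific arrival log
#' @export
setGeneric("nonspecificEvents", function(x) standardGeneric("nonspecificEvents"))
#' @export
setMethod("nonspecificEvents", "TraceSet", function(x) x@nonspecific)

#' @describeIn MovieStack-class raw frame array
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @export
setMethod("frames", "MovieStack", function(x) x@frames)

#' @describeIn EventSeries-class detected step events
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @export
setMethod("events", "EventSeries", function(x) x@events)

setMethod("show", "SimParams", function(object) {
    fi <- object@firstInit; rc <- object@recognition
    cat("SimParams (single-molecule translation simulator)\n")
    cat(sprintf("  first initiation: shifted log-normal x0=%.4g s, mu=%.4g, sigma=%.4g\n",
                fi[["x0"]], fi[["mu"]], fi[["sigma"]]))
    cat(sprintf("  elongation: %.3g aa/s over %d codons; epitope exposed after %d aa\n",
                object@elongationRate, object@nCodons, object@tagExposureAa))
    cat(sprintf("  recognition: tau %.3g / %.3g s, fast fraction %.3g\n",
                rc[["tauFast"]], rc[["tauSlow"]], rc[["fastFraction"]]))
    cat(sprintf("  re-initiation mean %.4g s (clearance %d aa); bleach rate %.3g /s\n",
                object@reinitMean, object@clearanceAa, object@bleachRate))
    cat(sprintf("  acquisition: %.3g s/frame, window %.5g s, noise sd %.3g, seed %d\n",
                object@frameInterval, object@movieLength, object@noiseSigma,
                object@seed))
})

setMethod("show", "EventTimeline", function(object) {
    cat(sprintf("EventTimeline '%s': %d initiation(s), %d observed binding(s), %d censored\n",
                object@mrnaId, length(object@initiations),
                length(object@bindings), sum(object@censored)))
    if (length(object@bindings)) {
        n <- min(5L, length(object@bindings))
        cat(sprintf("  first binding at %.4g s; departures: %s%s\n",
                    object@bindings[1L],
                    paste(signif(object@departures[seq_len(n)], 4), collapse = ", "),
                    if (length(object@bindings) > n) ", ..." else ""))
    }
})

setMethod("show", "Trace", function(object) {
    cat(sprintf("Trace '%s': %d frames at %.3g s/frame (%.5g s)%s\n",
                object@traceId, length(object@times), object@frameInterval,
                if (length(object@times)) diff(range(object@times)) else 0,
                if (is.null(object@truth)) "" else "; ground truth attached"))
})

setMethod("show", "TraceSet", function(object) {
    cat(sprintf("TraceSet: %d specific trace(s), %d nonspecific arrival(s)\n",
                length(object@traces), nrow(object@nonspecific)))
})

setMethod("show", "MovieStack", function(object) {
    d <- dim(object@frames)
    cat(sprintf("MovieStack: %d x %d px, %d frame(s) at %.3g s/frame; psf sigma %.3g px; %d molecule(s)\n",
                d[2L], d[1L], d[3L], object@frameInterval, object@psfSigma,
                nrow(object@positions)))
    if (any(object@driftPath != 0)) cat("  rigid drift applied\n")
})

setMethod("show", "EventSeries", function(object) {
    cat(sprintf("EventSeries '%s': t0 = %.4g s, %d event(s)%s\n",
                object@traceId, object@t0, nrow(object@events),
                if (object@valid) "" else " [invalid: pre-delivery binding]"))
    if (!object@firstArrivalCensored)
        cat(sprintf("  first arrival %.4g s; %d dwell(s)\n",
                    object@firstArrival, nrow(object@dwells)))
    else cat(sprintf("  first arrival censored at %.4g s\n", object@censorTime))
})

setMethod("show", "DoubleExpFit", function(object) {
    cat(sprintf("Double-exponential fit (%s, n = %d)%s\n", object@method,
                object@n, if (object@degenerate) " [degenerate]" else ""))
    cat(sprintf("  tau1 = %.3g +/- %.2g s, tau2 = %.3g +/- %.2g s\n",
                object@tau1, object@se[["tau1"]], object@tau2,
                object@se[["tau2"]]))
    cat(sprintf("  A1/A2 = %.3g +/- %.2g (fast fraction %.1f%%)\n",
                object@ampRatio, object@se[["ampRatio"]],
                100 * object@fastFraction))
})

setMethod("show", "ShiftedLogNormalFit", function(object) {
    cat(sprintf("Shifted log-normal fit (n = %d, %d bins)\n", object@n,
                length(object@binEdges) - 1L))
    cat(sprintf("  x0 = %.4g +/- %.2g, mu = %.4g +/- %.2g, sigma = %.4g +/- %.2g\n",
                object@x0, object@se[["x0"]], object@mu, object@se[["mu"]],
                object@sigma, object@se[["sigma"]]))
    cat(sprintf("  y0 = %.3g, A = %.4g\n", object@y0, object@A))
    cat(sprintf("  mean = %.4g +/- %.2g s, peak = %.4g +/- %.2g s\n",
                object@mean, object@seMean, object@peak, object@sePeak))
})

setMethod("show", "LogNormalFit", function(object) {
    cat(sprintf("Log-normal dwell fit (n = %d): mu = %.4g, sigma = %.4g\n",
                object@n, object@mu, object@sigma))
    cat(sprintf("  mean dwell = %.4g +/- %.2g\n", object@mean, object@seMean))
})

setMethod("show", "AsynchronyProfile", function(object) {
    cat(sprintf("Asynchrony profile: %d interval(s) of %.4g s (n = %d)\n",
                object@nIntervals, object@intervalWidth, object@n))
    k <- min(4L, object@nIntervals)
    cat(sprintf("  first intervals: %s; remainder %.1f%%\n",
                paste(sprintf("%.1f%%", 100 * object@fractions[seq_len(k)]),
                      collapse = ", "),
                100 * object@remainder))
})
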