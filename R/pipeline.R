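## Pipeline orchestration, fixtures, and file I/O (traces CSV, ground-truth
## JSON event logs, multi-page TIFF movies with JSON sidecars).

#' Write traces to CSV
#'
#' Long format, one row per frame: `trace_id, frame, time_s, intensity`.
#'
#' @param traces list of [Trace-class] objects or a [TraceSet-class].
#' @param path output file.
#' @export
writeTraces <- function(traces, path) {
    if (is(traces, "TraceSet")) traces <- traces@traces
    rows <- lapply(traces, function(tr)
        data.frame(trace_id = tr@traceId,
                   frame = seq_along(tr@times) - 1L,
                   time_s = tr@times, intensity = tr@intensities))
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}

#' Read traces from CSV
#'
#' @param path CSV written by [writeTraces()].
#' @return list of [Trace-class] objects.
#' @export
readTraces <- function(path) {
    df <- utils::read.csv(path)
    lapply(split(df, df$trace_id), function(d) {
        d <- d[order(d$frame), ]
        fi <- if (nrow(d) > 1L) d$time_s[2L] - d$time_s[1L] else 1
        new("Trace", traceId = as.character(d$trace_id[1L]),
            times = d$time_s, intensities = d$intensity,
            frameInterval = fi, truth = NULL, truthAmplitudes = numeric(),
            t0Truth = NA_real_)
    })
}

#' Write detected events to CSV
#'
#' @param seriesList list of [EventSeries-class] objects.
#' @param path output file.
#' @export
writeEvents <- function(seriesList, path) {
    rows <- lapply(seriesList, function(s) {
        if (!nrow(s@events)) return(NULL)
        data.frame(trace_id = s@traceId, time_s = s@events$time,
                   direction = s@events$direction,
                   amplitude = s@events$amplitude)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(trace_id = character(), time_s = numeric(),
                          direction = character(), amplitude = numeric())
    utils::write.csv(out, path, row.names = FALSE)
    invisible(path)
}

#' Write ground-truth event timelines as a JSON log
#'
#' @param timelines list of [EventTimeline-class] objects.
#' @param path output file.
#' @export
writeTruth <- function(timelines, path) {
    payload <- lapply(timelines, function(tl) list(
        mrna_id = tl@mrnaId, initiations = tl@initiations,
        exposures = tl@exposures, bindings = tl@bindings,
        binding_round = tl@bindingRound, releases = tl@releases,
        bleaches = tl@bleaches, departures = tl@departures,
        censored = tl@censored, movie_length = tl@movieLength))
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' Write a movie stack as 16-bit multi-page TIFF plus JSON sidecar
#'
#' Intensities are linearly scaled to the unsigned 16-bit range; the
#' sidecar records the scaling, frame interval, PSF width, positions and
#' drift path needed to interpret the TIFF.
#'
#' @param movie a [MovieStack-class].
#' @param path TIFF output path; the sidecar is `<path>.json`.
#' @export
writeMovie <- function(movie, path) {
    fr <- movie@frames
    hi <- max(fr); lo <- min(fr)
    scale <- if (hi > lo) 65535 / (hi - lo) else 1
    pages <- lapply(seq_len(dim(fr)[3L]), function(k)
        pmin(pmax((fr[, , k] - lo) * scale / 65535, 0), 1))  # tiff wants [0,1]
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    jsonlite::write_json(list(
        frame_interval = movie@frameInterval, psf_sigma = movie@psfSigma,
        intensity_offset = lo, intensity_scale = scale,
        positions = movie@positions, drift_path = movie@driftPath,
        t0 = movie@t0Truth), paste0(path, ".json"), digits = NA,
        auto_unbox = TRUE, matrix = "rowmajor")
    invisible(path)
}

#' Read a movie stack written by [writeMovie()]
#'
#' @param path TIFF path with `<path>.json` sidecar.
#' @return A [MovieStack-class] (without ground-truth timelines).
#' @export
readMovie <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    arr <- array(0, c(dim(pages[[1L]]), length(pages)))
    for (k in seq_along(pages))
        arr[, , k] <- pages[[k]] * 65535 / meta$intensity_scale +
            meta$intensity_offset
    arr <- pmax(arr, 0)
    pos <- matrix(as.numeric(meta$positions), ncol = 2L)
    drift <- matrix(as.numeric(meta$drift_path), ncol = 2L)
    new("MovieStack", frames = arr, frameInterval = meta$frame_interval,
        positions = pos, psfSigma = meta$psf_sigma, background = 0,
        driftPath = drift, truth = list(), truthAmplitudes = list(),
        t0Truth = if (is.null(meta$t0)) NA_real_ else meta$t0)
}

## apply named overrides to SimParams constructor defaults
.paramsFromConfig <- function(cfg) {
    args <- cfg$simParams
    if (is.null(args)) args <- list()
    if (!is.null(cfg$seed)) args$seed <- as.integer(cfg$seed)
    for (nm in c("firstInit", "recognition", "dyeCountRange"))
        if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
    do.call(SimParams, args)
}

#' Run the simulate -> (render/process) -> events -> fit pipeline
#'
#' Executes the requested stages on a synthetic field and returns a report
#' with counts, censoring fractions, fit summaries, SNBR and the
#' asynchrony profile. With an output directory, all intermediate
#' artifacts (traces CSV, truth JSON, events CSV, report and resolved
#' config JSON) are written; identical seeds give identical outputs.
#'
#' @param config list (or path to a JSON file) with entries: `seed`,
#'   `nMrna`, `simParams` (overrides for [SimParams()]), `movie` (logical:
#'   route traces through movie rendering and the imaging pipeline),
#'   `movieDim`, `minAmplitudeSigma`, `nBoot`, `mrnaDensityRatio`,
#'   `outDir`.
#' @return report list (invisibly also written to `outDir`).
#' @examples
#' \donttest{
#' rep <- runPipeline(list(seed = 1, nMrna = 40,
#'                         simParams = list(movieLength = 900)))
#' }
#' @export
runPipeline <- function(config = list()) {
    if (is.character(config))
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    cfg <- utils::modifyList(list(
        seed = 1L, nMrna = 100L, movie = FALSE, movieDim = c(48L, 48L),
        minAmplitudeSigma = 5, nBoot = 200L, mrnaDensityRatio = 1,
        outDir = NULL), config)
    params <- .paramsFromConfig(cfg)
    outDir <- cfg$outDir
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    emit <- function(name, fn) if (!is.null(outDir))
        fn(file.path(outDir, name))

    ## -- simulate ----------------------------------------------------------
    fld <- tryCatch(simulateField(params, cfg$nMrna,
                                  fieldSize = cfg$movieDim),
                    error = function(e) stop("simulate stage: ",
                                             conditionMessage(e)))
    trs <- fld@traces
    emit("traces.csv", function(p) writeTraces(trs, p))
    emit("truth.json", function(p)
        writeTruth(lapply(trs, slot, "truth"), p))

    ## -- optional movie round-trip ----------------------------------------
    if (isTRUE(cfg$movie)) {
        mv <- tryCatch(
            renderMovie(trs, fld@positions, params, dim = cfg$movieDim,
                        nonspecific = fld@nonspecific),
            error = function(e) stop("render stage: ", conditionMessage(e)))
        emit("movie.tif", function(p) writeMovie(mv, p))
        mv <- correctDrift(mv)
        mv <- subtractBackground(mv)
        trs <- suppressWarnings(extractTraces(mv))
    }

    ## -- events ------------------------------------------------------------
    t0 <- tryCatch(fieldTimeZero(trs),
                   error = function(e) stop("events stage: ",
                                            conditionMessage(e)))
    series <- lapply(trs, traceEvents, t0 = t0,
                     minAmplitudeSigma = cfg$minAmplitudeSigma)
    emit("events.csv", function(p) writeEvents(series, p))
    fa <- firstArrivals(series)
    dw <- dwellTimes(series, monosomeOnly = TRUE)
    dwAll <- dwellTimes(series, monosomeOnly = FALSE)
    if (!is.null(outDir)) {
        utils::write.csv(fa, file.path(outDir, "first_arrivals.csv"),
                         row.names = FALSE)
        utils::write.csv(dwAll, file.path(outDir, "dwells.csv"),
                         row.names = FALSE)
    }

    spec <- bindingCountTimecourse(series)
    nonspec <- bindingCountTimecourse(fld@nonspecific, times = spec$time)
    snbr <- computeSNBR(spec, nonspec, cfg$mrnaDensityRatio)

    ## -- fits --------------------------------------------------------------
    t1 <- fa$t1[!fa$censored]
    slnFit <- if (length(t1) >= 100L)
        fitShiftedLogNormal(t1, nBoot = cfg$nBoot, seed = cfg$seed) else NULL
    dwellFit <- if (nrow(dw) >= 50L)
        fitLognormalDwell(dw$duration, nBoot = cfg$nBoot, seed = cfg$seed)
        else NULL
    elong <- if (!is.null(dwellFit))
        elongationRate(dwellFit@mean, params@nCodons) else NULL
    async <- if (!is.null(dwellFit) && length(t1) >= 14L)
        asynchronyProfile(t1, dwellFit@mean) else NULL

    report <- list(
        seed = cfg$seed, nMrna = cfg$nMrna, nTraces = length(trs),
        nEvents = sum(vapply(series, function(s) nrow(s@events),
                             integer(1L))),
        nInvalid = sum(!vapply(series, slot, logical(1L), "valid")),
        t0 = t0, nFirstArrivals = length(t1),
        censoringFraction = mean(fa$censored),
        nMonosomeDwells = nrow(dw), snbr = snbr,
        firstArrivalFit = if (is.null(slnFit)) NULL else list(
            x0 = slnFit@x0, mu = slnFit@mu, sigma = slnFit@sigma,
            y0 = slnFit@y0, A = slnFit@A, mean = slnFit@mean,
            peak = slnFit@peak, seMean = slnFit@seMean,
            sePeak = slnFit@sePeak),
        dwellFit = if (is.null(dwellFit)) NULL else list(
            mu = dwellFit@mu, sigma = dwellFit@sigma, mean = dwellFit@mean,
            seMean = dwellFit@seMean),
        elongationRate = if (is.null(elong)) NULL else as.list(elong),
        asynchrony = if (is.null(async)) NULL else list(
            intervalWidth = async@intervalWidth,
            fractions = async@fractions, remainder = async@remainder))
    if (!is.null(outDir)) {
        jsonlite::write_json(report, file.path(outDir, "report.json"),
                             digits = NA, auto_unbox = TRUE, null = "null")
        jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                             digits = NA, auto_unbox = TRUE, null = "null")
    }
    invisible(report)
}

#' Generate a preset synthetic dataset
#'
#' Each preset emulates one experiment archetype of the assay:
#' \describe{
#'   \item{`ye_specific`}{polysome-capable field of a tagged reporter:
#'     sigmoidal specific binding accumulation.}
#'   \item{`ye_nonspecific`}{tag-free control: only linear nonspecific
#'     accumulation.}
#'   \item{`prebound_recognition`}{epitopes pre-exposed before antibody
#'     delivery, so first arrivals are pure recognition delays.}
#'   \item{`stalled_survival`}{antibodies pre-bound and elongation stalled:
#'     fluorescence loss reflects only the translation-irrelevant clock.}
#'   \item{`hairpin_pair`}{two fields identical except for a configured
#'     shift `hairpinShift` of the initiation-time distribution.}
#'   \item{`movie_small`}{a small rendered movie with ground truth.}
#' }
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @param nMrna molecules per field.
#' @param hairpinShift initiation-time shift of the second `hairpin_pair`
#'   field, s.
#' @param outDir optional directory for artifacts.
#' @return list with the generated objects (fields, traces or movie) and
#'   the parameters used.
#' @export
generateFixtures <- function(preset = c("ye_specific", "ye_nonspecific",
                                        "prebound_recognition",
                                        "stalled_survival", "hairpin_pair",
                                        "movie_small"),
                             seed = 1L, nMrna = 150L, hairpinShift = 78,
                             outDir = NULL) {
    preset <- match.arg(preset)
    res <- switch(preset,
        ye_specific = {
            p <- SimParams(seed = seed, reinitMean = 60)
            list(params = p, field = simulateField(p, nMrna))
        },
        ye_nonspecific = {
            p <- SimParams(seed = seed)
            list(params = p, field = simulateField(p, 0L))
        },
        prebound_recognition = {
            p <- SimParams(seed = seed,
                           firstInit = c(x0 = 0, mu = -Inf, sigma = 0),
                           tagExposureAa = 0L, movieLength = 600)
            list(params = p, field = simulateField(p, nMrna))
        },
        stalled_survival = {
            ## pre-bound antibodies, elongation stalled: release far beyond
            ## the window, loss only via the bleach clock
            p <- SimParams(seed = seed,
                           firstInit = c(x0 = 0, mu = -Inf, sigma = 0),
                           tagExposureAa = 0L,
                           recognition = c(tauFast = 0, tauSlow = 0,
                                           fastFraction = 1),
                           elongationRate = 0.01, nCodons = 100000L)
            list(params = p, field = simulateField(p, nMrna))
        },
        hairpin_pair = {
            fiRef <- c(x0 = 120, mu = log(240), sigma = 0.8)
            fiHp <- fiRef + c(hairpinShift, 0, 0)
            pRef <- SimParams(seed = seed, firstInit = fiRef)
            pHp <- SimParams(seed = seed + 1L, firstInit = fiHp)
            list(paramsRef = pRef, paramsHp = pHp,
                 fieldRef = simulateField(pRef, nMrna),
                 fieldHp = simulateField(pHp, nMrna), shift = hairpinShift)
        },
        movie_small = {
            p <- SimParams(seed = seed, movieLength = 400,
                           firstInit = c(x0 = 30, mu = log(60), sigma = 0.5),
                           reinitMean = 120)
            fld <- simulateField(p, min(nMrna, 8L), fieldSize = c(48L, 48L),
                                 margin = 6)
            mv <- renderMovie(fld@traces, fld@positions, p,
                              dim = c(48L, 48L))
            list(params = p, field = fld, movie = mv)
        })
    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        if (!is.null(res$field))
            writeTraces(res$field, file.path(outDir,
                                             paste0(preset, "_traces.csv")))
        if (!is.null(res$movie))
            writeMovie(res$movie, file.path(outDir,
                                            paste0(preset, "_movie.tif")))
    }
    res
}
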