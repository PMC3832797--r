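## End-to-end orchestration: full single-movie analysis, synthetic slice
## batches, and a config-driven pipeline runner writing CSV result tables.

#' Full quantification of one movie
#'
#' Runs the standard chain -- dF/F conversion, reference-region bleach
#' correction, spatial binning, region trace extraction -- and measures each
#' response region: magnitude and polarity, onset latency, rate of rise, and
#' the inter-region lags (Lag 1: layer II to DEn; Lag 2: layer II to layer
#' III) when the three circuit regions are present.
#'
#' @param raw a \code{\link{RawMovie}}.
#' @param regions a \code{\link{RegionSet}} at raw resolution including a
#'   reference region.
#' @param slice slice/movie identifier carried into the results.
#' @param binFactor spatial bin factor (default 3).
#' @param invert apply the dye sign inversion.
#' @param criterion,persist onset-detection settings
#'   (\code{\link{estimateOnset}}).
#' @param windowS response window length in seconds after stimulus onset.
#' @param k polarity detection threshold in baseline SDs.
#' @return data.frame with one row per response region: \code{slice},
#'   \code{region}, \code{frequencyHz}, \code{magnitude}, \code{polarity},
#'   \code{onsetMs}, \code{rateOfRise}, \code{lag1Ms}, \code{lag2Ms}.
#' @export
analyzeMovie <- function(raw, regions, slice = "movie1", binFactor = 3,
                         invert = TRUE, criterion = 0.2, persist = 2,
                         windowS = 10, k = 3) {
  stopifnot(is(raw, "RawMovie"), is(regions, "RegionSet"))
  dff <- computeDff(raw, invert = invert)
  dff <- bleachCorrect(dff, regions)
  dffB <- binPixels(dff, binFactor)
  regB <- binRegions(regions, binFactor)
  onset <- stimOnset(protocol(raw))
  win <- c(onset, onset + windowS)
  resRegions <- setdiff(regionNames(regions), REFERENCE_REGION)
  rows <- lapply(resRegions, function(r) {
    tr <- extractRegionTrace(dffB, regB, r)
    m <- responseMagnitude(tr, onset, window = win, k = k)
    on <- if (m$polarity == "none") NA_real_
          else estimateOnset(tr, onset, criterion = criterion,
                             persist = persist, window = win)
    rr <- if (m$polarity == "none") NA_real_
          else rateOfRise(tr, onset, window = win)
    data.frame(slice = slice, region = r,
               frequencyHz = effectiveFrequency(protocol(raw)),
               magnitude = m$magnitude, polarity = m$polarity,
               onsetMs = on, rateOfRise = rr)
  })
  out <- do.call(rbind, rows)
  lag1 <- lag2 <- NA_real_
  if (all(CIRCUIT_REGIONS %in% out$region)) {
    on <- stats::setNames(out$onsetMs, out$region)
    lags <- lagPair(on[["layerII"]], on[["DEn"]], on[["layerIII"]])
    lag1 <- lags[["lag1Ms"]]
    lag2 <- lags[["lag2Ms"]]
  }
  out$lag1Ms <- lag1
  out$lag2Ms <- lag2
  out
}

#' Simulate and quantify a batch of synthetic slices
#'
#' Generates one movie per slice and stimulation frequency with
#' \code{\link{generateMovie}}, analyzes each with
#' \code{\link{analyzeMovie}}, and returns the pooled measurement table.
#' Each slice gets its own seed (\code{seed}, \code{seed + 1}, ...) and a
#' slice-level amplitude scale drawn uniformly from \code{scaleRange},
#' emulating dye-loading variability; per-movie noise seeds are derived
#' deterministically from the slice seed and the frequency.
#'
#' @param params a \code{\link{CircuitParams}}.
#' @param frequencies stimulation frequencies (Hz).
#' @param nSlices number of slices.
#' @param seed base seed; slice s uses \code{seed + s - 1}.
#' @param frameIntervalMs acquisition rate (ms/frame).
#' @param scaleRange range of the uniform slice amplitude scale.
#' @param quantize see \code{\link{generateMovie}}.
#' @param ... further arguments to \code{\link{analyzeMovie}}.
#' @return measurement data.frame (as \code{analyzeMovie}), slices named
#'   \code{"slice<seed>"}.
#' @export
measureSliceBatch <- function(params, frequencies, nSlices, seed = 1,
                              frameIntervalMs = 5, scaleRange = c(0.7, 1.3),
                              quantize = TRUE, ...) {
  stopifnot(is(params, "CircuitParams"))
  regions <- circuitRegions(params)
  out <- list()
  for (s in seq_len(nSlices)) {
    sliceSeed <- seed + s - 1
    scale <- withSeed(sliceSeed, stats::runif(1, scaleRange[1L],
                                              scaleRange[2L]))
    for (f in frequencies) {
      movieSeed <- (sliceSeed %% 2000000) * 1000 + round(f)
      sim <- generateMovie(params, StimProtocol(f), seed = movieSeed,
                           frameIntervalMs = frameIntervalMs,
                           amplitudeScale = scale, quantize = quantize)
      out[[length(out) + 1L]] <- analyzeMovie(sim$movie, regions,
                                              slice = paste0("slice",
                                                             sliceSeed), ...)
    }
  }
  do.call(rbind, out)
}

#' Validate a pipeline run configuration
#'
#' Checks types and ranges of every recognized key and rejects unknown
#' top-level sections, so a malformed config fails before any computation.
#'
#' @param config a named list (e.g. from \code{yaml::read_yaml}).
#' @return the config, invisibly, with defaults filled in.
#' @export
validateRunConfig <- function(config) {
  known <- c("seed", "outdir", "simulate", "inputs", "regions", "preprocess",
             "quantify", "curves", "spikes")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("config validation error: unknown section(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(config$outdir))
    stop("config validation error: 'outdir' is required")
  config$seed <- config$seed %||% 1
  pp <- config$preprocess %||% list()
  pp$binFactor <- pp$binFactor %||% 3
  pp$invert <- pp$invert %||% TRUE
  if (pp$binFactor < 1 || pp$binFactor != round(pp$binFactor))
    stop("config validation error: preprocess.binFactor must be a positive ",
         "integer")
  config$preprocess <- pp
  qq <- config$quantify %||% list()
  qq$criterion <- qq$criterion %||% 0.2
  qq$persist <- qq$persist %||% 2
  qq$windowS <- qq$windowS %||% 10
  qq$k <- qq$k %||% 3
  if (qq$criterion <= 0 || qq$criterion >= 1)
    stop("config validation error: quantify.criterion must be inside (0, 1)")
  config$quantify <- qq
  cc <- config$curves %||% list()
  cc$referenceFreq <- cc$referenceFreq %||% 20
  cc$logFrequency <- cc$logFrequency %||% FALSE
  config$curves <- cc
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$condition <- sim$condition %||% "control"
    if (!sim$condition %in% c("control", "kindled", "cut"))
      stop("config validation error: simulate.condition must be control, ",
           "kindled or cut")
    sim$frequencies <- sim$frequencies %||% c(5, 10, 20, 40, 60, 80, 100)
    sim$nSlices <- sim$nSlices %||% 8
    sim$frameIntervalMs <- sim$frameIntervalMs %||% 5
    config$simulate <- sim
  }
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates a reproducible end-to-end run: either simulates a synthetic
#' slice batch (\code{simulate} section) or reads movie TIFF/JSON pairs
#' (\code{inputs} + \code{regions} sections), quantifies every movie,
#' normalizes to the reference frequency, fits per-region sigmoidal gain
#' curves, and writes CSV tables (\code{measures.csv}, \code{fits.csv}) plus
#' the resolved configuration (\code{config.yaml}) into the output
#' directory.  Per-movie failures are recorded in \code{errors.csv} without
#' aborting the batch; an empty input list is a warning, not an error.
#'
#' @param config named list or path to a YAML file (see
#'   \code{\link{validateRunConfig}} for recognized keys).
#' @return list with \code{measures}, \code{fits} (data.frames) and
#'   \code{errors}, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validateRunConfig(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(config$outdir, "config.yaml"))
  errors <- data.frame(movie = character(), error = character())
  measures <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    params <- defaultParams(sim$condition)
    measures <- measureSliceBatch(params, sim$frequencies, sim$nSlices,
                                  seed = config$seed,
                                  frameIntervalMs = sim$frameIntervalMs,
                                  binFactor = config$preprocess$binFactor,
                                  invert = config$preprocess$invert,
                                  criterion = config$quantify$criterion,
                                  persist = config$quantify$persist,
                                  windowS = config$quantify$windowS,
                                  k = config$quantify$k)
  } else if (length(config$inputs)) {
    regions <- readRegionSet(config$regions$path,
                             regionNames = config$regions$names)
    rows <- list()
    for (inp in config$inputs) {
      rows[[inp$tiff]] <- tryCatch({
        raw <- readMovie(inp$tiff, inp$meta %||%
                           sub("\\.tiff?$", ".json", inp$tiff))
        analyzeMovie(raw, regions, slice = inp$id %||% basename(inp$tiff),
                     binFactor = config$preprocess$binFactor,
                     invert = config$preprocess$invert,
                     criterion = config$quantify$criterion,
                     persist = config$quantify$persist,
                     windowS = config$quantify$windowS, k = config$quantify$k)
      }, error = function(e) {
        errors <<- rbind(errors, data.frame(movie = inp$tiff,
                                            error = conditionMessage(e)))
        NULL
      })
    }
    measures <- do.call(rbind, rows)
  } else {
    warning("no inputs and no simulate section: nothing to do")
  }
  fits <- NULL
  if (!is.null(measures) && nrow(measures)) {
    measures <- normalizeToReference(measures,
                                     refFreq = config$curves$referenceFreq)
    utils::write.csv(measures, file.path(config$outdir, "measures.csv"),
                     row.names = FALSE)
    fitRows <- list()
    for (r in unique(measures$region)) {
      inhibitory <- mean(measures$normalizedMagnitude[
        measures$region == r] < 0, na.rm = TRUE) > 0.5
      curve <- assembleIoCurve(measures, r, absolute = inhibitory)
      ft <- if (length(unique(curve@points$frequencyHz)) >= 4L)
        curveFit(fitSigmoid(curve, logFrequency = config$curves$logFrequency))
      else SigmoidFit()
      fitRows[[r]] <- data.frame(region = r, base = ft@base, top = ft@top,
                                 fHalf = ft@fHalf, hill = ft@hill,
                                 rss = ft@rss, converged = ft@converged)
    }
    fits <- do.call(rbind, fitRows)
    utils::write.csv(fits, file.path(config$outdir, "fits.csv"),
                     row.names = FALSE)
  }
  if (nrow(errors))
    utils::write.csv(errors, file.path(config$outdir, "errors.csv"),
                     row.names = FALSE)
  invisible(list(measures = measures, fits = fits, errors = errors))
}
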