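## Accessor generics and show methods.  Slots are never accessed directly by
## user code; these accessors are the supported surface.

#' @rdname accessors
#' @param object,x an object of the documented class.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("dffValues", function(x) standardGeneric("dffValues"))
#' @rdname accessors
#' @export
setGeneric("movieMeta", function(x) standardGeneric("movieMeta"))
#' @rdname accessors
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameIntervalMs", function(x) standardGeneric("frameIntervalMs"))
#' @rdname accessors
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("stimOnset", function(x) standardGeneric("stimOnset"))
#' @rdname accessors
#' @export
setGeneric("stimOffset", function(x) standardGeneric("stimOffset"))
#' @rdname accessors
#' @export
setGeneric("effectiveFrequency", function(x)
  standardGeneric("effectiveFrequency"))
#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname accessors
#' @param name region name.
#' @export
setGeneric("regionMask", function(x, name) standardGeneric("regionMask"))
#' @rdname accessors
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))
#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setGeneric("traceUnits", function(x) standardGeneric("traceUnits"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("sweepDuration", function(x) standardGeneric("sweepDuration"))
#' @rdname accessors
#' @export
setGeneric("isSignInverted", function(x) standardGeneric("isSignInverted"))
#' @rdname accessors
#' @export
setGeneric("isBleachCorrected", function(x)
  standardGeneric("isBleachCorrected"))
#' @rdname accessors
#' @export
setGeneric("invalidMask", function(x) standardGeneric("invalidMask"))
#' @rdname accessors
#' @export
setGeneric("percentPer10mV", function(x) standardGeneric("percentPer10mV"))
#' @rdname accessors
#' @export
setGeneric("halfMaxFrequency", function(x) standardGeneric("halfMaxFrequency"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))
#' @rdname accessors
#' @export
setGeneric("curveSummary", function(x) standardGeneric("curveSummary"))
#' @rdname accessors
#' @export
setGeneric("curveFit", function(x) standardGeneric("curveFit"))
#' @rdname accessors
#' @export
setGeneric("regionGains", function(x) standardGeneric("regionGains"))
#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname accessors
#' @export
setGeneric("truthTraces", function(x) standardGeneric("truthTraces"))
#' @rdname accessors
#' @export
setGeneric("truthOnsets", function(x) standardGeneric("truthOnsets"))
#' @rdname accessors
#' @export
setGeneric("truthGains", function(x) standardGeneric("truthGains"))
#' @rdname accessors
#' @export
setGeneric("truthLags", function(x) standardGeneric("truthLags"))

#' Accessors for vsdigain classes
#'
#' Small read-only accessors returning slot contents of the package's S4
#' classes: movie frames and metadata, protocol timing, region labels, trace
#' samples, spike times, fit parameters and generator ground truth.
#'
#' @name accessors
#' @return The corresponding slot value.
NULL

## ---- StimProtocol ----
#' @rdname accessors
#' @export
setMethod("stimOnset", "StimProtocol", function(x) x@baselineS)
#' @rdname accessors
#' @export
setMethod("stimOffset", "StimProtocol", function(x) x@baselineS + x@trainS)
#' @rdname accessors
#' @export
setMethod("effectiveFrequency", "StimProtocol", function(x)
  if (is.na(x@nPulses)) x@frequencyHz else x@nPulses / x@trainS)
#' @rdname accessors
#' @export
setMethod("sweepDuration", "StimProtocol", function(x) x@recordS)

setMethod("show", "StimProtocol", function(object) {
  cat(sprintf(
    "StimProtocol: %g s baseline | %g s train @ %g Hz | %g s sweep\n",
    object@baselineS, object@trainS, effectiveFrequency(object),
    object@recordS))
})

## ---- MovieMeta ----
#' @rdname accessors
#' @export
setMethod("protocol", "MovieMeta", function(x) x@protocol)
#' @rdname accessors
#' @export
setMethod("nFrames", "MovieMeta", function(x) x@dim[1L])
#' @rdname accessors
#' @export
setMethod("frameIntervalMs", "MovieMeta", function(x) x@frameIntervalMs)
#' @rdname accessors
#' @export
setMethod("pixelSizeUm", "MovieMeta", function(x) x@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("frameTimes", "MovieMeta", function(x)
  (seq_len(x@dim[1L]) - 1) * x@frameIntervalMs / 1000)

setMethod("show", "MovieMeta", function(object) {
  cat(sprintf("MovieMeta: %d frames %dx%d px | %g ms/frame | %g um/px\n",
              object@dim[1L], object@dim[2L], object@dim[3L],
              object@frameIntervalMs, object@pixelSizeUm))
  show(object@protocol)
})

## ---- RawMovie / DffMovie ----
#' @rdname accessors
#' @export
setMethod("frames", "RawMovie", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("movieMeta", "RawMovie", function(x) x@meta)
#' @rdname accessors
#' @export
setMethod("protocol", "RawMovie", function(x) x@meta@protocol)
#' @rdname accessors
#' @export
setMethod("nFrames", "RawMovie", function(x) x@meta@dim[1L])
#' @rdname accessors
#' @export
setMethod("frameTimes", "RawMovie", function(x) frameTimes(x@meta))

setMethod("show", "RawMovie", function(object) {
  cat("RawMovie (fluorescence counts)\n")
  show(object@meta)
  cat(sprintf("  counts range: [%g, %g]\n", min(object@frames),
              max(object@frames)))
})

#' @rdname accessors
#' @export
setMethod("dffValues", "DffMovie", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("movieMeta", "DffMovie", function(x) x@meta)
#' @rdname accessors
#' @export
setMethod("protocol", "DffMovie", function(x) x@meta@protocol)
#' @rdname accessors
#' @export
setMethod("nFrames", "DffMovie", function(x) x@meta@dim[1L])
#' @rdname accessors
#' @export
setMethod("frameTimes", "DffMovie", function(x) frameTimes(x@meta))
#' @rdname accessors
#' @export
setMethod("isSignInverted", "DffMovie", function(x) x@signInverted)
#' @rdname accessors
#' @export
setMethod("isBleachCorrected", "DffMovie", function(x) x@bleachCorrected)
#' @rdname accessors
#' @export
setMethod("invalidMask", "DffMovie", function(x) x@invalidMask)

setMethod("show", "DffMovie", function(object) {
  cat(sprintf("DffMovie (percent dF/F)%s%s\n",
              if (object@signInverted) ", sign-inverted" else "",
              if (object@bleachCorrected) ", bleach-corrected" else ""))
  show(object@meta)
  if (any(object@invalidMask))
    cat(sprintf("  %d invalid pixel(s)\n", sum(object@invalidMask)))
})

## ---- RegionSet ----
#' @rdname accessors
#' @export
setMethod("regionNames", "RegionSet", function(x) x@regionNames)
#' @rdname accessors
#' @export
setMethod("regionMask", "RegionSet", function(x, name) {
  k <- match(name, x@regionNames)
  if (is.na(k))
    stop("unknown region '", name, "'; available: ",
         paste(x@regionNames, collapse = ", "))
  x@labels == k
})

setMethod("show", "RegionSet", function(object) {
  n <- vapply(seq_along(object@regionNames),
              function(k) sum(object@labels == k), integer(1))
  cat(sprintf("RegionSet (%dx%d): %s\n", nrow(object@labels),
              ncol(object@labels),
              paste(sprintf("%s (%d px)", object@regionNames, n),
                    collapse = ", ")))
})

## ---- Trace ----
#' @rdname accessors
#' @export
setMethod("traceTime", "Trace", function(x) x@time)
#' @rdname accessors
#' @export
setMethod("traceValues", "Trace", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("traceUnits", "Trace", function(x) x@units)
#' @rdname accessors
#' @export
setMethod("length", "Trace", function(x) length(x@time))

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace: %d samples [%g, %g] s, units %s\n",
              length(object@time),
              if (length(object@time)) min(object@time) else NA,
              if (length(object@time)) max(object@time) else NA,
              object@units))
})

## ---- SpikeTrain ----
#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("sweepDuration", "SpikeTrain", function(x) x@durationS)
#' @rdname accessors
#' @export
setMethod("stimOnset", "SpikeTrain", function(x) x@trainOnsetS)
#' @rdname accessors
#' @export
setMethod("stimOffset", "SpikeTrain", function(x)
  x@trainOnsetS + x@trainDurationS)

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain: %d spikes over %g s (train %g-%g s)\n",
              length(object@times), object@durationS, object@trainOnsetS,
              object@trainOnsetS + object@trainDurationS))
})

## ---- Calibration ----
#' @rdname accessors
#' @export
setMethod("percentPer10mV", "Calibration", function(x) x@percentPer10mV)

setMethod("show", "Calibration", function(object) {
  cat(sprintf(
    "Calibration: %.4g%% dF/F per 10 mV (from %.4g%% over %g mV)\n",
    object@percentPer10mV, object@sourceTotalPercent, object@sourceSpanMv))
})

## ---- SigmoidFit ----
#' @rdname accessors
#' @export
setMethod("isConverged", "SigmoidFit", function(x) x@converged)

setMethod("show", "SigmoidFit", function(object) {
  if (object@converged)
    cat(sprintf(
      "SigmoidFit: base %.3g, top %.3g, fHalf %.3g Hz, hill %.3g (rss %.3g)\n",
      object@base, object@top, object@fHalf, object@hill, object@rss))
  else cat("SigmoidFit: not converged\n")
})

## ---- IoCurve ----
#' @rdname accessors
#' @export
setMethod("curvePoints", "IoCurve", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("curveSummary", "IoCurve", function(x) x@summary)
#' @rdname accessors
#' @export
setMethod("curveFit", "IoCurve", function(x) x@fit)

setMethod("show", "IoCurve", function(object) {
  cat(sprintf("IoCurve for %s: %d points at %d frequencies\n",
              object@region, nrow(object@points), nrow(object@summary)))
  if (!is.null(object@fit)) show(object@fit)
})

## ---- CircuitParams / GroundTruth ----
#' @rdname accessors
#' @export
setMethod("regionGains", "CircuitParams", function(x) x@gains)
#' @rdname accessors
#' @export
setMethod("condition", "CircuitParams", function(x) x@condition)

setMethod("show", "CircuitParams", function(object) {
  cat(sprintf("CircuitParams (%s condition)\n", object@condition))
  for (r in CIRCUIT_REGIONS) {
    g <- object@gains[[r]]
    cat(sprintf(
      "  %-8s fold %4.1f @80Hz, fHalf %2g Hz, hill %g, polarity %+d, %g%% @20Hz\n",
      r, g@topFold, g@fHalf, g@hill, g@polarity, g@baseAmplitudePercent))
  }
  cat(sprintf("  onset %g ms, lag1 %g ms, lag2 %g ms; rise %g ms, decay %g s\n",
              object@onsetLatencyMs, object@lag1Ms, object@lag2Ms,
              object@riseTauMs, object@decayTauS))
  cat(sprintf("  bleach tau %g s, noise %g%% of F0 = %g counts\n",
              object@bleachTauS, object@noiseSdPercent, object@f0Counts))
})

#' @rdname accessors
#' @export
setMethod("truthTraces", "GroundTruth", function(x) x@traces)
#' @rdname accessors
#' @export
setMethod("truthOnsets", "GroundTruth", function(x) x@onsets)
#' @rdname accessors
#' @export
setMethod("truthGains", "GroundTruth", function(x) x@gains)
#' @rdname accessors
#' @export
setMethod("truthLags", "GroundTruth", function(x)
  c(lag1Ms = x@lag1Ms, lag2Ms = x@lag2Ms))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: onsets [%s] s, lag1 %g ms, lag2 %g ms\n",
              paste(sprintf("%s=%g", names(object@onsets), object@onsets),
                    collapse = ", "),
              object@lag1Ms, object@lag2Ms))
})
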