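#' @import methods
NULL

## Region names used by the three-region disinhibition circuit.  The reference
## band is the stimulus-unresponsive area used for bleach correction.
CIRCUIT_REGIONS <- c("layerII", "DEn", "layerIII")
REFERENCE_REGION <- "reference"

#' Stimulation protocol
#'
#' Describes one optical or patch-clamp sweep: a pre-stimulus baseline epoch,
#' a stimulus train of fixed duration delivered at a given pulse frequency,
#' and the total recording length.  A fixed-pulse-count protocol can be
#' expressed by setting \code{nPulses}, in which case the effective frequency
#' is \code{nPulses / trainS}.
#'
#' @slot baselineS seconds of pre-stimulus baseline at the start of the sweep.
#' @slot trainS stimulus train duration in seconds.
#' @slot frequencyHz pulse rate of the train in Hz.
#' @slot pulseWidthMs width of each pulse in milliseconds.
#' @slot nPulses optional fixed pulse count overriding \code{frequencyHz};
#'   \code{NA} when the protocol is frequency-defined.
#' @slot recordS total sweep duration in seconds.
#' @exportClass StimProtocol
setClass("StimProtocol",
  representation(baselineS = "numeric", trainS = "numeric",
                 frequencyHz = "numeric", pulseWidthMs = "numeric",
                 nPulses = "numeric", recordS = "numeric"),
  prototype(baselineS = 2, trainS = 1, frequencyHz = 20, pulseWidthMs = 2,
            nPulses = NA_real_, recordS = 20))

setValidity("StimProtocol", function(object) {
  msg <- character()
  if (length(object@frequencyHz) != 1L || !is.finite(object@frequencyHz) ||
      object@frequencyHz <= 0)
    msg <- c(msg, "frequencyHz must be a single positive number")
  if (object@baselineS < 0 || object@trainS <= 0)
    msg <- c(msg, "baselineS must be >= 0 and trainS > 0")
  if (object@baselineS + object@trainS > object@recordS)
    msg <- c(msg, "baseline + train duration exceeds the recording duration")
  if (object@pulseWidthMs <= 0)
    msg <- c(msg, "pulseWidthMs must be positive")
  if (length(object@nPulses) != 1L ||
      (!is.na(object@nPulses) && (object@nPulses < 1 ||
       object@nPulses != round(object@nPulses))))
    msg <- c(msg, "nPulses must be a single positive integer or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a stimulation protocol
#'
#' @param frequencyHz pulse rate in Hz (5-100 in typical use).
#' @param baselineS pre-stimulus baseline duration (s).
#' @param trainS stimulus train duration (s).
#' @param pulseWidthMs pulse width (ms).
#' @param nPulses optional fixed pulse count; the effective frequency is then
#'   \code{nPulses / trainS}.
#' @param recordS total recording duration (s).
#' @return A \code{StimProtocol} object.
#' @examples
#' p <- StimProtocol(40)
#' stimOnset(p)   # 2 s
#' @export
StimProtocol <- function(frequencyHz = 20, baselineS = 2, trainS = 1,
                         pulseWidthMs = 2, nPulses = NA_real_, recordS = 20) {
  new("StimProtocol", baselineS = baselineS, trainS = trainS,
      frequencyHz = as.numeric(frequencyHz), pulseWidthMs = pulseWidthMs,
      nPulses = as.numeric(nPulses), recordS = recordS)
}

#' Movie metadata
#'
#' Acquisition metadata for a VSDI movie: frame interval, pixel size (after
#' magnification), array dimensions and the stimulation protocol.  Partial
#' recordings (shorter than the protocol's nominal sweep) are allowed, but the
#' baseline epoch must be fully covered by the frames present.
#'
#' @slot frameIntervalMs milliseconds per frame (3-10 ms typical).
#' @slot pixelSizeUm micrometres per pixel edge.
#' @slot dim integer vector (nFrames, nRows, nCols).
#' @slot protocol the \code{StimProtocol} of the sweep.
#' @exportClass MovieMeta
setClass("MovieMeta",
  representation(frameIntervalMs = "numeric", pixelSizeUm = "numeric",
                 dim = "integer", protocol = "StimProtocol"))

setValidity("MovieMeta", function(object) {
  msg <- character()
  if (object@frameIntervalMs <= 0)
    msg <- c(msg, "frameIntervalMs must be positive")
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be positive")
  if (length(object@dim) != 3L || any(object@dim <= 0L))
    msg <- c(msg, "dim must be three positive integers (frames, rows, cols)")
  nBase <- object@protocol@baselineS * 1000 / object@frameIntervalMs
  if (length(object@dim) == 3L && object@dim[1L] < nBase)
    msg <- c(msg, "recording does not cover the full baseline epoch")
  if (length(msg)) msg else TRUE
})

#' Construct movie metadata
#'
#' @param frameIntervalMs milliseconds per frame.
#' @param pixelSizeUm micrometres per pixel edge.
#' @param dim integer vector (nFrames, nRows, nCols).
#' @param protocol a \code{StimProtocol}.
#' @return A \code{MovieMeta} object.
#' @export
MovieMeta <- function(frameIntervalMs, pixelSizeUm, dim, protocol) {
  new("MovieMeta", frameIntervalMs = frameIntervalMs,
      pixelSizeUm = pixelSizeUm, dim = as.integer(dim), protocol = protocol)
}

#' Raw fluorescence movie
#'
#' A T x H x W stack of nonnegative fluorescence counts as produced by the
#' camera, together with its acquisition metadata.  The dye convention is that
#' depolarization decreases fluorescence; raw movies therefore show responses
#' as downward count deflections.
#'
#' @slot frames numeric array (nFrames, nRows, nCols) of counts, all >= 0.
#' @slot meta a \code{MovieMeta}.
#' @exportClass RawMovie
setClass("RawMovie",
  representation(frames = "array", meta = "MovieMeta"))

setValidity("RawMovie", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3-d array (frames, rows, cols)")
  else if (!all(d == object@meta@dim))
    msg <- c(msg, sprintf("frames dim (%s) does not match metadata dim (%s)",
                          paste(d, collapse = "x"),
                          paste(object@meta@dim, collapse = "x")))
  if (length(object@frames) && min(object@frames) < 0)
    msg <- c(msg, "fluorescence counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a raw movie
#'
#' @param frames numeric array (nFrames, nRows, nCols) of counts.
#' @param meta a \code{MovieMeta}; its \code{dim} must match \code{frames}.
#' @return A \code{RawMovie}.
#' @export
RawMovie <- function(frames, meta) new("RawMovie", frames = frames, meta = meta)

#' Processed dF/F movie
#'
#' Fractional fluorescence change per frame, in percent of the per-pixel
#' baseline.  With \code{signInverted = TRUE} (the working convention)
#' depolarization is positive and hyperpolarization negative.  Pixels whose
#' baseline fluorescence was zero are flagged invalid and carried as
#' \code{NA} rather than divided.
#'
#' @slot values numeric array (nFrames, nRows, nCols) of percent dF/F.
#' @slot meta a \code{MovieMeta} (pixel size reflects any binning applied).
#' @slot signInverted logical; TRUE once the dye's depolarization-dims-the-dye
#'   sign has been flipped so that excitation is positive.
#' @slot bleachCorrected logical; TRUE once the reference-region trace has
#'   been subtracted.
#' @slot invalidMask logical matrix (nRows, nCols); TRUE where the pixel is
#'   unusable (zero baseline).
#' @exportClass DffMovie
setClass("DffMovie",
  representation(values = "array", meta = "MovieMeta",
                 signInverted = "logical", bleachCorrected = "logical",
                 invalidMask = "matrix"))

setValidity("DffMovie", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    msg <- c(msg, "values must be a 3-d array (frames, rows, cols)")
  else {
    if (!all(d == object@meta@dim))
      msg <- c(msg, "values dim does not match metadata dim")
    if (!all(dim(object@invalidMask) == d[2:3]))
      msg <- c(msg, "invalidMask must be nRows x nCols")
  }
  if (length(msg)) msg else TRUE
})

DffMovie <- function(values, meta, signInverted = FALSE,
                     bleachCorrected = FALSE,
                     invalidMask = matrix(FALSE, dim(values)[2L],
                                          dim(values)[3L])) {
  new("DffMovie", values = values, meta = meta, signInverted = signInverted,
      bleachCorrected = bleachCorrected, invalidMask = invalidMask)
}

#' Named region set
#'
#' Integer label image assigning pixels to named, mutually disjoint regions.
#' Label 0 is background.  The region named \code{"reference"} marks the
#' stimulus-unresponsive area used for photobleaching correction and must be
#' disjoint from the response regions (guaranteed by the label-map encoding).
#'
#' @slot labels integer matrix (nRows, nCols) with values in 0..K.
#' @slot regionNames character vector of length K; \code{regionNames[k]} names
#'   label k.
#' @exportClass RegionSet
setClass("RegionSet",
  representation(labels = "matrix", regionNames = "character"))

setValidity("RegionSet", function(object) {
  msg <- character()
  labs <- object@labels
  k <- length(object@regionNames)
  if (anyDuplicated(object@regionNames))
    msg <- c(msg, "region names must be unique")
  if (any(labs != floor(labs)) || any(labs < 0) || any(labs > k))
    msg <- c(msg, "labels must be integers in 0..length(regionNames)")
  present <- tabulate(labs[labs > 0], nbins = k)
  if (k > 0 && any(present == 0L))
    msg <- c(msg, sprintf("empty region(s): %s",
                          paste(object@regionNames[present == 0L],
                                collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a region set from a label matrix
#'
#' @param labels integer matrix; 0 is background, k > 0 is region k.
#' @param regionNames character names for labels 1..K, typically from
#'   \code{c("layerII", "DEn", "layerIII", "reference")}.
#' @return A \code{RegionSet}.
#' @export
RegionSet <- function(labels, regionNames) {
  storage.mode(labels) <- "integer"
  new("RegionSet", labels = labels, regionNames = regionNames)
}

#' Pixel stripe
#'
#' An ordered run of exactly 10 pixel coordinates used to quantify dF/F along
#' a line placed across the tissue (e.g. before and after a knife cut).  At
#' the native 25 um pixel size a stripe covers 250 um.  Consecutive
#' coordinates must be 4- or 8-adjacent.
#'
#' @slot coords integer matrix 10 x 2 of (row, col), 1-based.
#' @exportClass Stripe
setClass("Stripe", representation(coords = "matrix"))

setValidity("Stripe", function(object) {
  msg <- character()
  co <- object@coords
  if (!is.numeric(co) || is.null(dim(co)) || nrow(co) != 10L || ncol(co) != 2L)
    msg <- c(msg, "a stripe must be exactly 10 (row, col) coordinates")
  else {
    if (any(co < 1) || any(co != floor(co)))
      msg <- c(msg, "stripe coordinates must be positive integers")
    step <- abs(diff(co))
    if (nrow(co) > 1L && any(apply(step, 1L, max) != 1L))
      msg <- c(msg, "consecutive stripe pixels must be 4- or 8-adjacent")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a stripe
#'
#' @param coords 10 x 2 matrix of (row, col) pixel coordinates, 1-based,
#'   consecutive entries 4- or 8-adjacent.
#' @return A \code{Stripe}.
#' @export
Stripe <- function(coords) {
  storage.mode(coords) <- "integer"
  new("Stripe", coords = coords)
}

#' Time series trace
#'
#' A single time series in physical units: percent dF/F for optical traces or
#' millivolts for patch-clamp voltage.  Time is in seconds from the start of
#' the recording and must be strictly increasing.
#'
#' @slot time numeric, seconds, strictly increasing.
#' @slot values numeric, same length as \code{time}.
#' @slot units unit label, e.g. \code{"percent dF/F"} or \code{"mV"}.
#' @slot provenance free-form list recording origin (region/stripe id, movie
#'   id).
#' @exportClass Trace
setClass("Trace",
  representation(time = "numeric", values = "numeric", units = "character",
                 provenance = "list"),
  prototype(units = "percent dF/F", provenance = list()))

setValidity("Trace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@values))
    msg <- c(msg, "time and values must have equal length")
  if (length(object@time) > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a trace
#'
#' @param time seconds from recording start, strictly increasing.
#' @param values sample values (same length as \code{time}).
#' @param units unit label.
#' @param provenance optional list describing the origin of the trace.
#' @return A \code{Trace}.
#' @export
Trace <- function(time, values, units = "percent dF/F", provenance = list()) {
  new("Trace", time = as.numeric(time), values = as.numeric(values),
      units = units, provenance = provenance)
}

#' Spike train
#'
#' Action-potential times from one patch-clamp sweep, with the stimulus train
#' timing needed for pre/post suppression statistics.
#'
#' @slot times spike times in seconds, strictly increasing, within
#'   [0, durationS].
#' @slot durationS sweep duration (s).
#' @slot trainOnsetS stimulus train onset (s).
#' @slot trainDurationS stimulus train duration (s).
#' @exportClass SpikeTrain
setClass("SpikeTrain",
  representation(times = "numeric", durationS = "numeric",
                 trainOnsetS = "numeric", trainDurationS = "numeric"))

setValidity("SpikeTrain", function(object) {
  msg <- character()
  t <- object@times
  if (length(t) > 1L && any(diff(t) <= 0))
    msg <- c(msg, "spike times must be strictly increasing")
  if (length(t) && (min(t) < 0 || max(t) > object@durationS))
    msg <- c(msg, "spike times must lie within [0, durationS]")
  if (object@trainOnsetS < 0 ||
      object@trainOnsetS + object@trainDurationS > object@durationS)
    msg <- c(msg, "stimulus train must lie within the sweep")
  if (length(msg)) msg else TRUE
})

#' Construct a spike train
#'
#' @param times spike times (s), strictly increasing.
#' @param durationS sweep duration (s).
#' @param trainOnsetS stimulus train onset (s).
#' @param trainDurationS stimulus train duration (s).
#' @return A \code{SpikeTrain}.
#' @export
SpikeTrain <- function(times, durationS, trainOnsetS, trainDurationS = 1) {
  new("SpikeTrain", times = as.numeric(times), durationS = durationS,
      trainOnsetS = trainOnsetS, trainDurationS = trainDurationS)
}

#' Fluorescence-to-voltage calibration
#'
#' Conversion factor between percent dF/F and membrane potential, derived
#' from a high-potassium depolarization experiment: a measured total percent
#' fluorescence change over a known membrane-potential span.
#'
#' @slot percentPer10mV percent dF/F per 10 mV of depolarization.
#' @slot sourceTotalPercent total percent change in the calibration
#'   experiment.
#' @slot sourceSpanMv membrane-potential span (mV) of that experiment.
#' @exportClass Calibration
setClass("Calibration",
  representation(percentPer10mV = "numeric", sourceTotalPercent = "numeric",
                 sourceSpanMv = "numeric"))

setValidity("Calibration", function(object) {
  expected <- object@sourceTotalPercent / (object@sourceSpanMv / 10)
  if (abs(object@percentPer10mV - expected) > 1e-9)
    "percentPer10mV inconsistent with sourceTotalPercent / (sourceSpanMv/10)"
  else TRUE
})

#' Sigmoidal input/output fit
#'
#' Parameters of the Hill-type sigmoid
#' \code{R(f) = base + (top - base) / (1 + (fHalf/f)^hill)} fitted to a
#' normalized input/output curve on linear frequency.  By this
#' parameterization \code{R(fHalf) = (base + top)/2} exactly, so \code{fHalf}
#' is the half-maximal stimulation frequency.
#'
#' @slot base lower asymptote (normalized units).
#' @slot top upper asymptote (normalized units).
#' @slot fHalf half-maximal frequency (Hz).
#' @slot hill Hill slope (dimensionless, > 0).
#' @slot rss residual sum of squares of the fit.
#' @slot converged logical; FALSE when the fit was refused (too little
#'   dynamic range) or did not converge, in which case the parameter slots
#'   are NA.
#' @exportClass SigmoidFit
setClass("SigmoidFit",
  representation(base = "numeric", top = "numeric", fHalf = "numeric",
                 hill = "numeric", rss = "numeric", converged = "logical"))

setValidity("SigmoidFit", function(object) {
  if (isTRUE(object@converged)) {
    msg <- character()
    if (!is.finite(object@fHalf) || object@fHalf <= 0)
      msg <- c(msg, "fHalf must be positive for a converged fit")
    if (!is.finite(object@hill) || object@hill <= 0)
      msg <- c(msg, "hill must be positive for a converged fit")
    if (object@top < object@base)
      msg <- c(msg, "top must be >= base")
    if (length(msg)) return(msg)
  }
  TRUE
})

SigmoidFit <- function(base = NA_real_, top = NA_real_, fHalf = NA_real_,
                       hill = NA_real_, rss = NA_real_, converged = FALSE) {
  new("SigmoidFit", base = base, top = top, fHalf = fHalf, hill = hill,
      rss = rss, converged = converged)
}

#' Input/output curve
#'
#' Normalized response magnitudes of one region across stimulation
#' frequencies, pooled over slices, with per-frequency summary statistics and
#' an optional sigmoidal fit.
#'
#' @slot region region name.
#' @slot points data.frame with columns \code{frequencyHz},
#'   \code{normalizedMagnitude}, \code{slice}.
#' @slot summary data.frame with per-frequency \code{mean}, \code{sem} (NA
#'   for a single slice) and \code{n}.
#' @slot fit a \code{SigmoidFit}, or NULL before fitting.
#' @exportClass IoCurve
setClass("IoCurve",
  representation(region = "character", points = "data.frame",
                 summary = "data.frame", fit = "ANY"),
  prototype(fit = NULL))

#' Frequency-gain description of one region
#'
#' Ground-truth gain curve of a circuit region in the forward generator.  The
#' normalized gain N(f) is a Hill-type sigmoid constrained to N(20 Hz) = 1
#' (the analysis normalizes to the 20 Hz response) and, where representable
#' with a nonnegative base, N(80 Hz) = \code{topFold}; see
#' \code{\link{gainCurve}}.
#'
#' @slot topFold requested response fold at 80 Hz relative to 20 Hz.
#' @slot fHalf half-maximal frequency (Hz) of the gain sigmoid.
#' @slot hill Hill slope.
#' @slot polarity +1 for depolarizing (excitatory) regions, -1 for
#'   hyperpolarizing (inhibitory) ones.
#' @slot baseAmplitudePercent peak dF/F amplitude (percent) of the 20 Hz
#'   response.
#' @exportClass RegionGain
setClass("RegionGain",
  representation(topFold = "numeric", fHalf = "numeric", hill = "numeric",
                 polarity = "numeric", baseAmplitudePercent = "numeric"))

setValidity("RegionGain", function(object) {
  msg <- character()
  if (object@fHalf <= 0) msg <- c(msg, "fHalf must be positive")
  if (object@hill <= 0) msg <- c(msg, "hill must be positive")
  if (!object@polarity %in% c(-1, 1))
    msg <- c(msg, "polarity must be +1 or -1")
  if (object@topFold < 0) msg <- c(msg, "topFold must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a region gain description
#'
#' @param topFold response fold at 80 Hz relative to 20 Hz.
#' @param fHalf half-maximal frequency (Hz).
#' @param hill Hill slope.
#' @param polarity +1 (depolarizing) or -1 (hyperpolarizing).
#' @param baseAmplitudePercent peak percent dF/F of the 20 Hz response.
#' @return A \code{RegionGain}.
#' @export
RegionGain <- function(topFold, fHalf, hill = 3, polarity = 1,
                       baseAmplitudePercent = 1) {
  new("RegionGain", topFold = topFold, fHalf = fHalf, hill = hill,
      polarity = polarity, baseAmplitudePercent = baseAmplitudePercent)
}

#' Ground-truth circuit parameters for the forward generator
#'
#' Everything the synthetic movie and spike-train generators need: per-region
#' gain curves, the layer II onset latency and the DEn / layer III lags,
#' response kinetics, photobleaching and sensor noise, the spatial band
#' layout, and the spontaneous-firing suppression model.
#'
#' @slot gains named list of \code{RegionGain} for layerII, DEn, layerIII.
#' @slot onsetLatencyMs layer II response onset after stimulus onset (ms).
#' @slot lag1Ms DEn onset lag after the layer II onset (ms).
#' @slot lag2Ms layer III onset lag after the layer II onset (ms).
#' @slot riseTauMs response rise time constant (ms).
#' @slot decayTauS response decay time constant (s).
#' @slot bleachTauS photobleaching exponential time constant (s).
#' @slot noiseSdPercent per-pixel Gaussian count noise, SD as percent of the
#'   resting fluorescence.
#' @slot f0Counts resting fluorescence per pixel (camera counts).
#' @slot layout list: \code{height}, \code{width}, and \code{bands}, a named
#'   list of row index vectors for layerII, DEn, layerIII, reference.
#' @slot condition one of \code{"control"}, \code{"kindled"}, \code{"cut"}.
#' @slot spike list: \code{baselineRateRangeHz} (length 2), the per-sweep
#'   uniform range of spontaneous rate; \code{suppressedRateHz}; \code{holdS},
#'   the flat suppression period after train offset; \code{recoveryTauS}.
#' @exportClass CircuitParams
setClass("CircuitParams",
  representation(gains = "list", onsetLatencyMs = "numeric",
                 lag1Ms = "numeric", lag2Ms = "numeric",
                 riseTauMs = "numeric", decayTauS = "numeric",
                 bleachTauS = "numeric", noiseSdPercent = "numeric",
                 f0Counts = "numeric", layout = "list",
                 condition = "character", spike = "list"))

setValidity("CircuitParams", function(object) {
  msg <- character()
  if (!all(CIRCUIT_REGIONS %in% names(object@gains)))
    msg <- c(msg, "gains must name layerII, DEn and layerIII")
  if (!object@lag1Ms < object@lag2Ms)
    msg <- c(msg, "lag1Ms must be smaller than lag2Ms")
  if (object@riseTauMs <= 0 || object@decayTauS <= 0 ||
      object@bleachTauS <= 0)
    msg <- c(msg, "all time constants must be positive")
  if (object@noiseSdPercent < 0)
    msg <- c(msg, "noiseSdPercent must be >= 0")
  if (!object@condition %in% c("control", "kindled", "cut"))
    msg <- c(msg, "condition must be control, kindled or cut")
  if (object@condition == "cut") {
    if (object@gains[["DEn"]]@topFold != 0)
      msg <- c(msg, "cut condition requires a zero DEn gain")
    if (object@gains[["layerIII"]]@polarity != 1)
      msg <- c(msg, "cut condition requires excitatory layer III polarity")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth accompanying a generated movie
#'
#' @slot traces named list of noiseless per-region dF/F \code{Trace}s (sign
#'   convention: depolarization positive), before bleaching, noise and
#'   quantization.
#' @slot onsets named numeric; true response onset (kernel start) per region,
#'   seconds from recording start.  NA for a region without a response.
#' @slot gains named numeric; true normalized gain (relative to 20 Hz) at the
#'   protocol frequency.
#' @slot lag1Ms true Lag 1 (ms).
#' @slot lag2Ms true Lag 2 (ms).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(traces = "list", onsets = "numeric", gains = "numeric",
                 lag1Ms = "numeric", lag2Ms = "numeric"))
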