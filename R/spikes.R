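## Patch-clamp spike-train analysis: threshold detection, rate time course
## and the 5 s-pre / 5 s-post suppression statistic.

#' Detect action potentials by threshold crossing
#'
#' A spike is scored at every upward crossing of the voltage threshold;
#' further crossings within the refractory window are ignored.  Spike times
#' are the times of the crossing samples.  The trace must be uniformly
#' sampled.
#'
#' @param voltage a \code{\link{Trace}} in mV.
#' @param thresholdMv absolute detection threshold (mV), above baseline
#'   noise.
#' @param refractoryMs refractory window (ms).
#' @param trainOnsetS,trainDurationS stimulus train timing carried into the
#'   returned \code{\link{SpikeTrain}}.
#' @param samplingTol maximum relative deviation of inter-sample intervals
#'   from their median before the trace is rejected as non-uniform.
#' @return A \code{\link{SpikeTrain}}.
#' @export
detectSpikes <- function(voltage, thresholdMv = -20, refractoryMs = 2,
                         trainOnsetS = 0, trainDurationS = 0,
                         samplingTol = 1e-6) {
  stopifnot(is(voltage, "Trace"))
  tt <- traceTime(voltage)
  v <- traceValues(voltage)
  dt <- diff(tt)
  if (length(dt) && max(abs(dt / stats::median(dt) - 1)) > samplingTol)
    stop("non-uniform sampling: inter-sample intervals vary beyond tolerance")
  up <- which(v[-1L] >= thresholdMv & v[-length(v)] < thresholdMv) + 1L
  refS <- refractoryMs / 1000
  times <- numeric(0)
  last <- -Inf
  for (i in up) {
    if (tt[i] - last > refS) {
      times <- c(times, tt[i])
      last <- tt[i]
    }
  }
  SpikeTrain(times = times, durationS = max(tt),
             trainOnsetS = trainOnsetS, trainDurationS = trainDurationS)
}

#' Firing-rate time course
#'
#' Spike counts in contiguous bins divided by the bin width, in Hz.  A
#' trailing partial bin is included with its actual width.
#'
#' @param train a \code{\link{SpikeTrain}}.
#' @param binS bin width in seconds.
#' @return list with \code{edges} (bin edges, s) and \code{rateHz}.
#' @export
rateTimecourse <- function(train, binS = 1) {
  stopifnot(is(train, "SpikeTrain"))
  if (!is.finite(binS) || binS <= 0)
    stop("argument error: binS must be positive")
  dur <- sweepDuration(train)
  edges <- seq(0, dur, by = binS)
  if (edges[length(edges)] < dur) edges <- c(edges, dur)
  counts <- graphics::hist(spikeTimes(train), breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  list(edges = edges, rateHz = counts / diff(edges))
}

#' Pre/post stimulus spike-rate reduction
#'
#' Average firing frequency in the \code{windowS} seconds before train onset
#' and in the \code{windowS} seconds after train offset;
#' the reduction is \code{100 * (ratePre - ratePost) / ratePre} percent.
#' Undefined (\code{NA}) when no spikes occur in the pre window.
#'
#' @param train a \code{\link{SpikeTrain}} with its stimulus train timing
#'   set.
#' @param windowS window length in seconds (default 5).
#' @return list with \code{ratePreHz}, \code{ratePostHz},
#'   \code{reductionPercent}.
#' @export
prePostReduction <- function(train, windowS = 5) {
  stopifnot(is(train, "SpikeTrain"))
  onset <- stimOnset(train)
  offset <- stimOffset(train)
  if (onset - windowS < 0 || offset + windowS > sweepDuration(train))
    stop("argument error: ", windowS,
         " s windows do not fit inside the recording")
  st <- spikeTimes(train)
  pre <- sum(st >= onset - windowS & st < onset) / windowS
  post <- sum(st >= offset & st < offset + windowS) / windowS
  list(ratePreHz = pre, ratePostHz = post,
       reductionPercent = if (pre == 0) NA_real_ else 100 * (pre - post) / pre)
}
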