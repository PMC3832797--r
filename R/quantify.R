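## Per-response measurements: region/stripe traces, magnitude and polarity,
## 20 Hz normalization, onset latency, inter-region lags and rate of rise.

#' Extract the mean trace of a named region
#'
#' Per-frame unweighted mean of the region's pixels (invalid pixels
#' excluded).  For binned movies pass regions binned with
#' \code{\link{binRegions}}.
#'
#' @param dff a \code{\link{DffMovie}}.
#' @param regions a \code{\link{RegionSet}} at the movie's resolution.
#' @param name region name.
#' @return A \code{\link{Trace}} in percent dF/F.
#' @export
extractRegionTrace <- function(dff, regions, name) {
  stopifnot(is(dff, "DffMovie"), is(regions, "RegionSet"))
  d <- dff@meta@dim
  if (!all(dim(regions@labels) == d[2:3]))
    stop("argument error: region labels are ",
         paste(dim(regions@labels), collapse = "x"),
         " but the movie is ", paste(d[2:3], collapse = "x"),
         " (use binRegions() after binPixels())")
  mask <- regionMask(regions, name) & !invalidMask(dff)
  if (!any(mask))
    stop("argument error: region '", name, "' is empty at this resolution")
  M <- asTimeByPixel(dffValues(dff))
  Trace(time = frameTimes(dff),
        values = rowMeans(M[, as.vector(mask), drop = FALSE]),
        units = "percent dF/F", provenance = list(region = name))
}

#' Extract the mean trace along a stripe
#'
#' Per-frame unweighted mean of the stripe's 10 pixels.  Stripes are placed
#' on unbinned movies (10 pixels cover 250 um at the native 25 um pixel
#' size).
#'
#' @param dff a \code{\link{DffMovie}} at raw (unbinned) resolution.
#' @param stripe a \code{\link{Stripe}}.
#' @return A \code{\link{Trace}} in percent dF/F.
#' @export
extractStripeProfile <- function(dff, stripe) {
  stopifnot(is(dff, "DffMovie"), is(stripe, "Stripe"))
  validObject(stripe)
  d <- dff@meta@dim
  co <- stripe@coords
  if (any(co[, 1L] > d[2L]) || any(co[, 2L] > d[3L]))
    stop("argument error: stripe coordinates fall outside the ",
         paste(d[2:3], collapse = "x"), " frame")
  M <- asTimeByPixel(dffValues(dff))
  idx <- co[, 1L] + (co[, 2L] - 1L) * d[2L]
  inval <- as.vector(invalidMask(dff))[idx]
  Trace(time = frameTimes(dff),
        values = rowMeans(M[, idx[!inval], drop = FALSE]),
        units = "percent dF/F", provenance = list(stripe = TRUE))
}

## internal: baseline statistics from the pre-stimulus segment
baselineStats <- function(trace, stimOnsetS) {
  pre <- traceValues(trace)[traceTime(trace) < stimOnsetS]
  if (length(pre) < 2L)
    stop("argument error: no pre-stimulus baseline before ", stimOnsetS, " s")
  list(mean = mean(pre), sd = stats::sd(pre))
}

#' Response magnitude and polarity
#'
#' The magnitude is the signed value of the largest absolute deviation from
#' the pre-stimulus baseline mean within the response window (ties broken by
#' the earliest frame).  Polarity is excitatory for positive magnitude and
#' inhibitory for negative; it is \code{"none"} when the absolute magnitude
#' does not exceed \code{k} baseline standard deviations (or is exactly
#' zero), in which case no response was detected.
#'
#' @param trace a \code{\link{Trace}} (sign-inverted percent dF/F).
#' @param stimOnsetS stimulus onset in seconds from recording start.
#' @param window numeric (start, end) seconds of the response window;
#'   default stimulus onset to onset + 10 s.
#' @param k detection threshold in baseline standard deviations.
#' @return list with \code{magnitude} (signed percent dF/F), \code{polarity}
#'   (\code{"excitatory"}, \code{"inhibitory"} or \code{"none"}) and
#'   \code{peakTimeS}.
#' @export
responseMagnitude <- function(trace, stimOnsetS,
                              window = c(stimOnsetS, stimOnsetS + 10),
                              k = 3) {
  stopifnot(is(trace, "Trace"))
  tt <- traceTime(trace)
  if (window[2L] <= window[1L] || window[1L] >= max(tt) ||
      window[2L] <= min(tt))
    stop("argument error: response window [", window[1L], ", ", window[2L],
         "] s lies outside the recording")
  b <- baselineStats(trace, stimOnsetS)
  inWin <- tt >= window[1L] & tt <= window[2L]
  dev <- traceValues(trace)[inWin] - b$mean
  i <- which.max(abs(dev))  # earliest on ties
  magnitude <- dev[i]
  polarity <- if (magnitude == 0 || (b$sd > 0 && abs(magnitude) < k * b$sd))
    "none"
  else if (magnitude > 0) "excitatory" else "inhibitory"
  list(magnitude = magnitude, polarity = polarity,
       peakTimeS = tt[inWin][i])
}

#' Response onset latency
#'
#' The onset is the first time at or after stimulus onset at which the
#' absolute deviation from the pre-stimulus baseline mean reaches
#' \code{criterion} (default 20 percent) of the peak absolute deviation and
#' stays there for at least \code{persist} consecutive frames.  Returned in
#' milliseconds relative to stimulus onset; \code{NA} when no crossing is
#' found (an undefined, flagged measurement, never silently zero).
#'
#' @param trace a \code{\link{Trace}}.
#' @param stimOnsetS stimulus onset (s).
#' @param criterion fraction of peak deviation in (0, 1).
#' @param persist consecutive frames the criterion must hold.
#' @param window response window (s) used for the peak; default onset to
#'   onset + 10 s.
#' @return onset in ms, or \code{NA_real_}.
#' @export
estimateOnset <- function(trace, stimOnsetS, criterion = 0.2, persist = 2,
                          window = c(stimOnsetS, stimOnsetS + 10)) {
  stopifnot(is(trace, "Trace"))
  if (!is.finite(criterion) || criterion <= 0 || criterion >= 1)
    stop("argument error: criterion must be inside (0, 1)")
  tt <- traceTime(trace)
  if (stimOnsetS >= max(tt))
    stop("argument error: stimulus onset lies beyond the recording")
  b <- baselineStats(trace, stimOnsetS)
  post <- which(tt >= stimOnsetS & tt <= window[2L])
  dev <- abs(traceValues(trace)[post] - b$mean)
  peak <- max(dev)
  if (peak == 0) return(NA_real_)
  above <- dev >= criterion * peak
  n <- length(above)
  persist <- max(1L, as.integer(persist))
  for (i in seq_len(n - persist + 1L)) {
    if (all(above[i:(i + persist - 1L)]))
      return((tt[post[i]] - stimOnsetS) * 1000)
  }
  NA_real_
}

#' Inter-region activation lags
#'
#' Lag 1 is the DEn onset minus the layer II onset; Lag 2 the layer III
#' onset minus the layer II onset.  Undefined onsets propagate as \code{NA}.
#'
#' @param onsetLayerIIMs,onsetDEnMs,onsetLayerIIIMs onsets in ms (as from
#'   \code{\link{estimateOnset}}).
#' @return named numeric \code{c(lag1Ms, lag2Ms)}.
#' @examples
#' lagPair(100, 150, 300)  # lags of 50 and 200 ms
#' @export
lagPair <- function(onsetLayerIIMs, onsetDEnMs, onsetLayerIIIMs) {
  c(lag1Ms = onsetDEnMs - onsetLayerIIMs,
    lag2Ms = onsetLayerIIIMs - onsetLayerIIMs)
}

#' Rate of rise of a response
#'
#' Slope of the least-squares line fitted to the absolute deviation from
#' baseline between its 20 percent and 80 percent of-peak crossings, in
#' percent dF/F per second.  Undefined (\code{NA}) when fewer than two
#' samples fall between the crossings, as for a step sampled too coarsely.
#'
#' @inheritParams estimateOnset
#' @return slope in percent/s, or \code{NA_real_}.
#' @export
rateOfRise <- function(trace, stimOnsetS,
                       window = c(stimOnsetS, stimOnsetS + 10)) {
  stopifnot(is(trace, "Trace"))
  tt <- traceTime(trace)
  b <- baselineStats(trace, stimOnsetS)
  post <- which(tt >= stimOnsetS & tt <= window[2L])
  dev <- abs(traceValues(trace)[post] - b$mean)
  ipk <- which.max(dev)
  peak <- dev[ipk]
  if (peak == 0) return(NA_real_)
  i20 <- which(dev[seq_len(ipk)] >= 0.2 * peak)[1L]
  i80 <- which(dev[seq_len(ipk)] >= 0.8 * peak)[1L]
  if (is.na(i20) || is.na(i80) || i80 - i20 < 1L) return(NA_real_)
  seg <- i20:i80
  x <- tt[post[seg]]
  y <- dev[seg]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Normalize response magnitudes to the 20 Hz response
#'
#' Slice-to-slice differences in dye loading make raw dF/F magnitudes
#' incomparable, so all magnitudes of a region within a slice are divided by
#' the absolute magnitude of that region's response at the reference
#' frequency (20 Hz by default).  The reference entry maps to exactly +1 or
#' -1.
#'
#' @param measures data.frame with at least \code{slice}, \code{region},
#'   \code{frequencyHz}, \code{magnitude}.
#' @param refFreq reference frequency in Hz.
#' @return the data.frame with a \code{normalizedMagnitude} column.
#' @export
normalizeToReference <- function(measures, refFreq = 20) {
  stopifnot(is.data.frame(measures),
            all(c("slice", "region", "frequencyHz", "magnitude") %in%
                names(measures)))
  measures$normalizedMagnitude <- NA_real_
  for (grp in split(seq_len(nrow(measures)),
                    list(measures$slice, measures$region), drop = TRUE)) {
    ref <- grp[measures$frequencyHz[grp] == refFreq]
    slice <- measures$slice[grp[1L]]
    region <- measures$region[grp[1L]]
    if (length(ref) == 0L)
      stop("normalization error: no ", refFreq, " Hz reference for region ",
           region, ", slice ", slice)
    refMag <- abs(measures$magnitude[ref[1L]])
    if (!is.finite(refMag) || refMag == 0)
      stop("normalization error: zero or undefined ", refFreq,
           " Hz reference magnitude for region ", region, ", slice ", slice)
    measures$normalizedMagnitude[grp] <- measures$magnitude[grp] / refMag
  }
  measures
}
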