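## dF/F conversion, reference-region bleach correction, spatial binning and
## the fluorescence-to-voltage calibration.

## internal: view a (T, H, W) array as a T x (H*W) matrix and back
asTimeByPixel <- function(arr) {
  d <- dim(arr)
  dim(arr) <- c(d[1L], d[2L] * d[3L])
  arr
}
asMovieArray <- function(mat, nrow, ncol) {
  dim(mat) <- c(dim(mat)[1L], nrow, ncol)
  mat
}

#' Convert a raw movie to percent dF/F
#'
#' Computes the fractional fluorescence change per pixel and frame:
#' the baseline fluorescence F0 is the per-pixel mean count over the
#' baseline window, and the value is \code{100 * (F(t) - F0) / F0}.  Because
#' the dye dims as the membrane depolarizes, the sign is inverted by default
#' so that depolarization (excitation) is positive and hyperpolarization
#' (inhibition) negative.  Pixels with F0 = 0 are flagged invalid and carried
#' as \code{NA}, never divided.
#'
#' @param raw a \code{\link{RawMovie}}.
#' @param baselineWindow numeric (start, end) in seconds; must lie fully
#'   before stimulus onset and span at least two frames.  Default: the whole
#'   pre-stimulus baseline epoch.
#' @param invert logical; flip the dye sign so depolarization is positive
#'   (default TRUE).
#' @param maxInvalidFraction maximum tolerated fraction of zero-baseline
#'   pixels before the movie is rejected as unusable.
#' @return A \code{\link{DffMovie}} (not yet bleach-corrected).
#' @examples
#' p <- StimProtocol(40, baselineS = 0.5, recordS = 2)
#' m <- MovieMeta(10, 25, c(200, 8, 8), p)
#' raw <- RawMovie(array(100, c(200, 8, 8)), m)
#' dff <- computeDff(raw)
#' range(dffValues(dff))  # constant movie: all exactly 0
#' @export
computeDff <- function(raw, baselineWindow = NULL, invert = TRUE,
                       maxInvalidFraction = 0.1) {
  stopifnot(is(raw, "RawMovie"))
  meta <- movieMeta(raw)
  onset <- stimOnset(protocol(meta))
  if (is.null(baselineWindow)) baselineWindow <- c(0, onset)
  if (baselineWindow[2L] > onset + 1e-12)
    stop("argument error: baseline window [", baselineWindow[1L], ", ",
         baselineWindow[2L], "] s overlaps the stimulus (onset ", onset, " s)")
  tt <- frameTimes(meta)
  baseIdx <- which(tt >= baselineWindow[1L] & tt < baselineWindow[2L] - 1e-12)
  if (length(baseIdx) < 2L)
    stop("argument error: baseline window must contain at least 2 frames")
  d <- meta@dim
  M <- asTimeByPixel(frames(raw))
  f0 <- colMeans(M[baseIdx, , drop = FALSE])
  invalid <- f0 == 0
  if (mean(invalid) > maxInvalidFraction)
    stop(sprintf(
      "data-quality error: %.1f%% of pixels have zero baseline fluorescence",
      100 * mean(invalid)))
  f0[invalid] <- NA_real_
  sgn <- if (invert) -1 else 1
  vals <- 100 * sgn * (M * rep(1 / f0, each = d[1L]) - 1)
  DffMovie(values = asMovieArray(vals, d[2L], d[3L]), meta = meta,
           signInverted = invert, bleachCorrected = FALSE,
           invalidMask = matrix(invalid, d[2L], d[3L]))
}

#' Subtract the reference-region trace (bleach correction)
#'
#' Photobleaching is a stimulus-independent, common-mode loss of
#' fluorescence.  It is removed by subtracting, frame by frame, the mean
#' dF/F trace of a region of the slice that is unresponsive to the stimulus
#' from every pixel.  After correction the reference region's own trace is
#' identically zero, and any common-mode component shared by all pixels is
#' removed exactly.
#'
#' @param dff a \code{\link{DffMovie}} that has not been corrected yet.
#' @param regions a \code{\link{RegionSet}} at the movie's resolution,
#'   containing a region named \code{"reference"}.
#' @return The corrected \code{DffMovie} with \code{isBleachCorrected(x)}
#'   set.
#' @export
bleachCorrect <- function(dff, regions) {
  stopifnot(is(dff, "DffMovie"), is(regions, "RegionSet"))
  if (isBleachCorrected(dff))
    stop("state error: movie is already bleach-corrected")
  if (!REFERENCE_REGION %in% regionNames(regions))
    stop("argument error: region set has no '", REFERENCE_REGION,
         "' region for bleach correction")
  d <- dff@meta@dim
  if (!all(dim(regions@labels) == d[2:3]))
    stop("argument error: region labels are ",
         paste(dim(regions@labels), collapse = "x"),
         " but the movie is ", paste(d[2:3], collapse = "x"))
  mask <- regionMask(regions, REFERENCE_REGION) & !invalidMask(dff)
  if (!any(mask))
    stop("argument error: reference region is empty (or fully invalid)")
  M <- asTimeByPixel(dffValues(dff))
  refTrace <- rowMeans(M[, as.vector(mask), drop = FALSE])
  M <- M - refTrace  # recycles down columns: frame-wise subtraction
  DffMovie(values = asMovieArray(M, d[2L], d[3L]), meta = dff@meta,
           signInverted = dff@signInverted, bleachCorrected = TRUE,
           invalidMask = dff@invalidMask)
}

#' Spatially bin a dF/F movie
#'
#' Averages non-overlapping \code{factor x factor} pixel blocks into one
#' representative signal per block and frame (3 x 3 by default).  Trailing
#' rows/columns that do not fill a complete block are dropped, and the pixel
#' size in the metadata is scaled by \code{factor}.  Invalid pixels are
#' excluded from block means; a block is invalid only if all its source
#' pixels are.
#'
#' @param dff a \code{\link{DffMovie}}.
#' @param factor integer block edge, >= 1.
#' @return The binned \code{DffMovie}.
#' @export
binPixels <- function(dff, factor = 3) {
  stopifnot(is(dff, "DffMovie"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("argument error: factor must be >= 1")
  d <- dff@meta@dim
  if (factor > d[2L] || factor > d[3L])
    stop("argument error: bin factor ", factor,
         " exceeds the movie's spatial dimensions ",
         paste(d[2:3], collapse = "x"))
  if (factor == 1L) return(dff)
  nr <- d[2L] %/% factor
  nc <- d[3L] %/% factor
  vals <- dffValues(dff)
  inval <- invalidMask(dff)
  if (any(inval)) {            # zero out invalid pixels, count them per block
    M <- asTimeByPixel(vals)
    M[, as.vector(inval)] <- 0
    vals <- asMovieArray(M, d[2L], d[3L])
  }
  ## sum factor^2 shifted sub-arrays instead of materializing block groups
  rowStart <- (seq_len(nr) - 1L) * factor
  colStart <- (seq_len(nc) - 1L) * factor
  sums <- array(0, c(d[1L], nr, nc))
  nValid <- matrix(0, nr, nc)
  valid <- !inval
  for (di in seq_len(factor)) for (dj in seq_len(factor)) {
    sums <- sums + vals[, rowStart + di, colStart + dj, drop = FALSE]
    nValid <- nValid + valid[rowStart + di, colStart + dj]
  }
  out <- sums / rep(nValid, each = d[1L])            # NaN where no valid px
  out[!is.finite(out)] <- NA_real_
  meta <- MovieMeta(frameIntervalMs = dff@meta@frameIntervalMs,
                    pixelSizeUm = dff@meta@pixelSizeUm * factor,
                    dim = c(d[1L], nr, nc), protocol = protocol(dff))
  DffMovie(values = asMovieArray(out, nr, nc), meta = meta,
           signInverted = dff@signInverted,
           bleachCorrected = dff@bleachCorrected,
           invalidMask = matrix(nValid == 0, nr, nc))
}

#' Bin a region set to match a binned movie
#'
#' Assigns a binned pixel to a region only when every source pixel of its
#' block carries that region's label; mixed blocks become background.  This
#' conservative rule keeps binned regions strictly inside their originals.
#'
#' @param regions a \code{\link{RegionSet}} at raw resolution.
#' @param factor the bin factor used on the movie.
#' @return A \code{RegionSet} at binned resolution.
#' @export
binRegions <- function(regions, factor = 3) {
  stopifnot(is(regions, "RegionSet"))
  factor <- as.integer(factor)
  labs <- regions@labels
  nr <- nrow(labs) %/% factor
  nc <- ncol(labs) %/% factor
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    block <- labs[((i - 1L) * factor + 1L):(i * factor),
                  ((j - 1L) * factor + 1L):(j * factor)]
    u <- unique(as.vector(block))
    if (length(u) == 1L) out[i, j] <- u
  }
  RegionSet(out, regionNames(regions))
}

#' Fluorescence-to-voltage calibration
#'
#' Builds the conversion factor from a high-potassium depolarization
#' experiment: a measured total percent fluorescence change over a known
#' membrane-potential span gives
#' \code{percentPer10mV = totalPercent / (spanMv / 10)}.  The canonical
#' worked example is a 6.3 percent fluorescence decrease over a 70 mV
#' depolarization (resting potential about -70 mV to 0 mV), i.e. about 0.9
#' percent per 10 mV.
#'
#' @param totalPercent total percent dF/F change observed.
#' @param spanMv membrane-potential span in mV (> 0).
#' @return A \code{\link{Calibration}}.
#' @examples
#' percentPer10mV(calibrate(6.3, 70))  # 0.9
#' @export
calibrate <- function(totalPercent, spanMv) {
  if (!is.finite(spanMv) || spanMv <= 0)
    stop("argument error: spanMv must be positive")
  new("Calibration", percentPer10mV = totalPercent / (spanMv / 10),
      sourceTotalPercent = totalPercent, sourceSpanMv = spanMv)
}

#' Convert a dF/F trace to membrane potential
#'
#' Applies the calibration to a sign-inverted percent dF/F trace, returning
#' millivolts of depolarization relative to baseline.
#'
#' @param trace a \code{\link{Trace}} in percent dF/F (sign-inverted
#'   convention).
#' @param cal a \code{\link{Calibration}}.
#' @return A \code{Trace} in mV.
#' @export
dffToMv <- function(trace, cal) {
  stopifnot(is(trace, "Trace"), is(cal, "Calibration"))
  if (cal@percentPer10mV == 0)
    stop("argument error: calibration factor is zero")
  Trace(time = trace@time, values = trace@values * 10 / cal@percentPer10mV,
        units = "mV", provenance = trace@provenance)
}

#' @rdname dffToMv
#' @export
mvToDff <- function(trace, cal) {
  stopifnot(is(trace, "Trace"), is(cal, "Calibration"))
  Trace(time = trace@time, values = trace@values * cal@percentPer10mV / 10,
        units = "percent dF/F", provenance = trace@provenance)
}
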