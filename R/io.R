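## Readers/writers for the package's on-disk formats: 16-bit multi-frame TIFF
## movies with a JSON metadata sidecar, label-TIFF or polygon-JSON region
## masks, and CSV traces.

MAX_COUNT <- 65535  # 16-bit camera range

protocolToList <- function(p) {
  list(baseline_duration_s = p@baselineS, train_duration_s = p@trainS,
       frequency_hz = p@frequencyHz, pulse_width_ms = p@pulseWidthMs,
       n_pulses = if (is.na(p@nPulses)) NULL else p@nPulses,
       record_duration_s = p@recordS)
}

protocolFromList <- function(x) {
  required <- c("baseline_duration_s", "train_duration_s", "frequency_hz",
                "pulse_width_ms", "record_duration_s")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("metadata validation error: missing protocol field(s): ",
         paste(missing, collapse = ", "))
  StimProtocol(frequencyHz = x$frequency_hz,
               baselineS = x$baseline_duration_s,
               trainS = x$train_duration_s,
               pulseWidthMs = x$pulse_width_ms,
               nPulses = if (length(x$n_pulses) != 1L) NA_real_
                         else as.numeric(x$n_pulses),
               recordS = x$record_duration_s)
}

metaToList <- function(m) {
  list(frame_interval_ms = m@frameIntervalMs, pixel_size_um = m@pixelSizeUm,
       shape = as.integer(m@dim), protocol = protocolToList(m@protocol))
}

metaFromList <- function(x) {
  required <- c("frame_interval_ms", "pixel_size_um", "shape", "protocol")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("metadata validation error: missing field(s): ",
         paste(missing, collapse = ", "))
  MovieMeta(frameIntervalMs = x$frame_interval_ms,
            pixelSizeUm = x$pixel_size_um, dim = unlist(x$shape),
            protocol = protocolFromList(x$protocol))
}

#' Read a VSDI movie from a TIFF stack and JSON sidecar
#'
#' Loads a multi-frame 16-bit TIFF of fluorescence counts and its metadata
#' sidecar, checks that the declared shape matches the pixel data, and
#' returns a validated \code{\link{RawMovie}}.
#'
#' @param tiffPath path to the multi-frame TIFF stack.
#' @param metaPath path to the JSON metadata sidecar; defaults to
#'   \code{tiffPath} with the extension replaced by \code{.json}.
#' @return A \code{RawMovie}.
#' @seealso \code{\link{writeMovie}}
#' @export
readMovie <- function(tiffPath, metaPath = sub("\\.tiff?$", ".json",
                                               tiffPath)) {
  if (!file.exists(tiffPath)) stop("TIFF file not found: ", tiffPath)
  if (!file.exists(metaPath)) stop("metadata sidecar not found: ", metaPath)
  meta <- metaFromList(jsonlite::read_json(metaPath, simplifyVector = TRUE))
  pages <- tiff::readTIFF(tiffPath, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1L]]))
  if (!all(d == meta@dim))
    stop(sprintf(
      "shape mismatch: TIFF stack is %s but metadata declares %s",
      paste(d, collapse = "x"), paste(meta@dim, collapse = "x")))
  arr <- array(0, dim = d)
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  RawMovie(frames = arr, meta = meta)
}

#' Write a VSDI movie to a TIFF stack and JSON sidecar
#'
#' Writes integer fluorescence counts as a 16-bit multi-frame TIFF plus a
#' JSON metadata sidecar.  The pair is read back losslessly by
#' \code{\link{readMovie}}.
#'
#' @param movie a \code{RawMovie} with integer counts in [0, 65535].
#' @param tiffPath output TIFF path.
#' @param metaPath output JSON path; defaults to \code{tiffPath} with a
#'   \code{.json} extension.
#' @return Invisibly, \code{c(tiff = tiffPath, meta = metaPath)}.
#' @export
writeMovie <- function(movie, tiffPath, metaPath = sub("\\.tiff?$", ".json",
                                                       tiffPath)) {
  stopifnot(is(movie, "RawMovie"))
  validObject(movie)
  fr <- movie@frames
  if (any(fr != round(fr)))
    stop("counts must be integers for 16-bit TIFF output")
  if (max(fr) > MAX_COUNT)
    stop(sprintf("count range error: max count %g exceeds the 16-bit limit %d",
                 max(fr), MAX_COUNT))
  pages <- lapply(seq_len(dim(fr)[1L]), function(t) fr[t, , ] / MAX_COUNT)
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 16L)
  jsonlite::write_json(metaToList(movieMeta(movie)), metaPath,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(tiff = tiffPath, meta = metaPath))
}

#' Read or write a trace as CSV
#'
#' Traces are stored as a two-column CSV (\code{time_s}, \code{value})
#' preceded by a comment line declaring the units
#' (\code{# units: <label>}).  A file without the units line is rejected.
#'
#' @param path CSV path.
#' @return \code{readTraceCsv} returns a \code{\link{Trace}};
#'   \code{writeTraceCsv} invisibly returns \code{path}.
#' @export
readTraceCsv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!grepl("^#\\s*units:", first))
    stop("trace validation error: missing '# units:' header line in ", path)
  units <- trimws(sub("^#\\s*units:", "", first))
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "value") %in% names(d)))
    stop("trace validation error: expected columns time_s, value")
  Trace(time = d$time_s, values = d$value, units = units,
        provenance = list(path = path))
}

#' @rdname readTraceCsv
#' @param trace a \code{Trace}.
#' @export
writeTraceCsv <- function(trace, path) {
  stopifnot(is(trace, "Trace"))
  validObject(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", trace@units), con)
  utils::write.csv(data.frame(time_s = trace@time, value = trace@values),
                   con, row.names = FALSE)
  invisible(path)
}

#' Build a region set from polygons
#'
#' Rasterizes named polygons onto a label image by pixel-center inclusion: a
#' pixel belongs to a region when its center (row, col) falls inside the
#' polygon.  Later polygons overwrite earlier ones where they overlap, so
#' the resulting regions are disjoint.
#'
#' @param polygons named list; each element a matrix with two columns
#'   (row, col) giving polygon vertices in pixel coordinates.
#' @param shape integer (nRows, nCols) of the target frame.
#' @return A \code{\link{RegionSet}}.
#' @export
regionsFromPolygons <- function(polygons, shape) {
  labels <- matrix(0L, shape[1L], shape[2L])
  centers <- cbind(rep(seq_len(shape[1L]), shape[2L]),
                   rep(seq_len(shape[2L]), each = shape[1L]))
  for (k in seq_along(polygons)) {
    poly <- as.matrix(polygons[[k]])
    inside <- mgcv::in.out(poly, centers)
    labels[centers[inside, , drop = FALSE]] <- k
  }
  RegionSet(labels, names(polygons))
}

#' Read a region set from a label TIFF or polygon JSON
#'
#' Label TIFF: an integer image whose value k marks region k, with a
#' parallel \code{regionNames} argument.  Polygon JSON: an object with
#' \code{shape} ([rows, cols]) and \code{regions}, a list of
#' \code{{name, polygon: [[row, col], ...]}} entries, rasterized by
#' pixel-center inclusion.
#'
#' @param path path to a \code{.tif}/\code{.tiff} label image or a
#'   \code{.json} polygon file.
#' @param regionNames names for labels 1..K (label TIFF input only).
#' @return A \code{\link{RegionSet}}.
#' @export
readRegionSet <- function(path, regionNames = NULL) {
  if (grepl("\\.json$", path)) {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(spec$shape) || is.null(spec$regions))
      stop("region validation error: polygon JSON needs 'shape' and 'regions'")
    polys <- lapply(spec$regions$polygon, as.matrix)
    names(polys) <- spec$regions$name
    regionsFromPolygons(polys, unlist(spec$shape))
  } else {
    labels <- tiff::readTIFF(path, as.is = TRUE)
    if (is.null(regionNames))
      stop("regionNames must be given for a label TIFF")
    RegionSet(labels, regionNames)
  }
}
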