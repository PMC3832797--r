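## Input/output curve assembly, sigmoidal gain fitting, half-maximal
## frequency, and control-vs-kindled fold-change contrasts.

#' Assemble a normalized input/output curve for one region
#'
#' Groups normalized magnitudes by stimulation frequency and computes the
#' per-frequency mean and SEM across slices (SEM is \code{NA} with a single
#' slice).  Inhibitory curves are conventionally assembled on the absolute
#' normalized magnitude (\code{absolute = TRUE}) so that "activation of
#' inhibition" increases with frequency.
#'
#' @param measures data.frame with \code{slice}, \code{region},
#'   \code{frequencyHz}, \code{normalizedMagnitude} (see
#'   \code{\link{normalizeToReference}}).
#' @param region the single region to assemble.
#' @param absolute use the absolute normalized magnitude.
#' @return An \code{\link{IoCurve}} (unfitted).
#' @export
assembleIoCurve <- function(measures, region, absolute = FALSE) {
  stopifnot(is.data.frame(measures))
  if (length(region) != 1L)
    stop("argument error: assembleIoCurve takes exactly one region")
  rows <- measures[measures$region == region, , drop = FALSE]
  if (!nrow(rows))
    stop("argument error: no measurements for region '", region, "'")
  y <- rows$normalizedMagnitude
  if (absolute) y <- abs(y)
  points <- data.frame(frequencyHz = rows$frequencyHz,
                       normalizedMagnitude = y, slice = rows$slice)
  agg <- split(points$normalizedMagnitude, points$frequencyHz)
  summary <- data.frame(
    frequencyHz = as.numeric(names(agg)),
    mean = vapply(agg, mean, numeric(1)),
    sem = vapply(agg, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)),
    n = lengths(agg), row.names = NULL)
  new("IoCurve", region = region, points = points, summary = summary,
      fit = NULL)
}

## internal: the Hill-type sigmoid on linear frequency
sigmoidModel <- function(f, base, top, fHalf, hill)
  base + (top - base) / (1 + (fHalf / f)^hill)

#' Evaluate a sigmoid fit
#'
#' @param fit a converged \code{\link{SigmoidFit}}.
#' @param f frequencies (Hz).
#' @return predicted normalized magnitudes.
#' @export
predictSigmoid <- function(fit, f) {
  stopifnot(is(fit, "SigmoidFit"))
  if (!isConverged(fit)) stop("cannot predict from a non-converged fit")
  sigmoidModel(f, fit@base, fit@top, fit@fHalf, fit@hill)
}

#' Fit a sigmoidal dose/response function to an input/output curve
#'
#' Least-squares fit of
#' \code{R(f) = base + (top - base) / (1 + (fHalf/f)^hill)} on linear
#' frequency (the log-frequency variant is available via
#' \code{logFrequency = TRUE}, which fits the same Hill form to
#' \code{log(f)} midpoints).  Initialization is deterministic: base = min,
#' top = max, fHalf = the frequency nearest the half-range crossing,
#' hill = 2, with positivity bounds on fHalf and hill.  The fit is refused
#' (\code{converged = FALSE}) when the dynamic range of the data is below
#' \code{minRange} or when fewer than four distinct frequencies are present
#' (an error, since the four-parameter model would be underdetermined).
#'
#' @param curve an \code{\link{IoCurve}} or a data.frame with
#'   \code{frequencyHz} and \code{normalizedMagnitude}.
#' @param minRange minimum dynamic range (max - min of the response) below
#'   which fitting is refused.
#' @param logFrequency fit on log-transformed frequency.
#' @return For an \code{IoCurve} input, the curve with its \code{fit} slot
#'   populated; for a data.frame, the \code{\link{SigmoidFit}} itself.
#' @export
fitSigmoid <- function(curve, minRange = 0.5, logFrequency = FALSE) {
  pts <- if (is(curve, "IoCurve")) curvePoints(curve) else curve
  stopifnot(all(c("frequencyHz", "normalizedMagnitude") %in% names(pts)))
  pts <- pts[is.finite(pts$normalizedMagnitude) & is.finite(pts$frequencyHz), ]
  if (length(unique(pts$frequencyHz)) < 4L)
    stop("argument error: need at least 4 distinct frequencies to fit")
  f <- pts$frequencyHz
  y <- pts$normalizedMagnitude
  fit <- SigmoidFit()  # non-converged placeholder
  if (diff(range(y)) >= minRange) {
    x <- if (logFrequency) log(f) else f
    half <- (min(y) + max(y)) / 2
    start <- list(base = min(y), top = max(y),
                  fHalf = x[which.min(abs(y - half))], hill = 2)
    lower <- c(base = -Inf, top = -Inf, fHalf = 1e-6, hill = 1e-6)
    nl <- tryCatch(
      minpack.lm::nlsLM(y ~ base + (top - base) / (1 + (fHalf / x)^hill),
                        data = data.frame(x = x, y = y), start = start,
                        lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cf <- stats::coef(nl)
      fHalf <- if (logFrequency) exp(cf[["fHalf"]]) else cf[["fHalf"]]
      if (cf[["top"]] >= cf[["base"]] && fHalf > 0 && cf[["hill"]] > 0)
        fit <- SigmoidFit(base = cf[["base"]], top = cf[["top"]],
                          fHalf = fHalf, hill = cf[["hill"]],
                          rss = sum(stats::resid(nl)^2), converged = TRUE)
    }
  }
  if (is(curve, "IoCurve")) {
    curve@fit <- fit
    curve
  } else fit
}

#' @rdname accessors
#' @export
setMethod("halfMaxFrequency", "SigmoidFit", function(x) {
  if (!isConverged(x))
    stop("half-maximal frequency is undefined for a non-converged fit")
  x@fHalf
})

#' @rdname accessors
#' @export
setMethod("halfMaxFrequency", "IoCurve", function(x) {
  if (is.null(x@fit)) stop("curve has not been fitted; call fitSigmoid()")
  halfMaxFrequency(x@fit)
})

#' Control versus kindled fold-change contrast
#'
#' For each slice, the difference between the 20 Hz-normalized response and
#' 1 (its 20 Hz value) is computed at the contrast frequencies; group means
#' and the kindled-minus-control gap summarize how much more steeply the
#' kindled circuit's gain grows with stimulation frequency.
#'
#' @param control,kindled \code{\link{IoCurve}}s of the same region built
#'   from 20 Hz-normalized measures.
#' @param frequencies contrast frequencies (Hz).
#' @return list with \code{perSlice} (data.frame: group, slice, frequencyHz,
#'   difference) and \code{summary} (data.frame: frequencyHz, controlMean,
#'   kindledMean, gap).
#' @export
foldChangeContrast <- function(control, kindled,
                               frequencies = c(40, 60, 80)) {
  stopifnot(is(control, "IoCurve"), is(kindled, "IoCurve"))
  grab <- function(curve, group) {
    pts <- curvePoints(curve)
    if (!any(pts$frequencyHz == 20))
      stop("argument error: ", group, " curve has no 20 Hz point")
    pts <- pts[pts$frequencyHz %in% frequencies, , drop = FALSE]
    data.frame(group = group, slice = pts$slice,
               frequencyHz = pts$frequencyHz,
               difference = abs(pts$normalizedMagnitude) - 1)
  }
  perSlice <- rbind(grab(control, "control"), grab(kindled, "kindled"))
  summary <- do.call(rbind, lapply(frequencies, function(f) {
    cm <- mean(perSlice$difference[perSlice$group == "control" &
                                     perSlice$frequencyHz == f])
    km <- mean(perSlice$difference[perSlice$group == "kindled" &
                                     perSlice$frequencyHz == f])
    data.frame(frequencyHz = f, controlMean = cm, kindledMean = km,
               gap = km - cm)
  }))
  list(perSlice = perSlice, summary = summary)
}
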