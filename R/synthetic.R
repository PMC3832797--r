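## Forward generator for the three-region feed-forward disinhibition circuit:
## synthetic VSDI movies (layer II, DEn, layer III plus a reference band) and
## suppressed spontaneous spike trains, with full ground truth.

## evaluate expr with a local, restored RNG stream seeded by `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Normalized frequency-gain curve of a region
#'
#' The gain sigmoid \code{N(f) = b + s / (1 + (fHalf/f)^hill)} is
#' parameterized by the paper-style quantities of
#' \code{\link{RegionGain}}: its half-maximal frequency and the response
#' fold at 80 Hz relative to 20 Hz.  \code{b} and \code{s} are solved from
#' the two constraints \code{N(20) = 1} (the analysis normalizes to the
#' 20 Hz response) and \code{N(80) = topFold}.  When the requested fold is
#' not representable with a nonnegative base -- which happens whenever the
#' half-max sits at or below the 20 Hz normalization point -- the base is
#' clamped to 0 and the curve becomes \code{N(f) = L(f)/L(20)}, capping the
#' attainable fold.  Negative tails are truncated at zero: a region produces
#' no response, rather than a wrong-polarity one, at ineffective
#' frequencies.  A \code{topFold} of exactly 0 silences the region
#' (the severed DEn input in the cut condition).
#'
#' @param gain a \code{\link{RegionGain}}.
#' @param f stimulation frequencies (Hz).
#' @return normalized gain values (1 at 20 Hz by construction).
#' @examples
#' g <- RegionGain(topFold = 3.5, fHalf = 40)
#' gainCurve(g, c(20, 40, 80))  # 1, mid, 3.5
#' @export
gainCurve <- function(gain, f) {
  stopifnot(is(gain, "RegionGain"))
  if (gain@topFold == 0) return(rep(0, length(f)))
  L <- function(fr) 1 / (1 + (gain@fHalf / fr)^gain@hill)
  l20 <- L(20); l80 <- L(80)
  s <- (gain@topFold - 1) / (l80 - l20)
  b <- 1 - s * l20
  if (b < 0 || s < 0) {        # fold not representable; clamp base at zero
    b <- 0
    s <- 1 / l20
  }
  pmax(0, b + s * L(f))
}

bandLayout <- function(height = 64, width = 64) {
  stopifnot(height %% 4 == 0)
  h <- height %/% 4
  list(height = height, width = width,
       bands = list(layerII = seq_len(h), DEn = h + seq_len(h),
                    layerIII = 2 * h + seq_len(h),
                    reference = 3 * h + seq_len(h)))
}

#' Default circuit parameters per experimental condition
#'
#' Fully populated \code{\link{CircuitParams}} for the three study
#' conditions.  Control: layer II gain 3.5-fold at 80 Hz with half-max
#' 40 Hz; DEn 5-fold, half-max 40 Hz; layer III (inhibitory) half-max 20 Hz.
#' Kindled: layer II 6-fold, DEn 10-fold, layer III 4.5-fold with the
#' kindled inhibition diverging from control only above 40 Hz (half-max
#' 40 Hz).  Cut: the DEn response is abolished, layer III becomes weakly
#' excitatory, and the layer II gain is reduced.  Timing defaults: layer II
#' onset 20 ms after stimulus onset, Lag 1 = 50 ms, Lag 2 = 200 ms, rise
#' tau 50 ms, decay tau 4 s.  Acquisition defaults: resting fluorescence
#' 3000 counts, bleach tau 100 s, per-pixel noise SD 0.3 percent of F0,
#' 64 x 64 frame in four horizontal bands (layer II, DEn, layer III,
#' reference).  Spike model: spontaneous rate uniform in 8-10 Hz, suppressed
#' to 3.4 Hz through the train and for 5 s after it, then exponential
#' recovery (tau 5 s).  See the package vignette for the rationale behind
#' each value.
#'
#' @param condition \code{"control"}, \code{"kindled"} or \code{"cut"}.
#' @param frameHeight,frameWidth frame size in pixels (multiples of 4).
#' @return A \code{\link{CircuitParams}}.
#' @examples
#' defaultParams("control")
#' @export
defaultParams <- function(condition = c("control", "kindled", "cut"),
                          frameHeight = 64, frameWidth = 64) {
  condition <- match.arg(condition)
  gains <- switch(condition,
    control = list(
      layerII = RegionGain(3.5, 40, 3, +1, 2.0),
      DEn = RegionGain(5, 40, 3, +1, 1.5),
      layerIII = RegionGain(2.5, 20, 3, -1, 1.0)),
    kindled = list(
      layerII = RegionGain(6, 40, 3, +1, 2.0),
      DEn = RegionGain(10, 40, 4, +1, 1.5),
      layerIII = RegionGain(4.5, 40, 3, -1, 1.0)),
    cut = list(
      layerII = RegionGain(2.5, 40, 3, +1, 1.0),
      DEn = RegionGain(0, 40, 3, +1, 0),
      layerIII = RegionGain(2.5, 40, 3, +1, 0.5)))
  new("CircuitParams", gains = gains, onsetLatencyMs = 20, lag1Ms = 50,
      lag2Ms = 200, riseTauMs = 50, decayTauS = 4, bleachTauS = 100,
      noiseSdPercent = 0.3, f0Counts = 3000,
      layout = bandLayout(frameHeight, frameWidth), condition = condition,
      spike = list(baselineRateRangeHz = c(8, 10), suppressedRateHz = 3.4,
                   holdS = 5, recoveryTauS = 5))
}

#' Region set matching a generator layout
#'
#' @param params a \code{\link{CircuitParams}}.
#' @return A \code{\link{RegionSet}} with the four horizontal bands.
#' @export
circuitRegions <- function(params) {
  stopifnot(is(params, "CircuitParams"))
  lay <- params@layout
  labels <- matrix(0L, lay$height, lay$width)
  nm <- names(lay$bands)
  for (k in seq_along(nm)) labels[lay$bands[[k]], ] <- k
  RegionSet(labels, nm)
}

## response kernel: exponential rise times exponential decay, 0 before onset
responseKernel <- function(t, onsetS, riseS, decayS) {
  dt <- t - onsetS
  ifelse(dt < 0, 0, (1 - exp(-dt / riseS)) * exp(-dt / decayS))
}

#' Generate a synthetic VSDI movie with ground truth
#'
#' Forward model of one optical sweep.  Per region the noiseless dF/F is
#' \code{polarity * A(f) * (1 - exp(-(t - tOn)/riseTau)) *
#' exp(-(t - tOn)/decayTau)} for \code{t >= tOn}, where the amplitude
#' \code{A(f) = baseAmplitudePercent * gainCurve(gain, f)} and the onsets
#' are stimulus onset + \code{onsetLatencyMs} for layer II, plus Lag 1 for
#' the DEn and plus Lag 2 for layer III.  Camera counts follow the dye
#' convention (depolarization dims the dye):
#' \code{F0 * (1 - dFF/100) * exp(-t/bleachTau) + noise}, Gaussian noise per
#' pixel and frame; the reference band carries bleaching and noise only.
#' Identical seeds and parameters give bit-identical movies.
#'
#' @param params a \code{\link{CircuitParams}}.
#' @param protocol a \code{\link{StimProtocol}}.
#' @param seed integer seed for the movie's noise stream.
#' @param frameIntervalMs acquisition rate (ms/frame), default 5.
#' @param pixelSizeUm pixel size, default 25.
#' @param amplitudeScale multiplicative slice-level amplitude factor
#'   (emulates dye-loading variability; normalization removes it).
#' @param quantize round counts to integers and clip to the 16-bit range, as
#'   the camera would.  Set \code{FALSE} for noiseless diagnostics where
#'   exact-zero traces matter.
#' @return list with \code{movie} (a \code{\link{RawMovie}}) and
#'   \code{truth} (a \code{\link{GroundTruth}}).
#' @export
generateMovie <- function(params, protocol, seed, frameIntervalMs = 5,
                          pixelSizeUm = 25, amplitudeScale = 1,
                          quantize = TRUE) {
  stopifnot(is(params, "CircuitParams"), is(protocol, "StimProtocol"))
  validObject(protocol)
  f <- effectiveFrequency(protocol)
  lay <- params@layout
  nT <- round(protocol@recordS * 1000 / frameIntervalMs)
  tt <- (seq_len(nT) - 1) * frameIntervalMs / 1000
  onsets <- c(layerII = 0, DEn = params@lag1Ms,
              layerIII = params@lag2Ms) / 1000 +
    stimOnset(protocol) + params@onsetLatencyMs / 1000
  riseS <- params@riseTauMs / 1000
  bleach <- exp(-tt / params@bleachTauS)
  f0 <- params@f0Counts
  nPix <- lay$height * lay$width
  M <- matrix(f0 * bleach, nT, nPix)
  traces <- list()
  gains <- numeric()
  for (r in CIRCUIT_REGIONS) {
    g <- params@gains[[r]]
    gf <- gainCurve(g, f)
    A <- g@polarity * g@baseAmplitudePercent * gf * amplitudeScale
    s <- A * responseKernel(tt, onsets[[r]], riseS, params@decayTauS)
    cols <- which(rep(seq_len(lay$height) %in% lay$bands[[r]], lay$width))
    M[, cols] <- f0 * (1 - s / 100) * bleach
    traces[[r]] <- Trace(tt, s, units = "percent dF/F",
                         provenance = list(region = r, groundTruth = TRUE))
    gains[r] <- gf
    if (A == 0) onsets[r] <- NA_real_
  }
  if (params@noiseSdPercent > 0)
    M <- M + withSeed(seed, stats::rnorm(nT * nPix, 0,
                                         params@noiseSdPercent / 100 * f0))
  if (quantize) {
    M <- round(M)
    rng <- range(M)
    if (rng[1L] < 0) M[M < 0] <- 0
    if (rng[2L] > MAX_COUNT) M[M > MAX_COUNT] <- MAX_COUNT
  }
  meta <- MovieMeta(frameIntervalMs = frameIntervalMs,
                    pixelSizeUm = pixelSizeUm,
                    dim = c(nT, lay$height, lay$width), protocol = protocol)
  truth <- new("GroundTruth", traces = traces, onsets = onsets,
               gains = gains, lag1Ms = params@lag1Ms, lag2Ms = params@lag2Ms)
  list(movie = RawMovie(asMovieArray(M, lay$height, lay$width), meta),
       truth = truth)
}

#' Generate suppressed spontaneous spike trains
#'
#' Inhomogeneous Poisson spike trains emulating layer III patch-clamp
#' sweeps.  Each sweep draws its spontaneous baseline rate uniformly from
#' \code{baselineRateRangeHz}; the rate drops to \code{suppressedRateHz}
#' during the stimulus train and for \code{holdS} seconds after its offset,
#' then relaxes back to baseline exponentially with \code{recoveryTauS}, so
#' the rate has recovered to within a few percent of baseline by the end of
#' a 20 s sweep.  Simulation is by thinning; identical seeds give identical
#' trains.
#'
#' @param params a \code{\link{CircuitParams}} (its \code{spike} model is
#'   used).
#' @param protocol a \code{\link{StimProtocol}}; the default patch protocol
#'   is a 1 s train at 60 Hz after a 5 s baseline in a 20 s sweep.
#' @param n number of sweeps.
#' @param seed integer seed.
#' @return list of \code{\link{SpikeTrain}}s.
#' @export
generateSpikeTrains <- function(params, protocol = StimProtocol(
                                  60, baselineS = 5, recordS = 20),
                                n = 16, seed = 1) {
  stopifnot(is(params, "CircuitParams"), is(protocol, "StimProtocol"), n >= 1)
  sp <- params@spike
  if (sp$suppressedRateHz < 0 || any(sp$baselineRateRangeHz <= 0))
    stop("argument error: spike rates must be positive")
  onset <- stimOnset(protocol)
  offset <- stimOffset(protocol)
  dur <- protocol@recordS
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      b <- stats::runif(1, sp$baselineRateRangeHz[1L],
                        sp$baselineRateRangeHz[2L])
      s <- min(sp$suppressedRateHz, b)
      rate <- function(t) {
        recov <- b - (b - s) * exp(-(t - (offset + sp$holdS)) /
                                     sp$recoveryTauS)
        ifelse(t < onset, b,
               ifelse(t < offset + sp$holdS, s, recov))
      }
      ## thinning at the baseline (maximal) rate
      nCand <- stats::rpois(1, b * dur)
      cand <- sort(stats::runif(nCand, 0, dur))
      keep <- stats::runif(nCand) < rate(cand) / b
      SpikeTrain(times = cand[keep], durationS = dur, trainOnsetS = onset,
                 trainDurationS = offset - onset)
    })
  })
}
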