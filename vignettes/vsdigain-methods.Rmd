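---
title: "Methods: VSDI quantification and the synthetic disinhibition circuit"
author: "vsdigain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VSDI quantification and the synthetic disinhibition circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the signal
model behind each preprocessing step, the definitions chosen for every
response measurement, the gain model fitted to input/output curves, the
forward generator used to validate the whole chain, and the numerical and
design decisions taken where the underlying experimental convention is
genuinely open. No empirical claim is made here beyond what the package's
test suite and `scripts/acceptance.R` themselves compute.

## 1. Signal model and preprocessing

A voltage-sensitive dye converts membrane potential into fluorescence
with negative slope: depolarization *dims* the dye. A recording is a
T × H × W stack of 16-bit camera counts `F(t, x)` with a stimulation
protocol (2 s baseline, then a 1 s pulse train at 5–100 Hz, in a sweep of
about 20 s) and a frame interval of 3–10 ms.

**ΔF/F.** Per pixel, the baseline fluorescence `F0(x)` is the mean count
over the pre-stimulus baseline window (the full 2 s epoch by default; the
window is configurable but must end at or before stimulus onset). The
fractional change is `100·(F(t,x) − F0(x))/F0(x)` percent, multiplied by
−1 by default so that depolarization reads positive and hyperpolarization
negative — the conventional display. Pixels with `F0 = 0` cannot be
divided; they are flagged invalid and carried as `NA` through every later
stage (never silently zeroed), and a movie with more than 10 % such
pixels is rejected outright as a data-quality failure.

**Bleach correction.** Photobleaching is modeled as a stimulus-independent
common-mode decay shared by all pixels. Following standard practice the
user designates a *reference* region that is unresponsive to the
stimulus; its mean ΔF/F trace is subtracted frame-wise from every pixel.
This removes *any* common-mode component exactly (not just an
exponential), which is why direct subtraction was chosen over fitting an
exponential to the reference: it is assumption-free and leaves the
reference trace identically zero. The correction is guarded against
double application. Reference selection is manual by design — automatic
selection by minimal stimulus-locked variance is easy to add but was
deliberately left out of the default path, since a wrongly auto-chosen
reference silently corrupts every trace.

**Binning.** 3 × 3 blocks of pixels are averaged into one representative
signal (factor configurable). Trailing rows/columns that do not fill a
complete block are dropped — the simplest deterministic edge policy — and
the metadata pixel size is scaled accordingly. Block means skip invalid
pixels; a binned pixel is invalid only if all nine sources are. Region
masks are binned conservatively: a binned pixel keeps a label only when
all nine source pixels carry it, so binned regions never bleed across
boundaries.

**Calibration.** A high-potassium depolarization experiment gives the
conversion factor: a total fluorescence change of 6.3 % over an assumed
70 mV span (resting potential ≈ −70 mV depolarized to 0 mV) yields
0.9 % ΔF/F per 10 mV, and `dffToMv()` applies the inverse mapping to any
trace.

**Indexing convention.** Frames are indexed `(t, row, col)` with R's
native 1-based indexing, origin top-left; the physical position of a
pixel is `(index − 1) × pixelSize`. All on-disk formats (TIFF + JSON
sidecar, CSV traces) are bit-exact round-trippable, which the test suite
checks at byte level.

## 2. Response measurements

All measurements refer to a *baseline mean* computed from the
pre-stimulus segment of the trace and a *response window* that defaults
to stimulus onset → onset + 10 s.

- **Magnitude** is the signed value of the extremum of largest absolute
  deviation from the baseline mean within the window (ties broken by the
  earliest frame). Peak was chosen over an integral because the
  characteristic quantity of these responses is their amplitude; the
  window and the choice are configurable and documented rather than
  implicit.
- **Polarity** is excitatory/inhibitory by the sign of the magnitude, or
  `"none"` when the absolute magnitude stays below `k` baseline standard
  deviations (default `k = 3`) — a response that never leaves the noise
  is reported as absent, not as a small number.
- **Onset latency** is the time from stimulus onset to the first frame at
  which the absolute deviation reaches 20 % of the peak deviation *and
  stays there for two consecutive frames*. The 20 % criterion is
  interpreted relative to the peak (not as an absolute 20 % above the
  baseline value, which would be ill-defined for a zero baseline), and
  the persistence requirement makes the crossing robust to single-frame
  noise. Both are configurable. A trace with no crossing returns `NA`.
- **Lags.** Lag 1 = DEn onset − layer II onset; Lag 2 = layer III onset −
  layer II onset. Because the response kernel is identical across regions
  up to amplitude, and the onset criterion is scale-invariant, the
  threshold-crossing bias cancels in the differences: at zero noise the
  estimated lags equal the generator's programmed lags to within one
  frame interval.
- **Rate of rise** is the least-squares slope of the absolute deviation
  between its 20 % and 80 % of-peak crossings (%/s). A 20–80 % secant was
  chosen because it is insensitive to both the noisy foot and the
  saturating shoulder; a step sampled too coarsely to have two samples
  between the crossings is flagged undefined.
- **Normalization.** Dye loading varies slice to slice, so magnitudes are
  comparable only after dividing by the same region's response to the
  20 Hz stimulus in the same slice. The reference point maps to exactly
  ±1; a missing or zero reference is an error naming the region and
  slice, never a silent `NaN`.

## 3. Input/output curves and the gain fit

Normalized magnitudes are grouped by stimulation frequency (mean and SEM
per frequency across slices). The fitted model is a Hill-type sigmoid on
linear frequency,

```
R(f) = base + (top − base) / (1 + (fHalf / f)^hill),
```

so that `R(fHalf) = (base + top)/2` exactly — `fHalf` *is* the
half-maximal stimulation frequency, with no post-hoc interpolation. A
log-frequency variant is available behind a switch. Fitting uses
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with
deterministic initialization (base = min, top = max, `fHalf` = frequency
nearest the half-range crossing, hill = 2) and positivity bounds on
`fHalf` and `hill`, so results are reproducible and order-invariant. The
fit refuses (`converged = FALSE`) when fewer than four distinct
frequencies are available or when the dynamic range of the data is below
0.5 normalized units — a flat curve has no meaningful midpoint, and
reporting one would be worse than declining.

Inhibitory (layer III) curves are assembled on the *absolute* normalized
magnitude so that "activation of inhibition" increases with frequency
and the same sigmoid applies.

The control-vs-kindled contrast reports, per slice and frequency
(40/60/80 Hz), the difference between the normalized response and its
20 Hz value (which is 0 at 20 Hz by construction), with group means and
the kindled-minus-control gap.

## 4. Spike-train analysis

Action potentials are detected as upward crossings of a fixed voltage
threshold (default −20 mV absolute) with a 2 ms refractory window; the
paper-style statistic is the percent reduction in mean firing rate
between the 5 s before train onset and the 5 s after train *offset*
("after the trains" is read as after the train ends). A sweep with no
pre-train spikes has an undefined reduction and is flagged, not counted
as 0 or 100. The rate time course is a plain binned histogram (1 s bins
by default).

## 5. The forward generator

The generator encodes the feed-forward disinhibition circuit as ground
truth so that every estimator above can be tested for parameter
recovery. One movie is built as follows.

**Response kernel.** Each region r responds with
`polarity · A_r(f) · (1 − e^{−(t−tOn)/τ_rise}) · e^{−(t−tOn)/τ_decay}`
for `t ≥ tOn`. The product-of-exponentials kernel is the simplest shape
with a finite rise time and a slow decay; `τ_rise = 50 ms` and
`τ_decay = 4 s` were chosen so that activity persists on the order of
10 s after the train, as in the recordings the model emulates. Onsets
are stimulus onset + 20 ms for layer II (a plausible mono-synaptic
latency; the exact value is immaterial because all estimates of interest
are onset *differences*), plus Lag 1 = 50 ms for the DEn and
Lag 2 = 200 ms for layer III.

**Gain curves.** The amplitude is
`A_r(f) = baseAmplitude_r · N_r(f)` with `N_r` a sigmoid in the model
family of section 3, parameterized by the two quantities the experimental
literature actually reports: the half-maximal frequency and the response
fold at 80 Hz relative to 20 Hz. Given `(fold, fHalf, hill)` the base and
top are solved from the two constraints `N(20) = 1` and `N(80) = fold`.
One structural fact falls out of this parameterization: when the
half-max sits at (or below) the 20 Hz normalization point, the midpoint
value is the normalized value 1, so the plateau of any nonnegative
sigmoid is capped at 2 — a 2.5-fold at 80 Hz with a 20 Hz half-max is not
jointly representable. For the control layer III curve the half-maximal
frequency was kept exact (it is the physiologically meaningful quantity)
and the base is clamped at 0, giving an effective fold of ≈ 1.97; the
same clamp caps the kindled DEn at 8-fold (requested 10). Negative tails
are truncated at zero: at ineffective frequencies a region produces no
response rather than a wrong-polarity one. For the kindled layer III
curve the half-max was placed at 40 Hz — the defaults must produce
inhibition that diverges from control only above 40 Hz while reaching
4.5-fold at 80 Hz, and both facts together force the midpoint to the
right.

Condition defaults (fold at 80 Hz / fHalf / polarity / % ΔF/F at 20 Hz):

| region   | control           | kindled          | cut               |
|----------|-------------------|------------------|-------------------|
| layerII  | 3.5 / 40 / + / 2.0 | 6 / 40 / + / 2.0 | 2.5 / 40 / + / 1.0 |
| DEn      | 5 / 40 / + / 1.5   | 10 / 40 / + / 1.5 | 0 (silent)        |
| layerIII | 2.5* / 20 / − / 1.0 | 4.5 / 40 / − / 1.0 | 2.5 / 40 / + / 0.5 |

(* capped at ≈ 1.97, see above.) The cut condition abolishes the DEn
response entirely, converts layer III to a weak excitation (the residual
feed-forward drive onto layer III interneurons), and reduces the layer II
gain — the qualitative signature of severing the layer II output axons.
The 20 Hz amplitudes (2.0 / 1.5 / 1.0 % ΔF/F) are ordinary response sizes
for this preparation, with the DEn somewhat smaller than layer II and the
inhibition smaller still.

**Acquisition model.** Counts are
`F0 · (1 − ΔF/F / 100) · e^{−t/τ_bleach} + ε`, with `F0 = 3000` counts
(mid-range of a 16-bit camera operated at 50–80 % saturation),
`τ_bleach = 100 s` (≈ 18 % signal loss over a 20 s sweep, a plausible
styryl-dye bleaching rate under halogen illumination, and small enough
that reference subtraction leaves ≲ 1.5 % multiplicative bias at the
response peak), and `ε` i.i.d. Gaussian per pixel and frame with SD 0.3 %
of `F0`. Spatially correlated noise is deliberately not modeled (see
§ 7). The reference band carries bleaching and noise only. The spatial
layout is four horizontal bands (layer II, DEn, layer III, reference) in
a 64 × 64 frame by default (100 × 100 available via the layout
arguments); the default frame interval is 5 ms, inside the 3–10 ms range
the data model accepts. With `quantize = TRUE` (default) counts are
rounded and clipped to the 16-bit range as a camera would;
`quantize = FALSE` keeps continuous counts for noiseless diagnostics
where exact-zero traces matter (e.g. proving the severed DEn is *below
detection*, not merely small). Identical seeds and parameters give
bit-identical movies; batch helpers derive per-movie seeds
deterministically from the slice seed and frequency, and slice-level
dye-loading variability is emulated by a uniform amplitude scale in
[0.7, 1.3] that normalization removes exactly.

**Spike trains.** Layer III sweeps are inhomogeneous Poisson processes
simulated by thinning. Each sweep draws a spontaneous rate uniformly
from 8–10 Hz; the rate drops to 3.4 Hz at train onset, holds for 5 s
after train offset, then relaxes back exponentially with τ = 5 s, so the
rate is back within a few percent of baseline by the end of the 20 s
sweep. The suppressed-rate default was set so the *expected* 5 s-pre /
5 s-post reduction, `E[1 − 3.4/B]` with `B ~ U(8, 10)`, is 62 % — the
headline suppression statistic — while still reading as "about 4 Hz"
post-train; a literal 4 Hz floor would cap the expected reduction near
55 %, and the two printed figures cannot both hold exactly. The patch
protocol uses a 5 s baseline (the 5 s pre-window plus a 14 s post-train
time course require it), unlike the 2 s optical baseline.

## 6. Problem sizes and numerical choices

The validation suite and the acceptance script run at the study's own
scale where the quantity demands it and at reduced scale elsewhere: lag
recovery uses 20 movies (64 × 64, 5 ms/frame, 4000 frames) at 40 Hz; gain
recovery uses 8 slices × 7 frequencies; the kindled contrast 8 slices per
condition; spike statistics 16 sweeps; oracle-equivalence properties run
on 120 randomized small fixtures against brute-force loop
implementations. Unit tests use a 32 × 32 frame, 10 ms/frame, 8 s sweep
circuit, which preserves every structural property at a fraction of the
cost. Other numerical conventions: extremum ties break to the earliest
frame; sub-block remainders are dropped in binning; onset persistence is
2 frames; all flagged-undefined measurements propagate as `NA`; the
sigmoid fit tolerates at most 500 LM iterations and reports its residual
sum of squares.

## 7. What the generator does and does not emulate

It emulates the temporal and statistical structure the analysis relies
on: lagged region onsets with a common kernel, frequency-dependent gain
with the documented half-max frequencies and folds, multiplicative
bleaching, per-pixel sensor noise, 16-bit quantization, slice-level
amplitude variability, and suppressed-then-recovering spontaneous firing.
It does not emulate: spatially correlated (shot/vignetting) noise,
heterogeneous response shapes within a region, pulse-locked fast
transients inside the train, conduction or synaptic dynamics
(it is a phenomenological, not conductance-based, model), motion, or
pharmacological manipulations. Passing tests therefore demonstrate that
the estimators recover known structure under realistic noise — not that
real tissue satisfies the model; on real data the reference-region
choice, spatial noise correlations and within-region heterogeneity are
the places where judgment is still required.

## 8. Known limitations

- The onset estimator's threshold-crossing bias cancels only between
  regions with similar kernels; comparing onsets across very different
  waveforms would need a model-based estimator.
- The 20 %-of-peak criterion ties onset to the peak estimate; in very low
  SNR traces the peak (an extremum of noisy data) is biased upward, which
  can delay the estimated onset by a frame.
- Direct reference subtraction assumes bleaching is spatially uniform; a
  strongly vignetted field would need per-pixel bleach models.
- The sigmoid's four parameters are weakly identified from seven
  frequencies when the dynamic range is small; the refusal threshold
  exists precisely to keep such fits out of downstream summaries.
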