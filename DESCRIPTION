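Package: vsdigain
Title: Quantification of Voltage-Sensitive Dye Imaging Responses and
    Circuit Gain in the Piriform Cortex Slice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify voltage-sensitive dye imaging (VSDI) movies of
    cortical slice preparations: fractional fluorescence (dF/F) conversion with
    reference-region photobleaching correction and sign inversion, 3x3 spatial
    binning, region and stripe trace extraction, response magnitude and
    polarity, threshold-crossing onset latency and inter-region lags, rate of
    rise, 20 Hz-normalized input/output curves with sigmoidal gain fits and
    half-maximal frequency, control versus kindled fold-change contrasts, and
    spike-train suppression statistics from patch-clamp recordings. Includes a
    forward generator for the three-region feed-forward disinhibition circuit
    (layer II, dorsal endopiriform nucleus, layer III) producing synthetic
    movies and spike trains with full ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    mgcv
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'preprocess.R'
    'quantify.R'
    'curves.R'
    'spikes.R'
    'synthetic.R'
    'pipeline.R'
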