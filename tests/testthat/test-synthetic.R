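test_that("condition defaults encode the circuit's gain structure", {
  ctl <- defaultParams("control")
  expect_equal(ctl@lag1Ms, 50)
  expect_equal(ctl@lag2Ms, 200)
  expect_equal(regionGains(ctl)[["layerII"]]@topFold, 3.5)
  expect_equal(regionGains(ctl)[["layerII"]]@fHalf, 40)
  expect_equal(regionGains(ctl)[["layerIII"]]@fHalf, 20)
  expect_equal(regionGains(ctl)[["layerIII"]]@polarity, -1)
  kin <- defaultParams("kindled")
  expect_equal(regionGains(kin)[["layerII"]]@topFold, 6)
  expect_equal(regionGains(kin)[["DEn"]]@topFold, 10)
  cut <- defaultParams("cut")
  expect_equal(regionGains(cut)[["DEn"]]@topFold, 0)
  expect_equal(regionGains(cut)[["layerIII"]]@polarity, +1)
  expect_error(defaultParams("sham"), "arg")
})

test_that("the gain curve is anchored at 20 Hz and at the requested fold", {
  g <- RegionGain(3.5, 40, 3)
  expect_equal(gainCurve(g, 20), 1, tolerance = 1e-12)
  expect_equal(gainCurve(g, 80), 3.5, tolerance = 1e-12)
  expect_true(all(diff(gainCurve(g, c(5, 10, 20, 40, 60, 80, 100))) > 0))
  ## a half-max at the normalization point caps the attainable fold at 2
  gIII <- RegionGain(2.5, 20, 3)
  expect_equal(gainCurve(gIII, 20), 1, tolerance = 1e-12)
  expect_lt(gainCurve(gIII, 80), 2)
  expect_gt(gainCurve(gIII, 80), 1.9)
  expect_true(all(gainCurve(gIII, c(1, 2, 5)) >= 0))
  expect_equal(gainCurve(RegionGain(0, 40, 3), c(20, 80)), c(0, 0))
})

test_that("movie generation is deterministic per seed", {
  a <- testMovie(seed = 7)
  b <- testMovie(seed = 7)
  c <- testMovie(seed = 8)
  expect_identical(frames(a$movie), frames(b$movie))
  expect_false(identical(frames(a$movie), frames(c$movie)))
})

test_that("generated counts follow the dye and bleaching model", {
  sim <- testMovie(noise = 0, quantize = FALSE, frequencyHz = 40)
  p <- testParams()
  fr <- frames(sim$movie)
  tt <- frameTimes(sim$movie)
  ## reference band: pure bleaching at F0
  refRow <- p@layout$bands$reference[1]
  expect_equal(fr[, refRow, 1], 3000 * exp(-tt / 100), tolerance = 1e-12)
  ## layer II dims as it depolarizes: counts drop below the bleach line
  iiRow <- p@layout$bands$layerII[1]
  during <- tt > 2.3 & tt < 3
  expect_true(all(fr[during, iiRow, 1] < 3000 * exp(-tt[during] / 100)))
  ## layer III hyperpolarizes: counts rise above the bleach line
  iiiRow <- p@layout$bands$layerIII[1]
  expect_true(all(fr[during, iiiRow, 1] > 3000 * exp(-tt[during] / 100)))
  ## ground truth traces carry the sign convention (depolarization positive)
  expect_gt(max(traceValues(truthTraces(sim$truth)$layerII)), 0)
  expect_lt(min(traceValues(truthTraces(sim$truth)$layerIII)), 0)
  ## true onsets are stimulus onset + latency (+ lags)
  expect_equal(unname(truthOnsets(sim$truth)),
               c(2.02, 2.07, 2.22), tolerance = 1e-12)
})

test_that("cut-condition movies abolish DEn and invert layer III", {
  p <- testParams("cut")
  p@noiseSdPercent <- 0
  regions <- circuitRegions(p)
  for (seed in 1:3) {
    sim <- generateMovie(p, testProtocol(40), seed = seed,
                         frameIntervalMs = 10, quantize = FALSE)
    meas <- analyzeMovie(sim$movie, regions)
    expect_equal(meas$polarity[meas$region == "DEn"], "none")
    expect_equal(meas$polarity[meas$region == "layerIII"], "excitatory")
    expect_true(is.na(truthOnsets(sim$truth)[["DEn"]]))
  }
})

test_that("spike trains honour the suppression model", {
  p <- testParams()
  trains <- generateSpikeTrains(p, n = 16, seed = 5)
  expect_length(trains, 16)
  ## determinism
  again <- generateSpikeTrains(p, n = 16, seed = 5)
  expect_identical(spikeTimes(trains[[3]]), spikeTimes(again[[3]]))
  ## empirical baseline rate within 3 SE of the programmed 8-10 Hz band
  for (tr in trains[1:5]) {
    pre <- sum(spikeTimes(tr) < 5) / 5
    se <- sqrt(9 / 5)
    expect_gt(pre, 8 - 3 * se)
    expect_lt(pre, 10 + 3 * se)
  }
  ## post-train suppression below the pre rate in nearly all sweeps
  red <- vapply(trains, function(tr) prePostReduction(tr)$reductionPercent,
                numeric(1))
  expect_gte(mean(red > 0), 0.95)
  ## the rate has recovered near baseline by the end of the 20 s sweep
  lateRate <- mean(vapply(trains, function(tr)
    sum(spikeTimes(tr) >= 18) / 2, numeric(1)))
  expect_gt(lateRate, 0.8 * 8)
})

test_that("suppression limits behave as expected", {
  p <- testParams()
  p@spike$suppressedRateHz <- 0
  zero <- generateSpikeTrains(p, n = 8, seed = 6)
  red <- vapply(zero, function(tr) prePostReduction(tr)$reductionPercent,
                numeric(1))
  expect_true(all(red == 100))
  ## suppressed = baseline: no systematic reduction
  p2 <- testParams()
  p2@spike$suppressedRateHz <- 9
  p2@spike$baselineRateRangeHz <- c(9, 9)
  same <- generateSpikeTrains(p2, n = 40, seed = 7)
  redSame <- vapply(same, function(tr) prePostReduction(tr)$reductionPercent,
                    numeric(1))
  expect_lt(abs(mean(redSame)), 15)   # sampling error only
  p3 <- testParams()
  p3@spike$baselineRateRangeHz <- c(-1, 2)
  expect_error(generateSpikeTrains(p3, n = 2, seed = 1), "rates")
})

test_that("noiseless full-pipeline gain recovery is near-exact", {
  p <- testParams()
  p@noiseSdPercent <- 0
  regions <- circuitRegions(p)
  meas <- do.call(rbind, lapply(c(20, 40, 80), function(f) {
    sim <- generateMovie(p, testProtocol(f), seed = 1, frameIntervalMs = 10,
                         quantize = FALSE)
    analyzeMovie(sim$movie, regions, slice = "s1")
  }))
  meas <- normalizeToReference(meas)
  for (r in c("layerII", "DEn", "layerIII")) {
    g <- regionGains(p)[[r]]
    want <- gainCurve(g, c(20, 40, 80)) * g@polarity
    got <- meas$normalizedMagnitude[meas$region == r]
    expect_equal(got, want, tolerance = 1e-3)
  }
})
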