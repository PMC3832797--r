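test_that("dF/F of a constant movie is identically zero and scale-invariant", {
  mov <- constantMovie(value = 500)
  dff <- computeDff(mov)
  expect_true(all(dffValues(dff) == 0))
  expect_true(isSignInverted(dff))
  ## scaling all counts leaves dF/F unchanged
  set.seed(21)
  pr <- tinyProtocol()
  meta <- MovieMeta(10, 25, c(50, 5, 5), pr)
  counts <- array(runif(50 * 25, 50, 150), c(50, 5, 5))
  d1 <- dffValues(computeDff(RawMovie(counts, meta)))
  d2 <- dffValues(computeDff(RawMovie(counts * 7, meta)))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("dF/F arithmetic and sign convention follow the dye model", {
  ## baseline 100 counts, dip to 90 during the response; inverted -> +10%
  mov <- constantMovie(value = 100, nT = 50)
  fr <- frames(mov)
  fr[30:50, , ] <- 90
  mov <- RawMovie(fr, movieMeta(mov))
  dff <- computeDff(mov)
  expect_equal(dffValues(dff)[40, 1, 1], 10)
  expect_equal(dffValues(computeDff(mov, invert = FALSE))[40, 1, 1], -10)
})

test_that("the high-potassium calibration scenario is reproduced end to end", {
  ## a 6.3% fluorescence decrease should read out as a +6.3% plateau,
  ## i.e. 70 mV of depolarization under the 0.9%/10 mV calibration
  mov <- constantMovie(value = 3000, nT = 100)
  fr <- frames(mov)
  fr[51:100, , ] <- 3000 * (1 - 0.063)
  mov <- RawMovie(fr, movieMeta(mov))
  tr <- extractRegionTrace(computeDff(mov),
                           RegionSet(matrix(1L, 6, 6), "layerII"), "layerII")
  expect_equal(traceValues(tr)[80], 6.3, tolerance = 1e-9)
  mv <- dffToMv(tr, calibrate(6.3, 70))
  expect_equal(traceValues(mv)[80], 70, tolerance = 1e-9)
})

test_that("zero-baseline pixels are flagged invalid, not divided", {
  mov <- constantMovie(value = 100, nT = 50, h = 6, w = 6)
  fr <- frames(mov)
  fr[, 1, 1] <- 0
  dff <- computeDff(RawMovie(fr, movieMeta(mov)))
  expect_true(invalidMask(dff)[1, 1])
  expect_true(all(is.na(dffValues(dff)[, 1, 1])))
  ## too many dead pixels is a data-quality error
  fr[, 1:4, ] <- 0
  expect_error(computeDff(RawMovie(fr, movieMeta(mov))), "data-quality")
  ## a baseline window reaching into the stimulus is rejected
  expect_error(computeDff(mov, baselineWindow = c(0, 0.4)), "overlaps")
})

test_that("bleach correction removes common-mode decay exactly", {
  pr <- tinyProtocol()
  meta <- MovieMeta(10, 25, c(50, 6, 6), pr)
  tt <- frameTimes(meta)
  counts <- aperm(array(3000 * exp(-tt / 3), c(50, 6, 6)), c(1, 2, 3))
  labs <- matrix(0L, 6, 6)
  labs[1:2, ] <- 1L
  labs[5:6, ] <- 2L
  regions <- RegionSet(labs, c("layerII", "reference"))
  dff <- bleachCorrect(computeDff(RawMovie(counts, meta)), regions)
  expect_true(isBleachCorrected(dff))
  expect_lt(max(abs(dffValues(dff))), 1e-6)
  ## the corrected reference trace is zero-mean to 1e-9
  ref <- traceValues(extractRegionTrace(dff, regions, "reference"))
  expect_lt(abs(mean(ref)), 1e-9)
  ## guards: double correction, missing reference
  expect_error(bleachCorrect(dff, regions), "already")
  expect_error(bleachCorrect(computeDff(RawMovie(counts, meta)),
                             RegionSet(matrix(1L, 6, 6), "layerII")),
               "reference")
})

test_that("bleach-corrected pipeline recovers generator amplitudes within 2%", {
  sim <- testMovie(noise = 0, quantize = FALSE, seed = 1)
  p <- testParams()
  dff <- bleachCorrect(computeDff(sim$movie), circuitRegions(p))
  dffB <- binPixels(dff, 3)
  regB <- binRegions(circuitRegions(p), 3)
  for (r in c("layerII", "DEn", "layerIII")) {
    got <- responseMagnitude(extractRegionTrace(dffB, regB, r), 2)$magnitude
    truthPeak <- traceValues(truthTraces(sim$truth)[[r]])
    want <- truthPeak[which.max(abs(truthPeak))]
    expect_equal(got, want, tolerance = 0.02)
  }
})

test_that("binning matches the explicit block-mean oracle", {
  set.seed(5)
  pr <- tinyProtocol()
  for (rep in 1:3) {
    d <- c(10, sample(6:12, 1), sample(6:12, 1))
    meta <- MovieMeta(10, 25, d, pr)
    dff <- DffMovie(array(rnorm(prod(d)), d), meta)
    for (factor in 2:3) {
      got <- binPixels(dff, factor)
      expect_equal(dffValues(got), oracleBin(dffValues(dff), factor),
                   tolerance = 1e-12)
      expect_equal(pixelSizeUm(movieMeta(got)), 25 * factor)
    }
  }
})

test_that("binning identities and edge policy hold", {
  pr <- tinyProtocol()
  meta <- MovieMeta(10, 25, c(10, 9, 9), pr)
  uni <- DffMovie(array(4.2, c(10, 9, 9)), meta)
  expect_true(all(dffValues(binPixels(uni, 3)) == 4.2))
  expect_identical(binPixels(uni, 1), uni)
  expect_error(binPixels(uni, 12), "exceeds")
  ## frame means are preserved when dimensions divide evenly
  set.seed(6)
  rnd <- DffMovie(array(rnorm(10 * 81), c(10, 9, 9)), meta)
  b <- binPixels(rnd, 3)
  expect_equal(apply(dffValues(b), 1, mean), apply(dffValues(rnd), 1, mean),
               tolerance = 1e-12)
  ## binning commutes with frame-wise affine maps
  aff <- DffMovie(2 * dffValues(rnd) + 1, meta)
  expect_equal(dffValues(binPixels(aff, 3)), 2 * dffValues(b) + 1,
               tolerance = 1e-12)
})

test_that("the voltage calibration is exact arithmetic", {
  expect_identical(percentPer10mV(calibrate(6.3, 70)), 0.9)
  expect_identical(percentPer10mV(calibrate(0, 70)), 0)
  expect_identical(percentPer10mV(calibrate(9, 90)), 1)
  expect_error(calibrate(6.3, 0), "spanMv")
  expect_error(calibrate(6.3, -70), "spanMv")
  cal <- calibrate(6.3, 70)
  tr <- Trace(c(0, 1), c(0.9, 6.3))
  expect_equal(traceValues(dffToMv(tr, cal)), c(10, 70))
  expect_equal(traceValues(mvToDff(dffToMv(tr, cal), cal)),
               traceValues(tr), tolerance = 1e-12)
  expect_error(dffToMv(tr, calibrate(0, 70)), "zero")
})
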