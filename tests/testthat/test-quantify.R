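test_that("region and stripe extraction equal the loop oracles", {
  set.seed(9)
  pr <- tinyProtocol()
  for (rep in 1:5) {
    d <- c(8, 12, 12)
    meta <- MovieMeta(10, 25, d, pr)
    dff <- DffMovie(array(rnorm(prod(d)), d), meta)
    labs <- matrix(0L, 12, 12)
    labs[sample(144, 30)] <- 1L
    rs <- RegionSet(labs, "layerII")
    got <- traceValues(extractRegionTrace(dff, rs, "layerII"))
    expect_equal(got, oracleRegionTrace(dffValues(dff), labs == 1L),
                 tolerance = 1e-12)
    r0 <- sample(3:10, 1)
    st <- Stripe(cbind(r0, 2:11))
    gotS <- traceValues(extractStripeProfile(dff, st))
    maskS <- matrix(FALSE, 12, 12)
    maskS[r0, 2:11] <- TRUE
    expect_equal(gotS, oracleRegionTrace(dffValues(dff), maskS),
                 tolerance = 1e-12)
  }
})

test_that("extraction degenerate cases behave as documented", {
  pr <- tinyProtocol()
  meta <- MovieMeta(10, 25, c(8, 12, 12), pr)
  set.seed(10)
  vals <- array(rnorm(8 * 144), c(8, 12, 12))
  dff <- DffMovie(vals, meta)
  ## single-pixel region reproduces that pixel's series
  labs <- matrix(0L, 12, 12)
  labs[3, 4] <- 1L
  tr <- extractRegionTrace(dff, RegionSet(labs, "layerII"), "layerII")
  expect_equal(traceValues(tr), vals[, 3, 4])
  ## uniform movie: any region or stripe equals the uniform series
  uni <- DffMovie(array(rep(1:8, 144), c(8, 12, 12)), meta)
  labs2 <- matrix(0L, 12, 12); labs2[5:7, 5:9] <- 1L
  expect_equal(traceValues(extractRegionTrace(uni, RegionSet(labs2, "x"),
                                              "x")), as.numeric(1:8))
  expect_equal(traceValues(extractStripeProfile(uni, Stripe(cbind(6, 2:11)))),
               as.numeric(1:8))
  ## out-of-frame stripe is rejected
  expect_error(extractStripeProfile(dff, Stripe(cbind(12, 8:17))),
               "outside")
  ## a region too small to survive binning violates the non-empty invariant
  small <- matrix(0L, 12, 12); small[1, 1] <- 1L
  expect_error(binRegions(RegionSet(small, "tiny"), 3), "empty")
  ## a region whose pixels are all invalid is empty at extraction time
  inv <- matrix(FALSE, 12, 12); inv[3, 4] <- TRUE
  dffInv <- DffMovie(vals, meta, invalidMask = inv)
  expect_error(extractRegionTrace(dffInv, RegionSet(labs, "layerII"),
                                  "layerII"), "empty")
})

test_that("response magnitude takes the largest signed deviation", {
  tt <- seq(0, 3, by = 0.01)
  flat <- Trace(tt, rep(0, length(tt)))
  m <- responseMagnitude(flat, 1)
  expect_equal(m$magnitude, 0)
  expect_equal(m$polarity, "none")
  v <- rep(0, length(tt))
  v[tt > 1.2 & tt < 1.4] <- 2
  v[tt > 1.6 & tt < 1.8] <- -0.5
  m2 <- responseMagnitude(Trace(tt, v), 1)
  expect_equal(m2$magnitude, 2)
  expect_equal(m2$polarity, "excitatory")
  m3 <- responseMagnitude(Trace(tt, -v), 1)
  expect_equal(m3$magnitude, -2)
  expect_equal(m3$polarity, "inhibitory")
  expect_error(responseMagnitude(flat, 1, window = c(5, 6)), "outside")
})

test_that("noiseless generator magnitudes are recovered to 1e-6", {
  sim <- testMovie(noise = 0, quantize = FALSE)
  truth <- truthTraces(sim$truth)[["layerIII"]]
  m <- responseMagnitude(truth, 2)
  expect_equal(m$magnitude, -max(abs(traceValues(truth))), tolerance = 1e-6)
  expect_equal(m$polarity, "inhibitory")
})

test_that("onset detection follows the 20%-of-peak criterion", {
  ## ramp starting 100 ms after the stimulus, rising linearly over 500 ms:
  ## 20% of peak is reached 100 ms into the ramp -> onset 200 ms
  tt <- seq(0, 3, by = 0.005)
  v <- rep(0, length(tt))
  i0 <- 221L                      # sample at t = 1.100 s
  v[i0 + 0:100] <- (0:100) / 100  # linear rise to the peak over 500 ms
  v[(i0 + 101L):length(tt)] <- 1
  expect_equal(estimateOnset(Trace(tt, v), 1), 200)
  expect_equal(estimateOnset(Trace(tt, -v), 1), 200)  # polarity symmetric
  expect_error(estimateOnset(Trace(tt, v), 1, criterion = 1.5), "criterion")
  expect_error(estimateOnset(Trace(tt, v), 1, criterion = 0), "criterion")
  ## no crossing -> flagged undefined
  expect_true(is.na(estimateOnset(Trace(tt, rep(0, length(tt))), 1)))
})

test_that("onset equals the exhaustive frame-scan oracle on noisy traces", {
  set.seed(12)
  tt <- seq(0, 5, by = 0.01)
  for (rep in 1:30) {
    on <- runif(1, 1.05, 2)
    amp <- runif(1, 0.5, 3)
    v <- amp * pmax(0, 1 - exp(-(tt - on) / 0.05)) * exp(-(tt - on) / 2) +
      rnorm(length(tt), 0, 0.05)
    got <- estimateOnset(Trace(tt, v), 1)
    want <- oracleOnset(tt, v, 1)
    expect_identical(got, want)
  }
})

test_that("onset is shift-equivariant and scale-invariant", {
  set.seed(13)
  tt <- seq(0, 5, by = 0.01)
  v <- pmax(0, 1 - exp(-(tt - 1.5) / 0.05)) * exp(-(tt - 1.5) / 2) +
    rnorm(length(tt), 0, 0.02)
  base <- estimateOnset(Trace(tt, v), 1)
  expect_equal(estimateOnset(Trace(tt + 0.7, v), 1.7), base)
  expect_equal(estimateOnset(Trace(tt, 13 * v), 1), base)
})

test_that("lags are onset differences with NA propagation", {
  expect_equal(lagPair(100, 150, 300), c(lag1Ms = 50, lag2Ms = 200))
  expect_equal(lagPair(80, 80, 80), c(lag1Ms = 0, lag2Ms = 0))
  la <- lagPair(100, NA, 300)
  expect_true(is.na(la[["lag1Ms"]]))
  expect_equal(la[["lag2Ms"]], 200)
})

test_that("noiseless generator lags are exact to one frame interval", {
  sim <- testMovie(noise = 0, quantize = FALSE)
  p <- testParams()
  meas <- analyzeMovie(sim$movie, circuitRegions(p))
  expect_lte(abs(meas$lag1Ms[1] - 50), 10)
  expect_lte(abs(meas$lag2Ms[1] - 200), 10)
  ## pipeline onsets equal onsets measured on the ground-truth traces
  for (r in c("layerII", "DEn", "layerIII")) {
    truthOn <- estimateOnset(truthTraces(sim$truth)[[r]], 2)
    expect_lte(abs(meas$onsetMs[meas$region == r] - truthOn), 10)
  }
})

test_that("rate of rise is exact for a ramp and undefined for a step", {
  tt <- seq(0, 3, by = 0.005)
  v <- rep(0, length(tt))
  ramp <- tt >= 1 & tt <= 2
  v[ramp] <- (tt[ramp] - 1) * 1.0   # 1 %/s
  v[tt > 2] <- 1
  expect_equal(rateOfRise(Trace(tt, v), 1), 1.0, tolerance = 1e-6)
  step <- ifelse(tt >= 1.5, 1, 0)
  expect_true(is.na(rateOfRise(Trace(tt, step), 1)))
})

test_that("rate of rise increases with generator drive amplitude", {
  p <- testParams()
  p@noiseSdPercent <- 0
  regions <- circuitRegions(p)
  rr <- sapply(c(20, 40, 80), function(f) {
    sim <- generateMovie(p, testProtocol(f), seed = 1, frameIntervalMs = 10,
                         quantize = FALSE)
    analyzeMovie(sim$movie, regions)[1, "rateOfRise"]  # layerII row
  })
  expect_true(all(diff(rr) > 0))
})

test_that("normalization to the 20 Hz reference is exact", {
  meas <- data.frame(slice = "s1", region = "layerII",
                     frequencyHz = c(20, 40), magnitude = c(0.5, 1.5))
  out <- normalizeToReference(meas)
  expect_equal(out$normalizedMagnitude, c(1, 3))
  ## inhibitory reference maps to exactly -1
  neg <- data.frame(slice = "s1", region = "layerIII",
                    frequencyHz = c(20, 40), magnitude = c(-0.5, -1.5))
  expect_equal(normalizeToReference(neg)$normalizedMagnitude, c(-1, -3))
  bad <- data.frame(slice = "s1", region = "layerII",
                    frequencyHz = c(20, 40), magnitude = c(0, 1.5))
  expect_error(normalizeToReference(bad), "zero")
  expect_error(normalizeToReference(meas[meas$frequencyHz != 20, ]),
               "no 20 Hz reference")
})
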