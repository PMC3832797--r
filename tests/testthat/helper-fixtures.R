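## Shared fixtures: small, fast synthetic inputs built in code.

## a compact circuit for unit tests: 32x32 frame, 10 ms frames, 8 s sweeps
testParams <- function(condition = "control")
  defaultParams(condition, frameHeight = 32, frameWidth = 32)

testProtocol <- function(frequencyHz = 40, recordS = 8)
  StimProtocol(frequencyHz, baselineS = 2, trainS = 1, recordS = recordS)

testMovie <- function(condition = "control", frequencyHz = 40, seed = 1,
                      noise = NULL, quantize = TRUE, recordS = 8) {
  p <- testParams(condition)
  if (!is.null(noise)) p@noiseSdPercent <- noise
  generateMovie(p, testProtocol(frequencyHz, recordS), seed = seed,
                frameIntervalMs = 10, quantize = quantize)
}

## constant-count movie with a tiny protocol (100 ms frames: a 0.2 s
## baseline is two frames)
constantMovie <- function(value = 100, nT = 50, h = 6, w = 6,
                          frameIntervalMs = 100) {
  pr <- StimProtocol(40, baselineS = 0.2, trainS = 0.1, recordS = 0.5)
  meta <- MovieMeta(frameIntervalMs, 25, c(nT, h, w), pr)
  RawMovie(array(value, c(nT, h, w)), meta)
}

## protocol for hand-built DffMovie fixtures with few, fast frames
tinyProtocol <- function()
  StimProtocol(40, baselineS = 0.05, trainS = 0.05, recordS = 0.5)

## voltage trace with rectangular 2 ms spikes at given times
spikeVoltage <- function(spikeTimes, durationS = 10, dt = 5e-4,
                         restMv = -65, peakMv = 15, noiseSd = 0) {
  tt <- seq(0, durationS, by = dt)
  v <- rep(restMv, length(tt))
  for (s in spikeTimes) v[tt >= s & tt < s + 0.002] <- peakMv
  if (noiseSd > 0) v <- v + rnorm(length(v), 0, noiseSd)
  Trace(tt, v, units = "mV")
}

## independent oracles -----------------------------------------------------

## block means by explicit loops
oracleBin <- function(vals, factor) {
  d <- dim(vals)
  nr <- d[2L] %/% factor
  nc <- d[3L] %/% factor
  out <- array(NA_real_, c(d[1L], nr, nc))
  for (t in seq_len(d[1L])) for (i in seq_len(nr)) for (j in seq_len(nc))
    out[t, i, j] <- mean(vals[t, (i - 1) * factor + seq_len(factor),
                              (j - 1) * factor + seq_len(factor)])
  out
}

## region mean trace by explicit loops
oracleRegionTrace <- function(vals, mask) {
  sapply(seq_len(dim(vals)[1L]), function(t) {
    acc <- c()
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
      if (mask[i, j]) acc <- c(acc, vals[t, i, j])
    mean(acc)
  })
}

## literal onset definition: first frame at/after stimulus where the
## absolute deviation from the pre-stimulus mean stays >= criterion * peak
## for `persist` frames
oracleOnset <- function(time, values, stimOnsetS, criterion = 0.2,
                        persist = 2, windowEndS = stimOnsetS + 10) {
  base <- mean(values[time < stimOnsetS])
  post <- which(time >= stimOnsetS & time <= windowEndS)
  dev <- abs(values[post] - base)
  thr <- criterion * max(dev)
  if (max(dev) == 0) return(NA_real_)
  for (i in seq_along(post)) {
    if (i + persist - 1 > length(post)) break
    if (all(dev[i:(i + persist - 1)] >= thr))
      return((time[post[i]] - stimOnsetS) * 1000)
  }
  NA_real_
}

## literal spike detector: walk every sample
oracleSpikes <- function(time, v, thr, refS) {
  out <- numeric(0)
  last <- -Inf
  for (i in 2:length(v)) {
    if (v[i] >= thr && v[i - 1] < thr && time[i] - last > refS) {
      out <- c(out, time[i])
      last <- time[i]
    }
  }
  out
}
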