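# Contractility outcome measures.

test_that("instantaneous mean tracks constants, ramps and sinusoid means", {
  evts <- function(x) detectPeaksTroughs(x)
  # constant trace with synthetic peak indices: mean identically 100
  im <- instantaneousMean(rep(100, 120), seq(10, 110, by = 20))
  expect_true(all(im$values == 100))
  # linear ramp: centred average equals the ramp at interior points
  ramp <- seq(0, 50, length.out = 201)
  im2 <- instantaneousMean(ramp, c(50L, 100L, 150L))
  inner <- !im2$excluded
  expect_equal(im2$values[inner], ramp[inner], tolerance = 1e-12)
  # sinusoid amplitude 10 about 100, window ~1.5 periods: the residual
  # oscillation is the sinc attenuation |sin(pi W/T)|/(pi W/T) ~ 0.215,
  # so interior values stay within 100 +- 2.2; also cross-check against an
  # independently computed centred rolling mean
  x <- 100 + 10 * sin(2 * pi * (0:299) / 25)
  ev3 <- evts(x)
  im3 <- instantaneousMean(x, ev3)
  expect_true(all(abs(im3$values[!im3$excluded] - 100) < 2.2))
  W <- im3$window
  oracle <- stats::filter(x, rep(1 / W, W), sides = 2)
  inner <- which(!im3$excluded)
  expect_equal(im3$values[inner], as.numeric(oracle[inner]),
               tolerance = 1e-12)
  expect_error(instantaneousMean(x, integer(0)), "at least 2 peaks")
})

test_that("cycle measurement pairs peaks with following troughs", {
  # square-ish trace: peaks of 120 at 25/75, troughs of 80 at 50/100
  x <- rep(100, 140)
  x[c(25, 75)] <- 120; x[c(50, 100)] <- 80
  ev <- new("PeakTroughSet", peaks = c(25L, 75L), troughs = c(50L, 100L),
            scalePeaks = new("ScaleSelection", gamma = 0, lambda = 1L, L = 1L),
            scaleTroughs = new("ScaleSelection", gamma = 0, lambda = 1L, L = 1L),
            n = 140L)
  im <- list(values = rep(100, 140), excluded = rep(FALSE, 140),
             window = NA_integer_)
  cyc <- measureCycles(x, ev, im, valueMethod = "raw")
  expect_identical(nrow(cyc), 2L)
  expect_equal(cyc$pct_amplitude, c(40, 40))
  # a peak with no following trough contributes no cycle
  ev2 <- new("PeakTroughSet", peaks = 120L, troughs = integer(0),
             scalePeaks = ev@scalePeaks, scaleTroughs = ev@scaleTroughs,
             n = 140L)
  expect_identical(nrow(measureCycles(x, ev2, im)), 0L)
})

test_that("noiseless phantom amplitude is recovered within a point", {
  # closed-form sinusoid: depth is exact
  ws <- contractionParams(depth = 0.4, frequency = 6, waveform = "sinusoid")
  g <- generateTraces(ws, "diameter", frameRate = 2.5, duration = 180)
  s <- summarizeTrace(g$trace)
  expect_equal(frequency(s), 6)
  expect_lt(abs(pctAmplitude(s) - 40), 1)
  expect_equal(pumpingScore(s), frequency(s) * pctAmplitude(s))
  # pulse waveform: sharp nadirs are marginally resolved at 2.5 samples/s,
  # so allow the documented 2-point budget
  wp <- contractionParams(depth = 0.3, frequency = 6)
  g2 <- generateTraces(wp, "diameter", frameRate = 2.5, duration = 180)
  expect_lt(abs(pctAmplitude(summarizeTrace(g2$trace)) - 30), 2)
})

test_that("contraction frequency counts peaks per minute", {
  expect_equal(contractionFrequency(seq(1, 440, by = 25), 180), 6)
  expect_equal(contractionFrequency(integer(0), 60), 0)
  expect_equal(contractionFrequency(seq_len(13), 120), 6.5)
  expect_error(contractionFrequency(1:3, 0), "positive")
})

test_that("percent amplitude and pumping score follow the conventions", {
  cyc <- data.frame(pct_amplitude = c(30, 50, 40))
  expect_equal(percentAmplitude(cyc), 40)
  expect_true(is.na(percentAmplitude(cyc[0, , drop = FALSE])))
  expect_equal(pumpingScore(6.5, 40), 260)
  expect_equal(pumpingScore(10, 30), 300)
  expect_equal(pumpingScore(0, NA_real_), 0)        # quiescent vessel
  expect_true(is.na(pumpingScore(5, NA_real_)))     # undefined amplitude
})

test_that("tone change is the post/pre mean ratio in percent", {
  expect_equal(toneChange(rep(7, 30), rep(7, 30)), 100)
  expect_equal(toneChange(rep(1000, 20), rep(656, 20)), 65.6)
  expect_equal(toneChange(1:10, 2 * (1:10)), 200)
  expect_error(toneChange(rep(0, 10), rep(1, 10)), "positive")
})

test_that("Pearson correlation and deviation statistics match hand values", {
  a <- c(1, 2, 3, 4)
  expect_equal(pearsonCorrelation(a, 2 * a + 1), 1)
  expect_equal(pearsonCorrelation(a, -a), -1)
  expect_equal(pearsonCorrelation(a, c(1, 3, 2, 4)), 0.8)
  expect_error(pearsonCorrelation(a, rep(1, 4)), "variance")
  expect_error(pearsonCorrelation(a, 1:5), "equal length")
  d0 <- deviationStats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(d0), c(mad = 0, rmsd = 0))
  d1 <- deviationStats(c(1, 2, 3), c(2, 2, 5))
  expect_equal(d1$mad, 1)
  expect_equal(d1$rmsd, sqrt(5 / 3))
  expect_equal(unlist(deviationStats(10, 13)), c(mad = 3, rmsd = 3))
})

test_that("rmsd is never below mad", {
  set.seed(5)
  for (rep in 1:20) {
    a <- rnorm(sample(1:40, 1)); b <- rnorm(length(a))
    d <- deviationStats(a, b)
    expect_gte(d$rmsd, d$mad - 1e-12)
  }
})

test_that("a constant trace summarizes as quiescent", {
  s <- summarizeTrace(Trace(rep(42, 100), 2.5))
  expect_equal(frequency(s), 0)
  expect_true(is.na(pctAmplitude(s)))
  expect_equal(pumpingScore(s), 0)
  expect_equal(meanLevel(s), 42)
  expect_identical(nCycles(s), 0L)
})

test_that("disjoint windows of a stationary phantom agree", {
  w <- contractionParams(frequency = 6, depth = 0.3)
  g <- generateTraces(w, "diameter", noiseSigma = 0.03 * 27.6,
                      frameRate = 2.5, duration = 360, seed = 17)
  s1 <- summarizeTrace(g$trace, c(0, 180))
  s2 <- summarizeTrace(g$trace, c(180, 360))
  expect_lt(abs(frequency(s1) - frequency(s2)), 0.5)
  expect_lt(abs(pctAmplitude(s1) - pctAmplitude(s2)), 2)
  expect_lt(abs(meanLevel(s1) - meanLevel(s2)) / meanLevel(s1), 0.01)
})

test_that("ratio metrics are invariant to positive intensity scaling", {
  w <- contractionParams(frequency = 6.5, depth = 0.3)
  g <- generateTraces(w, "diameter", noiseSigma = 0.8, frameRate = 2.5,
                      duration = 180, seed = 3)
  s1 <- summarizeTrace(g$trace)
  for (k in c(0.2, 7)) {
    s2 <- summarizeTrace(Trace(k * traceValues(g$trace), 2.5))
    expect_equal(frequency(s2), frequency(s1))
    expect_equal(pctAmplitude(s2), pctAmplitude(s1), tolerance = 1e-9)
    expect_equal(pumpingScore(s2), pumpingScore(s1), tolerance = 1e-9)
  }
  x <- traceValues(g$trace)
  expect_equal(toneChange(3 * x, 3 * rev(x)), toneChange(x, rev(x)))
})

test_that("baseline normalization produces percent-of-baseline effects", {
  w <- contractionParams(frequency = 6)
  g <- generateTraces(w, "diameter", frameRate = 2.5, duration = 180)
  s <- summarizeTrace(g$trace)
  same <- normalizeToBaseline(s, s)
  expect_equal(unname(effectPercents(same)), rep(100, 4))
  # frequency doubling
  s2 <- s; s2@frequency <- 2 * s@frequency
  s2@pumpingScore <- s2@frequency * s2@pctAmplitude
  eff <- normalizeToBaseline(s, s2)
  expect_equal(effectPercents(eff)[["frequency"]], 200)
  # zero baseline flags NA but other ratios survive
  s0 <- s; s0@frequency <- 0; s0@pumpingScore <- 0
  eff0 <- normalizeToBaseline(s0, s)
  expect_true(is.na(effectPercents(eff0)[["frequency"]]))
  expect_false(is.na(effectPercents(eff0)[["tone"]]))
})

test_that("fluorescence amplitude doubles diameter amplitude for small depth", {
  ws <- contractionParams(depth = 0.1, frequency = 6, waveform = "sinusoid")
  gd <- generateTraces(ws, "diameter", frameRate = 2.5, duration = 180)
  gf <- generateTraces(ws, "fluorescence", frameRate = 2.5, duration = 180)
  ratio <- pctAmplitude(summarizeTrace(gf$trace)) /
    pctAmplitude(summarizeTrace(gd$trace))
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.1)
})

test_that("diameter and fluorescence traces correlate tightly at 5% noise", {
  w <- contractionParams(frequency = 6, depth = 0.3)
  gd <- generateTraces(w, "diameter", noiseSigma = 0.05 * 27.6,
                       frameRate = 2.5, duration = 180, seed = 21)
  gfClean <- generateTraces(w, "fluorescence", frameRate = 2.5, duration = 180)
  sigF <- 0.05 * gfClean$truth$excursion
  gf <- generateTraces(w, "fluorescence", noiseSigma = sigF,
                       frameRate = 2.5, duration = 180, seed = 22)
  expect_gt(pearsonCorrelation(gd$trace, gf$trace), 0.95)
})
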