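test_that("decomposition level selection follows the band-edge rule", {
  lv <- selectDecompositionLevels(360, fLow = 7, fHigh = 50)
  expect_equal(lv$i, 2)                  # approximation edge 45 Hz
  expect_equal(lv$j, 3)                  # edge 5.625 Hz
  expect_equal(lv$edgeHigh, 45)
  expect_equal(lv$edgeLow, 5.625)

  lv2 <- selectDecompositionLevels(720, fLow = 7, fHigh = 50)
  expect_equal(lv2$i, 3)
  expect_equal(lv2$j, 3)

  # band edges halve per level
  expect_equal(lv$edgeHigh / 2^lv$j, lv$edgeLow)

  expect_error(selectDecompositionLevels(360, fLow = 60, fHigh = 50),
               "fLow < fHigh")
})

test_that("wavelet approximation keeps DC, length and kills high tones", {
  const <- ECGSignal(rep(2.5, 512), 360)
  out <- waveletDenoiseHigh(const, 3)
  expect_equal(signalValues(out), rep(2.5, 512), tolerance = 1e-10)
  expect_equal(length(out), 512)

  t <- (0:3599) / 360
  tone <- ECGSignal(sin(2 * pi * 100 * t), 360)     # above 45 Hz edge at i=2
  att <- waveletDenoiseHigh(tone, 2)
  expect_lt(sum(signalValues(att)^2), 0.1 * sum(signalValues(tone)^2))

  # analysis/synthesis is a perfect-reconstruction pair
  set.seed(1)
  x <- rnorm(1000)
  dec <- iemmc:::dwtDecompose(x, 5, "db4")
  expect_equal(iemmc:::dwtReconstruct(dec, zeroDetails = FALSE), x,
               tolerance = 1e-10)

  expect_error(waveletDenoiseHigh(ECGSignal(1:3, 360), 1), "shorter")
})

test_that("low-frequency reference extraction isolates additive drift", {
  expect_equal(signalValues(extractLowReference(ECGSignal(rep(0, 512), 360), 3)),
               rep(0, 512), tolerance = 1e-12)

  fix <- genSyntheticECG(fs = 360, duration = 10, heartRate = 75, seed = 2)
  t <- signalTimes(fix$signal)
  drift <- 0.5 * sin(2 * pi * 0.3 * t)
  E1 <- waveletDenoiseHigh(addNoise(fix$signal,
                                    noiseSpec(bwAmp = 0.5, bwFreq = 0.3)), 2)
  E2 <- extractLowReference(E1, 6)
  expect_gt(cor(signalValues(E2), drift), 0.9)

  tone <- ECGSignal(sin(2 * pi * 30 * t), 360)      # far above the E2 band
  ref <- extractLowReference(tone, 6)
  expect_lt(sum(signalValues(ref)^2), 0.1 * sum(signalValues(tone)^2))
})

test_that("LMS cancels a shared interferer and respects its contracts", {
  fix <- genSyntheticECG(fs = 360, duration = 20, heartRate = 75, seed = 3)
  clean <- signalValues(fix$signal)
  t <- signalTimes(fix$signal)
  v <- 0.5 * sin(2 * pi * 0.3 * t)
  prim <- ECGSignal(clean + v, 360)

  # zero reference: weights never move, output equals primary
  z <- lmsFilter(prim, ECGSignal(rep(0, length(t)), 360))
  expect_equal(signalValues(z), clean + v, tolerance = 1e-12)

  # steady-state cancellation >= 20 dB on the tail half
  out <- lmsFilter(prim, ECGSignal(v, 360))
  half <- (length(t) %/% 2 + 1):length(t)
  before <- mean(v[half]^2)
  after <- mean((signalValues(out) - clean)[half]^2)
  expect_gte(10 * log10(before / after), 20)

  # grossly overlarge step diverges with an error naming mu
  expect_error(lmsFilter(prim, ECGSignal(v, 360), mu = 1e7), "mu")
})

test_that("the composed filter denoises and never hurts on noisy input", {
  for (s in 1:3) {
    fix <- genSyntheticECG(fs = 360, duration = 10, heartRate = 75,
                           rrJitter = 0.03, seed = s)
    clean <- signalValues(fix$signal)
    noisy <- addNoise(fix$signal,
                      noiseSpec(bwAmp = 0.9, bwFreq = 0.3, emgSd = 0.12,
                                seed = s + 100))
    filt <- preprocessECG(noisy)
    expect_gt(cor(signalValues(filt), clean), cor(signalValues(noisy), clean))
  }
})

test_that("the composed filter stays close to a clean input", {
  # the adaptive stage trades a little low-frequency fidelity for drift
  # removal, so the bound is below unity by design
  fix <- genSyntheticECG(fs = 360, duration = 10, heartRate = 75, seed = 4)
  filt <- preprocessECG(fix$signal)
  expect_gt(cor(signalValues(filt), signalValues(fix$signal)), 0.9)
  expect_equal(length(filt), length(fix$signal))

  # determinism
  filt2 <- preprocessECG(fix$signal)
  expect_identical(signalValues(filt), signalValues(filt2))
})
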