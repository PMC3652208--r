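test_that("beat scheduling is exact and seeded generation is deterministic", {
  fix <- genSyntheticECG(fs = 360, duration = 10, heartRate = 60, seed = 1)
  expect_equal(unique(diff(fix$truth$R)), 360)
  expect_equal(nrow(fix$truth), 10)

  fix2 <- genSyntheticECG(fs = 360, duration = 10, heartRate = 60, seed = 1)
  expect_identical(signalValues(fix$signal), signalValues(fix2$signal))
  expect_identical(fix$truth, fix2$truth)

  fix3 <- genSyntheticECG(fs = 360, duration = 10, classes = "N",
                          rrJitter = 0.05, seed = 3)
  fix4 <- genSyntheticECG(fs = 360, duration = 10, classes = "N",
                          rrJitter = 0.05, seed = 4)
  expect_false(identical(signalValues(fix3$signal), signalValues(fix4$signal)))
})

test_that("ground-truth landmarks are ordered P < Q < R < S < T on every beat", {
  for (s in 1:5) {
    fix <- genSyntheticECG(fs = 360, duration = 10,
                           classes = c("N", "S", "V", "F", "Q"),
                           rrJitter = 0.03, seed = s)
    with(fix$truth, {
      expect_true(all(P < Q & Q < R & R < S & S < T))
      expect_true(all(P >= 1 & T <= length(signalValues(fix$signal))))
    })
  }
})

test_that("class V has a wider generated QRS than class N and no P wave", {
  fixN <- genSyntheticECG(fs = 360, duration = 10, classes = "N", seed = 1)
  fixV <- genSyntheticECG(fs = 360, duration = 10, classes = "V", seed = 1)
  qrsN <- (fixN$truth$S - fixN$truth$Q) / 360
  qrsV <- (fixV$truth$S - fixV$truth$Q) / 360
  expect_true(min(qrsV) > max(qrsN))
  expect_true(all(fixN$truth$pPresent))
  expect_false(any(fixV$truth$pPresent))
})

test_that("too-short records are rejected", {
  expect_error(genSyntheticECG(fs = 360, duration = 1.5, heartRate = 60),
               "too short")
})

test_that("zero noise spec is the identity and components behave as specified", {
  fix <- genSyntheticECG(fs = 360, duration = 10, heartRate = 60, seed = 2)
  out <- addNoise(fix$signal, noiseSpec())
  expect_identical(signalValues(out), signalValues(fix$signal))

  # pure baseline wander: dominant DFT peak of the difference at 0.3 Hz
  bw <- addNoise(fix$signal, noiseSpec(bwAmp = 0.5, bwFreq = 0.3))
  d <- signalValues(bw) - signalValues(fix$signal)
  sp <- Mod(stats::fft(d))[2:1800]          # positive frequencies
  freqs <- (1:1799) / 10                     # Hz, 10 s record
  expect_equal(freqs[which.max(sp)], 0.3, tolerance = 1e-9)

  # broadband component: sample sd within 10 % of the requested sd
  em <- addNoise(fix$signal, noiseSpec(emgSd = 0.1, seed = 9))
  expect_equal(sd(signalValues(em) - signalValues(fix$signal)), 0.1,
               tolerance = 0.1)

  # deterministic (sinusoidal) components compose additively, exactly
  a <- noiseSpec(bwAmp = 0.4, bwFreq = 0.5)
  b <- noiseSpec(plAmp = 0.05, plFreq = 50)
  both <- addNoise(addNoise(fix$signal, a), b)
  ab <- signalValues(addNoise(fix$signal, noiseSpec(
    bwAmp = 0.4, bwFreq = 0.5, plAmp = 0.05, plFreq = 50)))
  expect_identical(signalValues(both), ab)
})

test_that("baseline wander frequency above 7 Hz is rejected", {
  expect_error(noiseSpec(bwAmp = 0.1, bwFreq = 8), "below 7")
})

test_that("cluster generator enforces balance, separation and determinism", {
  gd <- genClusterData(60, 2, separation = 6, dims = 2, seed = 1)
  expect_equal(sum(ifelse(gd$labels == 1, 1, -1)), 0)
  gd2 <- genClusterData(60, 2, separation = 6, dims = 2, seed = 1)
  expect_identical(gd$X, gd2$X)

  expect_error(genClusterData(61, 2, sizes = c(50, 11), balance = 0),
               "infeasible balance")

  # law of large numbers: sample means near true centroids
  gd3 <- genClusterData(200, 2, separation = 6, dims = 2, seed = 5)
  ctr <- 6 / sqrt(2)
  m1 <- colMeans(gd3$X[gd3$labels == 1, ])
  m2 <- colMeans(gd3$X[gd3$labels == 2, ])
  expect_lt(sqrt(sum((m1 - c(ctr, 0))^2)), 0.5)
  expect_lt(sqrt(sum((m2 - c(0, ctr))^2)), 0.5)
  # centroid distance equals separation (in within-sd units) by construction
  expect_equal(sqrt(sum((c(ctr, 0) - c(0, ctr))^2)), 6)
})

test_that("ECG fixtures round-trip through CSV + JSON sidecar", {
  fix <- genSyntheticECG(fs = 250, duration = 6, heartRate = 80, seed = 11)
  path <- file.path(tempdir(), "fix.csv")
  writeECGFixture(fix$signal, path, truth = fix$truth)
  back <- readECGFixture(path)
  expect_equal(signalValues(back$signal), signalValues(fix$signal),
               tolerance = 1e-12)
  expect_equal(samplingRate(back$signal), 250)
  expect_equal(as.data.frame(back$truth)$R, fix$truth$R)
})

test_that("ECGSignal validity catches bad inputs", {
  expect_error(ECGSignal(numeric(0), 360), "at least one sample")
  expect_error(ECGSignal(c(1, NA), 360), "finite")
  expect_error(ECGSignal(1:10, -1), "positive")
})
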