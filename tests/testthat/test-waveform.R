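msTol <- function(fs, ms) round(ms / 1000 * fs)

test_that("R peaks on a clean fixture are found within 25 ms", {
  fix <- genSyntheticECG(fs = 360, duration = 10, heartRate = 60, seed = 1)
  r <- detectRPeaks(fix$signal)
  expect_length(r, nrow(fix$truth))
  expect_true(all(abs(r - fix$truth$R) <= msTol(360, 25)))
  expect_true(all(diff(r) > 0))
})

test_that("refractory period prevents double detection on tall T waves", {
  pars <- beatClassParams()
  pars$N$waves$amp[pars$N$waves$wave == "T"] <- 0.9 * 1.5
  fix <- genSyntheticECG(fs = 360, duration = 10, heartRate = 70,
                         params = pars, seed = 2)
  r <- detectRPeaks(fix$signal)
  expect_length(r, nrow(fix$truth))
  expect_true(all(abs(r - fix$truth$R) <= msTol(360, 25)))
  refr <- round(0.2 * 360)
  expect_true(all(diff(r) > refr))
})

test_that("search-back recovers a low-amplitude beat", {
  scale <- rep(1, 11); scale[5] <- 0.3
  fix <- genSyntheticECG(fs = 360, duration = 10, heartRate = 70, seed = 3,
                         beatAmpScale = scale)
  r <- detectRPeaks(fix$signal)
  expect_length(r, nrow(fix$truth))
  expect_true(all(vapply(fix$truth$R,
                         function(tR) any(abs(r - tR) <= msTol(360, 25)),
                         logical(1))))
})

test_that("a flat signal yields an empty result with a warning", {
  flat <- ECGSignal(rep(0, 720), 360)
  expect_warning(r <- detectRPeaks(flat), "no")
  expect_length(r, 0)
})

test_that("Q and S land within 10 ms of truth and keep Q < R < S", {
  fix <- genSyntheticECG(fs = 360, duration = 10, heartRate = 60, seed = 1)
  r <- detectRPeaks(fix$signal)
  qs <- detectQS(fix$signal, r)
  expect_true(all(qs$valid))
  expect_true(all(qs$Q < qs$R & qs$R < qs$S))
  expect_true(all(abs(qs$Q - fix$truth$Q) <= msTol(360, 10)))
  expect_true(all(abs(qs$S - fix$truth$S) <= msTol(360, 10)))
})

test_that("a window truncated by the record edge is flagged, not fatal", {
  fix <- genSyntheticECG(fs = 360, duration = 10, heartRate = 60, seed = 1)
  qs <- detectQS(fix$signal, c(5L, fix$truth$R))
  expect_false(qs$valid[1])
  expect_true(all(qs$valid[-1]))
})

test_that("P and T land within 20 ms of truth with correct ordering", {
  fix <- genSyntheticECG(fs = 360, duration = 10, heartRate = 60, seed = 1)
  ann <- detectPT(fix$signal, detectQS(fix$signal, detectRPeaks(fix$signal)))
  ok <- ann$valid
  expect_true(all(abs(ann$P[ok] - fix$truth$P[ok]) <= msTol(360, 20)))
  expect_true(all(abs(ann$T[ok] - fix$truth$T[ok]) <= msTol(360, 20)))
  expect_true(all(ann$P[ok] < ann$Q[ok] & ann$S[ok] < ann$T[ok]))
  # last beat's T uses the fallback window and is flagged
  expect_true(ann$tFallback[nrow(ann)])
})

test_that("absent-P morphology is flagged low-confidence", {
  fix <- genSyntheticECG(fs = 360, duration = 10, classes = "V", seed = 5)
  ann <- detectPT(fix$signal, detectQS(fix$signal, detectRPeaks(fix$signal)))
  expect_true(mean(ann$pLowConf[ann$valid]) > 0.5)
})

test_that("annotateBeats drops boundary beats and orders annotations", {
  fix <- genSyntheticECG(fs = 360, duration = 10, heartRate = 60, seed = 1)
  ann <- annotateBeats(fix$signal)
  expect_equal(nrow(ann$annotations), nrow(fix$truth) - 2)
  expect_true(!is.unsorted(ann$annotations$R, strictly = TRUE))
  with(ann$annotations,
       expect_true(all(P < Q & Q < R & R < S & S < T)))

  ann2 <- annotateBeats(fix$signal)
  expect_identical(ann$annotations, ann2$annotations)

  short <- ECGSignal(signalValues(fix$signal)[1:800], 360)
  expect_error(suppressWarnings(annotateBeats(short)), "fewer than 3")
})

test_that("R detection matches truth across seeded fixtures", {
  tot <- 0; hit <- 0
  for (s in 1:10) {
    fix <- genSyntheticECG(fs = 360, duration = 10,
                           classes = c("N", "V", "S"),
                           rrJitter = 0.04, seed = s)
    r <- detectRPeaks(fix$signal)
    tot <- tot + nrow(fix$truth)
    hit <- hit + sum(vapply(fix$truth$R,
                            function(tR) any(abs(r - tR) <= msTol(360, 25)),
                            logical(1)))
  }
  expect_gte(hit / tot, 0.99)
})
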