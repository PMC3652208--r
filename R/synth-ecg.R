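#' Per-class beat morphology parameters
#'
#' Morphology templates for the five AAMI beat groups (N, S, V, F, Q), used
#' by [genSyntheticECG()]. Each beat is synthesized as a sum of five Gaussian
#' bumps (P, Q, R, S, T), parameterized by amplitude (mV), center offset
#' relative to the R peak (s) and width (Gaussian sd, s), plus a mean RR
#' interval (s). Class differences follow the usual electrophysiology:
#' S shortens the preceding RR with a smaller P wave; V widens the QRS and
#' suppresses the P wave; F has an intermediate QRS width; Q has aberrant
#' (paced/unclassifiable) amplitudes.
#'
#' @return Named list, one entry per class, each with elements \code{rrMean}
#'   (s) and \code{waves} (data.frame with columns wave, amp, offset, width).
#' @export
beatClassParams <- function() {
  wv <- function(p, q, r, s, t) {
    data.frame(wave = c("P", "Q", "R", "S", "T"),
               amp    = c(p[1], q[1], r[1], s[1], t[1]),
               offset = c(p[2], q[2], r[2], s[2], t[2]),
               width  = c(p[3], q[3], r[3], s[3], t[3]))
  }
  list(
    N = list(rrMean = 0.80, waves = wv(c(0.15, -0.17, 0.022),
                                       c(-0.12, -0.035, 0.009),
                                       c(1.50, 0.000, 0.013),
                                       c(-0.20, 0.035, 0.009),
                                       c(0.50, 0.300, 0.055))),
    S = list(rrMean = 0.55, waves = wv(c(0.08, -0.15, 0.020),
                                       c(-0.12, -0.035, 0.009),
                                       c(1.40, 0.000, 0.013),
                                       c(-0.20, 0.035, 0.009),
                                       c(0.45, 0.280, 0.050))),
    V = list(rrMean = 0.70, waves = wv(c(0.00, -0.17, 0.022),
                                       c(-0.25, -0.070, 0.018),
                                       c(1.20, 0.000, 0.030),
                                       c(-0.35, 0.070, 0.018),
                                       c(0.65, 0.330, 0.060))),
    F = list(rrMean = 0.75, waves = wv(c(0.12, -0.16, 0.020),
                                       c(-0.15, -0.050, 0.012),
                                       c(1.30, 0.000, 0.020),
                                       c(-0.25, 0.050, 0.012),
                                       c(0.55, 0.310, 0.055))),
    Q = list(rrMean = 0.85, waves = wv(c(0.05, -0.17, 0.022),
                                       c(-0.06, -0.035, 0.009),
                                       c(0.60, 0.000, 0.013),
                                       c(-0.10, 0.035, 0.009),
                                       c(0.15, 0.300, 0.055)))
  )
}

#' Generate a synthetic multi-beat ECG with exact ground truth
#'
#' Builds an ECG trace as a sum of per-beat Gaussian bumps (P, Q, R, S, T)
#' at scheduled beat times, and returns the exact landmark sample indices
#' and class label of every beat. Deterministic for a fixed seed.
#'
#' @param fs sampling frequency in Hz (>= 100).
#' @param duration record length in seconds; must cover at least 3 beats.
#' @param classes character vector of AAMI class codes (N, S, V, F, Q),
#'   recycled over beats.
#' @param heartRate optional heart rate in bpm; if given it overrides the
#'   per-class mean RR for every beat.
#' @param rrJitter standard deviation (s) of Gaussian RR-interval jitter.
#' @param beatAmpScale optional numeric vector of per-beat amplitude scale
#'   factors (recycled); used e.g. to plant a low-amplitude beat.
#' @param params morphology parameter list, see [beatClassParams()].
#' @param seed integer seed; identical arguments give bit-identical output.
#' @return list with elements \code{signal} (an [ECGSignal-class]) and
#'   \code{truth}, a data.frame with one row per beat: \code{beat},
#'   \code{class}, 1-based sample indices \code{P}, \code{Q}, \code{R},
#'   \code{S}, \code{T}, and \code{pPresent} (FALSE where the class
#'   suppresses the P wave).
#' @examples
#' fix <- genSyntheticECG(fs = 360, duration = 10, heartRate = 60, seed = 1)
#' diff(fix$truth$R)   # exactly 360 samples at 60 bpm, zero jitter
#' @export
genSyntheticECG <- function(fs = 360, duration = 10, classes = "N",
                            heartRate = NULL, rrJitter = 0,
                            beatAmpScale = NULL,
                            params = beatClassParams(), seed = 1) {
  stopIfNot(fs >= 100, "fs must be at least 100 Hz")
  stopIfNot(all(classes %in% names(params)),
            "classes must be AAMI codes among N, S, V, F, Q")
  # schedule beats: leading/trailing margins leave room for P and T waves
  margin <- 0.45
  rrOf <- function(cls) if (is.null(heartRate)) params[[cls]]$rrMean else 60 / heartRate
  tR <- margin
  beatT <- numeric(0); beatC <- character(0)
  k <- 1L
  jit <- withSubSeed(seed, "rr", stats::rnorm(10000, 0, rrJitter))
  while (tR <= duration - margin) {
    cls <- classes[((k - 1L) %% length(classes)) + 1L]
    beatT <- c(beatT, tR); beatC <- c(beatC, cls)
    tR <- tR + max(0.3, rrOf(classes[(k %% length(classes)) + 1L]) +
                     if (rrJitter > 0) jit[k] else 0)
    k <- k + 1L
  }
  if (length(beatT) < 3L)
    stop("duration too short: fewer than 3 complete beats fit in ",
         duration, " s", call. = FALSE)
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  scl <- if (is.null(beatAmpScale)) rep(1, length(beatT)) else
    rep_len(beatAmpScale, length(beatT))
  truth <- data.frame(beat = seq_along(beatT), class = beatC,
                      P = NA_integer_, Q = NA_integer_, R = NA_integer_,
                      S = NA_integer_, T = NA_integer_,
                      pPresent = TRUE, stringsAsFactors = FALSE)
  for (b in seq_along(beatT)) {
    w <- params[[beatC[b]]]$waves
    for (r in seq_len(nrow(w))) {
      if (w$amp[r] == 0) next
      ctr <- beatT[b] + w$offset[r]
      lo <- max(1L, floor((ctr - 5 * w$width[r]) * fs) + 1L)
      hi <- min(n, ceiling((ctr + 5 * w$width[r]) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] +
        scl[b] * w$amp[r] * exp(-0.5 * ((t[idx] - ctr) / w$width[r])^2)
    }
    li <- function(off) as.integer(round((beatT[b] + off) * fs)) + 1L
    truth$P[b] <- li(w$offset[w$wave == "P"])
    truth$Q[b] <- li(w$offset[w$wave == "Q"])
    truth$R[b] <- li(0)
    truth$S[b] <- li(w$offset[w$wave == "S"])
    truth$T[b] <- li(w$offset[w$wave == "T"])
    truth$pPresent[b] <- w$amp[w$wave == "P"] != 0
  }
  list(signal = ECGSignal(x, fs), truth = truth)
}

#' Noise specification for synthetic ECG contamination
#'
#' Describes the three contaminants the filtering stage targets: baseline
#' wander (a sub-7 Hz sinusoid, emulating respiration/motion artifact),
#' powerline interference, and broadband EMG-like white noise.
#'
#' @param bwAmp,bwFreq,bwPhase baseline-wander amplitude (mV), frequency
#'   (Hz, must be < 7) and phase (rad).
#' @param plAmp,plFreq,plPhase powerline amplitude (mV), frequency (Hz),
#'   phase (rad).
#' @param emgSd standard deviation (mV) of broadband Gaussian noise.
#' @param seed seed for the broadband component.
#' @return A validated list of class \code{"NoiseSpec"}.
#' @export
noiseSpec <- function(bwAmp = 0, bwFreq = 0.3, bwPhase = 0,
                      plAmp = 0, plFreq = 50, plPhase = 0,
                      emgSd = 0, seed = 1) {
  stopIfNot(bwAmp >= 0 && plAmp >= 0 && emgSd >= 0,
            "noise amplitudes must be non-negative")
  stopIfNot(bwFreq < 7, "baseline-wander frequency must be below 7 Hz")
  structure(list(bwAmp = bwAmp, bwFreq = bwFreq, bwPhase = bwPhase,
                 plAmp = plAmp, plFreq = plFreq, plPhase = plPhase,
                 emgSd = emgSd, seed = seed), class = "NoiseSpec")
}

#' Add synthetic noise to an ECG signal
#'
#' Adds, sample-wise, a baseline-wander sinusoid, a powerline sinusoid and
#' white broadband noise as described by a [noiseSpec()]. Length and
#' sampling frequency are unchanged; a zero spec returns the input exactly.
#'
#' @param signal an [ECGSignal-class].
#' @param spec a [noiseSpec()].
#' @return A new [ECGSignal-class].
#' @export
addNoise <- function(signal, spec) {
  stopIfNot(inherits(spec, "NoiseSpec"), "spec must come from noiseSpec()")
  t <- signalTimes(signal)
  x <- signalValues(signal)
  if (spec$bwAmp > 0)
    x <- x + spec$bwAmp * sin(2 * pi * spec$bwFreq * t + spec$bwPhase)
  if (spec$plAmp > 0)
    x <- x + spec$plAmp * sin(2 * pi * spec$plFreq * t + spec$plPhase)
  if (spec$emgSd > 0)
    x <- x + withSubSeed(spec$seed, "emg",
                         stats::rnorm(length(x), 0, spec$emgSd))
  ECGSignal(x, samplingRate(signal), signal@t0)
}

#' Generate labeled Gaussian feature clusters
#'
#' Seeded Gaussian blobs for clustering tests: \code{k} unit-sd clusters
#' whose centroids are pairwise \code{separation} (in within-cluster sd
#' units) apart, with near-equal sizes unless \code{sizes} is given.
#'
#' @param n total number of points.
#' @param k number of clusters (>= 2); requires \code{dims >= k} so that
#'   centroids can sit on a regular simplex with equal pairwise distances.
#' @param separation centroid pairwise distance in within-cluster sd units.
#' @param dims feature dimension.
#' @param balance for k = 2, the class-balance bound: the absolute label
#'   sum |n1 - n2| of the construction must not exceed it.
#' @param sizes optional integer vector of cluster sizes (sums to n).
#' @param seed integer seed.
#' @return list with \code{X} (n x dims matrix) and \code{labels}
#'   (integers 1..k).
#' @export
genClusterData <- function(n, k = 2, separation = 6, dims = 2,
                           balance = 0, sizes = NULL, seed = 1) {
  stopIfNot(n >= k && k >= 2, "need n >= k >= 2")
  stopIfNot(dims >= k, "need dims >= k for equidistant centroids")
  if (is.null(sizes)) {
    sizes <- rep(n %/% k, k)
    if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  }
  stopIfNot(sum(sizes) == n && all(sizes >= 1), "sizes must sum to n")
  if (k == 2 && abs(sizes[1] - sizes[2]) > max(balance, n %% 2))
    stop("infeasible balance: |n1 - n2| = ", abs(sizes[1] - sizes[2]),
         " exceeds bound ", balance, call. = FALSE)
  # regular simplex: unit vectors e_1..e_k have pairwise distance sqrt(2)
  centers <- matrix(0, k, dims)
  for (i in seq_len(k)) centers[i, i] <- separation / sqrt(2)
  labels <- rep(seq_len(k), times = sizes)
  X <- withSubSeed(seed, "blobs", {
    noise <- matrix(stats::rnorm(n * dims), n, dims)
    centers[labels, , drop = FALSE] + noise
  })
  list(X = X, labels = labels)
}

#' Write / read an ECG fixture as plain text
#'
#' The CSV holds two columns (\code{sample_index}, 1-based, and \code{mV});
#' a JSON sidecar of the same basename stores \code{fs}, \code{t0} and,
#' when given, the ground-truth landmark table.
#'
#' @param signal an [ECGSignal-class].
#' @param path path of the CSV file to write (sidecar gets extension .json).
#' @param truth optional ground-truth data.frame as from [genSyntheticECG()].
#' @return \code{path}, invisibly.
#' @export
writeECGFixture <- function(signal, path, truth = NULL) {
  utils::write.csv(data.frame(sample_index = seq_along(signalValues(signal)),
                              mV = signalValues(signal)),
                   path, row.names = FALSE)
  side <- list(fs = samplingRate(signal), t0 = signal@t0)
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeECGFixture
#' @return \code{readECGFixture}: list with \code{signal} and \code{truth}
#'   (NULL when the sidecar has none).
#' @export
readECGFixture <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  list(signal = ECGSignal(df$mV, side$fs, if (is.null(side$t0)) 0 else side$t0),
       truth = side$truth)
}
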