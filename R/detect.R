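#' Waveform detector configuration
#'
#' Tunables of the rule-based R/Q/S/P/T delineators. The 200 ms refractory
#' period, the 0.1 s QS window and the 0.16 s P window are physiological
#' constants; the remaining knobs operationalize rules the morphology does
#' not pin down exactly.
#'
#' @param thresholdFactor fraction of the running mean of recent accepted
#'   slope-peak heights used as the R candidate lower limit (0 < f < 1).
#' @param refractory period (s) after an accepted R during which new
#'   detections are suppressed (the big-T guard), default 0.200.
#' @param searchBackFactor RR intervals longer than this multiple of the
#'   median RR trigger a re-scan at half threshold (escaped-beat search).
#' @param qsWindow Q and S must lie within this window (s) around R.
#' @param pWindow P is the voltage maximum within this window (s) before Q.
#' @param tFallback T-wave search window (s) after S for the final beat,
#'   which has no following P.
#' @param pMinAmp P amplitude (mV above the window median) below which the
#'   P detection is flagged low-confidence (absent-P morphologies).
#' @param historyLen number of recent accepted peaks in the running mean.
#' @param smoothWindow moving-average width (s) applied to the rectified
#'   difference before thresholding; averages out broadband noise spikes
#'   (which would otherwise drag the adaptive threshold down) while the
#'   sustained QRS upstroke survives. Default 0.02 s.
#' @return A validated list of class \code{"DetectorConfig"}.
#' @export
detectorConfig <- function(thresholdFactor = 0.4, refractory = 0.2,
                           searchBackFactor = 1.66, qsWindow = 0.1,
                           pWindow = 0.16, tFallback = 0.4,
                           pMinAmp = 0.05, historyLen = 8,
                           smoothWindow = 0.02) {
  stopIfNot(thresholdFactor > 0 && thresholdFactor < 1,
            "thresholdFactor must be in (0, 1)")
  stopIfNot(refractory > 0, "refractory must be positive")
  stopIfNot(qsWindow > 0 && pWindow > 0 && tFallback > 0,
            "search windows must be positive")
  structure(list(thresholdFactor = thresholdFactor, refractory = refractory,
                 searchBackFactor = searchBackFactor, qsWindow = qsWindow,
                 pWindow = pWindow, tFallback = tFallback,
                 pMinAmp = pMinAmp, historyLen = historyLen,
                 smoothWindow = smoothWindow),
            class = "DetectorConfig")
}

# local maxima indices of v (strict on the left, non-strict right)
.localMaxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

# climb from index k to the nearest local maximum of x within +-w samples
.refineToPeak <- function(x, k, w) {
  lo <- max(1L, k - w); hi <- min(length(x), k + w)
  lo + which.max(x[lo:hi]) - 1L
}

#' Detect R peaks
#'
#' R waves carry the steepest slope in the ECG, so candidates are local
#' maxima of the rectified first difference above an adaptive lower limit
#' (a fraction of the running mean of recently accepted slope peaks).
#' Detections within the refractory period of the previous one are
#' suppressed, and suspiciously long RR intervals (escaped beats) are
#' re-scanned at half threshold. Returned indices are local maxima of the
#' raw signal, strictly increasing.
#'
#' @param signal an [ECGSignal-class] of at least 2 s.
#' @param cfg a [detectorConfig()].
#' @return Integer vector of R sample indices (possibly empty, with a
#'   warning, when nothing rises above the threshold).
#' @export
detectRPeaks <- function(signal, cfg = detectorConfig()) {
  x <- signalValues(signal); fs <- samplingRate(signal)
  stopIfNot(length(x) >= 2 * fs, "signal must be at least 2 s long")
  d <- c(0, abs(diff(x)))
  sw <- max(1L, as.integer(round(cfg$smoothWindow * fs)))
  if (sw > 1)
    d <- as.numeric(stats::filter(d, rep(1 / sw, sw), sides = 2)) |>
      (\(v) { v[is.na(v)] <- 0; v })()
  refr <- as.integer(round(cfg$refractory * fs))
  peakWin <- as.integer(round(0.09 * fs))
  cand <- .localMaxima(d)
  init <- max(d[seq_len(min(length(d), as.integer(2 * fs)))])
  if (init <= 0) { warning("no slope activity above threshold"); return(integer(0)) }
  hist <- init
  accept <- integer(0); acceptH <- numeric(0)
  lastI <- -refr
  for (k in cand) {
    thr <- cfg$thresholdFactor * mean(hist)
    if (d[k] <= thr) next
    if (k - lastI <= refr) next
    r <- .refineToPeak(x, k, peakWin)
    if (length(accept) && r - accept[length(accept)] <= refr) next
    accept <- c(accept, r); acceptH <- c(acceptH, d[k])
    hist <- utils::tail(c(hist, d[k]), cfg$historyLen)
    lastI <- k
  }
  if (!length(accept)) { warning("no R peaks above adaptive threshold"); return(integer(0)) }
  # search-back over long RR gaps at half the adaptive limit
  for (pass in 1:3) {
    if (length(accept) < 3) break
    rr <- diff(accept)
    medRR <- stats::median(rr)
    thr2 <- 0.5 * cfg$thresholdFactor * mean(utils::tail(acceptH, cfg$historyLen))
    added <- FALSE
    for (g in which(rr > cfg$searchBackFactor * medRR)) {
      lo <- accept[g] + refr; hi <- accept[g + 1] - refr
      if (hi - lo < 3) next
      seg <- lo:hi
      segCand <- seg[.localMaxima(d[seg])]
      segCand <- segCand[d[segCand] > thr2]
      if (!length(segCand)) next
      best <- segCand[which.max(d[segCand])]
      r <- .refineToPeak(x, best, peakWin)
      if (min(abs(r - accept)) > refr) {
        accept <- sort(c(accept, r)); acceptH <- c(acceptH, d[best])
        added <- TRUE
      }
    }
    if (!added) break
  }
  as.integer(accept)
}

#' Detect Q and S around each R
#'
#' Q is the turning point between the baseline and the falling edge into
#' the R upstroke, operationalized as the first local minimum (or slope
#' flattening below 10 percent of the QR slope magnitude) scanning outward
#' from R within the QS window; S symmetrically to the right.
#'
#' @param signal an [ECGSignal-class].
#' @param rPeaks integer R indices from [detectRPeaks()].
#' @param cfg a [detectorConfig()].
#' @return data.frame with columns \code{R}, \code{Q}, \code{S},
#'   \code{valid} (FALSE where the window is truncated by a record edge).
#' @export
detectQS <- function(signal, rPeaks, cfg = detectorConfig()) {
  x <- signalValues(signal); fs <- samplingRate(signal)
  w <- as.integer(round(cfg$qsWindow * fs))
  scanOut <- function(r, dir) {
    lim <- r + dir * w
    if (lim < 1 || lim > length(x)) return(NA_integer_)
    qrSlope <- max(abs(diff(x[sort(c(r, lim))[1]:sort(c(r, lim))[2]])))
    k <- r + dir
    while ((dir < 0 && k > lim) || (dir > 0 && k < lim)) {
      nxt <- k + dir
      if (x[nxt] >= x[k]) return(k)                    # local minimum
      if (abs(x[nxt] - x[k]) < 0.1 * qrSlope && x[k] < x[r]) return(k)
      k <- nxt
    }
    idx <- sort(c(r + dir, lim))
    idx[1] + which.min(x[idx[1]:idx[2]]) - 1L          # fallback: window argmin
  }
  out <- data.frame(R = as.integer(rPeaks), Q = NA_integer_,
                    S = NA_integer_, valid = TRUE)
  for (b in seq_along(rPeaks)) {
    q <- scanOut(rPeaks[b], -1L); s <- scanOut(rPeaks[b], +1L)
    if (is.na(q) || is.na(s)) { out$valid[b] <- FALSE; next }
    out$Q[b] <- q; out$S[b] <- s
  }
  out
}

#' Detect P and T for each beat
#'
#' P is the voltage maximum within the P window before Q; T is the voltage
#' maximum between S and the next beat's P. The final beat, which has no
#' following P, searches a fixed fallback window after S and is flagged.
#' Beats whose P amplitude over the window median falls below
#' \code{cfg$pMinAmp} are flagged low-confidence (absent-P morphologies
#' still return the argmax).
#'
#' @param signal an [ECGSignal-class].
#' @param qs data.frame from [detectQS()].
#' @param cfg a [detectorConfig()].
#' @return \code{qs} extended with columns \code{P}, \code{T},
#'   \code{pLowConf}, \code{tFallback}.
#' @export
detectPT <- function(signal, qs, cfg = detectorConfig()) {
  x <- signalValues(signal); fs <- samplingRate(signal)
  pw <- as.integer(round(cfg$pWindow * fs))
  tw <- as.integer(round(cfg$tFallback * fs))
  nb <- nrow(qs)
  qs$P <- NA_integer_; qs$T <- NA_integer_
  qs$pLowConf <- FALSE; qs$tFallback <- FALSE
  for (b in seq_len(nb)) {
    if (!qs$valid[b]) next
    lo <- qs$Q[b] - pw; hi <- qs$Q[b] - 1L
    if (lo < 1) { qs$valid[b] <- FALSE; next }
    win <- x[lo:hi]
    qs$P[b] <- lo + which.max(win) - 1L
    if (x[qs$P[b]] - stats::median(win) < cfg$pMinAmp) qs$pLowConf[b] <- TRUE
  }
  for (b in seq_len(nb)) {
    if (!qs$valid[b]) next
    lo <- qs$S[b] + 1L
    hi <- if (b < nb && qs$valid[b + 1] && !is.na(qs$P[b + 1])) {
      qs$P[b + 1] - 1L
    } else {
      qs$tFallback[b] <- TRUE
      min(length(x), qs$S[b] + tw)
    }
    if (hi <= lo) { qs$valid[b] <- FALSE; next }
    qs$T[b] <- lo + which.max(x[lo:hi]) - 1L
  }
  qs
}

#' Full rule-based beat delineation
#'
#' Runs R detection, Q/S morphology search and P/T window search, then
#' retains beats that are fully delineated and have both a preceding and a
#' following R (required for the two-period features).
#'
#' @param signal a preprocessed [ECGSignal-class].
#' @param cfg a [detectorConfig()].
#' @return list with \code{annotations} (data.frame: beat, P, Q, R, S, T,
#'   pLowConf, tFallback) and \code{rPeaks} (all detected R indices).
#' @export
annotateBeats <- function(signal, cfg = detectorConfig()) {
  r <- detectRPeaks(signal, cfg)
  if (length(r) < 3)
    stop("fewer than 3 R peaks detected; two succeeding periods are needed",
         call. = FALSE)
  ann <- detectPT(signal, detectQS(signal, r, cfg), cfg)
  keep <- which(ann$valid & !is.na(ann$P) & !is.na(ann$T))
  keep <- keep[keep > 1 & keep < nrow(ann)]   # need both neighbors
  out <- ann[keep, c("P", "Q", "R", "S", "T", "pLowConf", "tFallback")]
  out <- cbind(beat = keep, out,
               RRprev = (ann$R[keep] - ann$R[keep - 1]) / samplingRate(signal),
               RRnext = (ann$R[keep + 1] - ann$R[keep]) / samplingRate(signal))
  rownames(out) <- NULL
  list(annotations = out, rPeaks = r)
}
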