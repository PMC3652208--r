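#' LMS adaptive noise cancellation
#'
#' Classic adaptive noise canceller: at each sample the filter predicts the
#' primary input from the last \code{order} reference samples and outputs
#' the prediction error \code{e[n] = primary[n] - w'r[n]}; the weights
#' adapt by the power-normalized LMS rule \code{w <- w + mu_eff e[n] r[n]}
#' with \code{mu_eff = mu / (eps + M Pbar[n])}, where \code{Pbar} is a
#' leaky-average estimate of the reference power. Components of the primary
#' correlated with the reference (the shared baseline drift) are cancelled.
#'
#' Normalizing by the smoothed rather than the instantaneous tap power
#' avoids step blow-ups near zero crossings of narrowband references and
#' keeps the update stable for \code{0 < mu < 2} regardless of reference
#' scale; grossly larger steps diverge and raise an error. The step size
#' trades convergence speed against weight jitter driven by the ECG itself:
#' the default converges within a few seconds at common ECG sampling rates
#' while keeping the steady-state residual of a coherent interferer more
#' than 20 dB down.
#'
#' @param primary an [ECGSignal-class]: signal plus correlated interference.
#' @param reference an [ECGSignal-class] of equal length: the interference
#'   estimate.
#' @param mu adaptation step (normalized), default 0.001.
#' @param order number of filter taps M, default 8.
#' @return An [ECGSignal-class] with the cancelled output.
#' @export
lmsFilter <- function(primary, reference, mu = 0.001, order = 8) {
  p <- signalValues(primary); r <- signalValues(reference)
  stopIfNot(length(p) == length(r), "primary and reference lengths differ")
  stopIfNot(mu > 0, "mu must be positive")
  stopIfNot(order >= 1, "filter order must be >= 1")
  n <- length(p); M <- as.integer(order)
  w <- numeric(M)
  e <- numeric(n)
  rbuf <- numeric(M)
  eps <- 1e-8
  pbar <- mean(r^2)
  for (i in seq_len(n)) {
    rbuf <- c(r[i], rbuf[-M])
    pbar <- 0.99 * pbar + 0.01 * r[i]^2
    ei <- p[i] - sum(w * rbuf)
    if (!is.finite(ei) || abs(ei) > 1e12)
      stop("LMS diverged at sample ", i, " (mu = ", mu,
           " exceeds the stability bound)", call. = FALSE)
    w <- w + (mu / (eps + M * pbar)) * ei * rbuf
    e[i] <- ei
  }
  ECGSignal(e, samplingRate(primary), primary@t0)
}

#' Configuration of the wavelet-transform adaptive filter
#'
#' @param wavelet wavelet family (db2/db4/db6), default db4.
#' @param i,j decomposition depths; NULL (default) selects them from
#'   \code{fs}, \code{fLow} and \code{fHigh} via
#'   [selectDecompositionLevels()].
#' @param mu,order LMS step size and tap count, see [lmsFilter()].
#' @param fLow target upper edge (Hz) of the reference (baseline-wander)
#'   band. Default 0.8 Hz, close to the standard 0.67 Hz monitoring
#'   highpass cutoff: deep enough that the reference holds drift rather
#'   than P/T/QRS energy (wavelet approximations leak transient energy
#'   well above their nominal band edge, so the 7 Hz noise-band bound
#'   itself is far too shallow a reference cut).
#' @param fHigh upper edge (Hz) of the band that must retain QRS energy,
#'   default 50.
#' @return A validated list of class \code{"FilterConfig"}.
#' @export
filterConfig <- function(wavelet = "db4", i = NULL, j = NULL,
                         mu = 0.001, order = 8, fLow = 0.8, fHigh = 50) {
  stopIfNot(mu > 0, "mu must be positive")
  stopIfNot(order >= 1, "order must be >= 1")
  stopIfNot(is.null(i) || i >= 1, "i must be >= 1")
  stopIfNot(is.null(j) || j >= 1, "j must be >= 1")
  structure(list(wavelet = wavelet, i = i, j = j, mu = mu, order = order,
                 fLow = fLow, fHigh = fHigh), class = "FilterConfig")
}

#' The four-step wavelet-transform adaptive ECG filter
#'
#' Composition of the full preprocessing chain:
#' \enumerate{
#'   \item choose the least depth \code{i} separating the ECG band from
#'     high-frequency noise (from \code{fs} and \code{fHigh});
#'   \item depth-i approximation E1 = the ECG without high-frequency noise,
#'     the primary input of the adaptive filter;
#'   \item depth-j approximation of E1 = E2, the baseline-drift /
#'     motion-artifact estimate, the reference input;
#'   \item LMS adaptive cancellation of E2 from E1.
#' }
#'
#' @param signal an [ECGSignal-class].
#' @param config a [filterConfig()].
#' @param verbose emit a message with the chosen depths.
#' @return The filtered [ECGSignal-class].
#' @export
preprocessECG <- function(signal, config = filterConfig(), verbose = FALSE) {
  stopIfNot(inherits(config, "FilterConfig"),
            "config must come from filterConfig()")
  fs <- samplingRate(signal)
  if (is.null(config$i) || is.null(config$j)) {
    lv <- selectDecompositionLevels(fs, config$fLow, config$fHigh)
    i <- if (is.null(config$i)) lv$i else config$i
    j <- if (is.null(config$j)) lv$j else config$j
  } else { i <- config$i; j <- config$j }
  if (verbose)
    message(sprintf("wavelet adaptive filter: i = %d (edge %.3g Hz), j = %d (edge %.3g Hz)",
                    i, fs / 2^(i + 1), j, fs / 2^(i + j + 1)))
  E1 <- waveletDenoiseHigh(signal, i, config$wavelet)
  E2 <- extractLowReference(E1, j, config$wavelet)
  lmsFilter(E1, E2, mu = config$mu, order = config$order)
}
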