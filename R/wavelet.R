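# Discrete wavelet transform with symmetric signal extension.
#
# Daubechies filter banks and a single-level analysis/synthesis pair using
# symmetric (edge-repeating) extension. The analysis keeps the redundant
# boundary coefficients (length floor((n + L - 1)/2) per band), which makes
# the synthesis an exact inverse for arbitrary signal lengths; perfect
# reconstruction is asserted in the test suite.

# Orthonormal Daubechies lowpass decomposition filters (db2/db4/db6,
# filter lengths 4/8/12).
.dbFilters <- list(
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db6 = c(-0.00107730108499558, 0.004777257511010651, 0.0005538422009938016,
          -0.031582039318031156, 0.02752286553001629, 0.09750160558707936,
          -0.12976686756709563, -0.22626469396516913, 0.3152503517092432,
          0.7511339080215775, 0.4946238903983854, 0.11154074335008017)
)

waveletFilters <- function(wavelet) {
  lo <- .dbFilters[[wavelet]]
  if (is.null(lo))
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.dbFilters), collapse = ", "), call. = FALSE)
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)   # quadrature mirror
  list(decLo = lo, decHi = hi, recLo = rev(lo), recHi = rev(hi), L = L)
}

# symmetric (half-point, edge-repeating) extension by p samples each side
.symExt <- function(x, p) {
  n <- length(x)
  stopIfNot(n >= p, "signal shorter than one decomposition step")
  c(rev(x[seq_len(p)]), x, rev(x[(n - p + 1):n]))
}

.convFull <- function(x, f) stats::convolve(x, rev(f), type = "open")

# one analysis level: returns approximation and detail coefficient vectors
dwtStep <- function(x, flt) {
  ext <- .symExt(x, flt$L - 1L)
  nc <- (length(x) + flt$L - 1L) %/% 2L
  pick <- seq.int(flt$L + 1L, by = 2L, length.out = nc)
  list(cA = .convFull(ext, flt$decLo)[pick],
       cD = .convFull(ext, flt$decHi)[pick])
}

# one synthesis level: inverse of dwtStep for output length n
idwtStep <- function(cA, cD, flt, n) {
  up <- function(cf) { u <- numeric(2L * length(cf)); u[c(TRUE, FALSE)] <- cf; u }
  full <- .convFull(up(cA), flt$recLo) + .convFull(up(cD), flt$recHi)
  full[seq.int(flt$L - 1L, length.out = n)]
}

# multi-level decomposition of the approximation branch
dwtDecompose <- function(x, level, wavelet) {
  flt <- waveletFilters(wavelet)
  details <- vector("list", level)
  lens <- integer(level)
  cA <- x
  for (k in seq_len(level)) {
    lens[k] <- length(cA)
    s <- dwtStep(cA, flt)
    details[[k]] <- s$cD
    cA <- s$cA
  }
  list(cA = cA, details = details, lens = lens, flt = flt)
}

dwtReconstruct <- function(dec, zeroDetails = TRUE) {
  cA <- dec$cA
  for (k in rev(seq_along(dec$details))) {
    cD <- if (zeroDetails) numeric(length(dec$details[[k]])) else dec$details[[k]]
    cA <- idwtStep(cA, cD, dec$flt, dec$lens[k])
  }
  cA
}

#' Select wavelet decomposition depths from the noise band structure
#'
#' The depth-i approximation of a signal sampled at \code{fs} occupies the
#' band [0, fs/2^(i+1)]. The first depth \code{i} is the smallest whose
#' approximation band edge falls at or below \code{fHigh} (separating the
#' QRS-bearing band from high-frequency noise); the additional depth
#' \code{j} is the smallest for which the edge of the depth-(i+j)
#' approximation falls at or below \code{fLow} (isolating baseline wander
#' and motion artifact, which live below 7 Hz).
#'
#' @param fs sampling frequency (Hz).
#' @param fLow upper edge of the low-frequency noise band (Hz, default 7).
#' @param fHigh upper edge of the band that must retain the ECG signal (Hz).
#' @return list with integer depths \code{i} and \code{j} and the
#'   corresponding band edges \code{edgeHigh}, \code{edgeLow} (Hz).
#' @examples
#' selectDecompositionLevels(360, fLow = 7, fHigh = 50)  # i = 2, j = 3
#' @export
selectDecompositionLevels <- function(fs, fLow = 7, fHigh = 50) {
  stopIfNot(fLow > 0 && fLow < fHigh && fHigh < fs / 2,
            "need 0 < fLow < fHigh < fs/2")
  i <- 1L
  while (fs / 2^(i + 1) > fHigh) i <- i + 1L
  j <- 1L
  while (fs / 2^(i + j + 1) > fLow) j <- j + 1L
  list(i = i, j = j, edgeHigh = fs / 2^(i + 1), edgeLow = fs / 2^(i + j + 1))
}

#' Remove high-frequency noise by wavelet approximation
#'
#' Decomposes the signal to depth \code{i} and reconstructs from the
#' approximation branch alone (all detail coefficients zeroed): the
#' high-frequency components are removed outright rather than shrunk.
#' The result is the primary input of the adaptive filtering stage.
#'
#' @param signal an [ECGSignal-class].
#' @param i decomposition depth (>= 1).
#' @param wavelet wavelet family name (db2, db4 or db6; default db4, whose
#'   compact support matches QRS-like transients).
#' @return An [ECGSignal-class] of the same length and sampling rate.
#' @export
waveletDenoiseHigh <- function(signal, i, wavelet = "db4") {
  stopIfNot(i >= 1, "depth i must be >= 1")
  dec <- dwtDecompose(signalValues(signal), i, wavelet)
  out <- dwtReconstruct(dec, zeroDetails = TRUE)
  ECGSignal(out, samplingRate(signal), signal@t0)
}

#' Extract the low-frequency reference from the denoised signal
#'
#' Decomposes the high-frequency-denoised signal a further \code{j} levels
#' and reconstructs its approximation: the estimated baseline drift /
#' motion-artifact component, used as the reference input of the LMS
#' adaptive filter.
#'
#' @param E1 an [ECGSignal-class], typically from [waveletDenoiseHigh()].
#' @param j additional decomposition depth (>= 1).
#' @inheritParams waveletDenoiseHigh
#' @return An [ECGSignal-class] of the same length.
#' @export
extractLowReference <- function(E1, j, wavelet = "db4") {
  stopIfNot(j >= 1, "depth j must be >= 1")
  dec <- dwtDecompose(signalValues(E1), j, wavelet)
  out <- dwtReconstruct(dec, zeroDetails = TRUE)
  ECGSignal(out, samplingRate(E1), E1@t0)
}
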