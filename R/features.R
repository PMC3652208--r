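#' Canonical feature column order (normative for all feature I/O)
#' @return Character vector of the nine feature names.
#' @export
featureNames <- function() c("RRn", "RRnPrime", "QRSn", "PRn", "QTn",
                             "STn", "Rn", "Pn", "Tn")

#' Extract the nine time-domain beat features
#'
#' For every annotated beat with both neighbors, computes the features
#' spanning two succeeding cardiac periods: the preceding and following RR
#' intervals \code{RRn}, \code{RRnPrime}; the \code{QRSn} (Q-to-S),
#' \code{PRn} (P-to-R), \code{QTn} (Q-to-T-peak) and \code{STn}
#' (S-to-T-peak) intervals, all in seconds; and the \code{Rn}, \code{Pn},
#' \code{Tn} peak amplitudes in mV, measured against a per-beat baseline
#' estimated as the median of the PR segment (the samples between P and
#' Q). Beats with missing landmarks or non-positive intervals are dropped
#' with a warning.
#'
#' @param signal the [ECGSignal-class] the annotations refer to.
#' @param annotations annotation data.frame from [annotateBeats()].
#' @return data.frame: \code{beat} id plus the nine feature columns in
#'   canonical order.
#' @export
extractFeatures <- function(signal, annotations) {
  stopIfNot(nrow(annotations) >= 1, "no annotated beats")
  x <- signalValues(signal); fs <- samplingRate(signal)
  a <- annotations
  base <- vapply(seq_len(nrow(a)), function(b) {
    seg <- x[a$P[b]:a$Q[b]]
    stats::median(seg)
  }, numeric(1))
  feats <- data.frame(
    beat = a$beat,
    RRn      = a$RRprev,
    RRnPrime = a$RRnext,
    QRSn     = (a$S - a$Q) / fs,
    PRn      = (a$R - a$P) / fs,
    QTn      = (a$T - a$Q) / fs,
    STn      = (a$T - a$S) / fs,
    Rn       = x[a$R] - base,
    Pn       = x[a$P] - base,
    Tn       = x[a$T] - base
  )
  ival <- c("RRn", "RRnPrime", "QRSn", "PRn", "QTn", "STn")
  bad <- !stats::complete.cases(feats) |
    apply(feats[ival] <= 0, 1, any) | feats$QRSn >= feats$RRn
  if (any(bad)) {
    warning(sum(bad), " beat(s) dropped: disordered or incomplete landmarks")
    feats <- feats[!bad, , drop = FALSE]
  }
  rownames(feats) <- NULL
  feats
}

#' Normalize a feature matrix
#'
#' \code{method = "zscore"} centers every feature column to mean 0 and
#' scales to sd 1 (constant columns map to zeros with a warning, never
#' NaN); \code{method = "none"} is the identity. Raw features are already
#' in physical units (seconds, mV); the z-score step is offered for
#' clustering, where heterogeneous scales would dominate the kernel.
#'
#' @param X numeric matrix or data.frame of features (columns = features).
#' @param method \code{"none"} or \code{"zscore"}.
#' @return Same shape as \code{X}, numeric matrix.
#' @export
normalizeFeatures <- function(X, method = c("zscore", "none")) {
  method <- match.arg(method)
  M <- as.matrix(X)
  if (method == "none") return(M)
  stopIfNot(nrow(M) >= 2, "zscore needs at least 2 rows")
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  zeroSd <- sd <= .Machine$double.eps * 10
  if (any(zeroSd)) {
    warning("constant column(s) mapped to zero: ",
            paste(colnames(M)[zeroSd], collapse = ", "))
    sd[zeroSd] <- 1
  }
  Z <- sweep(sweep(M, 2, mu, "-"), 2, sd, "/")
  Z[, zeroSd] <- 0
  Z
}

#' Read / write feature tables as CSV
#'
#' The CSV column order follows the canonical nine-feature layout
#' (RRn, RRnPrime, QRSn, PRn, QTn, STn, Rn, Pn, Tn), optionally followed
#' by a \code{class} column.
#'
#' @param path CSV file path.
#' @return \code{readFeatureCSV}: data.frame with the nine feature columns
#'   (and \code{class} when present).
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- featureNames()
  stopIfNot(all(need %in% names(df)),
            paste("feature CSV must contain columns:",
                  paste(need, collapse = ", ")))
  df[, c(need, intersect("class", names(df))), drop = FALSE]
}

#' @rdname readFeatureCSV
#' @param X feature data.frame or matrix (nine canonical columns, optional
#'   \code{class}).
#' @export
writeFeatureCSV <- function(X, path) {
  df <- as.data.frame(X)
  keep <- c(featureNames(), intersect("class", names(df)))
  utils::write.csv(df[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
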