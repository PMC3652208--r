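#' ECGSignal: a uniformly sampled single-lead voltage trace
#'
#' Container for a raw or filtered ECG waveform: the sampled voltages in
#' millivolts, the sampling frequency in Hz, and the start time in seconds.
#'
#' @slot samples numeric vector of voltages (mV).
#' @slot fs sampling frequency (Hz), positive scalar.
#' @slot t0 start time of the first sample (s).
#'
#' @examples
#' sig <- ECGSignal(sin(2 * pi * 1 * (0:999) / 250), fs = 250)
#' samplingRate(sig)
#' @export
setClass("ECGSignal",
  representation(samples = "numeric", fs = "numeric", t0 = "numeric"),
  prototype(samples = numeric(0), fs = 1, t0 = 0)
)

setValidity("ECGSignal", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive finite number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "signal must contain at least one sample")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct an ECGSignal
#'
#' @param samples numeric vector of voltages (mV).
#' @param fs sampling frequency (Hz).
#' @param t0 start time (s), default 0.
#' @return An [ECGSignal-class] object.
#' @export
ECGSignal <- function(samples, fs, t0 = 0) {
  methods::new("ECGSignal", samples = as.numeric(samples),
               fs = as.numeric(fs), t0 = as.numeric(t0))
}

#' @describeIn ECGSignal-class number of samples
#' @param x an ECGSignal
#' @export
setMethod("length", "ECGSignal", function(x) length(x@samples))

#' @rdname ECGSignal-class
#' @param object an ECGSignal
#' @export
setMethod("show", "ECGSignal", function(object) {
  cat(sprintf("ECGSignal: %d samples @ %g Hz (%.3f s), range [%.3f, %.3f] mV\n",
              length(object@samples), object@fs,
              length(object@samples) / object@fs,
              min(object@samples), max(object@samples)))
  invisible(object)
})

#' @rdname ECGSignal-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname ECGSignal-class
#' @export
setMethod("samplingRate", "ECGSignal", function(x) x@fs)

#' @rdname ECGSignal-class
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname ECGSignal-class
#' @export
setMethod("signalValues", "ECGSignal", function(x) x@samples)

#' @rdname ECGSignal-class
#' @export
setGeneric("signalTimes", function(x) standardGeneric("signalTimes"))

#' @rdname ECGSignal-class
#' @export
setMethod("signalTimes", "ECGSignal", function(x)
  x@t0 + (seq_along(x@samples) - 1) / x@fs)

#' MMCModel: a fitted maximum-margin clustering model for a fixed labeling
#'
#' Result of the least-squares SVM inner solve for a fixed label vector
#' \code{y}: dual coefficients, bias, raw scores, per-sample slacks, the
#' square-loss objective J and its affinity F = exp(-J).
#'
#' @slot alpha numeric dual coefficients (one per sample).
#' @slot b bias term.
#' @slot y label vector in \{-1, +1\}.
#' @slot scores raw decision values w.phi(x_i) (bias excluded).
#' @slot eta per-sample slacks 1 - y_i (scores_i + b).
#' @slot C regularization constant.
#' @slot kernel list describing the kernel (kind, sigma).
#' @slot J objective value (>= 0).
#' @slot F affinity exp(-J) in (0, 1].
#' @export
setClass("MMCModel",
  representation(alpha = "numeric", b = "numeric", y = "numeric",
                 scores = "numeric", eta = "numeric", C = "numeric",
                 kernel = "list", J = "numeric", F = "numeric"),
  prototype(alpha = numeric(0), b = 0, y = numeric(0), scores = numeric(0),
            eta = numeric(0), C = 1, kernel = list(kind = "unset"),
            J = 0, F = 1)
)

setValidity("MMCModel", function(object) {
  msg <- character(0)
  if (!all(object@y %in% c(-1, 1)))
    msg <- c(msg, "y must contain only -1 and +1")
  if (length(object@J) != 1L || !is.finite(object@J) || object@J < -1e-8)
    msg <- c(msg, "J must be a finite non-negative scalar")
  if (length(msg)) msg else TRUE
})

#' @rdname MMCModel-class
#' @param object an MMCModel
#' @export
setMethod("show", "MMCModel", function(object) {
  cat(sprintf(
    "MMCModel: n = %d, kernel = %s, C = %g\n  J = %.6g, F = %.6g, |sum y| = %d\n",
    length(object@y), object@kernel$kind, object@C,
    object@J, object@F, abs(sum(object@y))))
  invisible(object)
})

#' @rdname MMCModel-class
#' @param x an MMCModel
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname MMCModel-class
#' @export
setMethod("objectiveValue", "MMCModel", function(x) x@J)

#' @rdname MMCModel-class
#' @export
setGeneric("affinityValue", function(x) standardGeneric("affinityValue"))

#' @rdname MMCModel-class
#' @export
setMethod("affinityValue", "MMCModel", function(x) x@F)

#' @rdname MMCModel-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname MMCModel-class
#' @export
setMethod("clusterLabels", "MMCModel", function(x) x@y)
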