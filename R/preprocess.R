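# Signal conditioning ahead of peak detection: mean removal and zero-phase
# low-pass filtering, plus the moving-average smoother used after
# thresholding. All stages are linear and length-preserving.

#' Low-pass filter specification
#'
#' Chewing occupies roughly 0.94-2 Hz, so the default is a 4th-order
#' Butterworth with a 3 Hz cutoff, applied forward-backward (zero phase) so
#' peak positions are not shifted by the filter.
#'
#' @param cutoff_hz Cutoff frequency in Hz; must be below Nyquist.
#' @param order Filter order (default 4).
#' @param zero_phase Apply forward-backward filtering (default TRUE).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 3, order = 4, zero_phase = TRUE) {
  stopifnot(cutoff_hz > 0, order >= 1)
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Remove the mean amplitude from a signal
#'
#' Subtracting the mean compensates for sensor offset drift; all later
#' stages assume a zero-mean signal.
#'
#' @param signal A [sensor_signal()].
#' @return A [sensor_signal()] with zero-mean samples.
#' @export
demean <- function(signal) {
  stopifnot(inherits(signal, "sensor_signal"))
  if (length(signal$samples) == 0L) stop("cannot demean an empty signal")
  signal$samples <- signal$samples - mean(signal$samples)
  signal
}

#' Zero-phase low-pass filter a signal
#'
#' Applies a Butterworth low-pass per `spec`. With `zero_phase = TRUE` the
#' filter runs forward and backward (via [signal::filtfilt()]), doubling the
#' effective order and cancelling group delay.
#'
#' @param x A [sensor_signal()].
#' @param spec A [filter_spec()].
#' @return A filtered [sensor_signal()] of the same length.
#' @export
lowpass <- function(x, spec = filter_spec()) {
  stopifnot(inherits(x, "sensor_signal"), inherits(spec, "filter_spec"))
  nyq <- x$fs / 2
  if (spec$cutoff_hz >= nyq) {
    stop("cutoff (", spec$cutoff_hz, " Hz) must be below Nyquist (",
         nyq, " Hz)")
  }
  bf <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = "low")
  x$samples <- if (spec$zero_phase) {
    # mirror the signal at both ends before the forward-backward pass so
    # edge transients do not attenuate peaks near the boundaries (and no
    # spurious DC step is introduced at the junctions)
    n <- length(x$samples)
    p <- min(n - 1L, as.integer(round(10 * x$fs / spec$cutoff_hz)))
    if (p > 0L) {
      xp <- c(x$samples[(p + 1L):2L], x$samples,
              x$samples[(n - 1L):(n - p)])
      signal::filtfilt(bf, xp)[(p + 1L):(p + n)]
    } else {
      signal::filtfilt(bf, x$samples)
    }
  } else {
    as.numeric(signal::filter(bf, x$samples))
  }
  x
}

#' Centered moving average with shrink-to-valid edges
#'
#' Smooths a sequence with a centered window of `window` samples. At the
#' edges the window shrinks to the available samples, so a constant input is
#' returned unchanged and no artificial boundary peaks are created.
#'
#' @param samples Numeric vector.
#' @param window Window length in samples (>= 1).
#' @return Numeric vector of the same length.
#' @examples
#' moving_average(c(0, 0, 1, 0, 0), 3)  # c(0, 1/3, 1/3, 1/3, 0)
#' @export
moving_average <- function(samples, window) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window != round(window)) {
    stop("`window` must be a positive integer")
  }
  n <- length(samples)
  if (n == 0L) return(numeric(0))
  window <- as.integer(window)
  if (window == 1L) return(as.numeric(samples))
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  cs <- cumsum(c(0, samples))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Preprocess a signal for chew counting
#'
#' Convenience wrapper: [demean()] then [lowpass()].
#'
#' @inheritParams lowpass
#' @return The conditioned [sensor_signal()].
#' @export
preprocess_signal <- function(x, spec = filter_spec()) {
  lowpass(demean(x), spec)
}

#' Anti-aliased decimation
#'
#' Optional speed stage: low-pass filters at 40% of the target Nyquist and
#' keeps every `factor`-th sample. All downstream parameters are expressed
#' in seconds, so processing is invariant to the native rate.
#'
#' @param x A [sensor_signal()].
#' @param factor Positive integer decimation factor.
#' @return A [sensor_signal()] at `fs / factor`.
#' @export
decimate_signal <- function(x, factor) {
  stopifnot(inherits(x, "sensor_signal"), factor >= 1,
            factor == round(factor))
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  target_nyq <- x$fs / factor / 2
  x <- lowpass(x, filter_spec(cutoff_hz = 0.8 * target_nyq, order = 8))
  x$samples <- x$samples[seq(1L, length(x$samples), by = factor)]
  x$fs <- x$fs / factor
  x
}
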