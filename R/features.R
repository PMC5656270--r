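# The 38-dimensional time/frequency feature vector computed per epoch.
#
# 19 time-domain features describe amplitude, shape and complexity of the
# epoch waveform; 19 frequency-domain features are derived from a
# Hann-windowed periodogram of the (per-epoch demeaned) signal. Chewing
# shows as quasi-periodic 0.94-2 Hz energy; speech and motion artifacts
# occupy higher bands, which is why the band set reaches into the kHz
# range when the sampling rate allows.
#
# Conventions for degenerate inputs: the amplitude-histogram entropy of a
# constant epoch is 0; the dominant frequency (and all spectral-shape
# features) of a zero-power epoch are 0.

FEATURE_BANDS <- list(
  c(0, 1), c(1, 2), c(2, 3), c(3, 5), c(5, 10), c(10, 50), c(50, 500),
  c(500, Inf)  # upper edge capped at fs/2 at computation time
)

#' Names of the 38 epoch features
#'
#' Stable identifiers, in the order produced by [compute_features()].
#'
#' @return Character vector of length 38.
#' @export
feature_names <- function() {
  c(
    # time domain (19)
    "mav", "rms", "variance", "sd", "peak_to_peak", "mad",
    "skewness", "kurtosis", "zero_crossings", "mean_crossing_rate",
    "slope_sign_changes", "waveform_length", "log_energy",
    "amplitude_entropy", "p10", "p25", "p75", "p90", "iqr",
    # frequency domain (19)
    "total_power",
    paste0("relpower_", c("0_1", "1_2", "2_3", "3_5", "5_10", "10_50",
                          "50_500", "500_nyq")),
    "dominant_freq", "dominant_power", "spectral_centroid",
    "spectral_spread", "spectral_entropy", "sef50", "sef90", "sef95",
    "spectral_skewness", "spectral_kurtosis"
  )
}

#' Compute the 38-feature vector for one epoch
#'
#' @param x Numeric vector of epoch samples (non-empty, finite), or one row
#'   of an `epoch_set`.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of exactly 38 finite values, in the order
#'   of [feature_names()].
#' @export
compute_features <- function(x, fs) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) stop("empty epoch")
  if (any(!is.finite(x))) stop("non-finite samples in epoch")
  stopifnot(fs > 0)

  # ---- time domain ----
  mu <- mean(x)
  v <- if (n > 1L) stats::var(x) else 0
  s <- sqrt(v)
  dx <- diff(x)
  zc <- sum(x[-n] * x[-1L] < 0)
  mc <- sum((x[-n] - mu) * (x[-1L] - mu) < 0)
  ssc <- if (n > 2L) sum(dx[-length(dx)] * dx[-1L] < 0) else 0
  qs <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7,
                        names = FALSE)
  skw <- if (s > 0 && n > 2L) e1071::skewness(x, type = 2) else 0
  krt <- if (s > 0 && n > 3L) e1071::kurtosis(x, type = 2) else 0
  time_feats <- c(
    mav = mean(abs(x)),
    rms = sqrt(mean(x^2)),
    variance = v,
    sd = s,
    peak_to_peak = max(x) - min(x),
    mad = stats::median(abs(x - stats::median(x))),
    skewness = skw,
    kurtosis = krt,
    zero_crossings = zc,
    mean_crossing_rate = mc / (n / fs),
    slope_sign_changes = ssc,
    waveform_length = sum(abs(dx)),
    log_energy = log(sum(x^2) + .Machine$double.eps),
    amplitude_entropy = histogram_entropy(x, bins = 16L),
    p10 = qs[1], p25 = qs[2], p75 = qs[3], p90 = qs[4],
    iqr = qs[3] - qs[2]
  )

  # ---- frequency domain (Hann periodogram, single segment) ----
  w <- hann_window(n)
  xw <- (x - mu) * w
  spec <- Mod(stats::fft(xw))^2
  nf <- n %/% 2L + 1L
  p <- spec[seq_len(nf)] / (fs * sum(w^2))
  if (nf > 2L) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]  # one-sided
  freqs <- (seq_len(nf) - 1L) * fs / n
  df_hz <- fs / n
  total_power <- sum(p) * df_hz
  freq_feats <- if (total_power <= 0) {
    c(total_power = 0,
      stats::setNames(rep(0, 8), paste0("relpower_", seq_len(8))),
      dominant_freq = 0, dominant_power = 0, spectral_centroid = 0,
      spectral_spread = 0, spectral_entropy = 0, sef50 = 0, sef90 = 0,
      sef95 = 0, spectral_skewness = 0, spectral_kurtosis = 0)
  } else {
    rel <- vapply(FEATURE_BANDS, function(b) {
      hi <- min(b[2], fs / 2)
      if (hi <= b[1]) return(0)
      # the band capped at Nyquist includes the Nyquist bin itself
      sel <- freqs >= b[1] &
        (freqs < hi | (hi >= fs / 2 - 1e-12 & freqs <= hi))
      sum(p[sel]) * df_hz / total_power
    }, numeric(1))
    # skip the DC bin when locating the dominant component
    imax <- which.max(p[-1L]) + 1L
    pn <- p / sum(p)
    centroid <- sum(freqs * pn)
    spread <- sqrt(sum((freqs - centroid)^2 * pn))
    pn_pos <- pn[pn > 0]
    sentropy <- -sum(pn_pos * log2(pn_pos)) / log2(length(pn))
    cumpow <- cumsum(pn)
    sef <- function(q) freqs[which(cumpow >= q)[1L]]
    sskew <- if (spread > 0) sum(((freqs - centroid) / spread)^3 * pn) else 0
    skurt <- if (spread > 0) sum(((freqs - centroid) / spread)^4 * pn) else 0
    c(total_power = total_power, stats::setNames(rel, paste0("rp", 1:8)),
      dominant_freq = freqs[imax], dominant_power = p[imax] * df_hz,
      spectral_centroid = centroid, spectral_spread = spread,
      spectral_entropy = sentropy, sef50 = sef(0.5), sef90 = sef(0.9),
      sef95 = sef(0.95), spectral_skewness = sskew,
      spectral_kurtosis = skurt)
  }

  out <- c(time_feats, freq_feats)
  names(out) <- feature_names()
  stopifnot(length(out) == 38L, all(is.finite(out)))
  out
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1L) / (n - 1L))
}

histogram_entropy <- function(x, bins = 16L) {
  r <- range(x)
  if (r[2] <= r[1]) return(0)  # constant signal: zero entropy by convention
  counts <- tabulate(
    pmin(bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * bins)),
    nbins = bins
  )
  pr <- counts[counts > 0] / length(x)
  -sum(pr * log2(pr))
}

#' Feature matrix for an epoch set
#'
#' Applies [compute_features()] to every epoch.
#'
#' @param epochs An `epoch_set` from [segment_epochs()].
#' @return Numeric matrix, one row per epoch, 38 named columns.
#' @export
features_matrix <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- nrow(epochs$samples)
  out <- matrix(NA_real_, nrow = n, ncol = 38L,
                dimnames = list(NULL, feature_names()))
  for (i in seq_len(n)) {
    out[i, ] <- compute_features(epochs$samples[i, ], epochs$fs)
  }
  out
}
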