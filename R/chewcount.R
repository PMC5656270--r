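# Percentile-threshold peak-detection chew counting.
#
# Each chew (jaw open-close cycle) produces one peak in the demeaned,
# low-pass-filtered sensor signal. Amplitude varies widely across subjects
# (adiposity, sensor placement) and foods, so the peak-detection threshold
# adapts to each segment: T = quantile(x, alpha) with alpha in [0.80, 0.97].
# Samples at or below T are zeroed, the retained signal is smoothed with a
# short moving average, and local maxima (with a refractory minimum
# separation) are counted as chews.

#' Percentile threshold of a segment
#'
#' The adaptive peak-detection threshold `T`: the `alpha`-quantile of the
#' segment's samples, using the linear-interpolation order statistic
#' (`stats::quantile` type 7). Only amplitudes in the upper `1 - alpha`
#' fraction of the segment are candidates for peaks.
#'
#' @param samples Numeric vector (non-empty).
#' @param alpha Quantile level in (0, 1).
#' @return Threshold value in the units of `samples` (volts).
#' @examples
#' percentile_threshold(0:99, 0.90)  # 89.1
#' @export
percentile_threshold <- function(samples, alpha) {
  if (length(samples) == 0L) stop("empty input")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single value in (0, 1)")
  }
  stats::quantile(samples, alpha, type = 7, names = FALSE)
}

# Strict local maxima of `x` that exceed zero, with plateau ties broken to
# the earliest sample, then thinned so that no two retained peaks are closer
# than `min_sep` samples (stronger peaks win; equal peaks keep the earlier).
find_local_peaks <- function(x, min_sep) {
  n <- length(x)
  if (n < 1L) return(integer(0))
  xpad <- c(-Inf, x, -Inf)
  rises <- xpad[2:(n + 1L)] > xpad[1:n]          # x[i] > x[i-1]
  not_below <- xpad[2:(n + 1L)] >= xpad[3:(n + 2L)]  # x[i] >= x[i+1]
  cand <- which(rises & not_below & x > 0)
  if (length(cand) <= 1L || min_sep <= 1L) return(cand)
  ord <- cand[order(-x[cand], cand)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Count chews in a preprocessed segment
#'
#' The peak-detection chew counter. `segment` is assumed already demeaned
#' and low-pass filtered (see [preprocess_signal()]). The pipeline is:
#' threshold at `T = percentile_threshold(segment, alpha)` (samples <= T set
#' to 0), smooth with a [moving_average()] of `smooth_window` samples, and
#' count local maxima at least `min_separation_s` apart. The chewing rate is
#' `count / duration` (chews per second).
#'
#' @param segment Numeric vector of preprocessed samples.
#' @param fs Sampling rate in Hz.
#' @param alpha Threshold quantile level (default 0.90).
#' @param min_separation_s Minimum time between reported peaks, seconds
#'   (default 0.3, just below the period of the fastest plausible chewing,
#'   ~2.5 chews/s).
#' @param smooth_window Moving-average window in samples (default 100).
#' @return A list of class `count_result`: `n_peaks`, `peak_times` (seconds,
#'   strictly increasing), `rate` (chews/s), `threshold` (volts).
#' @examples
#' fs <- 1000
#' x <- sin(2 * pi * 1.5 * seq(0, 10 - 1 / fs, by = 1 / fs))
#' count_chews(x, fs)$n_peaks  # 15
#' @export
count_chews <- function(segment, fs, alpha = 0.90, min_separation_s = 0.3,
                        smooth_window = 100) {
  if (length(segment) == 0L) stop("empty segment")
  if (min_separation_s <= 0) stop("min_separation_s must be positive")
  duration <- length(segment) / fs
  thr <- percentile_threshold(segment, alpha)
  y <- ifelse(segment > thr, segment, 0)
  y <- moving_average(y, smooth_window)
  idx <- find_local_peaks(y, min_sep = min_separation_s * fs)
  structure(
    list(n_peaks = length(idx), peak_times = (idx - 1L) / fs,
         rate = length(idx) / duration, threshold = thr),
    class = "count_result"
  )
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %d peaks, rate %.3f chews/s, T = %.4g V\n",
              x$n_peaks, x$rate, x$threshold))
  invisible(x)
}

#' Chewing rate of a segment
#'
#' `CR(k) = CNT(k) / D(k)`: chews per second over a segment of duration
#' `D(k)` seconds.
#'
#' @param cnt Chew count (>= 0).
#' @param duration_s Segment duration in seconds (> 0).
#' @return Rate in chews per second.
#' @export
chewing_rate <- function(cnt, duration_s) {
  if (any(duration_s <= 0)) stop("duration_s must be positive")
  cnt / duration_s
}

# 1-based sample index range of the half-open interval [start_s, end_s).
segment_sample_range <- function(start_s, end_s, fs, n) {
  k_lo <- ceiling(start_s * fs - 1e-9)
  k_hi <- ceiling(end_s * fs - 1e-9) - 1
  if (k_lo < 0 || k_hi + 1 > n) {
    stop("segment [", start_s, ", ", end_s, ") outside signal extent")
  }
  (k_lo + 1L):(k_hi + 1L)
}

#' Semi-automatic chew counting over a visit
#'
#' Runs the chew counter inside each manually annotated intake segment of a
#' visit. The whole recording is demeaned and low-pass filtered once, then
#' the percentile threshold is computed per segment. Returns the visit
#' summary with annotated (`acnt`, `acr`) and estimated (`ecnt`, `ecr`)
#' cumulative chew counts and mean chewing rates: `ECNT(n)` is the sum of
#' per-segment counts and `ECR(n)` the mean of per-segment rates.
#'
#' @param signal A raw [sensor_signal()].
#' @param segments A [chew_segments()] table for the same visit.
#' @param alpha Threshold quantile level.
#' @param spec [filter_spec()] for preprocessing.
#' @inheritParams count_chews
#' @return A list of class `visit_summary` with `n_sequences`, `acnt`,
#'   `acr`, `ecnt`, `ecr`, and a `per_segment` data frame. Visits with no
#'   intake segments have all counts and rates 0.
#' @export
count_visit_semi_automatic <- function(signal, segments, alpha = 0.90,
                                       spec = filter_spec(),
                                       min_separation_s = 0.3,
                                       smooth_window = 100) {
  stopifnot(inherits(signal, "sensor_signal"))
  pre <- preprocess_signal(signal, spec)
  intake <- segments[segments$label == "intake", , drop = FALSE]
  n_seq <- nrow(intake)
  if (n_seq == 0L) {
    return(new_visit_summary(signal, 0L, 0, 0, 0, 0,
                             per_segment = empty_segment_table()))
  }
  est <- vapply(seq_len(n_seq), function(k) {
    idx <- segment_sample_range(intake$start_s[k], intake$end_s[k],
                                pre$fs, length(pre$samples))
    cr <- count_chews(pre$samples[idx], pre$fs, alpha = alpha,
                      min_separation_s = min_separation_s,
                      smooth_window = smooth_window)
    cr$n_peaks
  }, numeric(1))
  dur <- intake$duration_s
  per_segment <- data.frame(
    start_s = intake$start_s, end_s = intake$end_s, duration_s = dur,
    cnt_ref = intake$chew_count, cnt_est = est,
    rate_ref = ifelse(is.na(intake$chew_count), NA,
                      chewing_rate(intake$chew_count, dur)),
    rate_est = chewing_rate(est, dur)
  )
  new_visit_summary(
    signal, n_seq,
    acnt = sum(intake$chew_count, na.rm = TRUE),
    acr = if (any(!is.na(per_segment$rate_ref))) {
      mean(per_segment$rate_ref, na.rm = TRUE)
    } else 0,
    ecnt = sum(est),
    ecr = mean(per_segment$rate_est),
    per_segment = per_segment
  )
}

new_visit_summary <- function(signal, n_sequences, acnt, acr, ecnt, ecr,
                              per_segment) {
  structure(
    list(subject_id = signal$subject_id, visit_id = signal$visit_id,
         n_sequences = n_sequences, acnt = acnt, acr = acr,
         ecnt = ecnt, ecr = ecr, per_segment = per_segment),
    class = "visit_summary"
  )
}

empty_segment_table <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             duration_s = numeric(0), cnt_ref = numeric(0),
             cnt_est = numeric(0), rate_ref = numeric(0),
             rate_est = numeric(0))
}

#' @export
print.visit_summary <- function(x, ...) {
  cat(sprintf(
    "<visit_summary> subject=%s visit=%s N=%d ACNT=%g ACR=%.3f ECNT=%g ECR=%.3f\n",
    x$subject_id, x$visit_id, x$n_sequences, x$acnt, x$acr, x$ecnt, x$ecr))
  invisible(x)
}

#' Calibrate the threshold quantile by leave-one-visit-out grid search
#'
#' Replicates the threshold-selection scheme: a seeded random subset of
#' `n_subset` visits is drawn; for each held-out visit, the grid value of
#' `alpha` minimizing the mean absolute percent chew-count error over the
#' remaining visits is recorded; the calibrated `alpha` is the mean of the
#' per-fold optima. Ties on the error curve break to the smallest `alpha`.
#'
#' @param visits List of visits, each a list with elements `signal` (a
#'   [sensor_signal()]) and `segments` (a [chew_segments()] table with at
#'   least one intake segment carrying a reference chew count).
#' @param grid Candidate quantile levels (default `seq(0.80, 0.97, 0.01)`,
#'   an 18-point grid at the interval's printed precision).
#' @param n_subset Number of visits used for calibration (default
#'   `min(20, length(visits))`).
#' @param seed Seed for the subset draw.
#' @inheritParams count_visit_semi_automatic
#' @return The calibrated quantile level, with attributes `per_fold` (data
#'   frame of held-out visit index and per-fold optimum) and `error_curve`
#'   (mean absolute percent error per grid value over the subset).
#' @export
calibrate_alpha <- function(visits, grid = seq(0.80, 0.97, by = 0.01),
                            n_subset = min(20L, length(visits)), seed = 1L,
                            spec = filter_spec(), min_separation_s = 0.3,
                            smooth_window = 100) {
  if (length(grid) == 0L) stop("empty alpha grid")
  if (length(visits) < n_subset) {
    stop("fewer visits (", length(visits), ") than n_subset (", n_subset, ")")
  }
  ok <- vapply(visits, function(v) {
    any(v$segments$label == "intake" & !is.na(v$segments$chew_count))
  }, logical(1))
  if (!all(ok)) {
    stop("every visit needs >= 1 intake segment with a reference chew count")
  }
  subset_idx <- if (n_subset == length(visits)) {
    seq_along(visits)
  } else {
    set.seed(seed)
    sort(sample.int(length(visits), n_subset))
  }
  # per-visit absolute percent error at every grid value, computed once
  err <- t(vapply(visits[subset_idx], function(v) {
    pre <- preprocess_signal(v$signal, spec)
    intake <- v$segments[v$segments$label == "intake", , drop = FALSE]
    acnt <- sum(intake$chew_count, na.rm = TRUE)
    ecnt_per_alpha <- vapply(grid, function(a) {
      sum(vapply(seq_len(nrow(intake)), function(k) {
        idx <- segment_sample_range(intake$start_s[k], intake$end_s[k],
                                    pre$fs, length(pre$samples))
        count_chews(pre$samples[idx], pre$fs, alpha = a,
                    min_separation_s = min_separation_s,
                    smooth_window = smooth_window)$n_peaks
      }, numeric(1)))
    }, numeric(1))
    abs(acnt - ecnt_per_alpha) * 100 / acnt
  }, numeric(length(grid))))
  err <- matrix(err, nrow = length(subset_idx))  # visits x grid
  per_fold <- vapply(seq_len(nrow(err)), function(j) {
    mae <- if (nrow(err) > 1L) colMeans(err[-j, , drop = FALSE]) else err[j, ]
    grid[which.min(mae)]
  }, numeric(1))
  out <- mean(per_fold)
  attr(out, "per_fold") <- data.frame(visit = subset_idx, alpha = per_fold)
  attr(out, "error_curve") <- stats::setNames(colMeans(err),
                                              sprintf("%.2f", grid))
  out
}
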