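# Synthetic jaw-sensor signal generator with exact ground truth.
#
# Emulates the statistical structure of laboratory meal recordings: a rest
# period, an eating episode made of chewing bouts separated by pauses, and
# a closing rest period. Each chew is a raised-cosine (half-period Hann)
# strike repeated at the chewing period — burst-like, as strain signals
# are, so every chew is one unambiguous peak and the per-bout ground truth
# is well defined. On top sit additive Gaussian noise, slow sinusoidal
# baseline drift, and transient artifacts (biphasic motion spikes and
# 100-400 Hz speech-band bursts). All randomness flows from a single
# master seed; meal (s, v) of a cohort uses the derived seed
# `(seed * 10007 + s * 101 + v) mod 2^31`.

#' Specification of a synthetic cohort
#'
#' Defaults encode the study conditions the generator emulates: chewing
#' frequency uniform on 0.94-2.0 Hz, bout durations 7.35 +/- 5.16 s
#' truncated at 1.5 s, and wide per-subject amplitude variation. Desk-scale
#' choices (documented in the methods vignette): fs = 1000 Hz, 30-s lead
#' and trail rest, 8-14 bouts per meal, 2-10 s pauses, 0.5 V base pulse
#' amplitude with 15% per-chew jitter, 2 artifacts/min, 0.05 V drift.
#'
#' @param n_subjects,visits_per_subject Cohort shape.
#' @param bout_duration_mean_s,bout_duration_sd_s,bout_duration_min_s
#'   Chewing-bout duration distribution (s), truncated at the minimum.
#' @param chew_freq_range Chewing frequency range (Hz).
#' @param bouts_per_meal Integer range, bouts per meal.
#' @param rest_duration_range Pause length range between bouts (s).
#' @param lead_rest_s,trail_rest_s Rest before / after the eating episode.
#' @param base_amp Base chew-pulse amplitude (V).
#' @param amp_jitter Per-chew amplitude jitter (fraction of `base_amp`).
#' @param pulse_width_s Duration of one chew strike (s).
#' @param noise_sd Additive white-noise standard deviation (V).
#' @param artifact_rate Transient artifacts per minute.
#' @param drift_amplitude Slow baseline-drift amplitude (V).
#' @param subject_gain_range Per-subject amplitude gain, drawn log-uniform.
#' @param fs Sampling rate (Hz).
#' @param seed Master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10L, visits_per_subject = 3L,
                        bout_duration_mean_s = 7.35,
                        bout_duration_sd_s = 5.16,
                        bout_duration_min_s = 1.5,
                        chew_freq_range = c(0.94, 2.0),
                        bouts_per_meal = c(8L, 14L),
                        rest_duration_range = c(2, 10),
                        lead_rest_s = 30, trail_rest_s = 30,
                        base_amp = 0.5, amp_jitter = 0.15,
                        pulse_width_s = 0.22,
                        noise_sd = 0.05, artifact_rate = 2,
                        drift_amplitude = 0.05,
                        subject_gain_range = c(0.3, 3),
                        fs = 1000, seed = 1L) {
  stopifnot(n_subjects >= 1, visits_per_subject >= 1, fs > 0,
            chew_freq_range[1] >= 0.5, chew_freq_range[2] <= 2.5,
            diff(chew_freq_range) >= 0, bout_duration_min_s > 0,
            bouts_per_meal[1] >= 0, diff(range(bouts_per_meal)) >= 0,
            all(rest_duration_range > 0), base_amp > 0,
            pulse_width_s > 0, pulse_width_s < 1 / chew_freq_range[2],
            noise_sd >= 0, artifact_rate >= 0, drift_amplitude >= 0,
            all(subject_gain_range > 0))
  structure(as.list(environment()), class = "cohort_spec")
}

#' Noise level for a target bout signal-to-noise ratio
#'
#' Computes the white-noise standard deviation giving the requested SNR
#' (in dB) relative to the within-bout RMS of the clean chew-pulse train
#' at the spec's base amplitude and mid-range chewing frequency.
#'
#' @param snr_db Target bout SNR in dB.
#' @param spec A [cohort_spec()].
#' @return Noise standard deviation in volts.
#' @export
noise_sd_for_snr <- function(snr_db, spec = cohort_spec()) {
  duty <- spec$pulse_width_s * mean(spec$chew_freq_range)
  bout_rms <- spec$base_amp * sqrt(0.375 * duty)  # mean(hann^2) = 3/8
  bout_rms / 10^(snr_db / 20)
}

# One raised-cosine strike of width `w_samp` samples, unit peak.
hann_pulse <- function(w_samp) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(w_samp) - 0.5) / w_samp)
}

#' Generate one chewing bout
#'
#' `n_chews` raised-cosine strikes at period `1/freq`; bout duration is
#' exactly `n_chews / freq` seconds, so the true chewing rate equals
#' `freq`.
#'
#' @param n_chews Number of chews (>= 1).
#' @param freq Chewing frequency in Hz (0.5-2.5).
#' @param fs Sampling rate (Hz).
#' @param amp_jitter Per-chew amplitude jitter fraction (>= 0).
#' @param seed Optional seed; when given the bout is reproducible.
#' @param base_amp Peak amplitude of an unjittered chew (V).
#' @param pulse_width_s Strike duration (s), must fit within one period.
#' @return List with `samples`, `fs`, `n_chews`, `duration_s`, `freq`.
#' @export
generate_bout <- function(n_chews, freq, fs = 1000, amp_jitter = 0.15,
                          seed = NULL, base_amp = 1, pulse_width_s = 0.22) {
  if (n_chews < 1) stop("n_chews must be >= 1")
  if (freq < 0.5 || freq > 2.5) stop("freq must be in [0.5, 2.5] Hz")
  if (!is.null(seed)) set.seed(seed)
  w <- min(pulse_width_s, 0.9 / freq)
  w_samp <- max(3L, round(w * fs))
  n <- round(n_chews / freq * fs)
  x <- numeric(n)
  pulse <- hann_pulse(w_samp)
  amps <- base_amp * pmax(0.2, 1 + amp_jitter * stats::rnorm(n_chews))
  centers <- round(((seq_len(n_chews) - 0.5) / freq) * fs)
  for (k in seq_len(n_chews)) {
    i0 <- centers[k] - w_samp %/% 2L
    idx <- (i0 + 1L):(i0 + w_samp)
    keep <- idx >= 1L & idx <= n
    x[idx[keep]] <- x[idx[keep]] + amps[k] * pulse[keep]
  }
  list(samples = x, fs = fs, n_chews = as.integer(n_chews),
       duration_s = n / fs, freq = freq)
}

#' Generate one synthetic meal recording
#'
#' Layout: lead rest, alternating chewing bouts and pauses, trail rest;
#' plus noise, drift, and transient artifacts per the spec. Ground truth
#' (per-bout chew counts, the per-sample intake mask) is returned alongside
#' CSV-compatible annotations.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed for this meal.
#' @param subject_id,visit_id Identity stamped on the outputs.
#' @return A list of class `synthetic_meal`: `signal` (a
#'   [sensor_signal()]), `segments` (a [chew_segments()] table with intake
#'   rows for every bout and non-intake rows for the rest periods),
#'   `intake_mask` (logical, per sample), `truth` (list: `acnt`, `bouts`
#'   data frame with start/end/n_chews/freq).
#' @export
generate_meal <- function(spec = cohort_spec(), seed = 1L,
                          subject_id = "s1", visit_id = "v1") {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  fs <- spec$fs
  n_bouts <- if (diff(range(spec$bouts_per_meal)) == 0) {
    spec$bouts_per_meal[1]
  } else {
    sample(seq(min(spec$bouts_per_meal), max(spec$bouts_per_meal)), 1L)
  }
  bouts <- list()
  t_cursor <- spec$lead_rest_s
  for (b in seq_len(n_bouts)) {
    freq <- stats::runif(1, spec$chew_freq_range[1], spec$chew_freq_range[2])
    dur <- max(spec$bout_duration_min_s,
               stats::rnorm(1, spec$bout_duration_mean_s,
                            spec$bout_duration_sd_s))
    n_chews <- max(2L, as.integer(round(dur * freq)))
    strength <- stats::runif(1, 0.8, 1.2) * spec$base_amp
    bout <- generate_bout(n_chews, freq, fs = fs,
                          amp_jitter = spec$amp_jitter,
                          base_amp = strength,
                          pulse_width_s = spec$pulse_width_s)
    bouts[[b]] <- list(start_s = t_cursor, samples = bout$samples,
                       n_chews = bout$n_chews,
                       duration_s = bout$duration_s, freq = freq)
    t_cursor <- t_cursor + bout$duration_s
    if (b < n_bouts) {
      t_cursor <- t_cursor + stats::runif(1, spec$rest_duration_range[1],
                                          spec$rest_duration_range[2])
    }
  }
  eat_end <- t_cursor
  total_s <- eat_end + spec$trail_rest_s
  n <- round(total_s * fs)
  x <- numeric(n)
  mask <- logical(n)
  for (b in bouts) {
    i0 <- round(b$start_s * fs)
    idx <- (i0 + 1L):(i0 + length(b$samples))
    x[idx] <- x[idx] + b$samples
    mask[idx] <- TRUE
  }
  # slow baseline drift + white noise
  tt <- (seq_len(n) - 1L) / fs
  if (spec$drift_amplitude > 0) {
    f_drift <- stats::runif(1, 0.005, 0.02)
    x <- x + spec$drift_amplitude * sin(2 * pi * f_drift * tt +
                                          stats::runif(1, 0, 2 * pi))
  }
  if (spec$noise_sd > 0) x <- x + stats::rnorm(n, 0, spec$noise_sd)
  # transient artifacts: biphasic motion spikes and speech-band bursts
  n_art <- stats::rpois(1, spec$artifact_rate * total_s / 60)
  for (a in seq_len(n_art)) {
    at <- stats::runif(1, 0, total_s)
    if (stats::runif(1) < 0.5) {
      w_samp <- round(0.06 * fs)
      shape <- sin(2 * pi * seq_len(w_samp) / w_samp) *
        hann_pulse(w_samp)
      amp <- stats::runif(1, 0.4, 1.2) * spec$base_amp * 2
    } else {
      w_samp <- round(stats::runif(1, 0.3, 1) * fs)
      carrier <- stats::runif(1, 100, min(400, 0.4 * fs))
      shape <- sin(2 * pi * carrier * seq_len(w_samp) / fs) *
        hann_pulse(w_samp)
      amp <- stats::runif(1, 0.3, 0.9) * spec$base_amp
    }
    i0 <- round(at * fs)
    idx <- (i0 + 1L):(i0 + w_samp)
    keep <- idx >= 1L & idx <= n
    x[idx[keep]] <- x[idx[keep]] + amp * shape[keep]
  }

  bout_df <- data.frame(
    start_s = vapply(bouts, `[[`, numeric(1), "start_s"),
    duration_s = vapply(bouts, `[[`, numeric(1), "duration_s"),
    n_chews = vapply(bouts, function(b) as.numeric(b$n_chews), numeric(1)),
    freq = vapply(bouts, `[[`, numeric(1), "freq")
  )
  bout_df$end_s <- bout_df$start_s + bout_df$duration_s
  segments <- if (n_bouts > 0) {
    chew_segments(
      subject_id = subject_id, visit_id = visit_id,
      start_s = c(bout_df$start_s, 0, eat_end),
      end_s = c(bout_df$end_s, spec$lead_rest_s, total_s),
      label = c(rep("intake", n_bouts), "non-intake", "non-intake"),
      chew_count = c(bout_df$n_chews, NA, NA)
    )
  } else {
    chew_segments(subject_id, visit_id, c(0, eat_end),
                  c(spec$lead_rest_s, total_s),
                  rep("non-intake", 2), c(NA, NA))
  }
  structure(
    list(signal = sensor_signal(x, fs, subject_id, visit_id),
         segments = segments, intake_mask = mask,
         truth = list(acnt = sum(bout_df$n_chews), bouts = bout_df)),
    class = "synthetic_meal"
  )
}

#' Generate a cohort of synthetic meals
#'
#' Draws a per-subject amplitude gain (log-uniform over
#' `spec$subject_gain_range`, emulating adiposity and sensor-placement
#' differences) and generates `visits_per_subject` meals per subject with
#' derived seeds, so the whole cohort is reproducible from
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort`: `meals` (list of
#'   `synthetic_meal`, gain applied to the signal), `gains` (per subject),
#'   `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  gains <- exp(stats::runif(spec$n_subjects,
                            log(spec$subject_gain_range[1]),
                            log(spec$subject_gain_range[2])))
  meals <- list()
  for (s in seq_len(spec$n_subjects)) {
    for (v in seq_len(spec$visits_per_subject)) {
      meal_seed <- (spec$seed * 10007 + s * 101 + v) %% 2147483647L
      meal <- generate_meal(spec, seed = meal_seed,
                            subject_id = sprintf("s%02d", s),
                            visit_id = sprintf("v%d", v))
      meal$signal$samples <- meal$signal$samples * gains[s]
      meals[[length(meals) + 1L]] <- meal
    }
  }
  structure(list(meals = meals, gains = gains, spec = spec),
            class = "synthetic_cohort")
}

#' Epoch feature/label dataset from a cohort
#'
#' Segments every meal into epochs, labels them with the 50% rule from the
#' ground-truth annotations, and computes the 38-feature vectors, grouped
#' per subject — the input shape required by [loso_cv()].
#'
#' @param cohort A `synthetic_cohort`, or a plain list of
#'   `synthetic_meal`s.
#' @param epoch_s Epoch duration (s).
#' @return Named list per subject: `features` (matrix), `labels`.
#' @export
build_epoch_dataset <- function(cohort, epoch_s = 5) {
  meals <- if (inherits(cohort, "synthetic_cohort")) cohort$meals else cohort
  by_subject <- split(meals, vapply(meals, function(m) m$signal$subject_id,
                                    character(1)))
  lapply(by_subject, function(ms) {
    feats <- list()
    labs <- integer(0)
    for (m in ms) {
      ep <- segment_epochs(demean(m$signal), epoch_s)
      if (nrow(ep$samples) == 0L) next
      feats[[length(feats) + 1L]] <- features_matrix(ep)
      labs <- c(labs, label_epochs(ep, m$segments))
    }
    list(features = do.call(rbind, feats), labels = labs)
  })
}

#' Constructed cohort for threshold-calibration recovery
#'
#' A deterministic fixture whose per-`alpha` error curve has its minimum at
#' `alpha = 0.90` by construction. Each visit holds one annotated chewing
#' segment containing 20 strong chews (unit-amplitude raised-cosine pulses,
#' 0.8 s wide, 1 s apart), 4 weak chews at amplitude 0.56, and 4 uncounted
#' distractor bumps at amplitude 0.52 (reference count 24), padded with
#' baseline so that the fraction of samples above the weak-chew peaks is
#' just under 10% and above the distractor peaks just over 10%. The
#' percentile threshold therefore crosses the distractor peaks near
#' `alpha = 0.894` and the weak-chew peaks near `alpha = 0.906`: below
#' 0.90 the distractors are counted (overcount), above 0.90 the weak chews
#' are missed (undercount), and only `alpha = 0.90` on the 0.01 grid counts
#' exactly. Visits differ only by a random gain, which the counter is
#' invariant to.
#'
#' @param n_visits Number of visits (default 6).
#' @param fs Sampling rate (Hz).
#' @param seed Seed for the per-visit gains.
#' @return List of visits, each `list(signal, segments)`, as
#'   [calibrate_alpha()] expects.
#' @export
generate_alpha_cohort <- function(n_visits = 6L, fs = 1000, seed = 7L) {
  set.seed(seed)
  w_samp <- round(0.8 * fs)
  pulse <- hann_pulse(w_samp)
  amps <- rep(1.0, 28)
  amps[c(5, 11, 17, 23)] <- 0.56   # weak chews (counted)
  amps[c(8, 14, 20, 26)] <- 0.52   # distractor bumps (not counted)
  is_chew <- rep(TRUE, 28)
  is_chew[c(8, 14, 20, 26)] <- FALSE
  core <- numeric(round(28 * fs))
  for (k in 1:28) {
    i0 <- round((k - 1) * fs) + round(0.1 * fs)
    core[(i0 + 1L):(i0 + w_samp)] <- amps[k] * pulse
  }
  # pad so that the sample mass above the weak-chew peak level is 9.35%
  n_total <- round(sum(core > 0.56) / 0.0935)
  x <- c(core, numeric(n_total - length(core)))
  cnt_ref <- sum(is_chew)
  lapply(seq_len(n_visits), function(v) {
    gain <- stats::runif(1, 0.5, 2)
    sig <- sensor_signal(x * gain, fs, subject_id = sprintf("s%02d", v),
                         visit_id = "v1")
    seg <- chew_segments(sig$subject_id, "v1", 0,
                         length(x) / fs, "intake", cnt_ref)
    list(signal = sig, segments = seg)
  })
}
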