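# Visit-level aggregation, error statistics, the fully automatic pipeline,
# and the method-comparison one-way ANOVA.

#' Fully automatic chew counting over a visit
#'
#' The two-stage pipeline: the recording is split into non-overlapping
#' epochs, each epoch is classified intake / non-intake (by the supplied
#' network, or by externally supplied labels such as annotation-derived
#' ground truth), and the chew counter runs on every predicted-intake
#' epoch. `ECNT(n)` is the sum of per-epoch counts; `ECR(n)` is the mean
#' per-epoch chewing rate over predicted-intake epochs (epochs predicted
#' non-intake carry no rate). Features are computed on the raw (per-epoch
#' demeaned) signal; counting runs on the demeaned, low-pass-filtered
#' signal, with the percentile threshold computed per epoch.
#'
#' @param signal A raw [sensor_signal()].
#' @param model A trained `chew_ann`, or `NULL` when `labels` is given.
#' @param alpha Threshold quantile level.
#' @param epoch_s Epoch duration in seconds (default 5).
#' @param labels Optional vector of epoch labels in `{-1,+1}` overriding
#'   the classifier (e.g. ground truth from [label_epochs()]).
#' @param spec [filter_spec()] for the counting path.
#' @inheritParams count_chews
#' @return A `visit_summary` (see [count_visit_semi_automatic()]) whose
#'   `per_segment` table has one row per predicted-intake epoch; `acnt` and
#'   `acr` are `NA` (annotations are not consulted here).
#' @export
run_fully_automatic <- function(signal, model = NULL, alpha = 0.90,
                                epoch_s = 5, labels = NULL,
                                spec = filter_spec(),
                                min_separation_s = 0.3,
                                smooth_window = 100) {
  stopifnot(inherits(signal, "sensor_signal"))
  epochs <- segment_epochs(demean(signal), epoch_s)
  n_epochs <- nrow(epochs$samples)
  if (is.null(labels)) {
    if (is.null(model)) stop("either a model or epoch labels are required")
    labels <- if (n_epochs > 0L) {
      predict(model, features_matrix(epochs))
    } else integer(0)
  }
  if (length(labels) != n_epochs) stop("one label per epoch required")
  pre <- preprocess_signal(signal, spec)
  pre_epochs <- segment_epochs(pre, epoch_s)
  intake_idx <- which(labels == 1L)
  counts <- vapply(intake_idx, function(i) {
    count_chews(pre_epochs$samples[i, ], pre$fs, alpha = alpha,
                min_separation_s = min_separation_s,
                smooth_window = smooth_window)$n_peaks
  }, numeric(1))
  k <- length(intake_idx)
  per_epoch <- data.frame(
    start_s = epochs$starts_s[intake_idx],
    end_s = epochs$starts_s[intake_idx] + epoch_s,
    duration_s = rep(epoch_s, k),
    cnt_ref = rep(NA_real_, k), cnt_est = counts,
    rate_ref = rep(NA_real_, k),
    rate_est = if (k) chewing_rate(counts, epoch_s) else numeric(0)
  )
  out <- new_visit_summary(
    signal, n_sequences = n_epochs, acnt = NA_real_, acr = NA_real_,
    ecnt = sum(counts),
    ecr = if (length(counts)) mean(per_epoch$rate_est) else 0,
    per_segment = per_epoch
  )
  out$predicted_labels <- labels
  out
}

#' Epoch-wise semi-automatic counting
#'
#' The oracle-classifier counterpart of [run_fully_automatic()]: epoch
#' labels come from the annotations via the 50% rule instead of a trained
#' network. Under identical epoch grids, its `ecnt` equals the fully
#' automatic `ecnt` whenever the classifier predicts the ground-truth
#' labels.
#'
#' @inheritParams run_fully_automatic
#' @param segments A [chew_segments()] table.
#' @return A `visit_summary`, as [run_fully_automatic()].
#' @export
count_visit_epochwise <- function(signal, segments, alpha = 0.90,
                                  epoch_s = 5, spec = filter_spec(),
                                  min_separation_s = 0.3,
                                  smooth_window = 100) {
  epochs <- segment_epochs(signal, epoch_s)
  labels <- label_epochs(epochs, segments)
  run_fully_automatic(signal, model = NULL, alpha = alpha,
                      epoch_s = epoch_s, labels = labels, spec = spec,
                      min_separation_s = min_separation_s,
                      smooth_window = smooth_window)
}

#' Per-visit chew-count error report
#'
#' Signed per-visit percent error is `(ACNT - ECNT) * 100 / ACNT` (positive
#' means the algorithm undercounts). Reports the mean signed error, the
#' mean absolute error, their standard deviations, and the t-based 95%
#' confidence interval for the mean signed error (Student's t with `M - 1`
#' degrees of freedom).
#'
#' @param acnt,ecnt Equal-length vectors of annotated and estimated
#'   per-visit cumulative chew counts; all `acnt` must be positive.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `error_report`: `per_visit_signed`,
#'   `per_visit_abs`, `mean_signed`, `sd_signed`, `mean_abs`, `sd_abs`,
#'   `n_visits`, `ci_signed` (length 2).
#' @export
error_report <- function(acnt, ecnt, conf_level = 0.95) {
  if (length(acnt) != length(ecnt)) stop("length mismatch")
  if (any(acnt <= 0)) stop("all annotated counts must be positive")
  signed <- (acnt - ecnt) * 100 / acnt
  m <- length(signed)
  mean_signed <- mean(signed)
  ci <- if (m > 1L) {
    half <- stats::qt(1 - (1 - conf_level) / 2, df = m - 1L) *
      stats::sd(signed) / sqrt(m)
    c(mean_signed - half, mean_signed + half)
  } else {
    c(mean_signed, mean_signed)
  }
  structure(
    list(per_visit_signed = signed, per_visit_abs = abs(signed),
         mean_signed = mean_signed,
         sd_signed = if (m > 1L) stats::sd(signed) else 0,
         mean_abs = mean(abs(signed)),
         sd_abs = if (m > 1L) stats::sd(abs(signed)) else 0,
         n_visits = m, ci_signed = ci, conf_level = conf_level),
    class = "error_report"
  )
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "<error_report> M=%d  signed %.2f%% +/- %.2f%%  abs %.2f%% +/- %.2f%%  %d%% CI (%.2f%%, %.2f%%)\n",
    x$n_visits, x$mean_signed, x$sd_signed, x$mean_abs, x$sd_abs,
    round(100 * x$conf_level), x$ci_signed[1], x$ci_signed[2]))
  invisible(x)
}

#' One-way ANOVA comparison of chew-counting methods
#'
#' Tests the null hypothesis that the mean per-visit chew counts are the
#' same across methods (e.g. manually annotated vs. semi-automatic vs.
#' fully automatic), via the standard one-way decomposition into between-
#' and within-group sums of squares.
#'
#' @param groups Named list of numeric vectors, one per method, each with
#'   at least 2 values.
#' @return A list of class `anova_methods`: `table` (a data frame with
#'   rows Between/Within/Total: sum of squares, df, mean square, F, p,
#'   F-crit at the 5% level), `f`, `p_value`.
#' @export
anova_methods <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs at least 2 values")
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  method <- factor(rep(nm, lengths(groups)), levels = nm)
  fit <- stats::aov(values ~ method)
  sm <- summary(fit)[[1L]]
  ss_b <- sm["method", "Sum Sq"]; df_b <- sm["method", "Df"]
  ss_w <- sm["Residuals", "Sum Sq"]; df_w <- sm["Residuals", "Df"]
  f <- sm["method", "F value"]
  p <- sm["method", "Pr(>F)"]
  tab <- data.frame(
    source = c("Between Groups", "Within Groups", "Total"),
    sum_sq = c(ss_b, ss_w, ss_b + ss_w),
    df = c(df_b, df_w, df_b + df_w),
    mean_sq = c(ss_b / df_b, ss_w / df_w, NA),
    f = c(f, NA, NA),
    p_value = c(p, NA, NA),
    f_crit = c(stats::qf(0.95, df_b, df_w), NA, NA)
  )
  structure(list(table = tab, f = f, p_value = p), class = "anova_methods")
}

#' @export
print.anova_methods <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 6)
  invisible(x)
}

#' End-to-end evaluation of a synthetic cohort
#'
#' Runs the full study workflow on a generated cohort: calibrate the
#' threshold quantile by leave-one-visit-out grid search on a random
#' subset of visits, count chews semi-automatically in the annotated
#' segments of every meal, train and evaluate the epoch classifier with
#' leave-one-subject-out cross-validation, and run the fully automatic
#' pipeline per meal using that meal's held-out-subject model. Error
#' reports compare per-visit cumulative counts against the generator's
#' ground truth.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param n_calibration Number of visits for the alpha calibration subset.
#' @param n_hidden Hidden-layer size of the epoch classifier.
#' @param seed Seed for calibration subset draw and network training.
#' @param epoch_s Epoch duration (s).
#' @return A list of class `cohort_evaluation`: `alpha` (calibrated),
#'   `semi` and `full` ([error_report()]s), `loso` ([loso_cv()] result),
#'   `acr` / `ecr_semi` / `ecr_full` (mean chewing rates, chews/s), and
#'   the per-meal `counts` data frame.
#' @export
evaluate_synthetic_cohort <- function(cohort, n_calibration = 20L,
                                      n_hidden = 5L, seed = 1L,
                                      epoch_s = 5) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  visits <- lapply(cohort$meals, function(m) {
    list(signal = m$signal, segments = m$segments)
  })
  alpha <- as.numeric(calibrate_alpha(
    visits, n_subset = min(n_calibration, length(visits)), seed = seed))
  semi_vs <- lapply(visits, function(v) {
    count_visit_semi_automatic(v$signal, v$segments, alpha = alpha)
  })
  dataset <- build_epoch_dataset(cohort, epoch_s = epoch_s)
  loso <- loso_cv(dataset, n_hidden = n_hidden, seed = seed)
  subjects <- vapply(cohort$meals, function(m) m$signal$subject_id,
                     character(1))
  ecnt_full <- numeric(length(cohort$meals))
  ecr_full <- numeric(length(cohort$meals))
  for (s in unique(subjects)) {
    train <- dataset[names(dataset) != s]
    model <- train_ann(do.call(rbind, lapply(train, `[[`, "features")),
                       unlist(lapply(train, `[[`, "labels")),
                       n_hidden = n_hidden, seed = seed)
    for (i in which(subjects == s)) {
      vs <- run_fully_automatic(cohort$meals[[i]]$signal, model,
                                alpha = alpha, epoch_s = epoch_s)
      ecnt_full[i] <- vs$ecnt
      ecr_full[i] <- vs$ecr
    }
  }
  counts <- data.frame(
    subject = subjects,
    visit = vapply(cohort$meals, function(m) m$signal$visit_id,
                   character(1)),
    acnt = vapply(cohort$meals, function(m) m$truth$acnt, numeric(1)),
    ecnt_semi = vapply(semi_vs, `[[`, numeric(1), "ecnt"),
    ecnt_full = ecnt_full
  )
  structure(
    list(alpha = alpha,
         semi = error_report(counts$acnt, counts$ecnt_semi),
         full = error_report(counts$acnt, counts$ecnt_full),
         loso = loso,
         acr = mean(vapply(semi_vs, `[[`, numeric(1), "acr")),
         ecr_semi = mean(vapply(semi_vs, `[[`, numeric(1), "ecr")),
         ecr_full = mean(ecr_full),
         counts = counts),
    class = "cohort_evaluation"
  )
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("<cohort_evaluation> %d meals, alpha = %.2f\n",
              nrow(x$counts), x$alpha))
  cat(sprintf("  semi-automatic : MAE %.2f%%, signed %.2f%%\n",
              x$semi$mean_abs, x$semi$mean_signed))
  cat(sprintf("  fully automatic: MAE %.2f%%, signed %.2f%% (LOSO F1 %.3f)\n",
              x$full$mean_abs, x$full$mean_signed, x$loso$mean_f1))
  cat(sprintf("  chewing rates  : annotated %.2f, semi %.2f, full %.2f chews/s\n",
              x$acr, x$ecr_semi, x$ecr_full))
  invisible(x)
}

#' Meal-summary totals table
#'
#' Loads a per-meal-type summary table of totals (duration, mass, bites,
#' chews, swallows) with one row per meal type plus an `all` row. The
#' packaged fixture `inst/extdata/meal_totals.csv` carries the study-scale
#' reference totals used by the aggregation checks.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Data frame with columns `meal`, `duration_s`, `mass_g`,
#'   `bites`, `chews`, `swallows`.
#' @export
read_meal_totals <- function(path = system.file("extdata",
                                                "meal_totals.csv",
                                                package = "chewmeter")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Sum per-meal-type totals
#'
#' Aggregation check: summing the individual meal-type rows must reproduce
#' the `all` row of a meal-summary table exactly.
#'
#' @param totals Data frame as returned by [read_meal_totals()].
#' @return Named numeric vector of column sums over the non-`all` rows.
#' @export
sum_meal_totals <- function(totals = read_meal_totals()) {
  rows <- totals[totals$meal != "all", , drop = FALSE]
  colSums(rows[, c("duration_s", "mass_g", "bites", "chews", "swallows")])
}
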