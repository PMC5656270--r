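test_that("error reports implement the percent-error definitions", {
  r1 <- error_report(100, 90)
  expect_equal(r1$mean_signed, 10.0)
  expect_equal(r1$mean_abs, 10.0)
  r2 <- error_report(c(100, 200), c(110, 180))
  expect_equal(r2$mean_signed, 0.0)  # symmetric errors cancel
  expect_equal(r2$mean_abs, 10.0)
  expect_error(error_report(c(100, 0), c(90, 10)), "positive")
  expect_error(error_report(100, c(90, 95)), "mismatch")
})

test_that("the confidence interval matches the closed-form t interval", {
  set.seed(1)
  signed <- rnorm(30, 5, 10)
  acnt <- rep(100, 30)
  ecnt <- acnt - signed  # per-visit signed error == `signed` exactly
  rep <- error_report(acnt, ecnt)
  half <- qt(0.975, 29) * sd(signed) / sqrt(30)
  expect_equal(rep$ci_signed, c(mean(signed) - half, mean(signed) + half),
               tolerance = 1e-9)
  # interval contains the mean; abs error dominates |signed error|
  expect_gte(rep$mean_signed, rep$ci_signed[1])
  expect_lte(rep$mean_signed, rep$ci_signed[2])
  expect_gte(rep$mean_abs, abs(rep$mean_signed))
})

test_that("mean absolute error dominates the signed error on random data", {
  set.seed(6)
  for (i in 1:50) {
    m <- sample(2:30, 1)
    acnt <- sample(50:500, m, replace = TRUE)
    ecnt <- pmax(1, acnt + round(rnorm(m, 0, 30)))
    r <- error_report(acnt, ecnt)
    expect_gte(r$mean_abs + 1e-12, abs(r$mean_signed))
    # brute-force the two definitions
    e <- (acnt - ecnt) * 100 / acnt
    expect_equal(r$mean_signed, sum(e) / m, tolerance = 1e-9)
    expect_equal(r$mean_abs, sum(abs(e)) / m, tolerance = 1e-9)
  }
})

test_that("one-way ANOVA matches the brute-force sums of squares", {
  ident <- list(a = c(3, 4, 5), b = c(3, 4, 5), c = c(3, 4, 5))
  r0 <- anova_methods(ident)
  expect_equal(r0$f, 0)
  expect_equal(r0$p_value, 1)

  set.seed(2)
  groups <- list(a = rnorm(8, 0, 1), b = rnorm(12, 0, 4))
  r <- anova_methods(groups)
  # brute-force decomposition oracle
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_b <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - grand)^2
  }, numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- length(groups) - 1
  df_w <- length(all_v) - length(groups)
  f_oracle <- (ss_b / df_b) / (ss_w / df_w)
  expect_equal(r$table$sum_sq[1:2], c(ss_b, ss_w), tolerance = 1e-9)
  expect_equal(r$f, f_oracle, tolerance = 1e-9)
  expect_equal(r$p_value, pf(f_oracle, df_b, df_w, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_lt(r$f, 1)

  sep <- anova_methods(list(a = c(1, 2, 3), b = c(11, 12, 13)))
  expect_gt(sep$f, 100)
  expect_lt(sep$p_value, 0.01)
  expect_error(anova_methods(list(a = 1:3)), "2 groups")
  expect_error(anova_methods(list(a = 1:3, b = 2)), "at least 2 values")
})

test_that("fully automatic counting under oracle labels equals the
           epoch-wise semi-automatic count", {
  meal <- make_clean_meal(c(12, 9, 16), c(1.2, 1.0, 1.7))
  truth <- label_epochs(segment_epochs(meal$signal, 5), meal$segments)
  full <- run_fully_automatic(meal$signal, labels = truth, alpha = 0.9)
  semi_ep <- count_visit_epochwise(meal$signal, meal$segments, alpha = 0.9)
  expect_identical(full$ecnt, semi_ep$ecnt)
  expect_identical(full$per_segment$cnt_est, semi_ep$per_segment$cnt_est)
})

test_that("fully automatic edge cases behave by convention", {
  sig <- sensor_signal(rnorm(20000, 0, 0.01), 1000)
  res <- run_fully_automatic(sig, labels = rep(-1L, 4))
  expect_equal(res$ecnt, 0)
  expect_equal(res$ecr, 0)
  expect_error(run_fully_automatic(sig, labels = c(1L, -1L)), "one label")
  expect_error(run_fully_automatic(sig), "model or epoch labels")
})

test_that("a pure rest signal counts near zero against a trained model", {
  set.seed(21)
  cohort <- generate_cohort(cohort_spec(n_subjects = 4,
                                        visits_per_subject = 1, seed = 21))
  ds <- build_epoch_dataset(cohort)
  model <- train_ann(do.call(rbind, lapply(ds, `[[`, "features")),
                     unlist(lapply(ds, `[[`, "labels")), seed = 21)
  chew_meal <- cohort$meals[[1]]
  chew_ecnt <- run_fully_automatic(chew_meal$signal, model)$ecnt
  rest_spec <- cohort_spec(n_subjects = 1, visits_per_subject = 1,
                           bouts_per_meal = c(0, 0), lead_rest_s = 120,
                           trail_rest_s = 120, seed = 22)
  rest <- generate_meal(rest_spec, seed = 22)
  rest_ecnt <- run_fully_automatic(rest$signal, model)$ecnt
  expect_lte(rest_ecnt, 0.05 * chew_ecnt)
})

test_that("summing per-meal-type totals reproduces the all-meals row", {
  totals <- read_meal_totals()
  sums <- sum_meal_totals(totals)
  all_row <- totals[totals$meal == "all", ]
  expect_identical(unname(sums["chews"]), as.numeric(all_row$chews))
  expect_identical(unname(sums["duration_s"]),
                   as.numeric(all_row$duration_s))
  expect_identical(unname(sums["mass_g"]), as.numeric(all_row$mass_g))
  expect_identical(unname(sums["bites"]), as.numeric(all_row$bites))
  expect_identical(unname(sums["swallows"]), as.numeric(all_row$swallows))
})
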