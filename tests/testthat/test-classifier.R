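test_that("the network separates well-separated clusters perfectly", {
  d <- make_separable(200, seed = 1)
  model <- train_ann(d$features, d$labels, seed = 3)
  pred <- predict(model, d$features)
  expect_equal(classification_metrics(pred, d$labels)$f1, 1.0)
  # training loss decreases from initialization
  expect_lt(tail(model$train_trace, 1), model$train_trace[1])
  # outputs live in (-1, 1); labels are signs
  o <- chewmeter:::ann_output(model, d$features)
  expect_true(all(o > -1 & o < 1))
  # points deep inside each cluster classify to their cluster
  probe <- matrix(0, 2, 38)
  probe[1, 1] <- 5
  probe[2, 1] <- -5
  expect_equal(predict(model, probe), c(1L, -1L))
})

test_that("training is deterministic given the seed", {
  d <- make_separable(120, seed = 2)
  m1 <- train_ann(d$features, d$labels, seed = 9)
  m2 <- train_ann(d$features, d$labels, seed = 9)
  expect_identical(m1$weights, m2$weights)
  probe <- matrix(rnorm(380), 10, 38)
  expect_identical(predict(m1, probe), predict(m2, probe))
})

test_that("degenerate training inputs are rejected", {
  d <- make_separable(50, seed = 4)
  expect_error(train_ann(d$features, rep(1L, 50)), "both classes")
  expect_error(train_ann(d$features, d$labels[-1]), "mismatch")
  expect_error(train_ann(d$features, replace(d$labels, 1, 0L)),
               "\\{-1, \\+1\\}")
  model <- train_ann(d$features, d$labels)
  expect_identical(predict(model, d$features[0, , drop = FALSE]),
                   integer(0))
  expect_error(predict(model, d$features[, 1:10]), "mismatch")
})

test_that("the model scaler is fitted on training data only", {
  d <- make_separable(80, seed = 6)
  model <- train_ann(d$features, d$labels, seed = 1)
  expect_equal(unname(model$center), unname(colMeans(d$features)))
  expect_equal(unname(model$scale), unname(apply(d$features, 2, sd)))
})

test_that("model JSON serialization round-trips predictions", {
  d <- make_separable(100, seed = 5)
  model <- train_ann(d$features, d$labels, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_ann(model, f)
  back <- read_ann(f)
  expect_equal(predict(back, d$features), predict(model, d$features))
  expect_equal(back$n_hidden, model$n_hidden)
})

test_that("metrics match a brute-force confusion count on random labels", {
  expect_equal(
    unclass(classification_metrics(
      c(rep(1L, 10), -1L), c(rep(1L, 9), -1L, 1L)))[
        c("precision", "recall", "f1")],
    list(precision = 0.9, recall = 0.9, f1 = 0.9)
  )
  perfect <- classification_metrics(c(1L, -1L, 1L), c(1L, -1L, 1L))
  expect_equal(perfect$f1, 1.0)
  # TP = 0 with errors present -> all-zero convention
  degen <- classification_metrics(c(-1L, 1L), c(1L, -1L))
  expect_equal(degen$f1, 0)
  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:60, 1)
    pred <- sample(c(-1L, 1L), n, replace = TRUE)
    truth <- sample(c(-1L, 1L), n, replace = TRUE)
    m <- classification_metrics(pred, truth)
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (j in seq_len(n)) {  # brute-force enumeration oracle
      if (pred[j] == 1 && truth[j] == 1) tp <- tp + 1
      if (pred[j] == 1 && truth[j] == -1) fp <- fp + 1
      if (pred[j] == -1 && truth[j] == 1) fn <- fn + 1
      if (pred[j] == -1 && truth[j] == -1) tn <- tn + 1
    }
    expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(tp, fp, fn, tn))
    # order invariance
    perm <- sample(n)
    expect_equal(classification_metrics(pred[perm], truth[perm])$f1, m$f1)
  }
  expect_error(classification_metrics(1L, c(1L, -1L)), "length")
})

test_that("LOSO holds each subject out once and is symmetric", {
  d <- make_separable(60, seed = 7)
  dataset <- list(a = d, b = d)  # identical subjects
  res <- loso_cv(dataset, n_hidden = 3, seed = 1)
  expect_equal(nrow(res$per_subject), 2)
  expect_equal(res$per_subject$f1[1], res$per_subject$f1[2])
  expect_error(loso_cv(dataset["a"]), "2 subjects")
  expect_error(loso_cv(list(a = d, b = list(
    features = d$features[0, , drop = FALSE], labels = integer(0)))),
    "no epochs")
})

test_that("separable multi-subject data yields near-perfect LOSO F1", {
  dataset <- lapply(1:6, function(s) make_separable(60, seed = 100 + s))
  names(dataset) <- paste0("s", 1:6)
  res <- loso_cv(dataset, n_hidden = 5, seed = 2)
  expect_gte(res$mean_f1, 0.95)
})

test_that("permuted labels collapse LOSO F1 to the chance level", {
  dataset <- lapply(1:5, function(s) {
    d <- make_separable(60, seed = 200 + s)
    set.seed(5 + s)
    d$labels <- sample(d$labels)
    d
  })
  names(dataset) <- paste0("s", 1:5)
  res <- loso_cv(dataset, n_hidden = 3, seed = 5)
  # balanced classes: a label-independent classifier scores F1 near 0.5
  expect_lt(abs(res$mean_f1 - 0.5), 0.2)
})

test_that("hidden-unit selection applies the elbow rule", {
  d <- make_separable(90, seed = 8)  # linear boundary: capacity saturates
  k <- select_hidden_units(d$features, d$labels, k_range = c(1, 3, 8),
                           n_folds = 3, n_reps = 2, seed = 1,
                           max_iter = 150)
  expect_lte(as.integer(k), 3)
  tab <- attr(k, "table")
  expect_equal(tab$n_hidden, c(1, 3, 8))
  # single candidate: forced choice
  expect_equal(as.integer(select_hidden_units(
    d$features, d$labels, k_range = 4, n_folds = 3, n_reps = 1,
    max_iter = 100)), 4)
  # tolerance 0 degenerates to the argmax
  k0 <- select_hidden_units(d$features, d$labels, k_range = c(1, 2),
                            n_folds = 3, n_reps = 1, tolerance = 0,
                            max_iter = 100)
  tab0 <- attr(k0, "table")
  expect_equal(as.integer(k0), tab0$n_hidden[which.max(tab0$mean_f1)])
  expect_error(select_hidden_units(d$features, d$labels, n_folds = 1000),
               "exceeds")
})

test_that("nnet cross-checks the separable decision boundary", {
  skip_if_not_installed("nnet")
  d <- make_separable(150, seed = 10)
  ours <- train_ann(d$features, d$labels, seed = 1)
  set.seed(1)
  theirs <- nnet::nnet(d$features, (d$labels + 1) / 2, size = 5,
                       trace = FALSE, maxit = 300)
  probe <- make_separable(100, seed = 11)
  expect_equal(predict(ours, probe$features),
               ifelse(as.numeric(predict(theirs, probe$features)) >= 0.5,
                      1L, -1L))
})
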