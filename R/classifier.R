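# Feed-forward intake classifier and its evaluation machinery.
#
# Architecture: 38 inputs -> n_hidden tanh units (default 5) -> 1 tanh
# output; the predicted class is the sign of the output. Features are
# z-scored with statistics fitted on the training data only (tanh units
# saturate on raw amplitude-scale features). Training is full-batch
# backpropagation on the squared-error loss with Rprop step-size
# adaptation, early stopping on a seeded 10% validation split, and at most
# `max_iter` iterations; everything is deterministic given the seed.

#' Train the feed-forward intake classifier
#'
#' @param features Numeric matrix, one row per example, 38 columns (any
#'   fixed dimensionality is accepted; 38 is the package's epoch feature
#'   set).
#' @param labels Integer vector of class labels in `{-1, +1}`; both classes
#'   must be present.
#' @param n_hidden Number of hidden units (default 5).
#' @param seed Seed controlling weight initialization and the validation
#'   split.
#' @param max_iter Maximum training iterations (default 500).
#' @param val_frac Fraction of the training data held out for early
#'   stopping (default 0.1; set to 0 to disable).
#' @param patience Stop after this many iterations without validation
#'   improvement (default 50).
#' @return A list of class `chew_ann`: weights, per-feature scaler, seed,
#'   and the training/validation loss traces.
#' @export
train_ann <- function(features, labels, n_hidden = 5L, seed = 1L,
                      max_iter = 500L, val_frac = 0.1, patience = 50L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) stop("dimension mismatch")
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be in {-1, +1}")
  if (length(unique(labels)) < 2L) {
    stop("training set must contain both classes")
  }
  set.seed(seed)
  n <- nrow(features)
  d <- ncol(features)

  ctr <- colMeans(features)
  scl <- apply(features, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(features, 2L, ctr), 2L, scl, "/")

  n_val <- if (val_frac > 0) max(0L, floor(val_frac * n)) else 0L
  idx <- sample.int(n)
  val_idx <- head(idx, n_val)
  tr_idx <- setdiff(idx, val_idx)
  # the split must keep both classes in the training part
  if (length(unique(labels[tr_idx])) < 2L) {
    val_idx <- integer(0)
    tr_idx <- seq_len(n)
  }
  xt <- xs[tr_idx, , drop = FALSE]; yt <- labels[tr_idx]
  xv <- xs[val_idx, , drop = FALSE]; yv <- labels[val_idx]

  r1 <- 1 / sqrt(d); r2 <- 1 / sqrt(n_hidden)
  w1 <- matrix(stats::runif(d * n_hidden, -r1, r1), d, n_hidden)
  b1 <- stats::runif(n_hidden, -r1, r1)
  w2 <- matrix(stats::runif(n_hidden, -r2, r2), n_hidden, 1L)
  b2 <- stats::runif(1L, -r2, r2)

  params <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
  delta <- lapply(params, function(p) p * 0 + 0.01)  # Rprop step sizes
  prev_grad <- lapply(params, function(p) p * 0)

  mse <- function(pp, x, y) {
    if (length(y) == 0L) return(NA_real_)
    h <- tanh(sweep(x %*% pp$w1, 2L, pp$b1, "+"))
    o <- tanh(h %*% pp$w2 + pp$b2)
    mean((o - y)^2)
  }
  gradient <- function(pp, x, y) {
    m <- length(y)
    a1 <- sweep(x %*% pp$w1, 2L, pp$b1, "+")
    h <- tanh(a1)
    o <- as.numeric(tanh(h %*% pp$w2 + pp$b2))
    do <- 2 * (o - y) * (1 - o^2) / m          # dL/d(pre-activation out)
    dh <- (do %o% as.numeric(pp$w2)) * (1 - h^2)
    list(w1 = crossprod(x, dh), b1 = colSums(dh),
         w2 = crossprod(h, do), b2 = sum(do))
  }

  train_trace <- numeric(0)
  val_trace <- numeric(0)
  best <- params
  best_val <- Inf
  stall <- 0L
  for (it in seq_len(max_iter)) {
    g <- gradient(params, xt, yt)
    for (nm in names(params)) {
      same <- sign(g[[nm]]) * sign(prev_grad[[nm]])
      delta[[nm]] <- pmin(pmax(
        delta[[nm]] * ifelse(same > 0, 1.2, ifelse(same < 0, 0.5, 1)),
        1e-8), 1)
      params[[nm]] <- params[[nm]] - sign(g[[nm]]) * delta[[nm]]
    }
    prev_grad <- g
    train_trace[it] <- mse(params, xt, yt)
    if (length(val_idx) > 0L) {
      val_trace[it] <- mse(params, xv, yv)
      if (val_trace[it] < best_val - 1e-9) {
        best_val <- val_trace[it]; best <- params; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    } else {
      best <- params
    }
  }

  structure(
    list(n_inputs = d, n_hidden = as.integer(n_hidden),
         activation = "tanh",
         weights = best, center = ctr, scale = scl,
         feature_names = colnames(features), seed = as.integer(seed),
         train_trace = train_trace, val_trace = val_trace),
    class = "chew_ann"
  )
}

#' @export
print.chew_ann <- function(x, ...) {
  cat(sprintf("<chew_ann> %d-%d-1 tanh network (seed %d)\n",
              x$n_inputs, x$n_hidden, x$seed))
  invisible(x)
}

ann_output <- function(model, features) {
  x <- as.matrix(features)
  if (ncol(x) != model$n_inputs) stop("dimension mismatch")
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  h <- tanh(sweep(xs %*% model$weights$w1, 2L, model$weights$b1, "+"))
  as.numeric(tanh(h %*% model$weights$w2 + model$weights$b2))
}

#' Predict intake labels
#'
#' The predicted label is the sign of the network output (in `(-1, 1)`);
#' an output of exactly 0 breaks to `+1`.
#'
#' @param object A `chew_ann` model.
#' @param features Feature matrix (possibly 0 rows).
#' @param ... Unused.
#' @return Integer labels in `{-1, +1}`.
#' @export
predict.chew_ann <- function(object, features, ...) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) return(integer(0))
  o <- ann_output(object, features)
  ifelse(o >= 0, 1L, -1L)
}

#' Classification metrics for intake detection
#'
#' Positive class is intake (`+1`). `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `F1 = 2*precision*recall/(precision+recall)`.
#' Zero denominators yield 0 by convention.
#'
#' @param predicted,truth Equal-length label vectors in `{-1, +1}`.
#' @return A list of class `class_metrics`: `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (!all(c(predicted, truth) %in% c(-1L, 1L))) {
    stop("labels must be in {-1, +1}")
  }
  tp <- sum(predicted == 1L & truth == 1L)
  fp <- sum(predicted == 1L & truth == -1L)
  fn <- sum(predicted == -1L & truth == 1L)
  tn <- sum(predicted == -1L & truth == -1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf(
    "<class_metrics> TP=%d FP=%d FN=%d TN=%d  P=%.3f R=%.3f F1=%.3f\n",
    x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Leave-one-subject-out cross-validation
#'
#' Each subject's epochs are held out once; a model is trained on the
#' remaining subjects (feature scaling refitted per fold on training data
#' only) and evaluated on the held-out subject.
#'
#' @param dataset Named list, one element per subject, each a list with
#'   `features` (matrix) and `labels` (`{-1,+1}` vector).
#' @param n_hidden Hidden-layer size.
#' @param seed Training seed (one model per fold).
#' @param ... Passed to [train_ann()].
#' @return A list of class `loso_result`: `per_subject` data frame
#'   (precision, recall, f1 per held-out subject), `mean_f1`, `sd_f1`,
#'   and the pooled `metrics`.
#' @export
loso_cv <- function(dataset, n_hidden = 5L, seed = 1L, ...) {
  if (length(dataset) < 2L) stop("need at least 2 subjects")
  n_epochs <- vapply(dataset, function(d) nrow(d$features), numeric(1))
  if (any(n_epochs == 0L)) stop("subject with no epochs")
  subjects <- names(dataset) %||% as.character(seq_along(dataset))
  all_pred <- integer(0)
  all_truth <- integer(0)
  rows <- lapply(seq_along(dataset), function(j) {
    train_x <- do.call(rbind, lapply(dataset[-j], `[[`, "features"))
    train_y <- unlist(lapply(dataset[-j], `[[`, "labels"))
    model <- train_ann(train_x, train_y, n_hidden = n_hidden, seed = seed,
                       ...)
    pred <- predict(model, dataset[[j]]$features)
    m <- classification_metrics(pred, dataset[[j]]$labels)
    all_pred <<- c(all_pred, pred)
    all_truth <<- c(all_truth, dataset[[j]]$labels)
    data.frame(subject = subjects[j], tp = m$tp, fp = m$fp, fn = m$fn,
               tn = m$tn, precision = m$precision, recall = m$recall,
               f1 = m$f1)
  })
  per_subject <- do.call(rbind, rows)
  structure(
    list(per_subject = per_subject,
         mean_f1 = mean(per_subject$f1), sd_f1 = stats::sd(per_subject$f1),
         metrics = classification_metrics(all_pred, all_truth)),
    class = "loso_result"
  )
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> %d subjects, mean F1 = %.4f (sd %.4f)\n",
              nrow(x$per_subject), x$mean_f1, x$sd_f1))
  invisible(x)
}

#' Choose the hidden-layer size by repeated k-fold cross-validation
#'
#' For each candidate size, `n_folds`-fold cross-validation is repeated
#' `n_reps` times (fresh random fold assignment per repetition) and the
#' F1 scores are averaged. The chosen size is the smallest whose mean F1 is
#' within `tolerance` of the maximum — an explicit form of the elbow rule
#' "stop adding units once the gain is small".
#'
#' @param features,labels Pooled examples.
#' @param k_range Candidate hidden-layer sizes (default `1:15`).
#' @param n_folds Number of CV folds (default 30).
#' @param n_reps Number of repetitions (default 10).
#' @param seed Master seed; repetition r of size k uses a derived seed.
#' @param tolerance F1 tolerance for the elbow rule (default 0.005;
#'   0 degenerates to the argmax).
#' @param ... Passed to [train_ann()].
#' @return The chosen size, with attribute `table` (mean/sd F1 per size).
#' @export
select_hidden_units <- function(features, labels, k_range = 1:15,
                                n_folds = 30L, n_reps = 10L, seed = 1L,
                                tolerance = 0.005, ...) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(features)
  if (n_folds > n) stop("n_folds exceeds number of examples")
  if (length(k_range) == 0L) stop("empty k_range")
  scores <- matrix(NA_real_, nrow = length(k_range), ncol = n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed * 1000L + r)
    fold <- sample(rep_len(seq_len(n_folds), n))
    for (ki in seq_along(k_range)) {
      f1s <- vapply(seq_len(n_folds), function(f) {
        tr <- fold != f
        if (length(unique(labels[tr])) < 2L) return(NA_real_)
        model <- train_ann(features[tr, , drop = FALSE], labels[tr],
                           n_hidden = k_range[ki], seed = seed + r, ...)
        pred <- predict(model, features[!tr, , drop = FALSE])
        classification_metrics(pred, labels[!tr])$f1
      }, numeric(1))
      scores[ki, r] <- mean(f1s, na.rm = TRUE)
    }
  }
  mean_f1 <- rowMeans(scores)
  chosen <- k_range[which(mean_f1 >= max(mean_f1) - tolerance)[1L]]
  attr(chosen, "table") <- data.frame(
    n_hidden = k_range, mean_f1 = mean_f1,
    sd_f1 = apply(scores, 1L, stats::sd)
  )
  chosen
}

#' Save / load a trained classifier as JSON
#'
#' Serializes architecture, weights, scaler, seed and feature names to a
#' single JSON file.
#'
#' @param model A `chew_ann`.
#' @param path Output path.
#' @return `path` (write) or the restored `chew_ann` (read).
#' @export
write_ann <- function(model, path) {
  stopifnot(inherits(model, "chew_ann"))
  obj <- list(
    n_inputs = model$n_inputs, n_hidden = model$n_hidden,
    activation = model$activation, seed = model$seed,
    feature_names = model$feature_names,
    center = unname(model$center), scale = unname(model$scale),
    w1 = model$weights$w1, b1 = model$weights$b1,
    w2 = as.numeric(model$weights$w2), b2 = model$weights$b2
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ann
#' @export
read_ann <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(n_inputs = obj$n_inputs, n_hidden = obj$n_hidden,
         activation = obj$activation,
         weights = list(w1 = matrix(obj$w1, obj$n_inputs, obj$n_hidden,
                                    byrow = FALSE),
                        b1 = obj$b1,
                        w2 = matrix(obj$w2, obj$n_hidden, 1L),
                        b2 = obj$b2),
         center = obj$center, scale = obj$scale,
         feature_names = obj$feature_names, seed = obj$seed,
         train_trace = numeric(0), val_trace = numeric(0)),
    class = "chew_ann"
  )
}
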