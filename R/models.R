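# Model training: random forest and Tanimoto-kernel SVM, a fixed
# hyperparameter grid, random grid search with validation-MCC selection,
# and loss-based tie-breaking (log loss for RF, hinge loss for SVM).
#
# Class label encoding is fixed alphabetically: the first class id maps to
# 0 (RF) / -1 (SVM) and the second to 1 / +1, so orientation is
# deterministic across trials.

#' The fixed hyperparameter grid
#'
#' RF: n_estimators \{100, 500\}, criterion \{gini, entropy\},
#' min_samples_split \{2..5\}, max_features \{sqrt, log2\}, bootstrap
#' \{TRUE, FALSE\} (64 settings). SVM: cost C over 14 distinct values from
#' 0.1 to 10000 and stopping tolerance over \{1e-3, 1e-2, 0.1, 1, 2, 3\}
#' (84 settings).
#'
#' @return List with `RF` and `SVM` setting tables.
#' @export
default_hyperparameter_grid <- function() {
  rf <- expand.grid(
    n_estimators = c(100L, 500L),
    criterion = c("gini", "entropy"),
    min_samples_split = 2:5,
    max_features = c("sqrt", "log2"),
    bootstrap = c(TRUE, FALSE),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  svm <- expand.grid(
    C = c(0.1, 1, 10, 50, 100, 200, 400, 500, 750, 1000, 2500, 5000,
          7500, 10000),
    tol = c(1e-3, 1e-2, 0.1, 1, 2, 3),
    KEEP.OUT.ATTRS = FALSE)
  list(RF = rf, SVM = svm)
}

#' Tanimoto kernel matrix between binary fingerprint sets
#'
#' `K[i, j] = c / (a + b - c)` with `c` the number of shared on-bits and
#' `a`, `b` the on-bit counts of the two fingerprints; defined as 0 when
#' both fingerprints are empty.
#'
#' @param A,B Binary matrices with equal feature dimension (`B` defaults
#'   to `A`).
#' @return Similarity matrix of dimension `nrow(A) x nrow(B)`.
#' @export
tanimoto_kernel <- function(A, B = A) {
  if (is.vector(A)) A <- matrix(A, nrow = 1L)
  if (is.vector(B)) B <- matrix(B, nrow = 1L)
  check_binary_matrix(A, "A")
  check_binary_matrix(B, "B")
  if (ncol(A) != ncol(B)) stop("feature dimensions differ")
  cc <- tcrossprod(A, B)
  denom <- outer(rowSums(A), rowSums(B), "+") - cc
  K <- ifelse(denom == 0, 0, cc / denom)
  dim(K) <- dim(cc)
  K
}

#' Confusion-matrix performance metrics
#'
#' Computes the Matthews correlation coefficient, balanced accuracy, and
#' F1 score. MCC is defined as 0 when any factor of its denominator is 0;
#' a BA term or F1 with zero denominator contributes 0.
#'
#' @param TP,TN,FP,FN Non-negative confusion counts, sum > 0.
#' @return Object of class `performance_report` (list with the counts and
#'   `MCC`, `BA`, `F1`).
#' @export
compute_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("confusion counts must not all be zero")

  den <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  mcc <- if (any(den == 0)) 0 else {
    (TP * TN - FP * FN) / sqrt(prod(den))
  }
  sens <- if (TP + FN == 0) 0 else TP / (TP + FN)
  spec <- if (TN + FP == 0) 0 else TN / (TN + FP)
  ba <- (sens + spec) / 2
  f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)

  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 MCC = mcc, BA = ba, F1 = f1),
            class = "performance_report")
}

#' @export
#' @method print performance_report
print.performance_report <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d | MCC=%.4f BA=%.4f F1=%.4f\n",
              x$TP, x$TN, x$FP, x$FN, x$MCC, x$BA, x$F1))
  invisible(x)
}

#' Tie-breaking loss for hyperparameter selection
#'
#' RF: mean log loss of predicted probabilities (`truths` in \{0, 1\},
#' probabilities clipped at 1e-15). SVM: mean hinge loss of decision
#' values (`truths` in \{-1, 1\}).
#'
#' @param algorithm `"RF"` or `"SVM"`.
#' @param truths True labels in the algorithm's encoding.
#' @param outputs RF probabilities of label 1, or SVM decision values.
#' @return Mean loss.
#' @export
tie_break_loss <- function(algorithm, truths, outputs) {
  algorithm <- match.arg(algorithm, c("RF", "SVM"))
  if (length(truths) != length(outputs)) stop("mismatched lengths")
  if (algorithm == "RF") {
    if (!all(truths %in% c(0, 1))) stop("RF truths must be 0/1")
    eps <- 1e-15
    p <- pmin(pmax(outputs, eps), 1 - eps)
    mean(-(truths * log(p) + (1 - truths) * log(1 - p)))
  } else {
    if (!all(truths %in% c(-1, 1))) stop("SVM truths must be -1/+1")
    mean(pmax(0, 1 - truths * outputs))
  }
}

max_features_mode <- function(mode) {
  switch(mode, sqrt = 0L, log2 = 1L,
         stop("max_features must be 'sqrt' or 'log2'"))
}

fit_rf <- function(X, y01, params, seed) {
  storage.mode(X) <- "integer"
  with_seed(seed, {
    .rf_fit_cpp(X, as.integer(y01), as.integer(params$n_estimators),
                if (params$criterion == "gini") 0L else 1L,
                as.integer(params$min_samples_split),
                max_features_mode(params$max_features),
                isTRUE(params$bootstrap))
  })
}

fit_svm <- function(X, ypm, params) {
  K <- tanimoto_kernel(X)
  .svm_smo_cpp(K, as.integer(ypm), params$C, params$tol,
               max_iter = 500000L)
}

#' Train one model with random grid search
#'
#' Samples up to `n_search` hyperparameter settings uniformly without
#' replacement from the algorithm's grid, fits each on the training set,
#' and selects the setting with the largest validation MCC; ties on MCC
#' are broken by the smaller tie-break loss (log loss for RF, hinge loss
#' for SVM), remaining ties by sampling order. The training fingerprints
#' are retained on the model: the SVM decision function and the RF Shapley
#' background need them.
#'
#' @param job List or one-row data.frame with `algorithm`, `class_a`,
#'   `class_b`, `size`.
#' @param splits A [make_trial_splits()] result.
#' @param pool The `fpshap_dataset` the split ids refer to.
#' @param grid Hyperparameter grid (default [default_hyperparameter_grid()]).
#' @param n_search Number of settings to try (default 50).
#' @param seed Integer seed for the search (defaults to `job$seed`).
#' @return Object of class `fpshap_model`.
#' @export
train_model_with_search <- function(job, splits, pool,
                                    grid = default_hyperparameter_grid(),
                                    n_search = 50L, seed = NULL) {
  algorithm <- match.arg(job$algorithm, c("RF", "SVM"))
  if (n_search < 1L) stop("n_search must be >= 1")
  seed <- seed %||% job$seed
  classes <- sort(c(job$class_a, job$class_b))

  size_key <- as.character(job$size)
  if (!size_key %in% names(splits$sizes)) {
    stop(sprintf("size %s not present in the trial splits", size_key))
  }
  sp <- splits$sizes[[size_key]]
  X <- fingerprint_matrix(pool)
  labels <- pool$labels

  X_train <- X[sp$train, , drop = FALSE]
  y_train <- labels[sp$train]
  X_val <- X[sp$validation, , drop = FALSE]
  y_val <- labels[sp$validation]
  if (length(unique(y_train)) < 2L) {
    stop("degenerate training set: only one class present")
  }

  y01_train <- as.integer(y_train == classes[2L])
  y01_val <- as.integer(y_val == classes[2L])
  ypm_train <- 2L * y01_train - 1L
  ypm_val <- 2L * y01_val - 1L

  settings <- grid[[algorithm]]
  idx <- with_seed(derive_seed(seed, "grid"), {
    sample(nrow(settings), min(n_search, nrow(settings)))
  })

  K_val <- if (algorithm == "SVM") tanimoto_kernel(X_val, X_train) else NULL

  best <- NULL
  for (k in seq_along(idx)) {
    params <- as.list(settings[idx[k], , drop = FALSE])
    if (algorithm == "RF") {
      fit <- fit_rf(X_train, y01_train, params, derive_seed(seed, "fit", k))
      p_val <- .rf_predict_cpp(fit, {
        Xv <- X_val; storage.mode(Xv) <- "integer"; Xv
      })
      pred01 <- as.integer(p_val > 0.5)
      loss <- tie_break_loss("RF", y01_val, p_val)
    } else {
      fit <- fit_svm(X_train, ypm_train, params)
      d_val <- as.vector(K_val %*% (fit$alpha * ypm_train)) + fit$b
      pred01 <- as.integer(d_val > 0)
      loss <- tie_break_loss("SVM", ypm_val, d_val)
    }
    tp <- sum(pred01 == 1L & y01_val == 1L)
    tn <- sum(pred01 == 0L & y01_val == 0L)
    fp <- sum(pred01 == 1L & y01_val == 0L)
    fn <- sum(pred01 == 0L & y01_val == 1L)
    mcc <- compute_metrics(tp, tn, fp, fn)$MCC

    better <- is.null(best) || mcc > best$mcc ||
      (mcc == best$mcc && loss < best$loss)
    if (better) {
      best <- list(fit = fit, params = params, mcc = mcc, loss = loss,
                   order = k)
    }
  }

  structure(
    list(algorithm = algorithm, fit = best$fit, hyperparams = best$params,
         classes = classes, X_train = X_train, y_train = y_train,
         validation_mcc = best$mcc, tie_loss = best$loss,
         seed = seed, size = job$size,
         train_ids = sp$train, validation_ids = sp$validation),
    class = "fpshap_model")
}

#' Predict with a trained model
#'
#' @param object An `fpshap_model`.
#' @param X Binary fingerprint matrix (or single fingerprint vector).
#' @param type `"class"` for class labels, `"score"` for the raw model
#'   output: probability of the alphabetically second class for RF,
#'   decision value for SVM (positive = second class).
#' @param ... Unused.
#' @return Character vector of class labels or numeric scores.
#' @export
predict.fpshap_model <- function(object, X, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  storage.mode(X) <- "integer"
  if (object$algorithm == "RF") {
    score <- .rf_predict_cpp(object$fit, X)
    cls <- ifelse(score > 0.5, object$classes[2L], object$classes[1L])
  } else {
    ypm <- 2L * as.integer(object$y_train == object$classes[2L]) - 1L
    K <- tanimoto_kernel(X, object$X_train)
    score <- as.vector(K %*% (object$fit$alpha * ypm)) + object$fit$b
    cls <- ifelse(score > 0, object$classes[2L], object$classes[1L])
  }
  if (type == "score") score else cls
}

#' Evaluate a model on a test set
#'
#' The alphabetically second class is taken as the positive class of the
#' confusion matrix.
#'
#' @param model An `fpshap_model`.
#' @param X Binary test fingerprints.
#' @param labels True class labels.
#' @return List with `report` (a [compute_metrics()] result),
#'   `predictions`, and `correct` (logical vector).
#' @export
evaluate_model <- function(model, X, labels) {
  pred <- predict(model, X, type = "class")
  pos <- model$classes[2L]
  tp <- sum(pred == pos & labels == pos)
  tn <- sum(pred != pos & labels != pos)
  fp <- sum(pred == pos & labels != pos)
  fn <- sum(pred != pos & labels == pos)
  list(report = compute_metrics(tp, tn, fp, fn), predictions = pred,
       correct = pred == labels)
}

#' @export
#' @method print fpshap_model
print.fpshap_model <- function(x, ...) {
  hp <- paste(names(x$hyperparams),
              vapply(x$hyperparams, as.character, character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("<fpshap_model> %s (%s vs %s), %d train compounds\n  %s\n  validation MCC %.4f, tie-break loss %.4g\n",
              x$algorithm, x$classes[1L], x$classes[2L], nrow(x$X_train),
              hp, x$validation_mcc, x$tie_loss))
  invisible(x)
}
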