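# Exact Shapley value engines.
#
# Three routes are provided: a brute-force enumeration over all feature
# coalitions (the normative reference for small feature counts), a closed
# form for the Tanimoto-kernel SVM game, and an interventional game for
# random forests computed exactly per tree. The closed forms are
# optimizations and must reproduce the brute-force oracle; the test suite
# enforces this equivalence.

new_shapley_explanation <- function(compound_id, values, base_value,
                                    model_output, orientation, classes,
                                    kind) {
  structure(
    list(compound_id = compound_id, values = values,
         base_value = base_value, model_output = model_output,
         orientation = orientation, classes = classes, kind = kind),
    class = "shapley_explanation")
}

#' @export
#' @method print shapley_explanation
print.shapley_explanation <- function(x, ...) {
  cat(sprintf(
    "<shapley_explanation> %s: %d features, base %.4f, output %.4f (positive supports '%s')\n",
    x$compound_id %||% "?", length(x$values), x$base_value, x$model_output,
    x$orientation))
  invisible(x)
}

#' Local accuracy error of an explanation
#'
#' @param expl A `shapley_explanation`.
#' @return `|base_value + sum(values) - model_output|`.
#' @export
local_accuracy_error <- function(expl) {
  abs(expl$base_value + sum(expl$values) - expl$model_output)
}

#' Brute-force Shapley values over an arbitrary coalition game
#'
#' Enumerates all `2^m` coalitions and applies the Shapley formula
#' `phi_j = sum_S |S|! (m - |S| - 1)! / m! * (v(S + j) - v(S))`. This is
#' the normative reference for the exact engines; it is only feasible for
#' small `m`.
#'
#' @param v Value function taking a (possibly empty) integer vector of
#'   1-based feature indices.
#' @param m Number of features.
#' @param max_m Enumeration bound (default 15); larger `m` is refused.
#' @return Numeric vector of length `m`; satisfies
#'   `sum(phi) = v(1:m) - v(integer(0))`.
#' @export
brute_force_shapley <- function(v, m, max_m = 15L) {
  m <- as.integer(m)
  if (m > max_m) {
    stop(sprintf(
      "m = %d exceeds the enumeration bound %d; use the closed-form engines for larger feature sets",
      m, max_m))
  }
  n_masks <- bitwShiftL(1L, m)
  masks <- 0:(n_masks - 1L)
  bits <- bitwShiftL(1L, 0:(m - 1L))

  vals <- vapply(masks, function(mask) {
    v(which(bitwAnd(mask, bits) > 0L))
  }, numeric(1))

  sizes <- integer(n_masks)
  for (b in bits) sizes <- sizes + (bitwAnd(masks, b) > 0L)
  # weight by coalition size |S| (S excludes j)
  w <- exp(lfactorial(0:(m - 1L)) + lfactorial(m - 1L - (0:(m - 1L))) -
             lfactorial(m))

  phi <- numeric(m)
  for (j in seq_len(m)) {
    bit <- bits[j]
    without <- masks[bitwAnd(masks, bit) == 0L]
    s <- sizes[without + 1L]
    phi[j] <- sum(w[s + 1L] * (vals[bitwOr(without, bit) + 1L] -
                                 vals[without + 1L]))
  }
  phi
}

#' Restricted Tanimoto-kernel coalition game
#'
#' The per-support-vector game explained by [svm_tanimoto_shapley()]:
#' for a coalition `S`, the Tanimoto similarity between `x` and `s` is
#' evaluated over the positions in `S` only, with `v(S) = 0` when the
#' restricted denominator is 0 (including the empty coalition).
#'
#' @param x,s Binary fingerprints of equal length.
#' @return A value function suitable for [brute_force_shapley()].
#' @export
tanimoto_restricted_game <- function(x, s) {
  stopifnot(length(x) == length(s))
  force(x); force(s)
  function(S) {
    if (length(S) == 0L) return(0)
    a <- sum(x[S]); b <- sum(s[S]); cc <- sum(x[S] & s[S])
    den <- a + b - cc
    if (den == 0) 0 else cc / den
  }
}

#' Exact Shapley values for a Tanimoto-kernel SVM prediction
#'
#' Explains the decision function `f(x) = sum_i alpha_i y_i K(x, s_i) + b`
#' by linearity over per-support-vector restricted-kernel games (see
#' [tanimoto_restricted_game()]). Features fall into at most four
#' equivalence classes by `(x_j, s_j)`; values are identical within a
#' class and `(0, 0)` features receive exactly 0. The base value is the
#' bias `b`, and local accuracy holds exactly.
#'
#' The returned explanation is oriented so that positive values support
#' the alphabetically first class; the raw decision function (positive =
#' second class) is negated accordingly.
#'
#' @param model An `fpshap_model` with `algorithm == "SVM"`.
#' @param x Binary fingerprint to explain.
#' @param compound_id Optional identifier stored on the explanation.
#' @return A `shapley_explanation` (`kind = "decision"`).
#' @export
svm_tanimoto_shapley <- function(model, x, compound_id = NULL) {
  if (!inherits(model, "fpshap_model") || model$algorithm != "SVM") {
    stop("model must be a Tanimoto-kernel SVM fpshap_model")
  }
  x <- as.integer(x)
  if (!all(x %in% c(0L, 1L))) stop("x must be a binary fingerprint")
  if (length(x) != ncol(model$X_train)) stop("fingerprint length mismatch")

  ypm <- 2L * as.integer(model$y_train == model$classes[2L]) - 1L
  coef <- model$fit$alpha * ypm
  sv <- which(abs(coef) > 0)
  Xtr <- model$X_train
  storage.mode(Xtr) <- "integer"

  phi <- if (length(sv) > 0L) {
    .tanimoto_shap_cpp(x, Xtr[sv, , drop = FALSE], coef[sv])
  } else {
    numeric(length(x))
  }
  fx <- sum(coef[sv] * as.vector(tanimoto_kernel(
    matrix(x, nrow = 1L), Xtr[sv, , drop = FALSE]))) + model$fit$b

  # orient to the alphabetically first class
  new_shapley_explanation(
    compound_id = compound_id, values = -phi, base_value = -model$fit$b,
    model_output = -fx, orientation = model$classes[1L],
    classes = model$classes, kind = "decision")
}

#' Exact interventional Shapley values for a random forest prediction
#'
#' Explains the predicted probability of the alphabetically first class
#' under the interventional game: `v(S)` is the mean, over background
#' fingerprints `z`, of the forest probability of the composite that takes
#' `x` on `S` and `z` elsewhere. The computation is exact per tree (each
#' reachable leaf contributes a closed-form term) and aggregated over the
#' ensemble; the base value is the mean background probability.
#'
#' @param model An `fpshap_model` with `algorithm == "RF"`.
#' @param x Binary fingerprint to explain.
#' @param background Background fingerprint matrix (default: the model's
#'   training set). Must be non-empty.
#' @param compound_id Optional identifier stored on the explanation.
#' @return A `shapley_explanation` (`kind = "probability"`).
#' @export
rf_tree_shapley <- function(model, x, background = NULL, compound_id = NULL) {
  if (!inherits(model, "fpshap_model") || model$algorithm != "RF") {
    stop("model must be a random forest fpshap_model")
  }
  x <- as.integer(x)
  if (!all(x %in% c(0L, 1L))) stop("x must be a binary fingerprint")
  background <- background %||% model$X_train
  if (is.vector(background)) background <- matrix(background, nrow = 1L)
  if (nrow(background) == 0L) stop("background must be non-empty")
  storage.mode(background) <- "integer"

  res <- .rf_shap_cpp(model$fit, x, background)

  # raw values explain P(second class); orient to the first class
  new_shapley_explanation(
    compound_id = compound_id, values = -res$phi,
    base_value = 1 - res$base, model_output = 1 - res$output,
    orientation = model$classes[1L], classes = model$classes,
    kind = "probability")
}

#' Orient an explanation toward a compound's own class
#'
#' Flips the sign convention if `true_class` differs from the
#' explanation's current orientation, so that positive values always mean
#' "supports the compound's own class". Probability explanations map base
#' and output through `1 - p`; decision explanations are negated.
#'
#' @param expl A `shapley_explanation`.
#' @param true_class The compound's class label.
#' @return The oriented `shapley_explanation`.
#' @export
orient_explanation <- function(expl, true_class) {
  stopifnot(inherits(expl, "shapley_explanation"))
  true_class <- unname(as.character(true_class))
  if (!true_class %in% expl$classes) {
    stop(sprintf("unknown class id '%s'", true_class))
  }
  if (identical(true_class, expl$orientation)) return(expl)
  expl$values <- -expl$values
  if (expl$kind == "probability") {
    expl$base_value <- 1 - expl$base_value
    expl$model_output <- 1 - expl$model_output
  } else {
    expl$base_value <- -expl$base_value
    expl$model_output <- -expl$model_output
  }
  expl$orientation <- true_class
  expl
}
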