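# Analysis layer: prediction-pattern taxonomy, cumulative Shapley
# aggregation (instance- and feature-based), the feature contribution
# score f_cs, Pearson correlations with model performance, combined PCC
# values, feature-contribution patterns, and top-k feature intersections.

PREDICTION_PATTERNS <- c("consistently_correct", "consistently_incorrect",
                         "start_correct_end_incorrect",
                         "start_incorrect_end_correct", "variable")

#' Classify a per-compound correctness vector
#'
#' The bits record, over the training-size schedule, whether the compound
#' was predicted correctly (1) or not (0). All-ones and all-zeros map to
#' the consistent categories; a single 1->0 or 0->1 transition maps to the
#' start/end categories; everything else is variable.
#'
#' @param bits Non-empty binary vector.
#' @return One of `"consistently_correct"`, `"consistently_incorrect"`,
#'   `"start_correct_end_incorrect"`, `"start_incorrect_end_correct"`,
#'   `"variable"`.
#' @export
classify_prediction_pattern <- function(bits) {
  if (length(bits) == 0L) stop("bits must be non-empty")
  if (any(is.na(bits)) || !all(bits %in% c(0, 1))) {
    stop("bits must be binary")
  }
  if (all(bits == 1)) return("consistently_correct")
  if (all(bits == 0)) return("consistently_incorrect")
  d <- diff(bits)
  if (all(d <= 0)) return("start_correct_end_incorrect")
  if (all(d >= 0)) return("start_incorrect_end_correct")
  "variable"
}

#' Tabulate prediction patterns for RF vs SVM
#'
#' @param records `data.frame` with columns `compound_id`, `pair`,
#'   `trial`, `algorithm` (RF/SVM) and `category`; RF and SVM must cover
#'   identical `(compound_id, pair, trial)` keys.
#' @return `data.frame` with, per category: pattern counts and distinct
#'   compound counts for RF and SVM, the exact intersection (same category
#'   on the same key), and the intersection as a percentage of the RF
#'   count.
#' @export
pattern_tabulate <- function(records) {
  need <- c("compound_id", "pair", "trial", "algorithm", "category")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  key <- function(df) paste(df$compound_id, df$pair, df$trial, sep = "\r")
  rf <- records[records$algorithm == "RF", , drop = FALSE]
  svm <- records[records$algorithm == "SVM", , drop = FALSE]
  if (!setequal(key(rf), key(svm)) ||
      anyDuplicated(key(rf)) || anyDuplicated(key(svm))) {
    stop("RF and SVM must cover identical (compound, pair, trial) keys")
  }
  svm <- svm[match(key(rf), key(svm)), , drop = FALSE]

  out <- lapply(PREDICTION_PATTERNS, function(cat) {
    in_rf <- rf$category == cat
    in_svm <- svm$category == cat
    both <- in_rf & in_svm
    data.frame(
      category = cat,
      rf_patterns = sum(in_rf), svm_patterns = sum(in_svm),
      intersection_patterns = sum(both),
      patterns_pct = if (sum(in_rf) > 0) 100 * sum(both) / sum(in_rf)
                     else NA_real_,
      rf_compounds = length(unique(rf$compound_id[in_rf])),
      svm_compounds = length(unique(svm$compound_id[in_svm])),
      intersection_compounds = length(unique(rf$compound_id[both])),
      compounds_pct = if (length(unique(rf$compound_id[in_rf])) > 0)
        100 * length(unique(rf$compound_id[both])) /
          length(unique(rf$compound_id[in_rf])) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Instance-based cumulative Shapley values
#'
#' Splits the oriented feature attributions of one compound by feature
#' status: `cs_present` sums values over on-bits, `cs_absent` over
#' off-bits. Their sum equals `model_output - base_value` (efficiency).
#'
#' @param expl An oriented `shapley_explanation`.
#' @param x The compound's binary fingerprint.
#' @return List with `compound_id`, `cs_present`, `cs_absent`.
#' @export
instance_cumulative <- function(expl, x) {
  if (length(expl$values) != length(x)) stop("length mismatch")
  list(compound_id = expl$compound_id,
       cs_present = sum(expl$values[x == 1]),
       cs_absent = sum(expl$values[x == 0]))
}

#' Feature contribution score
#'
#' `f_cs` is the difference between the median instance-based cumulative
#' Shapley value for present features and for absent features over the
#' correctly predicted test compounds of one class under one model. A
#' positive score indicates higher importance of present than absent
#' features; a score near 0 indicates comparable contributions.
#'
#' @param cumulatives `data.frame` (or list of [instance_cumulative()]
#'   results) with elements `cs_present` and `cs_absent`.
#' @return `f_cs`, or `NA_real_` (with a warning) when no correctly
#'   predicted compound is available.
#' @export
feature_contribution_score <- function(cumulatives) {
  if (!is.data.frame(cumulatives)) {
    cumulatives <- data.frame(
      cs_present = vapply(cumulatives, `[[`, numeric(1), "cs_present"),
      cs_absent = vapply(cumulatives, `[[`, numeric(1), "cs_absent"))
  }
  if (nrow(cumulatives) == 0L) {
    warning("no correctly predicted compounds; f_cs undefined")
    return(NA_real_)
  }
  stats::median(cumulatives$cs_present) - stats::median(cumulatives$cs_absent)
}

#' Pearson correlation between feature contribution scores and MCC
#'
#' @param xs,ys Equal-length numeric vectors (length >= 2); by convention
#'   `xs` holds `f_cs` values and `ys` the matching model MCC values.
#' @return Product-moment correlation, or `NA_real_` when either variance
#'   is 0.
#' @export
pearson_cc <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("length mismatch")
  if (length(xs) < 2L) stop("need at least two observations")
  if (stats::var(xs) == 0 || stats::var(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

#' Combine the two per-class PCC values of an activity class pair
#'
#' RF combines absolute values (`|PCC1| + |PCC2|`); SVM combines signed
#' values (`PCC1 + PCC2`), so that both can be read against the same
#' threshold of 1.
#'
#' @param pcc1,pcc2 Per-class PCC values.
#' @param algorithm `"RF"` or `"SVM"`.
#' @return Combined value, `NA_real_` if either input is undefined.
#' @export
combined_pcc <- function(pcc1, pcc2, algorithm) {
  algorithm <- match.arg(algorithm, c("RF", "SVM"))
  if (is.na(pcc1) || is.na(pcc2)) return(NA_real_)
  if (algorithm == "RF") abs(pcc1) + abs(pcc2) else pcc1 + pcc2
}

#' Classify the feature contribution pattern of a class pair
#'
#' Pattern 1 (present *or* absent features decisive) occurs only for RF,
#' pattern 3 (*only* present features decisive) only for SVM; pattern 2
#' (present *and* absent) occurs for both. By default a combined PCC at or
#' above the threshold yields the algorithm-specific pattern (1 for RF, 3
#' for SVM) and a value below it yields pattern 2, following the
#' per-pattern PCC magnitudes; `above_is_specific = FALSE` swaps the
#' orientation.
#'
#' @param pcc1,pcc2 Per-class PCC values.
#' @param combined The [combined_pcc()] value.
#' @param algorithm `"RF"` or `"SVM"`.
#' @param threshold Decision threshold (default 1).
#' @param above_is_specific Orientation switch, see above.
#' @return Integer pattern label in \{1, 2, 3\}.
#' @export
classify_fc_pattern <- function(pcc1, pcc2, combined, algorithm,
                                threshold = 1.0, above_is_specific = TRUE) {
  algorithm <- match.arg(algorithm, c("RF", "SVM"))
  if (is.na(combined)) return(NA_integer_)
  specific <- if (algorithm == "RF") 1L else 3L
  above <- combined >= threshold
  if (identical(above, above_is_specific)) specific else 2L
}

#' Feature-based cumulative Shapley values
#'
#' Restricted to correctly predicted instances, each instance's oriented
#' attribution vector is normalized to absolute sum 1 and the normalized
#' values are then summed per feature and status (present/absent) within
#' the instance's class. Instances with an all-zero attribution vector are
#' skipped and counted.
#'
#' @param explanations List of oriented `shapley_explanation` objects.
#' @param X Binary fingerprint matrix aligned with `explanations`.
#' @param correct Logical vector: was the instance predicted correctly?
#' @param classes Character vector of the instances' (true) class labels.
#' @return Object of class `feature_cumulative`: per class, vectors
#'   `present` and `absent` of summed normalized values, occurrence counts
#'   `occ_present`/`occ_absent`, and instance counts. `NULL` elements mark
#'   classes without usable instances.
#' @export
feature_cumulative <- function(explanations, X, correct, classes) {
  n <- length(explanations)
  stopifnot(nrow(X) == n, length(correct) == n, length(classes) == n)
  m <- ncol(X)
  cls_ids <- sort(unique(classes))
  acc <- lapply(cls_ids, function(cl) {
    list(present = numeric(m), absent = numeric(m),
         occ_present = integer(m), occ_absent = integer(m),
         n_instances = 0L, n_skipped = 0L)
  })
  names(acc) <- cls_ids

  any_used <- FALSE
  for (i in seq_len(n)) {
    if (!correct[i]) next
    cl <- classes[i]
    phi <- explanations[[i]]$values
    tot <- sum(abs(phi))
    if (tot == 0) {
      acc[[cl]]$n_skipped <- acc[[cl]]$n_skipped + 1L
      next
    }
    nv <- phi / tot
    present <- X[i, ] == 1
    acc[[cl]]$present[present] <- acc[[cl]]$present[present] + nv[present]
    acc[[cl]]$absent[!present] <- acc[[cl]]$absent[!present] + nv[!present]
    acc[[cl]]$occ_present <- acc[[cl]]$occ_present + as.integer(present)
    acc[[cl]]$occ_absent <- acc[[cl]]$occ_absent + as.integer(!present)
    acc[[cl]]$n_instances <- acc[[cl]]$n_instances + 1L
    any_used <- TRUE
  }
  if (!any_used) {
    warning("all instances skipped; empty feature cumulative")
  }
  structure(list(classes = cls_ids, per_class = acc, n_features = m),
            class = "feature_cumulative")
}

top_k_features <- function(values, k) {
  nonzero <- which(values != 0)
  if (length(nonzero) < k) {
    ord <- nonzero[order(-values[nonzero], nonzero)]
    return(ord)
  }
  ord <- order(-values, seq_along(values))  # ties at rank k -> lower index
  ord[seq_len(k)]
}

#' Top-k feature intersection across models
#'
#' For each model the `k` features with the largest feature-based
#' cumulative Shapley values are ranked per class and status (present or
#' absent; ties broken by feature index), and the intersection of these
#' top sets across all models is formed. When fewer than `k` features have
#' nonzero cumulative values, all nonzero features are used.
#'
#' @param cumulatives List (>= 2) of [feature_cumulative()] objects, one
#'   per model.
#' @param k Set size (default 15).
#' @return Nested list: per class, per status, the intersection (integer
#'   feature indices); per-model top sets are attached as attribute
#'   `"top_sets"`.
#' @export
top_k_feature_intersection <- function(cumulatives, k = 15L) {
  if (length(cumulatives) < 2L) stop("need at least two models")
  cls_ids <- cumulatives[[1L]]$classes
  top_sets <- lapply(cumulatives, function(fc) {
    per_cls <- lapply(cls_ids, function(cl) {
      list(present = top_k_features(fc$per_class[[cl]]$present, k),
           absent = top_k_features(fc$per_class[[cl]]$absent, k))
    })
    names(per_cls) <- cls_ids
    per_cls
  })
  out <- lapply(cls_ids, function(cl) {
    list(
      present = Reduce(intersect,
                       lapply(top_sets, function(ts) ts[[cl]]$present)),
      absent = Reduce(intersect,
                      lapply(top_sets, function(ts) ts[[cl]]$absent)))
  })
  names(out) <- cls_ids
  attr(out, "top_sets") <- top_sets
  out
}
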