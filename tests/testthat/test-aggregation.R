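test_that("prediction patterns classify anchor vectors", {
  expect_identical(classify_prediction_pattern(rep(1, 12)),
                   "consistently_correct")
  expect_identical(classify_prediction_pattern(rep(0, 12)),
                   "consistently_incorrect")
  expect_identical(classify_prediction_pattern(c(0, 0, 0, rep(1, 9))),
                   "start_incorrect_end_correct")
  expect_identical(classify_prediction_pattern(c(rep(1, 4), rep(0, 8))),
                   "start_correct_end_incorrect")
  expect_identical(classify_prediction_pattern(c(1, 0, 1, 0)), "variable")
  expect_error(classify_prediction_pattern(c(1, 2)), "binary")
  expect_error(classify_prediction_pattern(numeric(0)), "non-empty")
})

test_that("the pattern rule partitions all binary vectors", {
  # exhaustive over 6-bit vectors: 1 + 1 + 5 + 5 + 52
  n <- 6
  cats <- vapply(0:(2^n - 1), function(mask) {
    bits <- as.integer(intToBits(mask))[1:n]
    classify_prediction_pattern(bits)
  }, character(1))
  counts <- table(factor(cats, levels = c(
    "consistently_correct", "consistently_incorrect",
    "start_correct_end_incorrect", "start_incorrect_end_correct",
    "variable")))
  expect_equal(unname(as.integer(counts)), c(1, 1, 5, 5, 52))
})

make_pattern_log <- function(cat_rf, cat_svm) {
  n <- length(cat_rf)
  rbind(
    data.frame(compound_id = sprintf("c%d", 1:n), pair = "A|B", trial = 1,
               algorithm = "RF", category = cat_rf,
               stringsAsFactors = FALSE),
    data.frame(compound_id = sprintf("c%d", 1:n), pair = "A|B", trial = 1,
               algorithm = "SVM", category = cat_svm,
               stringsAsFactors = FALSE))
}

test_that("pattern tabulation counts patterns, compounds, intersections", {
  cats <- c("consistently_correct", "variable", "consistently_correct")
  tab <- pattern_tabulate(make_pattern_log(cats, cats))
  cc <- tab[tab$category == "consistently_correct", ]
  expect_equal(cc$rf_patterns, 2)
  expect_equal(cc$intersection_patterns, 2)
  expect_equal(cc$patterns_pct, 100)
  expect_equal(cc$rf_compounds, 2)

  # disjoint categories: zero intersection both ways
  tab2 <- pattern_tabulate(make_pattern_log(
    "variable", "consistently_correct"))
  expect_equal(tab2$intersection_patterns[tab2$category == "variable"], 0)
  expect_equal(
    tab2$intersection_patterns[tab2$category == "consistently_correct"], 0)

  # hand-built 3-compound fixture
  rf <- c("consistently_correct", "start_incorrect_end_correct", "variable")
  svm <- c("consistently_correct", "variable", "variable")
  tab3 <- pattern_tabulate(make_pattern_log(rf, svm))
  expect_equal(tab3$rf_patterns,
               c(1, 0, 0, 1, 1))
  expect_equal(tab3$svm_patterns, c(1, 0, 0, 0, 2))
  expect_equal(tab3$intersection_patterns, c(1, 0, 0, 0, 1))
  # conservation: per algorithm, categories sum to the key count
  expect_equal(sum(tab3$rf_patterns), 3)
  expect_equal(sum(tab3$svm_patterns), 3)

  # mismatched keys are refused
  bad <- make_pattern_log(rf, svm)
  bad <- bad[-1, ]
  expect_error(pattern_tabulate(bad), "identical")
})

test_that("instance cumulatives split efficiency by feature status", {
  e <- fpshap:::new_shapley_explanation(
    "c1", values = c(0.2, -0.1, 0.3), base_value = 0.1,
    model_output = 0.5, orientation = "A", classes = c("A", "B"),
    kind = "probability")
  ic <- instance_cumulative(e, c(1, 0, 1))
  expect_equal(ic$cs_present, 0.5)
  expect_equal(ic$cs_absent, -0.1)
  expect_equal(ic$cs_present + ic$cs_absent,
               e$model_output - e$base_value)
  expect_equal(instance_cumulative(e, c(0, 0, 0))$cs_present, 0)
  expect_error(instance_cumulative(e, c(1, 0)), "mismatch")
})

test_that("f_cs is the difference of medians", {
  cum <- data.frame(cs_present = c(0.4, 0.4, 0.4),
                    cs_absent = c(0.1, 0.1, 0.1))
  expect_equal(feature_contribution_score(cum), 0.3)

  cum5 <- data.frame(cs_present = c(0.1, 0.5, 0.3, 0.9, 0.2),
                     cs_absent = c(-0.2, 0.0, -0.4, 0.1, -0.1))
  expect_equal(feature_contribution_score(cum5),
               median(cum5$cs_present) - median(cum5$cs_absent))

  same <- data.frame(cs_present = c(0.2, 0.3), cs_absent = c(0.3, 0.2))
  expect_equal(feature_contribution_score(same), 0)

  expect_warning(
    out <- feature_contribution_score(data.frame(cs_present = numeric(),
                                                 cs_absent = numeric())),
    "undefined")
  expect_true(is.na(out))
})

test_that("PCC handles linearity, degeneracy, and the hand-computed case", {
  xs <- c(0.1, 0.4, 0.9)
  expect_equal(pearson_cc(xs, 2 * xs + 1), 1)
  expect_true(is.na(pearson_cc(xs, c(2, 2, 2))))
  # closed form: cov = 2, var_x = 2, var_y = 14/3 -> r = sqrt(3/7)
  expect_equal(pearson_cc(c(1, 2, 3), c(2, 1, 4)), sqrt(3 / 7))
  expect_error(pearson_cc(1:3, 1:4), "mismatch")
})

test_that("combined PCC follows the per-algorithm formulas", {
  expect_equal(combined_pcc(0.7, -0.6, "RF"), 1.3)
  expect_equal(combined_pcc(0.7, -0.6, "SVM"), 0.1, tolerance = 1e-12)
  expect_equal(combined_pcc(0, 0, "RF"), 0)
  expect_equal(combined_pcc(0, 0, "SVM"), 0)
  expect_true(is.na(combined_pcc(NA, 0.5, "RF")))
})

test_that("FC patterns respect the observed-only-for constraints", {
  # RF, strong opposite correlations -> pattern 1
  expect_equal(classify_fc_pattern(0.6, -0.6, combined_pcc(0.6, -0.6, "RF"),
                                   "RF"), 1L)
  # SVM, both strongly positive -> pattern 3
  expect_equal(classify_fc_pattern(0.6, 0.6, combined_pcc(0.6, 0.6, "SVM"),
                                   "SVM"), 3L)
  # RF, one positive one near zero -> pattern 2
  expect_equal(classify_fc_pattern(0.55, 0.02,
                                   combined_pcc(0.55, 0.02, "RF"), "RF"), 2L)
  # pattern 3 never for RF, pattern 1 never for SVM
  for (p1 in seq(-1, 1, by = 0.25)) for (p2 in seq(-1, 1, by = 0.25)) {
    expect_false(identical(classify_fc_pattern(
      p1, p2, combined_pcc(p1, p2, "RF"), "RF"), 3L))
    expect_false(identical(classify_fc_pattern(
      p1, p2, combined_pcc(p1, p2, "SVM"), "SVM"), 1L))
  }
  # orientation switch swaps the mapping
  expect_equal(classify_fc_pattern(0.6, -0.6, 1.2, "RF",
                                   above_is_specific = FALSE), 2L)
})

make_expl <- function(values, id = "c") {
  fpshap:::new_shapley_explanation(
    id, values = values, base_value = 0, model_output = sum(values),
    orientation = "A", classes = c("A", "B"), kind = "decision")
}

test_that("feature cumulatives normalize each instance to absolute sum 1", {
  # phi = (0.6, -0.2): |sum| = 0.8 -> normalized (0.75, -0.25)
  fc <- feature_cumulative(list(make_expl(c(0.6, -0.2))),
                           X = rbind(c(1L, 0L)), correct = TRUE,
                           classes = "A")
  expect_equal(fc$per_class$A$present, c(0.75, 0))
  expect_equal(fc$per_class$A$absent, c(0, -0.25))
  expect_equal(fc$per_class$A$occ_present, c(1L, 0L))

  # two identical instances double the sums
  fc2 <- feature_cumulative(
    list(make_expl(c(0.6, -0.2)), make_expl(c(0.6, -0.2))),
    X = rbind(c(1L, 0L), c(1L, 0L)), correct = c(TRUE, TRUE),
    classes = c("A", "A"))
  expect_equal(fc2$per_class$A$present, 2 * fc$per_class$A$present)

  # incorrect predictions are excluded
  fc3 <- feature_cumulative(
    list(make_expl(c(0.6, -0.2)), make_expl(c(9, 9))),
    X = rbind(c(1L, 0L), c(1L, 1L)), correct = c(TRUE, FALSE),
    classes = c("A", "A"))
  expect_equal(fc3$per_class$A$present, fc$per_class$A$present)

  # all-zero attribution vectors are skipped, not divided by zero
  expect_warning(
    fc4 <- feature_cumulative(list(make_expl(c(0, 0))),
                              X = rbind(c(1L, 0L)), correct = TRUE,
                              classes = "A"),
    "skipped")
  expect_equal(fc4$per_class$A$n_skipped, 1L)
})

test_that("normalized vectors have absolute sum exactly 1", {
  set.seed(41)
  for (rep in 1:20) {
    phi <- rnorm(12)
    nv <- phi / sum(abs(phi))
    expect_equal(sum(abs(nv)), 1, tolerance = 1e-12)
  }
})

test_that("top-k intersections handle identical and disjoint rankings", {
  mk_fc <- function(present_a) {
    structure(list(
      classes = "A",
      per_class = list(A = list(present = present_a,
                                absent = rev(present_a),
                                occ_present = integer(8),
                                occ_absent = integer(8),
                                n_instances = 1L, n_skipped = 0L)),
      n_features = 8L), class = "feature_cumulative")
  }
  vals <- c(8, 7, 6, 5, 4, 3, 2, 1)
  same <- top_k_feature_intersection(list(mk_fc(vals), mk_fc(vals)), k = 3)
  expect_equal(sort(same$A$present), 1:3)

  disjoint <- top_k_feature_intersection(
    list(mk_fc(c(8, 7, 6, 0, 0, 0, 0, 0)),
         mk_fc(c(0, 0, 0, 0, 0, 6, 7, 8))), k = 3)
  expect_length(disjoint$A$present, 0)

  # fewer than k nonzero values: all nonzero used
  few <- top_k_feature_intersection(
    list(mk_fc(c(1, 2, 0, 0, 0, 0, 0, 0)),
         mk_fc(c(2, 1, 0, 0, 0, 0, 0, 0))), k = 5)
  expect_setequal(few$A$present, 1:2)

  expect_error(top_k_feature_intersection(list(mk_fc(vals))), "two models")
})
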