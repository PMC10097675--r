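test_that("brute force satisfies the dummy and linearity anchors", {
  # constant game: all values 0
  expect_equal(brute_force_shapley(function(S) 3.7, m = 5), rep(0, 5))

  # additive game: values are the weights
  w <- c(0.3, -1.2, 0.8, 0)
  v <- function(S) sum(w[S])
  expect_equal(brute_force_shapley(v, m = 4), w)

  # restricted Tanimoto game with x = s, m = 4: only the empty coalition
  # yields a nonzero marginal, weight 1/m
  x <- rep(1L, 4)
  expect_equal(brute_force_shapley(tanimoto_restricted_game(x, x), m = 4),
               rep(1 / 4, 4))

  expect_error(brute_force_shapley(function(S) 0, m = 16), "bound")
})

test_that("brute force satisfies efficiency on random games", {
  set.seed(31)
  for (rep in 1:5) {
    m <- sample(3:8, 1)
    vals <- rnorm(2^m)
    v <- function(S) vals[sum(2^(S - 1)) + 1]
    phi <- brute_force_shapley(v, m)
    expect_equal(sum(phi), v(seq_len(m)) - v(integer(0)), tolerance = 1e-10)
  }
})

test_that("SVM explanation anchors: dummy features and the self support vector", {
  m <- 8
  # all features (0,0): explanation is all zeros, output is the bias
  s <- rep(0L, m)
  model <- manual_svm_model(rbind(s), coef = 1, b = 0.3)
  e <- svm_tanimoto_shapley(model, rep(0L, m))
  expect_equal(e$values, rep(0, m))
  expect_equal(e$model_output, -0.3)  # oriented: positive supports class A
  expect_equal(e$base_value, -0.3)

  # single support vector equal to x, coef 1, b = 0: phi_j = 1/m on the
  # present features (oriented sign: supports class B -> negative for A)
  x <- c(1L, 1L, 0L, 1L, 0L)
  model <- manual_svm_model(rbind(x), coef = 1, b = 0)
  e <- svm_tanimoto_shapley(model, x)
  expected <- ifelse(x == 1, -1 / sum(x), 0)
  expect_equal(e$values, expected)
  expect_equal(local_accuracy_error(e), 0, tolerance = 1e-12)
})

test_that("SVM explanations match brute force on random cases", {
  set.seed(19)
  for (rep in 1:25) {
    m <- sample(4:10, 1)
    x <- as.integer(runif(m) < 0.5)
    nsv <- sample(1:3, 1)
    S <- matrix(as.integer(runif(nsv * m) < 0.5), nrow = nsv)
    coef <- rnorm(nsv)
    b <- rnorm(1)
    model <- manual_svm_model(S, coef, b)
    e <- svm_tanimoto_shapley(model, x)
    phi_bf <- brute_force_shapley(svm_decision_game(x, S, coef), m)
    expect_equal(e$values, -phi_bf, tolerance = 1e-10)
    expect_lt(local_accuracy_error(e), 1e-10)
  }
})

test_that("SVM values respect the four feature equivalence classes", {
  set.seed(23)
  x <- as.integer(runif(20) < 0.5)
  S <- matrix(as.integer(runif(40) < 0.5), nrow = 2)
  model <- manual_svm_model(S, c(0.8, -0.5), b = 0.1)
  e <- svm_tanimoto_shapley(model, x)
  # per support vector the value depends only on (x_j, s_j); with two
  # support vectors, features sharing both patterns must agree exactly
  key <- paste(x, S[1, ], S[2, ])
  for (k in unique(key)) {
    vals <- e$values[key == k]
    expect_equal(max(vals) - min(vals), 0)
  }
  # (0,0) across all support vectors is an exact dummy
  dummy <- x == 0 & colSums(S) == 0
  if (any(dummy)) expect_equal(e$values[dummy], rep(0, sum(dummy)))
})

test_that("RF stump anchors behave per the interventional game", {
  m <- 6
  # stump on feature 3 (leaves 0.2 / 0.8); node layout: root, left, right
  forest <- manual_forest(feature = c(2L, -1L, -1L), left = c(1L, -1L, -1L),
                          right = c(2L, -1L, -1L),
                          value = c(0.5, 0.2, 0.8), n_features = m)
  X_train <- matrix(0L, nrow = 2, ncol = m)
  model <- manual_rf_model(forest, X_train)

  # x and all background on the same side: no feature can move the leaf
  x <- rep(0L, m)
  bg_same <- matrix(0L, nrow = 3, ncol = m)
  e <- rf_tree_shapley(model, x, bg_same)
  expect_equal(e$values, rep(0, m))

  # background balanced across the split: phi_3 carries output - base
  x1 <- rep(0L, m); x1[3] <- 1L
  bg <- matrix(0L, nrow = 2, ncol = m); bg[2, 3] <- 1L
  e <- rf_tree_shapley(model, x1, bg)
  raw <- -e$values  # undo orientation to the probability of class B
  expect_equal(raw[3], 0.8 - 0.5)
  expect_equal(raw[-3], rep(0, m - 1))
  expect_lt(local_accuracy_error(e), 1e-12)
})

test_that("RF explanations match brute force on random small forests", {
  set.seed(29)
  for (rep in 1:10) {
    m <- sample(4:8, 1)
    n <- 40
    X <- matrix(as.integer(runif(n * m) < 0.5), nrow = n)
    y <- as.integer(xor(X[, 1], X[, 2]) | (runif(n) < 0.15))
    forest <- with_fixed_seed(100 + rep, {
      fpshap:::.rf_fit_cpp(X, y, 4L, rep %% 2L, 5L, 0L, TRUE)
    })
    model <- manual_rf_model(forest, X)
    x <- as.integer(runif(m) < 0.5)
    Z <- matrix(as.integer(runif(4 * m) < 0.5), nrow = 4)
    e <- rf_tree_shapley(model, x, Z)
    phi_bf <- brute_force_shapley(rf_interventional_game(forest, x, Z), m)
    expect_equal(e$values, -phi_bf, tolerance = 1e-10)
    expect_lt(local_accuracy_error(e), 1e-10)
  }
})

test_that("orientation flips signs consistently", {
  x <- c(1L, 1L, 0L, 1L)
  model <- manual_svm_model(rbind(x), coef = 1, b = 0.05)
  e <- svm_tanimoto_shapley(model, x, compound_id = "c1")
  expect_identical(orient_explanation(e, "A"), e)
  eb <- orient_explanation(e, "B")
  expect_equal(eb$values, -e$values)
  expect_equal(eb$model_output, -e$model_output)
  expect_identical(eb$orientation, "B")
  expect_error(orient_explanation(e, "C"), "unknown class")

  # probability explanations map through 1 - p
  ds <- tiny_dataset(n_features = 16, n_per_class = 40, n_planted = 3,
                     seed = 5)
  d <- design_spec(class_ids = c("A", "B"), size_schedule = 15,
                   n_trials = 1, test_per_class = 10, master_seed = 9)
  sp <- make_trial_splits(ds, d, c("A", "B"), 1)
  job <- list(job_id = 1, pair_id = "A|B", class_a = "A", class_b = "B",
              size = 15, trial = 1, algorithm = "RF", seed = 14)
  mrf <- train_model_with_search(job, sp, ds, n_search = 5)
  X <- fingerprint_matrix(ds)
  ev <- evaluate_model(mrf, X[sp$test, ], ds$labels[sp$test])
  for (i in seq_along(sp$test)) {
    e <- rf_tree_shapley(mrf, X[sp$test[i], ])
    o <- orient_explanation(e, ds$labels[[sp$test[i]]])
    expect_lt(local_accuracy_error(o), 1e-8)
    if (ev$correct[i]) {
      # correctly predicted: oriented output exceeds the 0.5 threshold
      expect_gt(o$model_output, 0.5)
      expect_gt(o$base_value + sum(o$values), 0.5)
    }
  }
})
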