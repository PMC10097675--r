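# Fixtures shared across the suite. Everything is generated in code; no
# data files.

with_fixed_seed <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# small planted-structure dataset
tiny_dataset <- function(n_features = 32L, n_per_class = 60L,
                         n_planted = 6L, seed = 3L, ...) {
  spec <- synthetic_pair_spec(
    n_features = n_features, n_per_class = n_per_class,
    planted_a = seq_len(n_planted),
    planted_b = n_planted + seq_len(n_planted), seed = seed, ...)
  generate_class_pair(spec)
}

clean_record <- function(id = "cpd", mass = 500, ppot = 6.2, conf = 9L,
                         type = "Ki", ...) {
  compound_record(id, "A",
                  annotations = potency_annotations(
                    rep(type, length(ppot)), ppot, rep(conf, length(ppot))),
                  molecular_mass = mass, ...)
}

# hand-built SVM model around given support vectors and dual coefficients
# coef[i] = alpha_i * y_i; b is the bias of the decision function
manual_svm_model <- function(S, coef, b = 0) {
  storage.mode(S) <- "integer"
  y <- ifelse(coef >= 0, "B", "A")
  structure(
    list(algorithm = "SVM",
         fit = list(alpha = abs(coef), b = b),
         hyperparams = list(C = 1, tol = 1e-3),
         classes = c("A", "B"), X_train = S, y_train = y,
         validation_mcc = NA_real_, tie_loss = NA_real_, seed = 0L),
    class = "fpshap_model")
}

# hand-built single-tree forest; nodes given as parallel vectors
manual_forest <- function(feature, left, right, value, n_features) {
  list(trees = list(list(
    feature = as.integer(feature), left = as.integer(left),
    right = as.integer(right), value = as.numeric(value),
    nsamp = rep(0L, length(feature)))),
    n_features = as.integer(n_features))
}

manual_rf_model <- function(forest, X_train) {
  storage.mode(X_train) <- "integer"
  structure(
    list(algorithm = "RF", fit = forest,
         hyperparams = list(n_estimators = 1L),
         classes = c("A", "B"), X_train = X_train,
         y_train = rep(c("A", "B"), length.out = nrow(X_train)),
         validation_mcc = NA_real_, tie_loss = NA_real_, seed = 0L),
    class = "fpshap_model")
}

# interventional value function of a forest for brute_force_shapley
rf_interventional_game <- function(forest, x, Z) {
  force(forest); force(x); force(Z)
  function(S) {
    comp <- Z
    if (length(S) > 0L) {
      for (r in seq_len(nrow(Z))) comp[r, S] <- x[S]
    }
    storage.mode(comp) <- "integer"
    mean(fpshap:::.rf_predict_cpp(forest, comp))
  }
}

# full SVM decision-function game: sum of restricted Tanimoto games
svm_decision_game <- function(x, S, coef) {
  games <- lapply(seq_len(nrow(S)), function(k) {
    tanimoto_restricted_game(x, S[k, ])
  })
  function(idx) {
    sum(vapply(seq_along(games), function(k) coef[k] * games[[k]](idx),
               numeric(1)))
  }
}

# one shared desk-scale pipeline run, computed lazily and reused by the
# acceptance criteria (the run itself takes a few minutes)
.fixture_env <- new.env(parent = emptyenv())

desk_run <- function() {
  if (is.null(.fixture_env$desk)) {
    dir <- file.path(tempdir(), "fpshap_desk_run")
    .fixture_env$desk <- run_pipeline(pipeline_config(), out_dir = dir,
                                      resume = FALSE)
  }
  .fixture_env$desk
}
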