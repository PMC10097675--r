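# Experimental design: schedule of balanced training-set sizes, trial
# enumeration, and disjoint train/validation/test splits.
#
# For every unordered class pair, training sets of 12 increasing per-class
# sizes are drawn in each of n_trials independent trials. The validation
# set is 20% of the training-set size (so the smallest set of 10 = 5 + 5
# compounds gets a validation set of 2 = 1 + 1), and a constant balanced
# test set (default 100 per class) is drawn first and reused to score all
# model sizes of the trial, which makes prediction patterns well-defined.

#' Experimental design specification
#'
#' @param class_ids Class identifiers (>= 2, unique).
#' @param size_schedule Strictly increasing per-class training counts. The
#'   default spans the published endpoints (5 and 720 per class) over 12
#'   sizes.
#' @param n_trials Independent trials per (pair, size).
#' @param test_per_class Test compounds drawn per class.
#' @param validation_fraction Validation size as a fraction of the
#'   training-set size, in (0, 1).
#' @param algorithms Subset of `c("RF", "SVM")`.
#' @param master_seed Integer seed from which all job/split seeds derive.
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(class_ids = paste0("class_", 1:7),
                        size_schedule = c(5, 10, 25, 50, 75, 100, 125,
                                          250, 375, 500, 625, 720),
                        n_trials = 10L,
                        test_per_class = 100L,
                        validation_fraction = 0.2,
                        algorithms = c("RF", "SVM"),
                        master_seed = 1L) {
  class_ids <- as.character(class_ids)
  if (anyDuplicated(class_ids)) stop("invalid design: duplicate class ids")
  if (length(class_ids) < 2L) stop("invalid design: need >= 2 classes")
  size_schedule <- as.integer(size_schedule)
  if (any(diff(size_schedule) <= 0L)) {
    stop("invalid design: size schedule must be strictly increasing")
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("invalid design: validation_fraction must be in (0, 1)")
  }
  algorithms <- match.arg(algorithms, c("RF", "SVM"), several.ok = TRUE)
  structure(
    list(class_ids = sort(class_ids), size_schedule = size_schedule,
         n_trials = as.integer(n_trials),
         test_per_class = as.integer(test_per_class),
         validation_fraction = validation_fraction,
         algorithms = algorithms, master_seed = as.integer(master_seed)),
    class = "design_spec")
}

# balanced validation count per class: round-half-up the total, force an
# even split with at least one compound per class (10 -> 2 = 1 + 1)
validation_per_class <- function(size, validation_fraction) {
  total <- round_half_up(validation_fraction * 2 * size)
  max(1L, as.integer(round_half_up(total / 2)))
}

#' Enumerate the full job manifest
#'
#' One row per (unordered class pair, training size, trial, algorithm),
#' with a deterministic derived seed per job.
#'
#' @param design A [design_spec()].
#' @return `data.frame` manifest.
#' @export
enumerate_jobs <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  pairs <- utils::combn(design$class_ids, 2L)
  rows <- list()
  k <- 0L
  for (p in seq_len(ncol(pairs))) {
    class_a <- pairs[1L, p]
    class_b <- pairs[2L, p]
    pair_id <- paste(class_a, class_b, sep = "|")
    for (size in design$size_schedule) {
      for (trial in seq_len(design$n_trials)) {
        for (alg in design$algorithms) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            job_id = k, pair_id = pair_id, class_a = class_a,
            class_b = class_b, size = size, trial = trial, algorithm = alg,
            seed = derive_seed(design$master_seed, "job", pair_id, size,
                               trial, alg),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Draw the balanced, disjoint splits of one trial
#'
#' The test set is drawn first (`test_per_class` per class); training and
#' validation sets for each schedule size are then drawn independently from
#' the remaining pool, balanced per class, with training and validation
#' disjoint within a size and everything disjoint from the test set.
#'
#' @param pool An `fpshap_dataset` (or list with `labels` named by
#'   compound id).
#' @param design A [design_spec()].
#' @param pair Character vector of the two class ids.
#' @param trial_index Trial number (1-based).
#' @return Object of class `trial_split`: `test` ids plus, per size,
#'   `train` and `validation` ids.
#' @export
make_trial_splits <- function(pool, design, pair, trial_index) {
  stopifnot(inherits(design, "design_spec"))
  pair <- sort(as.character(pair))
  labels <- pool$labels
  ids_by_class <- lapply(pair, function(cl) names(labels)[labels == cl])
  names(ids_by_class) <- pair

  max_size <- max(design$size_schedule)
  need <- design$test_per_class + max_size +
    validation_per_class(max_size, design$validation_fraction)
  for (cl in pair) {
    have <- length(ids_by_class[[cl]])
    if (have < need) {
      stop(sprintf(
        "pool too small for class '%s': need %d compounds per class, have %d",
        cl, need, have))
    }
  }

  seed <- derive_seed(design$master_seed, "split", paste(pair, collapse = "|"),
                      trial_index)
  with_seed(seed, {
    test <- lapply(pair, function(cl) {
      sample(ids_by_class[[cl]], design$test_per_class)
    })
    names(test) <- pair
    remainder <- lapply(pair, function(cl) {
      setdiff(ids_by_class[[cl]], test[[cl]])
    })
    names(remainder) <- pair

    sizes <- lapply(design$size_schedule, function(size) {
      v <- validation_per_class(size, design$validation_fraction)
      train <- validation <- character(0)
      for (cl in pair) {
        tr <- sample(remainder[[cl]], size)
        va <- sample(setdiff(remainder[[cl]], tr), v)
        train <- c(train, tr)
        validation <- c(validation, va)
      }
      list(train = train, validation = validation)
    })
    names(sizes) <- as.character(design$size_schedule)

    structure(
      list(pair = pair, trial_index = as.integer(trial_index),
           test = unlist(unname(test)), sizes = sizes),
      class = "trial_split")
  })
}
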