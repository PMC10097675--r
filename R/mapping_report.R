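# Atom-level projection of feature attributions and the run-level
# pipeline: generate -> curate -> design -> train -> explain -> aggregate
# -> map, with per-job JSON artifacts that make runs resumable and
# reproducible from one master seed.

#' Project present-feature Shapley values onto atoms
#'
#' Each present feature's full Shapley value is added to every atom the
#' feature covers (set `split_value = TRUE` to divide the value evenly
#' across the feature's atoms instead). Atoms are then binned for display:
#' negative values oppose the correct prediction (cyan), values within
#' `tau` of 0 are neutral (white), positive values support it (magenta).
#'
#' @param expl An oriented `shapley_explanation`.
#' @param x The compound's binary fingerprint.
#' @param atom_map List mapping feature index to atom indices; must cover
#'   every present feature.
#' @param tau Neutral-bin tolerance (default 1e-6).
#' @param split_value Divide a feature's value evenly over its atoms.
#' @return `data.frame` with columns `atom`, `value`, `bin`.
#' @export
map_feature_values_to_atoms <- function(expl, x, atom_map, tau = 1e-6,
                                        split_value = FALSE) {
  if (length(expl$values) != length(x)) stop("length mismatch")
  present <- which(x == 1)
  covered <- vapply(present, function(j) {
    j <= length(atom_map) && length(atom_map[[j]]) > 0
  }, logical(1))
  if (any(!covered)) {
    stop("present features without atom assignment: ",
         paste(present[!covered], collapse = ", "))
  }
  n_atoms <- if (length(atom_map)) max(unlist(atom_map)) else 0L
  value <- numeric(n_atoms)
  for (j in present) {
    atoms <- atom_map[[j]]
    add <- if (split_value) expl$values[j] / length(atoms) else expl$values[j]
    value[atoms] <- value[atoms] + add
  }
  bin <- ifelse(value < -tau, "cyan", ifelse(value > tau, "magenta", "white"))
  data.frame(atom = seq_len(n_atoms), value = value, bin = bin,
             stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Defaults describe the desk-scale benchmark: a synthetic two-class pair
#' with 64-bit fingerprints, 10 planted discriminative bits per class, a
#' 12-point training-size schedule, 3 trials, and both algorithms. The
#' schedule tops out at 100 compounds per class so a full run (training,
#' exact explanation of every test compound, aggregation) stays within a
#' desk-scale compute budget; all sizes are configurable up to the
#' published design (schedule to 720 per class, 10 trials, 100 test
#' compounds per class).
#'
#' @param n_features Fingerprint length.
#' @param n_per_class Generated compounds per class.
#' @param n_planted Planted discriminative bits per class.
#' @param p_planted_on,p_cross_on,p_background,noise_rate Generator
#'   probabilities, see [synthetic_pair_spec()].
#' @param size_schedule,n_trials,test_per_class,validation_fraction,algorithms
#'   Design parameters, see [design_spec()].
#' @param n_search Random grid-search trials per model.
#' @param grid Hyperparameter grid.
#' @param background_max Cap on the RF Shapley background sample (rows
#'   drawn deterministically from the training set when it is larger);
#'   `Inf` uses the full training set.
#' @param top_k Top-feature set size for intersections.
#' @param write_explanations Write per-job dense explanation matrices.
#' @param master_seed Integer master seed.
#' @return Config list (class `fpshap_config`).
#' @export
pipeline_config <- function(n_features = 64L, n_per_class = 200L,
                            n_planted = 10L,
                            p_planted_on = 0.9, p_cross_on = 0.05,
                            p_background = 0.1, noise_rate = 0.01,
                            size_schedule = c(5L, 10L, 15L, 20L, 25L, 30L,
                                              40L, 50L, 60L, 70L, 85L, 100L),
                            n_trials = 3L, test_per_class = 50L,
                            validation_fraction = 0.2,
                            algorithms = c("RF", "SVM"),
                            n_search = 50L,
                            grid = default_hyperparameter_grid(),
                            background_max = 64L,
                            top_k = 15L,
                            write_explanations = FALSE,
                            master_seed = 1L) {
  structure(as.list(environment()), class = "fpshap_config")
}

read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

job_filename <- function(out_dir, job_id) {
  file.path(out_dir, "jobs", sprintf("job_%04d.json", job_id))
}

compute_job <- function(job, splits, dataset, config, expl_path = NULL) {
  model <- train_model_with_search(job, splits, dataset,
                                   grid = config$grid,
                                   n_search = config$n_search,
                                   seed = job$seed)
  X <- fingerprint_matrix(dataset)
  test_ids <- splits$test
  Xt <- X[test_ids, , drop = FALSE]
  labels_t <- dataset$labels[test_ids]
  ev <- evaluate_model(model, Xt, labels_t)

  background <- NULL
  if (job$algorithm == "RF") {
    background <- model$X_train
    if (is.finite(config$background_max) &&
        nrow(background) > config$background_max) {
      keep <- with_seed(derive_seed(job$seed, "background"), {
        sort(sample(nrow(background), config$background_max))
      })
      background <- background[keep, , drop = FALSE]
    }
  }

  n <- length(test_ids)
  oriented <- vector("list", n)
  local_err <- 0
  for (i in seq_len(n)) {
    expl <- if (job$algorithm == "RF") {
      rf_tree_shapley(model, Xt[i, ], background, compound_id = test_ids[i])
    } else {
      svm_tanimoto_shapley(model, Xt[i, ], compound_id = test_ids[i])
    }
    local_err <- max(local_err, local_accuracy_error(expl))
    oriented[[i]] <- orient_explanation(expl, labels_t[i])
  }

  cs_present <- vapply(seq_len(n), function(i) {
    instance_cumulative(oriented[[i]], Xt[i, ])$cs_present
  }, numeric(1))
  cs_absent <- vapply(seq_len(n), function(i) {
    instance_cumulative(oriented[[i]], Xt[i, ])$cs_absent
  }, numeric(1))

  fc <- feature_cumulative(oriented, Xt, ev$correct, labels_t)
  norm_dev <- 0
  for (i in seq_len(n)) {
    if (!ev$correct[i]) next
    phi <- oriented[[i]]$values
    tot <- sum(abs(phi))
    if (tot > 0) norm_dev <- max(norm_dev, abs(sum(abs(phi / tot)) - 1))
  }

  rec <- list(
    job = list(job_id = job$job_id, pair_id = job$pair_id,
               class_a = job$class_a, class_b = job$class_b,
               size = job$size, trial = job$trial,
               algorithm = job$algorithm, seed = job$seed),
    hyperparams = model$hyperparams,
    validation_mcc = model$validation_mcc,
    tie_loss = model$tie_loss,
    metrics = unclass(ev$report),
    compounds = list(compound_id = I(test_ids),
                     true_class = I(unname(labels_t)),
                     predicted = I(unname(ev$predictions)),
                     correct = I(unname(ev$correct)),
                     cs_present = I(cs_present),
                     cs_absent = I(cs_absent)),
    fc = lapply(fc$per_class, function(pc) {
      list(present = I(pc$present), absent = I(pc$absent),
           occ_present = I(pc$occ_present), occ_absent = I(pc$occ_absent),
           n_instances = pc$n_instances, n_skipped = pc$n_skipped)
    }),
    diagnostics = list(local_error_max = local_err,
                       normalization_max_dev = norm_dev))

  if (!is.null(expl_path)) {
    mat <- do.call(rbind, lapply(oriented, function(e) e$values))
    rownames(mat) <- test_ids
    colnames(mat) <- colnames(X)
    utils::write.csv(mat, expl_path, row.names = TRUE)
  }
  rec
}

read_job <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full synthetic benchmark pipeline
#'
#' Generates a planted-structure dataset, curates it, enumerates the job
#' manifest, trains a model per job with random grid search, computes an
#' exact Shapley explanation for every test compound, and aggregates
#' prediction patterns, cumulative Shapley statistics, f_cs/PCC tables,
#' feature-contribution patterns, top-k feature intersections, and an
#' atom-level mapping for exemplar compounds. One JSON artifact is written
#' per job; an interrupted run resumes from the finished jobs and all
#' aggregates are rebuilt from the job files, so resumed runs are
#' byte-identical to uninterrupted ones.
#'
#' @param config A [pipeline_config()] or path to a JSON config file.
#' @param out_dir Run directory (created if needed).
#' @param resume Reuse existing per-job artifacts (default `TRUE`).
#' @return The run summary (list, class `fpshap_run`), invisibly. The
#'   summary is also written to `summary.json` in `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         resume = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "fpshap_config"))
  dir.create(file.path(out_dir, "jobs"), recursive = TRUE,
             showWarnings = FALSE)

  spec <- synthetic_pair_spec(
    n_features = config$n_features, n_per_class = config$n_per_class,
    planted_a = seq_len(config$n_planted),
    planted_b = config$n_planted + seq_len(config$n_planted),
    p_planted_on = config$p_planted_on, p_cross_on = config$p_cross_on,
    p_background = config$p_background, noise_rate = config$noise_rate,
    seed = derive_seed(config$master_seed, "dataset"),
    class_ids = c("A", "B"))
  dataset <- generate_class_pair(spec)
  write_truth_json(dataset, file.path(out_dir, "truth.json"))
  write_records_csv(dataset$records, file.path(out_dir, "records.csv"))

  curated <- curate_records(dataset$records)

  design <- design_spec(
    class_ids = spec$class_ids, size_schedule = config$size_schedule,
    n_trials = config$n_trials, test_per_class = config$test_per_class,
    validation_fraction = config$validation_fraction,
    algorithms = config$algorithms, master_seed = config$master_seed)
  manifest <- enumerate_jobs(design)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)

  pair_ids <- unique(manifest$pair_id)
  splits <- list()
  for (pid in pair_ids) {
    pair <- strsplit(pid, "|", fixed = TRUE)[[1]]
    splits[[pid]] <- lapply(seq_len(design$n_trials), function(t) {
      make_trial_splits(dataset, design, pair, t)
    })
  }

  for (r in seq_len(nrow(manifest))) {
    job <- as.list(manifest[r, ])
    path <- job_filename(out_dir, job$job_id)
    if (resume && file.exists(path)) next
    expl_path <- if (isTRUE(config$write_explanations)) {
      file.path(out_dir, "jobs", sprintf("explanations_%04d.csv", job$job_id))
    } else NULL
    rec <- compute_job(job, splits[[job$pair_id]][[job$trial]], dataset,
                       config, expl_path = expl_path)
    jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE)
  }

  summary <- aggregate_run(out_dir, manifest, design, dataset, config)
  summary$curation <- list(kept = length(curated$kept),
                           rejected = length(curated$rejected))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(summary, class = "fpshap_run", out_dir = out_dir))
}

# Rebuild every run-level aggregate from the per-job JSON artifacts (never
# from in-memory state), which is what makes resumed runs byte-identical.
aggregate_run <- function(out_dir, manifest, design, dataset, config) {
  jobs <- lapply(manifest$job_id, function(id) {
    read_job(job_filename(out_dir, id))
  })

  metrics <- do.call(rbind, lapply(jobs, function(jb) {
    data.frame(jb$job[c("job_id", "pair_id", "size", "trial", "algorithm")],
               validation_mcc = jb$validation_mcc,
               as.data.frame(jb$metrics), stringsAsFactors = FALSE)
  }))
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)

  schedule <- design$size_schedule
  patterns <- list()
  k <- 0L
  for (pid in unique(manifest$pair_id)) {
    for (alg in design$algorithms) {
      for (tr in seq_len(design$n_trials)) {
        sel <- which(manifest$pair_id == pid & manifest$algorithm == alg &
                       manifest$trial == tr)
        sel <- sel[order(manifest$size[sel])]
        stopifnot(length(sel) == length(schedule))
        correct <- vapply(jobs[sel], function(jb) jb$compounds$correct,
                          logical(length(jobs[[sel[1]]]$compounds$correct)))
        ids <- jobs[[sel[1]]]$compounds$compound_id
        for (i in seq_along(ids)) {
          bits <- as.integer(correct[i, ])
          k <- k + 1L
          patterns[[k]] <- data.frame(
            compound_id = ids[i], pair = pid, trial = tr, algorithm = alg,
            bits = paste(bits, collapse = ""),
            category = classify_prediction_pattern(bits),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  patterns <- do.call(rbind, patterns)
  utils::write.csv(patterns, file.path(out_dir, "prediction_patterns.csv"),
                   row.names = FALSE)
  pattern_table <- if (all(c("RF", "SVM") %in% design$algorithms)) {
    pt <- pattern_tabulate(patterns)
    utils::write.csv(pt, file.path(out_dir, "pattern_table.csv"),
                     row.names = FALSE)
    pt
  } else NULL

  # f_cs per (job, class) over correctly predicted compounds of the class
  fcs <- do.call(rbind, lapply(jobs, function(jb) {
    co <- jb$compounds
    do.call(rbind, lapply(sort(unique(co$true_class)), function(cl) {
      use <- co$correct & co$true_class == cl
      fc_val <- if (any(use)) {
        feature_contribution_score(data.frame(
          cs_present = co$cs_present[use], cs_absent = co$cs_absent[use]))
      } else NA_real_
      data.frame(jb$job[c("pair_id", "size", "trial", "algorithm")],
                 class = cl, f_cs = fc_val, mcc = jb$metrics$MCC,
                 n_correct = sum(use), stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(fcs, file.path(out_dir, "fcs.csv"), row.names = FALSE)

  pcc_rows <- list()
  k <- 0L
  for (pid in unique(fcs$pair_id)) {
    for (alg in design$algorithms) {
      pccs <- c()
      for (cl in sort(unique(fcs$class[fcs$pair_id == pid]))) {
        sub <- fcs[fcs$pair_id == pid & fcs$algorithm == alg &
                     fcs$class == cl & !is.na(fcs$f_cs), ]
        val <- if (nrow(sub) >= 2L) pearson_cc(sub$f_cs, sub$mcc) else
          NA_real_
        pccs[cl] <- val
      }
      comb <- combined_pcc(pccs[1L], pccs[2L], alg)
      k <- k + 1L
      pcc_rows[[k]] <- data.frame(
        pair_id = pid, algorithm = alg,
        class_1 = names(pccs)[1L], pcc_1 = unname(pccs[1L]),
        class_2 = names(pccs)[2L], pcc_2 = unname(pccs[2L]),
        combined_pcc = comb,
        fc_pattern = classify_fc_pattern(pccs[1L], pccs[2L], comb, alg),
        stringsAsFactors = FALSE)
    }
  }
  pcc_table <- do.call(rbind, pcc_rows)
  utils::write.csv(pcc_table, file.path(out_dir, "pcc.csv"),
                   row.names = FALSE)

  # feature-based cumulative objects per job, for intersections
  rebuild_fc <- function(jb) {
    cls <- sort(names(jb$fc))
    per_class <- lapply(cls, function(cl) jb$fc[[cl]])
    names(per_class) <- cls
    structure(list(classes = cls, per_class = per_class,
                   n_features = length(per_class[[1]]$present)),
              class = "feature_cumulative")
  }

  truth <- list(A = dataset$truth$planted_a, B = dataset$truth$planted_b)

  # intersection of top-k sets across >= 1 models (a single model yields
  # its own top sets)
  intersect_tops <- function(fcs, k) {
    if (length(fcs) >= 2L) return(top_k_feature_intersection(fcs, k = k))
    fc <- fcs[[1L]]
    out <- lapply(fc$classes, function(cl) {
      list(present = top_k_features(fc$per_class[[cl]]$present, k),
           absent = top_k_features(fc$per_class[[cl]]$absent, k))
    })
    names(out) <- fc$classes
    out
  }

  top_sets <- list()
  recovery <- list()
  for (alg in design$algorithms) {
    # intersection across the size schedule, per trial
    across_sizes <- lapply(seq_len(design$n_trials), function(tr) {
      sel <- which(manifest$algorithm == alg & manifest$trial == tr)
      sel <- sel[order(manifest$size[sel])]
      intersect_tops(lapply(jobs[sel], rebuild_fc), k = config$top_k)
    })
    top_sets[[alg]] <- lapply(across_sizes, function(ts) {
      lapply(ts, function(cl) lapply(cl, I))
    })
    # planted recovery at the largest size: top-k present sets of the
    # largest-size models, intersected over trials, scored against truth
    sel <- which(manifest$algorithm == alg &
                   manifest$size == max(schedule))
    inter <- intersect_tops(lapply(jobs[sel], rebuild_fc),
                            k = config$top_k)
    recovery[[alg]] <- lapply(names(truth), function(cl) {
      hit <- intersect(inter[[cl]]$present, truth[[cl]])
      list(class = cl, planted = I(truth[[cl]]),
           top_present = I(inter[[cl]]$present),
           fraction_recovered = length(hit) / length(truth[[cl]]))
    })
  }

  med_mcc <- lapply(design$algorithms, function(alg) {
    vapply(schedule, function(s) {
      stats::median(metrics$MCC[metrics$algorithm == alg &
                                  metrics$size == s])
    }, numeric(1))
  })
  names(med_mcc) <- design$algorithms
  monotone <- vapply(design$algorithms, function(alg) {
    v <- med_mcc[[alg]]
    # non-decreasing with a one-schedule-step tolerance
    all(v[-(1:2)] >= v[seq_len(length(v) - 2L)] - 1e-12) &&
      v[length(v)] >= v[1L]
  }, logical(1))

  exemplars <- atom_map_report(out_dir, manifest, design, dataset, config,
                               patterns)

  list(
    config = unclass(config)[setdiff(names(unclass(config)), "grid")],
    n_jobs = nrow(manifest),
    median_mcc_by_size = lapply(med_mcc, I),
    mcc_monotone = as.list(monotone),
    pattern_counts = as.list(table(patterns$category)),
    pattern_table = pattern_table,
    pcc_table = pcc_table,
    top_intersections = top_sets,
    planted_recovery = recovery,
    exemplar_atoms = exemplars,
    diagnostics = list(
      local_error_max = max(vapply(jobs, function(jb)
        jb$diagnostics$local_error_max, numeric(1))),
      normalization_max_dev = max(vapply(jobs, function(jb)
        jb$diagnostics$normalization_max_dev, numeric(1)))))
}

# Atom-level mapping for up to three exemplar compounds that start
# incorrect and end correct (falling back to the first test compounds),
# at the smallest, an intermediate, and the largest training-set size.
atom_map_report <- function(out_dir, manifest, design, dataset, config,
                            patterns) {
  schedule <- design$size_schedule
  sizes <- unique(c(schedule[1L],
                    schedule[ceiling(length(schedule) / 2)],
                    schedule[length(schedule)]))
  cand <- patterns[patterns$trial == 1L &
                     patterns$category == "start_incorrect_end_correct", ]
  ids <- unique(cand$compound_id)
  if (length(ids) == 0L) ids <- unique(patterns$compound_id)
  ids <- utils::head(ids, 3L)

  X <- fingerprint_matrix(dataset)
  rows <- list()
  k <- 0L
  for (alg in design$algorithms) {
    for (s in sizes) {
      sel <- manifest[manifest$algorithm == alg & manifest$size == s &
                        manifest$trial == 1L, ][1L, ]
      splits <- make_trial_splits(dataset, design,
                                  c(sel$class_a, sel$class_b), 1L)
      model <- train_model_with_search(as.list(sel), splits, dataset,
                                       grid = config$grid,
                                       n_search = config$n_search,
                                       seed = sel$seed)
      for (id in ids) {
        x <- X[id, ]
        expl <- if (alg == "RF") {
          bg <- model$X_train
          if (is.finite(config$background_max) &&
              nrow(bg) > config$background_max) {
            keep <- with_seed(derive_seed(sel$seed, "background"), {
              sort(sample(nrow(bg), config$background_max))
            })
            bg <- bg[keep, , drop = FALSE]
          }
          rf_tree_shapley(model, x, bg, compound_id = id)
        } else {
          svm_tanimoto_shapley(model, x, compound_id = id)
        }
        expl <- orient_explanation(expl, dataset$labels[[id]])
        am <- map_feature_values_to_atoms(expl, x, dataset$atom_map)
        am <- am[am$value != 0 | am$bin != "white", , drop = FALSE]
        if (nrow(am) == 0L) next
        k <- k + 1L
        rows[[k]] <- data.frame(compound_id = id, algorithm = alg,
                                size = s, am, stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- if (k > 0L) do.call(rbind, rows) else
    data.frame(compound_id = character(), algorithm = character(),
               size = integer(), atom = integer(), value = numeric(),
               bin = character())
  utils::write.csv(atoms, file.path(out_dir, "exemplar_atoms.csv"),
                   row.names = FALSE)
  list(compound_ids = I(ids), sizes = I(sizes), n_rows = nrow(atoms))
}
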