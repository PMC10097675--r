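toy_map <- function(m) lapply(seq_len(m), function(j) c(2L * j - 1L, 2L * j))

test_that("atom mapping sums present-feature values onto atoms", {
  # single present feature phi = 0.3 on atoms {1, 2}
  e <- fpshap:::new_shapley_explanation(
    "c", values = c(0.3, 0.5), base_value = 0, model_output = 0.8,
    orientation = "A", classes = c("A", "B"), kind = "decision")
  am <- map_feature_values_to_atoms(e, x = c(1, 0), atom_map = toy_map(2))
  expect_equal(am$value, c(0.3, 0.3, 0, 0))
  expect_equal(am$bin, c("magenta", "magenta", "white", "white"))

  # overlapping features: phi 0.2 on atoms {1,2}, -0.1 on {2,3}
  e2 <- fpshap:::new_shapley_explanation(
    "c", values = c(0.2, -0.1), base_value = 0, model_output = 0.1,
    orientation = "A", classes = c("A", "B"), kind = "decision")
  overlap_map <- list(c(1L, 2L), c(2L, 3L))
  am2 <- map_feature_values_to_atoms(e2, x = c(1, 1), atom_map = overlap_map)
  expect_equal(am2$value, c(0.2, 0.1, -0.1))
  expect_equal(am2$bin, c("magenta", "magenta", "cyan"))

  # all-zero explanation: everything white
  e3 <- fpshap:::new_shapley_explanation(
    "c", values = c(0, 0), base_value = 0, model_output = 0,
    orientation = "A", classes = c("A", "B"), kind = "decision")
  am3 <- map_feature_values_to_atoms(e3, x = c(1, 1), atom_map = toy_map(2))
  expect_true(all(am3$bin == "white"))

  # a present feature without atom assignment is an error naming it
  expect_error(
    map_feature_values_to_atoms(e, x = c(1, 1),
                                atom_map = list(c(1L, 2L), integer(0))),
    "without atom assignment: 2")
})

test_that("atom mapping conserves each feature's value once per atom", {
  set.seed(51)
  m <- 10
  amap <- toy_map(m)  # disjoint atom groups of size 2
  phi <- rnorm(m)
  x <- as.integer(runif(m) < 0.6)
  e <- fpshap:::new_shapley_explanation(
    "c", values = phi, base_value = 0, model_output = sum(phi),
    orientation = "A", classes = c("A", "B"), kind = "decision")
  am <- map_feature_values_to_atoms(e, x, amap)
  # every present feature contributes its full value to each of its atoms
  expect_equal(sum(am$value), 2 * sum(phi[x == 1]))
  # even-split mode divides instead
  am_split <- map_feature_values_to_atoms(e, x, amap, split_value = TRUE)
  expect_equal(sum(am_split$value), sum(phi[x == 1]))
})

mini_config <- function(seed = 101) {
  pipeline_config(
    n_features = 20L, n_per_class = 50L, n_planted = 4L,
    size_schedule = c(5L, 10L), n_trials = 1L, test_per_class = 10L,
    n_search = 4L, background_max = 16L, master_seed = seed)
}

test_that("the pipeline runs, validates, and is deterministic", {
  d1 <- file.path(tempdir(), "run_a")
  d2 <- file.path(tempdir(), "run_b")
  unlink(c(d1, d2), recursive = TRUE)
  s1 <- run_pipeline(mini_config(), out_dir = d1, resume = FALSE)
  s2 <- run_pipeline(mini_config(), out_dir = d2, resume = FALSE)

  expect_equal(s1$n_jobs, 4)  # 1 pair x 2 sizes x 1 trial x 2 algorithms
  for (f in c("manifest.csv", "metrics.csv", "prediction_patterns.csv",
              "pattern_table.csv", "fcs.csv", "pcc.csv", "summary.json",
              "truth.json", "records.csv", "exemplar_atoms.csv")) {
    expect_true(file.exists(file.path(d1, f)), info = f)
  }
  expect_lt(s1$diagnostics$local_error_max, 1e-8)

  # identical config + seed -> byte-identical summaries
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))

  # a different master seed changes the run
  d3 <- file.path(tempdir(), "run_c")
  unlink(d3, recursive = TRUE)
  run_pipeline(mini_config(seed = 202), out_dir = d3, resume = FALSE)
  expect_false(identical(readLines(file.path(d1, "summary.json")),
                         readLines(file.path(d3, "summary.json"))))
})

test_that("resumed runs are byte-identical to uninterrupted ones", {
  d1 <- file.path(tempdir(), "run_full")
  d2 <- file.path(tempdir(), "run_resumed")
  unlink(c(d1, d2), recursive = TRUE)
  run_pipeline(mini_config(), out_dir = d1, resume = FALSE)

  # simulate an interrupted run: half the job artifacts already present
  dir.create(file.path(d2, "jobs"), recursive = TRUE)
  jobs <- list.files(file.path(d1, "jobs"), full.names = TRUE)
  file.copy(jobs[seq_len(length(jobs) %/% 2)], file.path(d2, "jobs"))
  run_pipeline(mini_config(), out_dir = d2, resume = TRUE)

  for (f in c("summary.json", "metrics.csv", "prediction_patterns.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("config round-trips through JSON and rejects unknown fields", {
  cfg <- mini_config()
  path <- file.path(tempdir(), "cfg.json")
  jsonlite::write_json(
    unclass(cfg)[setdiff(names(unclass(cfg)), "grid")], path,
    digits = NA, auto_unbox = TRUE)
  loaded <- fpshap:::read_pipeline_config(path)
  expect_equal(loaded$size_schedule, cfg$size_schedule)
  expect_equal(loaded$master_seed, cfg$master_seed)

  jsonlite::write_json(list(bogus_field = 1), path, auto_unbox = TRUE)
  expect_error(fpshap:::read_pipeline_config(path), "unknown config")
})

test_that("fingerprints and records round-trip through MTX/CSV", {
  ds <- tiny_dataset(n_features = 16, n_per_class = 8, n_planted = 3)
  mtx <- file.path(tempdir(), "fp.mtx")
  write_fingerprints_mtx(fingerprint_matrix(ds), mtx)
  X2 <- read_fingerprints_mtx(mtx)
  expect_equal(unname(X2), unname(fingerprint_matrix(ds)))
  expect_identical(rownames(X2), rownames(fingerprint_matrix(ds)))

  csv <- file.path(tempdir(), "records.csv")
  write_records_csv(ds$records, csv)
  recs <- read_records_csv(csv)
  expect_length(recs, length(ds$records))
  expect_identical(recs[[3]]$compound_id, ds$records[[3]]$compound_id)
  expect_equal(recs[[3]]$annotations$ppot, ds$records[[3]]$annotations$ppot,
               tolerance = 1e-9)
})
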