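# Synthetic fingerprint generator with planted class structure.
#
# Two compound classes are emulated by binary fingerprints in which a small
# set of "planted" bits is preferentially switched on in the compound's own
# class (p_planted_on), rarely in the other class (p_cross_on), on top of
# shared background bits (p_background) and independent bit-flip noise.
# The planted sets are returned as ground truth so downstream attribution
# stages can be scored against a known answer.

#' Specification of a synthetic two-class fingerprint dataset
#'
#' @param n_features Fingerprint length (positive integer).
#' @param n_per_class Number of compounds generated per class.
#' @param planted_a,planted_b Disjoint 1-based feature indices that are
#'   discriminative for the first/second class.
#' @param p_planted_on Probability that a planted bit of the compound's own
#'   class is set.
#' @param p_cross_on Probability that a planted bit of the *other* class is
#'   set.
#' @param p_background Background on-probability for all remaining bits.
#' @param noise_rate Independent bit-flip probability applied after
#'   sampling.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   datasets.
#' @param class_ids Two distinct class identifiers (sorted alphabetically
#'   internally).
#' @return An object of class `synthetic_pair_spec`.
#' @export
synthetic_pair_spec <- function(n_features = 256L,
                                n_per_class = 1000L,
                                planted_a = 1:10,
                                planted_b = 11:20,
                                p_planted_on = 0.9,
                                p_cross_on = 0.05,
                                p_background = 0.1,
                                noise_rate = 0.01,
                                seed = 1L,
                                class_ids = c("A", "B")) {
  n_features <- as.integer(n_features)
  n_per_class <- as.integer(n_per_class)
  planted_a <- as.integer(planted_a)
  planted_b <- as.integer(planted_b)
  if (n_features < 1L) stop("invalid spec: n_features must be positive")
  if (n_per_class < 1L) stop("invalid spec: n_per_class must be positive")
  if (length(intersect(planted_a, planted_b)) > 0L) {
    stop("invalid spec: planted sets must be disjoint")
  }
  if (any(c(planted_a, planted_b) < 1L) ||
      any(c(planted_a, planted_b) > n_features)) {
    stop("invalid spec: planted indices must lie in [1, n_features]")
  }
  probs <- c(p_planted_on, p_cross_on, p_background, noise_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("invalid spec: probabilities must be in [0, 1]")
  }
  if (length(class_ids) != 2L || anyDuplicated(class_ids)) {
    stop("invalid spec: class_ids must be two distinct identifiers")
  }
  structure(
    list(n_features = n_features, n_per_class = n_per_class,
         planted_a = planted_a, planted_b = planted_b,
         p_planted_on = p_planted_on, p_cross_on = p_cross_on,
         p_background = p_background, noise_rate = noise_rate,
         seed = as.integer(seed), class_ids = sort(as.character(class_ids))),
    class = "synthetic_pair_spec")
}

#' Single compound record
#'
#' Carries one compound's class label, fingerprint, potency annotations
#' (type, pPot as negative decadic log molar, assay confidence), molecular
#' mass in Da, curation flags, and an optional feature-to-atom map.
#'
#' @param compound_id Identifier string.
#' @param class_label Class identifier.
#' @param fingerprint Integer 0/1 vector (may be `NULL` for record-only
#'   fixtures).
#' @param annotations `data.frame` with columns `type`
#'   (Kd/Ki/IC50), `ppot`, `confidence`; zero rows allowed.
#' @param molecular_mass Mass in Da, must be positive.
#' @param interference_flag,aggregator_flag,rule_violation_flag Booleans
#'   standing in for published assay-interference/aggregator/medchem-rule
#'   catalogs.
#' @param atom_map Optional list mapping feature index to atom indices.
#' @return An object of class `compound_record`.
#' @export
compound_record <- function(compound_id, class_label, fingerprint = NULL,
                            annotations = potency_annotations(),
                            molecular_mass = 500,
                            interference_flag = FALSE,
                            aggregator_flag = FALSE,
                            rule_violation_flag = FALSE,
                            atom_map = NULL) {
  if (!is.null(fingerprint)) {
    fingerprint <- as.integer(fingerprint)
    if (any(is.na(fingerprint)) || !all(fingerprint %in% c(0L, 1L))) {
      stop("fingerprint entries must be 0/1")
    }
  }
  if (!is.data.frame(annotations) ||
      !all(c("type", "ppot", "confidence") %in% names(annotations))) {
    stop("annotations must have columns type/ppot/confidence")
  }
  if (nrow(annotations) > 0L) {
    if (!all(annotations$type %in% c("Kd", "Ki", "IC50"))) {
      stop("annotation types must be Kd, Ki or IC50")
    }
    if (any(!is.finite(annotations$ppot))) stop("pPot values must be finite")
  }
  if (!is.finite(molecular_mass) || molecular_mass <= 0) {
    stop("molecular mass must be positive")
  }
  structure(
    list(compound_id = as.character(compound_id),
         class_label = as.character(class_label),
         fingerprint = fingerprint,
         annotations = annotations,
         molecular_mass = molecular_mass,
         interference_flag = isTRUE(interference_flag),
         aggregator_flag = isTRUE(aggregator_flag),
         rule_violation_flag = isTRUE(rule_violation_flag),
         atom_map = atom_map),
    class = "compound_record")
}

#' Build a potency-annotation table
#'
#' @param type Measurement types (`Kd`, `Ki`, `IC50`).
#' @param ppot Negative decadic logarithmic potencies.
#' @param confidence Assay confidence scores.
#' @return `data.frame` with one row per annotation.
#' @export
potency_annotations <- function(type = character(), ppot = numeric(),
                                confidence = integer()) {
  data.frame(type = as.character(type), ppot = as.numeric(ppot),
             confidence = as.integer(confidence),
             stringsAsFactors = FALSE)
}

# Toy feature->atom map: feature j covers atoms {2j-1, 2j} of a molecule
# with 2*n_features atoms, giving every bit a coherent substructure for the
# atom-mapping stage.
toy_atom_map <- function(n_features) {
  lapply(seq_len(n_features), function(j) c(2L * j - 1L, 2L * j))
}

#' Generate a synthetic two-class fingerprint dataset
#'
#' Samples each bit independently according to its role (planted-own,
#' planted-other, background), applies independent bit-flip noise, and
#' attaches clean potency annotations so that generated records pass the
#' curation filters. The result is fully reproducible from the spec.
#'
#' @param spec A [synthetic_pair_spec()].
#' @return An object of class `fpshap_dataset` with elements
#'   `fingerprints` (binary matrix, rownames = compound ids), `labels`
#'   (named character vector), `records` (list of [compound_record()]),
#'   `atom_map`, `truth` (planted index sets) and `spec`.
#' @export
generate_class_pair <- function(spec) {
  if (!inherits(spec, "synthetic_pair_spec")) {
    stop("invalid spec: expected a synthetic_pair_spec")
  }
  m <- spec$n_features
  n <- spec$n_per_class
  cls <- spec$class_ids

  prob_row <- function(own, other) {
    p <- rep(spec$p_background, m)
    p[own] <- spec$p_planted_on
    p[other] <- spec$p_cross_on
    p
  }
  p_a <- prob_row(spec$planted_a, spec$planted_b)
  p_b <- prob_row(spec$planted_b, spec$planted_a)

  out <- with_seed(spec$seed, {
    P <- rbind(matrix(p_a, nrow = n, ncol = m, byrow = TRUE),
               matrix(p_b, nrow = n, ncol = m, byrow = TRUE))
    X <- (matrix(runif(2L * n * m), nrow = 2L * n) < P) * 1L
    if (spec$noise_rate > 0) {
      flip <- matrix(runif(2L * n * m), nrow = 2L * n) < spec$noise_rate
      X <- abs(X - flip * 1L)
    }
    storage.mode(X) <- "integer"
    ann_type <- sample(c("Kd", "Ki", "IC50"), 2L * n, replace = TRUE)
    ann_ppot <- runif(2L * n, 5.5, 9.5)
    mass <- runif(2L * n, 250, 1000)
    list(X = X, ann_type = ann_type, ann_ppot = ann_ppot, mass = mass)
  })

  labels <- rep(cls, each = n)
  ids <- sprintf("%s_%04d", labels, rep(seq_len(n), times = 2L))
  rownames(out$X) <- ids
  colnames(out$X) <- sprintf("f%04d", seq_len(m))
  names(labels) <- ids

  amap <- toy_atom_map(m)
  records <- lapply(seq_along(ids), function(i) {
    compound_record(
      compound_id = ids[i], class_label = labels[i],
      fingerprint = out$X[i, ],
      annotations = potency_annotations(out$ann_type[i], out$ann_ppot[i], 9L),
      molecular_mass = out$mass[i], atom_map = amap)
  })

  structure(
    list(fingerprints = out$X, labels = labels, records = records,
         atom_map = amap,
         truth = list(planted_a = spec$planted_a,
                      planted_b = spec$planted_b),
         spec = spec),
    class = "fpshap_dataset")
}

#' Generate compound records exercising the curation filters
#'
#' Produces `n_clean` records that pass every curation rule and
#' `n_violating` records that each violate exactly one rule (cycling
#' through mass range, confidence, low potency, inconsistent potency
#' annotations, flags, and missing potency). The violated rule is stored in
#' the record's `violated_rule` element for test assertions.
#'
#' @param spec A [synthetic_pair_spec()] supplying the fingerprint length.
#' @param n_clean,n_violating Non-negative record counts.
#' @param seed Integer seed.
#' @return List of [compound_record()] objects.
#' @export
generate_activity_records <- function(spec, n_clean, n_violating, seed = 1L) {
  n_clean <- as.integer(n_clean)
  n_violating <- as.integer(n_violating)
  if (n_clean < 0L || n_violating < 0L) stop("record counts must be >= 0")
  m <- spec$n_features

  rules <- c("mass-range", "confidence", "low-potency",
             "inconsistent-potency", "flagged", "no-potency")

  with_seed(seed, {
    make_fp <- function() as.integer(runif(m) < spec$p_background)
    clean <- lapply(seq_len(n_clean), function(i) {
      rec <- compound_record(
        compound_id = sprintf("clean_%03d", i), class_label = "A",
        fingerprint = make_fp(),
        annotations = potency_annotations(
          sample(c("Kd", "Ki", "IC50"), 1L), runif(1, 5.5, 9.5), 9L),
        molecular_mass = runif(1, 250, 1000))
      rec$violated_rule <- NA_character_
      rec
    })
    bad <- lapply(seq_len(n_violating), function(i) {
      rule <- rules[(i - 1L) %% length(rules) + 1L]
      ann <- potency_annotations("Ki", runif(1, 5.5, 9.5), 9L)
      mass <- runif(1, 250, 1000)
      flags <- list(interference = FALSE, aggregator = FALSE,
                    rule_violation = FALSE)
      if (rule == "mass-range") {
        mass <- if (runif(1) < 0.5) runif(1, 1001, 1500) else runif(1, 50, 249)
      } else if (rule == "confidence") {
        ann$confidence <- 8L
      } else if (rule == "low-potency") {
        ann$ppot <- runif(1, 3, 5)
      } else if (rule == "inconsistent-potency") {
        ann <- potency_annotations(c("Ki", "IC50"),
                                   c(runif(1, 5.5, 9.5), runif(1, 3, 5)),
                                   c(9L, 9L))
      } else if (rule == "flagged") {
        flags$interference <- TRUE
      } else if (rule == "no-potency") {
        ann <- potency_annotations()
      }
      rec <- compound_record(
        compound_id = sprintf("bad_%03d", i), class_label = "A",
        fingerprint = make_fp(), annotations = ann, molecular_mass = mass,
        interference_flag = flags$interference,
        aggregator_flag = flags$aggregator,
        rule_violation_flag = flags$rule_violation)
      rec$violated_rule <- rule
      rec
    })
    c(clean, bad)
  })
}

#' Extract the fingerprint matrix of a dataset
#' @param dataset An `fpshap_dataset`.
#' @return Integer 0/1 matrix, one row per compound.
#' @export
fingerprint_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "fpshap_dataset"))
  dataset$fingerprints
}

#' @export
#' @method print fpshap_dataset
print.fpshap_dataset <- function(x, ...) {
  cat(sprintf(
    "<fpshap_dataset> %d compounds x %d features, classes %s (%d each)\n",
    nrow(x$fingerprints), ncol(x$fingerprints),
    paste(x$spec$class_ids, collapse = "/"), x$spec$n_per_class))
  invisible(x)
}
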