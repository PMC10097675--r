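# Compound-record curation filters and similarity-based class selection.
#
# A record is kept only if every assay annotation has the highest
# confidence score of 9, its molecular mass lies in [250, 1000] Da, it has
# at least one Kd/Ki/IC50 annotation with pPot > 5 (10 micromolar), it has
# no annotation with pPot <= 5 (an active/inactive mix is inconsistent and
# discarded), and no interference/aggregator/medchem-rule flag is set.

# fixed, documented order in which violations are reported
CURATION_RULES <- c("mass-range", "confidence", "no-potency",
                    "low-potency", "inconsistent-potency", "flagged")

curation_violation <- function(record) {
  ann <- record$annotations
  if (record$molecular_mass < 250 || record$molecular_mass > 1000) {
    return("mass-range")
  }
  if (nrow(ann) > 0L && any(ann$confidence != 9L)) return("confidence")
  if (nrow(ann) == 0L) return("no-potency")
  active <- ann$ppot > 5
  if (!any(active)) return("low-potency")
  if (any(!active)) return("inconsistent-potency")
  if (record$interference_flag || record$aggregator_flag ||
      record$rule_violation_flag) {
    return("flagged")
  }
  NA_character_
}

#' Apply the compound curation filters
#'
#' @param records Non-empty list of [compound_record()] objects.
#' @return List with `kept` (records passing all rules) and `rejected`
#'   (list of `list(record, reason)`); the reason is the first violated
#'   rule in the fixed order mass-range, confidence, no-potency,
#'   low-potency, inconsistent-potency, flagged.
#' @export
curate_records <- function(records) {
  if (length(records) == 0L) stop("records must be non-empty")
  reasons <- vapply(records, curation_violation, character(1))
  keep <- is.na(reasons)
  rejected <- Map(function(rec, why) list(record = rec, reason = why),
                  records[!keep], reasons[!keep])
  list(kept = records[keep], rejected = unname(rejected))
}

#' Rejection reasons as a named vector
#' @param curated Result of [curate_records()].
#' @return Named character vector (names = compound ids).
#' @export
rejection_reasons <- function(curated) {
  vapply(curated$rejected, function(r) {
    stats::setNames(r$reason, r$record$compound_id)
  }, character(1))
}

mean_or_median <- function(x, stat) {
  if (stat == "median") stats::median(x) else mean(x)
}

#' Select activity classes by intra- vs inter-class similarity
#'
#' For each class the mean (or median) pairwise Tanimoto similarity within
#' the class (intra) and against the pooled compounds of all other classes
#' (inter) is computed. Classes are ranked by intra - inter, descending,
#' and the `k_omit` most self-similar classes are removed to limit
#' structural heterogeneity between prediction tasks. Ties are broken by
#' class id, lexicographically.
#'
#' @param classes Named list of binary fingerprint matrices.
#' @param k_omit Number of top-ranked classes to omit.
#' @param min_size Classes below this compound count are excluded before
#'   ranking (default 1000).
#' @param stat Similarity summary: `"mean"` (default) or `"median"`.
#' @return List with `selected` (character vector of retained class ids)
#'   and `table` (per-class intra/inter values, the difference, and the
#'   action taken).
#' @export
select_classes_by_similarity <- function(classes, k_omit, min_size = 1000,
                                         stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (is.null(names(classes)) || anyDuplicated(names(classes))) {
    stop("classes must be a uniquely named list of fingerprint matrices")
  }
  ids <- sort(names(classes))
  sizes <- vapply(classes[ids], nrow, integer(1))
  qualifying <- ids[sizes[ids] >= min_size]
  if (length(qualifying) < k_omit + 2L) {
    stop(sprintf(
      "need at least k_omit + 2 = %d classes with >= %d compounds, have %d",
      k_omit + 2L, min_size, length(qualifying)))
  }

  intra <- inter <- rep(NA_real_, length(ids))
  names(intra) <- names(inter) <- ids
  for (id in qualifying) {
    X <- classes[[id]]
    K <- tanimoto_kernel(X)
    intra[id] <- mean_or_median(K[upper.tri(K)], stat)
    others <- do.call(rbind, unname(classes[setdiff(qualifying, id)]))
    inter[id] <- mean_or_median(as.vector(tanimoto_kernel(X, others)), stat)
  }

  diff <- intra - inter
  ranked <- qualifying[order(-diff[qualifying], qualifying)]
  omitted <- utils::head(ranked, k_omit)
  selected <- sort(setdiff(qualifying, omitted))

  table <- data.frame(
    class_id = ids, n = as.integer(sizes[ids]),
    intra = intra[ids], inter = inter[ids], difference = diff[ids],
    action = ifelse(!(ids %in% qualifying), "below-min-size",
                    ifelse(ids %in% omitted, "omitted", "selected")),
    row.names = NULL, stringsAsFactors = FALSE)
  list(selected = selected, table = table)
}
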