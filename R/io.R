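# Plain-text interchange: fingerprints as MatrixMarket sparse matrices or
# CSV, compound records as flat CSV (annotations collapsed into one
# "type:pPot:confidence;..." column), truth sets as JSON.

#' Write / read fingerprints as a MatrixMarket sparse matrix
#'
#' Compound ids and feature names travel in a `<path>.rownames` /
#' `.colnames` sidecar pair, one name per line.
#'
#' @param X Binary fingerprint matrix.
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_fingerprints_mtx <- function(X, path) {
  check_binary_matrix(X)
  Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), path)
  writeLines(rownames(X) %||% character(0), paste0(path, ".rownames"))
  writeLines(colnames(X) %||% character(0), paste0(path, ".colnames"))
  invisible(path)
}

#' @rdname write_fingerprints_mtx
#' @export
read_fingerprints_mtx <- function(path) {
  X <- as.matrix(Matrix::readMM(path))
  storage.mode(X) <- "integer"
  rn <- paste0(path, ".rownames")
  cn <- paste0(path, ".colnames")
  if (file.exists(rn)) {
    nm <- readLines(rn)
    if (length(nm) == nrow(X)) rownames(X) <- nm
  }
  if (file.exists(cn)) {
    nm <- readLines(cn)
    if (length(nm) == ncol(X)) colnames(X) <- nm
  }
  X
}

collapse_annotations <- function(ann) {
  if (nrow(ann) == 0L) return("")
  paste(sprintf("%s:%.10g:%d", ann$type, ann$ppot, ann$confidence),
        collapse = ";")
}

expand_annotations <- function(s) {
  if (is.na(s) || !nzchar(s)) return(potency_annotations())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  potency_annotations(
    type = vapply(parts, `[[`, character(1), 1L),
    ppot = as.numeric(vapply(parts, `[[`, character(1), 2L)),
    confidence = as.integer(vapply(parts, `[[`, character(1), 3L)))
}

#' Write / read compound records as CSV
#'
#' Header: `compound_id, class_label, molecular_mass, annotations,
#' interference_flag, aggregator_flag, rule_violation_flag`. Fingerprints
#' are stored separately (see [write_fingerprints_mtx()]).
#'
#' @param records List of [compound_record()] objects.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  df <- data.frame(
    compound_id = vapply(records, `[[`, character(1), "compound_id"),
    class_label = vapply(records, `[[`, character(1), "class_label"),
    molecular_mass = vapply(records, `[[`, numeric(1), "molecular_mass"),
    annotations = vapply(records, function(r) collapse_annotations(r$annotations),
                         character(1)),
    interference_flag = vapply(records, `[[`, logical(1), "interference_flag"),
    aggregator_flag = vapply(records, `[[`, logical(1), "aggregator_flag"),
    rule_violation_flag = vapply(records, `[[`, logical(1),
                                 "rule_violation_flag"),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    compound_record(
      compound_id = df$compound_id[i], class_label = df$class_label[i],
      annotations = expand_annotations(df$annotations[i]),
      molecular_mass = df$molecular_mass[i],
      interference_flag = df$interference_flag[i],
      aggregator_flag = df$aggregator_flag[i],
      rule_violation_flag = df$rule_violation_flag[i])
  })
}

#' Write the planted-truth sets of a synthetic dataset as JSON
#' @param dataset An `fpshap_dataset`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(dataset, path) {
  jsonlite::write_json(dataset$truth, path, digits = NA)
  invisible(path)
}
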