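#' Read an expression matrix from tab-separated text
#'
#' Expects probes in rows, a header row of sample ids, and the probe id in
#' the first column.
#'
#' @param path file path.
#' @return numeric probe x sample matrix with dimnames.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1]]
  check_expression_matrix(m)
  m
}

#' Write an expression matrix as tab-separated text
#'
#' @param expr probe x sample matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(probe_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' One row per sample; must contain at least `sample_id` and `is_case`.
#'
#' @param path file path.
#' @return data.frame keyed by `sample_id`.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "is_case") %in% names(md)))
    stopf("metadata must have sample_id and is_case columns")
  md$is_case <- as.logical(md$is_case)
  md
}

#' Read a probe annotation table
#'
#' @param path file path.
#' @return data.frame keyed by `probe_id`.
#' @export
read_annotation <- function(path) {
  an <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chromosome", "is_specific", "is_retired")
  if (!all(need %in% names(an)))
    stopf("annotation must have columns: %s", paste(need, collapse = ", "))
  an
}

write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `expression.tsv`, `metadata.tsv`, `annotation.tsv` and a JSON
#' `truth.json` ground-truth file.
#'
#' @param dataset a `dcoex_dataset` from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(dataset$expression, file.path(dir, "expression.tsv"))
  write_table_tsv(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_table_tsv(dataset$annotation, file.path(dir, "annotation.tsv"))
  jsonlite::write_json(
    list(truth = dataset$truth, truth_samples = dataset$truth_samples),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
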