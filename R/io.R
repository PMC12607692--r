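# Plain-text readers/writers for the pipeline's interchange formats.

#' Write a probes x samples matrix as TSV
#'
#' First column holds probe IDs (header `probe_id`), remaining columns are
#' samples named by the matrix's column names.
#'
#' @param m numeric matrix with dimnames.
#' @param path output file.
#' @export
write_beta_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probes x samples TSV written by [write_beta_tsv()]
#'
#' @param path input file.
#' @return Numeric matrix with probe IDs as rownames and sample IDs as
#'   colnames.
#' @export
read_beta_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2, "beta TSV needs a probe_id column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a phenotype CSV
#'
#' Expects at least `sample_id` and a group column (default
#' `bedtime_group`).
#'
#' @param path input CSV.
#' @param group_col name of the group column.
#' @return data.frame with the group column as a factor.
#' @export
read_phenotypes <- function(path, group_col = "bedtime_group") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that("sample_id" %in% names(df), "phenotype table lacks sample_id")
  assert_that(group_col %in% names(df),
              "phenotype table lacks group column '%s'", group_col)
  df[[group_col]] <- factor(df[[group_col]])
  df
}

#' Serialize a SWAG model library as JSON lines
#'
#' One model per line: variables, parameter count, log-likelihood, AIC and
#' convergence flag. A companion summary (counts per dimension, minimum AIC)
#' is written alongside when `summary_path` is given.
#'
#' @param library a flat list of model records (see [swag()]).
#' @param path output `.jsonl` file.
#' @param summary_path optional summary JSON path.
#' @export
write_swag_library <- function(library, path, summary_path = NULL) {
  lines <- vapply(library, function(r) {
    jsonlite::toJSON(list(variables = r$variables, k = r$k,
                          loglik = r$loglik, aic = r$aic,
                          converged = r$converged),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  if (!is.null(summary_path)) {
    sizes <- vapply(library, function(r) length(r$variables), integer(1))
    jsonlite::write_json(
      list(n_models = length(library),
           per_dimension = as.list(table(sizes)),
           min_aic = if (length(library)) min(vapply(library, `[[`, 0, "aic")) else NA),
      summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a SWAG model library from JSON lines
#'
#' @param path `.jsonl` file written by [write_swag_library()].
#' @return A list of model records.
#' @export
read_swag_library <- function(path) {
  lapply(readLines(path), function(l) {
    r <- jsonlite::fromJSON(l)
    r$variables <- as.character(r$variables)
    r
  })
}
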