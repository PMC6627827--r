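# Plain-text readers/writers for the pipeline's tabular interchange formats.

#' Read an expression TSV (genes in rows, patients in columns)
#'
#' Expects a header row of patient identifiers and a first column of gene
#' identifiers (any name; renamed to `gene`).
#'
#' @param path File path.
#' @return A tibble with a `gene` column plus one numeric column per patient.
#' @export
read_expression_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "gene"
  as_expr_matrix(x)   # validate
  x
}

#' Write an expression table to TSV
#' @param expr Expression data frame or matrix.
#' @param path File path.
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(expr_as_tibble(as_expr_matrix(expr)), path)
}

#' Read a clinical TSV (`patient_id`, `time`, `event`, extra columns kept)
#' @param path File path.
#' @return A tibble.
#' @export
read_clinical_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("patient_id", "time", "event") %in% names(x))) {
    abort("clinical TSV needs columns patient_id, time, event")
  }
  x
}

#' Read a two-column PPI edge-list TSV (`from`, `to`)
#' @param path File path.
#' @return A tibble `from`, `to`.
#' @export
read_edge_list_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(x) < 2) abort("edge list needs two columns")
  names(x)[1:2] <- c("from", "to")
  x[1:2]
}

#' Write a synthetic cohort's tables to a directory
#'
#' Emits `expression.tsv`, `clinical.tsv`, `scaffold.tsv` and `truth.tsv`
#' in the layouts the pipeline readers expect.
#'
#' @param cohort A `synth_cohort` from [simulate_cohort()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$expression, file.path(outdir, "expression.tsv"))
  readr::write_tsv(cohort$clinical, file.path(outdir, "clinical.tsv"))
  readr::write_tsv(cohort$scaffold, file.path(outdir, "scaffold.tsv"))
  readr::write_tsv(cohort$truth, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}
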