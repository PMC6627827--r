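# Internal helpers shared across modules.

#' Derive a child seed from a master seed and a stream index
#'
#' Gives every randomised sub-computation (one per candidate pair, one per
#' matching run, ...) its own reproducible RNG stream so results do not depend
#' on evaluation order. Kept below 2^31 so it is always a valid R integer seed.
#' @noRd
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + as.numeric(index)) %%
               2147483647)
}

#' Run code under a temporary seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Coerce expression input to a genes x patients numeric matrix
#'
#' Accepts either a numeric matrix with gene rownames and patient colnames, or
#' a data frame whose first column (named `gene`) holds gene identifiers and
#' whose remaining columns are one per patient.
#' @noRd
as_expr_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(rownames(expr)) || is.null(colnames(expr))) {
      abort("expression matrix must have gene rownames and patient colnames")
    }
    m <- expr
  } else if (is.data.frame(expr)) {
    gene_col <- if ("gene" %in% names(expr)) "gene" else names(expr)[1]
    m <- as.matrix(expr[setdiff(names(expr), gene_col)])
    rownames(m) <- as.character(expr[[gene_col]])
  } else {
    abort("`expr` must be a matrix or a data frame with a gene column")
  }
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) abort("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) abort("duplicate patient identifiers")
  if (!all(is.finite(m))) abort("expression values must all be finite")
  m
}

#' Genes x patients matrix back to the package's wide tibble layout
#' @noRd
expr_as_tibble <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(gene = rownames(m)),
    tibble::as_tibble(m)
  )
}

#' Stop with the pipeline stage name attached to the condition message
#' @noRd
run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
          parent = e)
  })
}
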