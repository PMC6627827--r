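#' Select a differential signature from driver candidates by t-test
#'
#' Each candidate gene's *continuous* expression is compared between high-
#' and low-risk training patients with a two-sided two-sample t-test
#' (Welch by default; Student optionally). Genes with `p < threshold` form
#' the signature, sorted by ascending p-value. A gene with zero variance in
#' both classes is assigned `p = 1` by convention.
#'
#' @param expr Continuous expression (data frame with `gene` column, or
#'   matrix with gene rownames).
#' @param labels Risk-label table from [label_risk()]; only patients
#'   labelled high or low are used.
#' @param candidates Character vector of candidate gene identifiers
#'   (typically from [select_candidates()]).
#' @param threshold p-value cutoff (study default 0.002).
#' @param var_equal `FALSE` (Welch, default) or `TRUE` (Student).
#' @return A tibble of class `"signature"` with columns `gene`, `p_value`,
#'   rows sorted by ascending `p_value`, and attribute `threshold`.
#' @export
select_signature <- function(expr, labels, candidates, threshold = 0.002,
                             var_equal = FALSE) {
  m <- as_expr_matrix(expr)
  miss <- setdiff(candidates, rownames(m))
  if (length(miss) > 0) {
    abort(paste0("candidate genes missing from expression: ",
                 paste(utils::head(miss, 5), collapse = ", ")))
  }
  keep <- labels$label %in% c("high", "low")
  pats <- intersect(colnames(m), labels$patient_id[keep])
  risk <- labels$risk[match(pats, labels$patient_id)]
  hi <- pats[risk == 1]
  lo <- pats[risk == 0]
  if (length(hi) < 2 || length(lo) < 2) {
    abort("need at least 2 patients per risk class for the t-test")
  }
  p <- vapply(candidates, function(g) {
    x <- m[g, hi]
    y <- m[g, lo]
    if (sd(x) == 0 && sd(y) == 0) return(1)
    t.test(x, y, var.equal = var_equal)$p.value
  }, numeric(1))
  keep_g <- p < threshold
  out <- tibble::tibble(gene = candidates[keep_g], p_value = unname(p[keep_g])) %>%
    dplyr::arrange(.data$p_value, .data$gene)
  structure(out, threshold = threshold,
            n_candidates = length(candidates),
            class = c("signature", class(out)))
}
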