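# Nearest-centroid risk classifier over the signature genes. The model is a
# pair of class-mean expression vectors; a sample is scored by the linear
# statistic gamma = <s - c_mid, w> with c_mid the midpoint of the centroids
# and w their difference, which equals half the difference of squared
# Euclidean distances to the two centroids.

#' Fit a nearest-centroid classifier on signature genes
#'
#' Computes the arithmetic-mean expression centroid of the high-risk
#' (positive) and low-risk (negative) training patients over the signature
#' genes, their midpoint, and the weight vector `w = c_plus - c_minus`.
#' No feature standardization is applied by default; optionally expression
#' can be z-scored with training-set statistics.
#'
#' @param expr Continuous expression (data frame with `gene` column or
#'   matrix).
#' @param labels Risk-label table from [label_risk()]; high/low labelled
#'   patients present in `expr` form the training set.
#' @param signature Character vector of signature genes, or a `signature`
#'   tibble from [select_signature()].
#' @param standardize If `TRUE`, z-score each gene with training mean/sd
#'   before fitting (and store the statistics for prediction). Default
#'   `FALSE`.
#' @return A list of class `"centroid_model"`: `genes`, `c_plus`, `c_minus`,
#'   `c_mid`, `w`, `n_plus`, `n_minus`, `standardize` (+ `center`, `scale`
#'   when standardizing).
#' @export
fit_centroid <- function(expr, labels, signature, standardize = FALSE) {
  genes <- if (is.data.frame(signature)) signature$gene else as.character(signature)
  if (length(genes) == 0) abort("signature is empty")
  m <- as_expr_matrix(expr)
  miss <- setdiff(genes, rownames(m))
  if (length(miss) > 0) {
    abort(paste0("signature genes missing from expression: ",
                 paste(utils::head(miss, 5), collapse = ", ")))
  }
  keep <- labels$label %in% c("high", "low")
  pats <- intersect(colnames(m), labels$patient_id[keep])
  risk <- labels$risk[match(pats, labels$patient_id)]
  hi <- pats[risk == 1]
  lo <- pats[risk == 0]
  if (length(hi) < 1 || length(lo) < 1) {
    abort("both risk classes must be non-empty to fit centroids")
  }
  m <- m[genes, , drop = FALSE]
  center <- scale_ <- NULL
  if (standardize) {
    tr <- m[, pats, drop = FALSE]
    center <- rowMeans(tr)
    scale_ <- apply(tr, 1, sd)
    scale_[scale_ == 0] <- 1
    m <- (m - center) / scale_
  }
  c_plus <- rowMeans(m[, hi, drop = FALSE])
  c_minus <- rowMeans(m[, lo, drop = FALSE])
  structure(
    list(
      genes = genes,
      c_plus = c_plus, c_minus = c_minus,
      c_mid = (c_plus + c_minus) / 2,
      w = c_plus - c_minus,
      n_plus = length(hi), n_minus = length(lo),
      standardize = standardize, center = center, scale = scale_
    ),
    class = "centroid_model"
  )
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("Centroid classifier over ", length(x$genes), " signature genes (",
      x$n_plus, " high-risk vs ", x$n_minus, " low-risk training patients)\n",
      sep = "")
  invisible(x)
}

#' Score patients with a fitted centroid model
#'
#' For each patient vector `s` over the signature genes, computes
#' `gamma = <s - c_mid, w>` and predicts high risk (label 1) when
#' `gamma > 0`, low risk otherwise (`gamma = 0` maps to the negative class).
#' `sign(gamma)` is exactly the nearest-centroid assignment by Euclidean
#' distance, since `gamma = (||s - c_minus||^2 - ||s - c_plus||^2) / 2`.
#'
#' @param object A `centroid_model`.
#' @param expr Continuous expression covering all signature genes.
#' @param patients Optional character vector restricting which columns of
#'   `expr` to score; defaults to all.
#' @param ... Unused.
#' @return A tibble `patient_id`, `gamma`, `predicted_label` (integer 0/1).
#' @export
predict.centroid_model <- function(object, expr, patients = NULL, ...) {
  m <- as_expr_matrix(expr)
  miss <- setdiff(object$genes, rownames(m))
  if (length(miss) > 0) {
    abort(paste0("signature genes missing from expression: ",
                 paste(utils::head(miss, 5), collapse = ", ")))
  }
  if (is.null(patients)) patients <- colnames(m)
  bad <- setdiff(patients, colnames(m))
  if (length(bad) > 0) abort("unknown patients requested")
  s <- m[object$genes, patients, drop = FALSE]
  if (isTRUE(object$standardize)) s <- (s - object$center) / object$scale
  gamma <- as.numeric(crossprod(s - object$c_mid, object$w))
  tibble::tibble(
    patient_id = patients,
    gamma = gamma,
    predicted_label = as.integer(gamma > 0)
  )
}
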