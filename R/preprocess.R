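#' Median-binarize an expression matrix
#'
#' For each gene, values not exceeding that gene's median across the supplied
#' patients become 0 and values above it become 1. A constant gene therefore
#' maps to an all-zero row. Binarization is the input representation for the
#' mutual-information machinery of the dependency network; the classifier and
#' the t-test feature selection keep working on continuous expression.
#'
#' @param expr Expression as a data frame with a `gene` column plus one
#'   column per patient, or a numeric matrix with gene rownames. Restrict the
#'   columns first if medians should be computed over a patient subset.
#' @return A tibble of the same shape with values in `{0, 1}`.
#' @examples
#' m <- matrix(1:4, 1, dimnames = list("G1", paste0("P", 1:4)))
#' binarize_expression(m)   # 0 0 1 1
#' @export
binarize_expression <- function(expr) {
  m <- as_expr_matrix(expr)
  if (ncol(m) < 2) abort("need at least 2 patients to binarize")
  med <- apply(m, 1, median)
  expr_as_tibble((m > med) * 1)
}

#' Derive 5-year bone-metastasis risk labels from follow-up data
#'
#' Applies the standard 5-year rule: a patient with an observed event within
#' `threshold_years` is high-risk; a patient followed (with or without a
#' later event) beyond `threshold_years` event-free is low-risk; a patient
#' censored at or before the threshold is uninformative and explicitly marked
#' `excluded` rather than dropped.
#'
#' @param clinical Data frame with columns `patient_id`, `time`, `event`
#'   (1 = event observed, 0 = censored).
#' @param threshold_years Risk horizon, default 5 years.
#' @param time_unit `"years"` or `"months"`; times are converted to years
#'   before thresholding.
#' @return A tibble `patient_id`, `time` (years), `event`, `label` with
#'   `label` in `{"high", "low", "excluded"}` and `risk` (1/0/NA numeric).
#' @examples
#' cl <- data.frame(patient_id = c("a", "b", "c"),
#'                  time = c(3, 7, 3), event = c(1, 0, 0))
#' label_risk(cl)   # high, low, excluded
#' @export
label_risk <- function(clinical, threshold_years = 5, time_unit = c("years", "months")) {
  time_unit <- match.arg(time_unit)
  req <- c("patient_id", "time", "event")
  if (!all(req %in% names(clinical))) {
    abort("clinical table needs columns patient_id, time, event")
  }
  t_years <- if (time_unit == "months") clinical$time / 12 else clinical$time
  if (any(!is.finite(t_years)) || any(t_years < 0)) {
    abort("follow-up times must be finite and non-negative")
  }
  ev <- as.integer(clinical$event)
  if (!all(ev %in% c(0L, 1L))) abort("event must be 0/1")
  label <- dplyr::case_when(
    t_years > threshold_years ~ "low",
    ev == 1L ~ "high",
    .default = "excluded"
  )
  tibble::tibble(
    patient_id = as.character(clinical$patient_id),
    time = t_years,
    event = ev,
    label = label,
    risk = dplyr::case_when(label == "high" ~ 1, label == "low" ~ 0,
                            .default = NA_real_)
  )
}

#' Candidate ordered gene pairs from a PPI scaffold
#'
#' Restricting dependency tests to scaffold edges keeps the search space
#' biologically motivated and the false-discovery burden small. Every
#' undirected scaffold edge whose two genes are both measured contributes both
#' orientations — (B modulates A) and (A modulates B) — because the
#' conditional-mutual-information score is asymmetric. Self-loops and
#' duplicate edges are removed; the output order is deterministic
#' (sorted by modulator, then dependent).
#'
#' @param genes Character vector of measured gene identifiers.
#' @param scaffold Data frame with columns `from`, `to` (gene symbols).
#' @return A tibble `modulator`, `dependent`.
#' @examples
#' candidate_pairs(c("G1", "G2"), data.frame(from = "G1", to = "G2"))
#' @export
candidate_pairs <- function(genes, scaffold) {
  if (!all(c("from", "to") %in% names(scaffold))) {
    abort("scaffold needs columns from, to")
  }
  keep <- scaffold$from %in% genes & scaffold$to %in% genes &
    scaffold$from != scaffold$to
  if (!any(keep)) abort("no scaffold edge has both genes measured")
  a <- scaffold$from[keep]
  b <- scaffold$to[keep]
  out <- tibble::tibble(modulator = c(a, b), dependent = c(b, a)) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$modulator, .data$dependent)
  out
}
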