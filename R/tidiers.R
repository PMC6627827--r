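# broom-style tidiers for the package's fitted objects.

#' Tidy a dependency network into its edge table
#'
#' @param x A `dependency_network`.
#' @param tests If `TRUE`, return all candidate-pair test results rather
#'   than only the significant edges.
#' @param ... Unused.
#' @return A tibble, one row per (candidate) directed edge.
#' @export
tidy.dependency_network <- function(x, tests = FALSE, ...) {
  if (tests) x$tests else x$edges
}

#' One-row summary of a dependency network
#'
#' Degree statistics plus the inference parameters.
#' @param x A `dependency_network`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.dependency_network <- function(x, ...) {
  dplyr::bind_cols(
    network_stats(x),
    tibble::tibble(alpha = x$params$alpha, n_perm = x$params$n_perm,
                   fraction = x$params$fraction,
                   n_candidates = nrow(x$tests))
  )
}

#' Tidy a centroid model into a per-gene table
#'
#' @param x A `centroid_model`.
#' @param ... Unused.
#' @return A tibble `gene`, `c_plus`, `c_minus`, `c_mid`, `w`.
#' @export
tidy.centroid_model <- function(x, ...) {
  tibble::tibble(
    gene = x$genes,
    c_plus = unname(x$c_plus), c_minus = unname(x$c_minus),
    c_mid = unname(x$c_mid), w = unname(x$w)
  )
}

#' One-row summary of a centroid model
#' @param x A `centroid_model`.
#' @param ... Unused.
#' @return A one-row tibble `n_genes`, `n_plus`, `n_minus`, `standardized`.
#' @export
glance.centroid_model <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes), n_plus = x$n_plus,
                 n_minus = x$n_minus, standardized = isTRUE(x$standardize))
}

#' Tidy a survival comparison into its Kaplan-Meier curves
#' @param x A `survival_comparison`.
#' @param ... Unused.
#' @return The per-group KM curve tibble.
#' @export
tidy.survival_comparison <- function(x, ...) x$curves

#' One-row summary of a survival comparison
#' @param x A `survival_comparison`.
#' @param ... Unused.
#' @return A one-row tibble `logrank_chi2`, `logrank_p`.
#' @export
glance.survival_comparison <- function(x, ...) {
  tibble::tibble(logrank_chi2 = x$logrank_chi2, logrank_p = x$logrank_p)
}
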