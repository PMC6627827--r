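# Gene dependency network: conditional mutual information of (dependent gene,
# risk) between the extreme expression strata of a modulator gene, with
# permutation-test edge significance.

# plug-in MI in bits from the 2x2 cell counts; 0 * log(0) terms contribute 0
mi_from_counts <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  if (n == 0) return(0)
  nx1 <- n11 + n10          # x = 1 margin
  ny1 <- n11 + n01
  cell <- function(nxy, nx, ny) {
    if (nxy == 0) 0 else nxy / n * log2(nxy * n / (nx * ny))
  }
  cell(n11, nx1, ny1) + cell(n10, nx1, n - ny1) +
    cell(n01, n - nx1, ny1) + cell(n00, n - nx1, n - ny1)
}

# MI of two 0/1 vectors over an index subset; assumes clean inputs (hot path)
mi_binary_idx <- function(a, r, idx) {
  n <- length(idx)
  ai <- a[idx]
  ri <- r[idx]
  n11 <- sum(ai * ri)
  na <- sum(ai)
  nr <- sum(ri)
  mi_from_counts(n11, na - n11, nr - n11, n - na - nr + n11)
}

#' Mutual information of two binary vectors
#'
#' Plug-in estimate over the empirical 2x2 table,
#' `I(X;Y) = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )`, in bits, with
#' `0 * log` terms taken as 0. Always non-negative and symmetric.
#'
#' @param x,y Equal-length vectors with values in `{0, 1}` (logical allowed).
#' @return Mutual information in bits.
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1))   # 1 bit
#' mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1))   # 0
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least 2 observations")
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    abort("x and y must be binary (0/1)")
  }
  max(mi_binary_idx(x, y, seq_along(x)), 0)
}

# Extreme strata of the modulator: patients sorted ascending by its continuous
# expression after a random shuffle (so ties break randomly but
# reproducibly under the caller's seed); low = first k, high = last k.
modulator_strata <- function(b_raw, fraction) {
  n <- length(b_raw)
  k <- floor(fraction * n)
  if (k < 2) abort("stratum too small: floor(fraction * n) must be >= 2")
  perm <- sample.int(n)
  ord <- perm[order(b_raw[perm])]
  list(low = ord[seq_len(k)], high = ord[seq.int(n - k + 1L, n)], k = k)
}

#' Conditional mutual information of a gene-risk pair given a modulator
#'
#' Quantifies how much the association between a dependent gene's binarized
#' expression and the binary metastasis-risk label differs between patients
#' with extreme expression of a candidate modulator gene:
#' `CMI = I_high(A; risk) - I_low(A; risk)`, where the high (low) stratum is
#' the `fraction` of patients with the highest (lowest) *continuous*
#' expression of the modulator. Can be negative; either sign indicates
#' modulation.
#'
#' @param a_bin Binarized (0/1) expression of the dependent gene A.
#' @param b_raw Continuous expression of the modulator gene B.
#' @param risk Binary risk labels (1 = high risk), same length.
#' @param fraction Tail fraction per stratum, in (0, 0.5]; default 0.35.
#' @param seed Integer seed for the random tie-break in the modulator sort.
#' @return A list with `cmi` (bits), `n_high`, `n_low`.
#' @export
cmi_pair <- function(a_bin, b_raw, risk, fraction = 0.35, seed = 1L) {
  check_cmi_inputs(a_bin, b_raw, risk, fraction)
  a <- as.numeric(a_bin)
  r <- as.numeric(risk)
  with_seed(seed, {
    s <- modulator_strata(b_raw, fraction)
    list(
      cmi = mi_binary_idx(a, r, s$high) - mi_binary_idx(a, r, s$low),
      n_high = s$k, n_low = s$k
    )
  })
}

check_cmi_inputs <- function(a_bin, b_raw, risk, fraction) {
  n <- length(a_bin)
  if (length(b_raw) != n || length(risk) != n) {
    abort("a_bin, b_raw and risk must have equal length")
  }
  if (fraction <= 0 || fraction > 0.5) abort("fraction must lie in (0, 0.5]")
  if (!all(as.numeric(a_bin) %in% c(0, 1)) ||
      !all(as.numeric(risk) %in% c(0, 1))) {
    abort("a_bin and risk must be binary (0/1)")
  }
  if (!all(is.finite(b_raw))) abort("b_raw must be finite")
  invisible(n)
}

# Hot path shared by the permutation test and build_network(): assumes the
# RNG is already seeded and inputs are clean. Under a uniform permutation of
# the modulator's expression (random tie-break included), the two strata are
# exactly a uniformly random pair of disjoint k-subsets of the patients, so
# each null draw samples 2k indices directly instead of re-sorting.
cmi_perm_core <- function(a, b_raw, r, fraction, n_perm) {
  n <- length(a)
  s <- modulator_strata(b_raw, fraction)
  k <- s$k
  obs <- mi_binary_idx(a, r, s$high) - mi_binary_idx(a, r, s$low)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, 2L * k)
    d <- mi_binary_idx(a, r, idx[seq.int(k + 1L, 2L * k)]) -
      mi_binary_idx(a, r, idx[seq_len(k)])
    if (abs(d) >= abs(obs)) hits <- hits + 1L
  }
  c(cmi = obs, p_value = (1 + hits) / (n_perm + 1), k = k)
}

#' Permutation test for a conditional-mutual-information pair
#'
#' The modulator's expression vector is permuted uniformly at random
#' `n_perm` times, the CMI recomputed each time, and the two-sided empirical
#' p-value reported with a pseudocount:
#' `p = (1 + #random |CMI| >= |CMI_obs|) / (n_perm + 1)`.
#'
#' @inheritParams cmi_pair
#' @param n_perm Number of random permutations (the study default is 1000).
#' @param seed Integer seed; the observed tie-break and all null draws come
#'   from this stream.
#' @return A list with `cmi`, `p_value`, `n_high`, `n_low`, `n_perm`.
#' @export
cmi_permutation_test <- function(a_bin, b_raw, risk, fraction = 0.35,
                                 n_perm = 1000L, seed = 1L) {
  check_cmi_inputs(a_bin, b_raw, risk, fraction)
  if (n_perm < 1) abort("n_perm must be >= 1")
  a <- as.numeric(a_bin)
  r <- as.numeric(risk)
  res <- with_seed(seed, cmi_perm_core(a, b_raw, r, fraction, n_perm))
  list(cmi = unname(res["cmi"]), p_value = unname(res["p_value"]),
       n_high = unname(as.integer(res["k"])),
       n_low = unname(as.integer(res["k"])), n_perm = as.integer(n_perm))
}

#' Assemble the gene dependency network
#'
#' Runs the CMI permutation test for every candidate ordered pair
#' (modulator -> dependent) over the non-excluded patients and keeps pairs
#' with `p < alpha` as directed edges. Each pair gets its own RNG stream
#' derived from `seed` and the pair's position in the (deterministic)
#' candidate order, so results are reproducible and independent of
#' evaluation order.
#'
#' @param candidates Tibble from [candidate_pairs()] (`modulator`,
#'   `dependent`).
#' @param binarized Binarized expression (output of [binarize_expression()]).
#' @param expr Continuous expression, same genes/patients.
#' @param labels Risk-label table from [label_risk()]; only patients labelled
#'   high or low enter the test.
#' @param alpha Edge significance level (study default 0.05).
#' @param n_perm Permutations per pair (study default 1000).
#' @param fraction Modulator tail fraction (study default 0.35).
#' @param seed Master seed.
#' @param adjust Optional multiple-testing correction: `"none"` (default,
#'   matching the raw-threshold design) or `"BH"`.
#' @return A `dependency_network` object: list with `edges` (tibble
#'   `modulator`, `dependent`, `cmi`, `p_value`), `tests` (all candidate
#'   results), `nodes` (genes incident to at least one edge), `params`.
#'   [tidy()] returns the edge tibble, [glance()] the summary statistics.
#' @export
build_network <- function(candidates, binarized, expr, labels,
                          alpha = 0.05, n_perm = 1000L, fraction = 0.35,
                          seed = 1L, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  bin <- as_expr_matrix(binarized)
  raw <- as_expr_matrix(expr)
  keep <- labels$label %in% c("high", "low")
  pats <- intersect(colnames(bin), labels$patient_id[keep])
  if (length(pats) < 10) abort("too few labelled patients to build a network")
  risk <- labels$risk[match(pats, labels$patient_id)]
  bin <- bin[, pats, drop = FALSE]
  raw <- raw[, pats, drop = FALSE]
  miss <- setdiff(unique(c(candidates$modulator, candidates$dependent)),
                  rownames(bin))
  if (length(miss) > 0) {
    abort(paste0("candidate genes missing from expression: ",
                 paste(utils::head(miss, 5), collapse = ", ")))
  }

  n_pairs <- nrow(candidates)
  out <- matrix(NA_real_, n_pairs, 3)
  for (i in seq_len(n_pairs)) {
    a <- bin[candidates$dependent[i], ]
    b <- raw[candidates$modulator[i], ]
    out[i, ] <- with_seed(derive_seed(seed, i),
                          cmi_perm_core(a, b, risk, fraction, n_perm))
  }
  tests <- dplyr::mutate(
    tibble::as_tibble(candidates),
    cmi = out[, 1], p_value = out[, 2],
    n_high = as.integer(out[, 3]), n_low = as.integer(out[, 3])
  )
  p_eff <- if (adjust == "BH") stats::p.adjust(tests$p_value, "BH") else tests$p_value
  edges <- tests[p_eff < alpha, c("modulator", "dependent", "cmi", "p_value")]
  if (nrow(edges) == 0) warn("no significant dependency pairs at this alpha")
  structure(
    list(
      edges = tibble::as_tibble(edges),
      tests = tests,
      nodes = sort(unique(c(edges$modulator, edges$dependent))),
      params = list(alpha = alpha, n_perm = as.integer(n_perm),
                    fraction = fraction, seed = as.integer(seed),
                    adjust = adjust, n_patients = length(pats))
    ),
    class = "dependency_network"
  )
}

#' @export
print.dependency_network <- function(x, ...) {
  cat("Gene dependency network: ", nrow(x$edges), " directed edges among ",
      length(x$nodes), " genes\n", sep = "")
  cat("  (", nrow(x$tests), " candidate pairs tested, alpha = ",
      x$params$alpha, ", ", x$params$n_perm, " permutations, fraction = ",
      x$params$fraction, ")\n", sep = "")
  invisible(x)
}

# log10-log10 least-squares fit of the degree frequency distribution;
# degree-0 nodes and empty bins are excluded. Needs >= 3 distinct degrees.
powerlaw_fit <- function(deg) {
  tab <- table(deg[deg > 0])
  if (length(tab) < 3) return(c(r2 = NA_real_, corr = NA_real_))
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  fit <- stats::lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)   # perfect 3-point fits warn
  c(r2 = r2, corr = stats::cor(x, y))
}

#' Degree statistics and scale-free diagnostics of a dependency network
#'
#' Mean in-/out-degree (edges over nodes) and, for each direction, the R^2
#' and Pearson correlation of a least-squares line on log10(degree) vs
#' log10(frequency) — the conventional check that the degree distribution is
#' power-law-like. Fits with fewer than 3 distinct degrees are reported `NA`.
#'
#' @param net A `dependency_network`, or a data frame of directed edges with
#'   columns `modulator`, `dependent`.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `mean_in_degree`,
#'   `mean_out_degree`, `powerlaw_r2_in`, `powerlaw_r2_out`,
#'   `powerlaw_corr_in`, `powerlaw_corr_out`.
#' @export
network_stats <- function(net) {
  edges <- if (inherits(net, "dependency_network")) net$edges else net
  if (nrow(edges) == 0) abort("network has no edges")
  nodes <- sort(unique(c(edges$modulator, edges$dependent)))
  in_deg <- table(factor(edges$dependent, levels = nodes))
  out_deg <- table(factor(edges$modulator, levels = nodes))
  fin <- powerlaw_fit(as.numeric(in_deg))
  fout <- powerlaw_fit(as.numeric(out_deg))
  tibble::tibble(
    n_nodes = length(nodes), n_edges = nrow(edges),
    mean_in_degree = nrow(edges) / length(nodes),
    mean_out_degree = nrow(edges) / length(nodes),
    powerlaw_r2_in = unname(fin["r2"]), powerlaw_r2_out = unname(fout["r2"]),
    powerlaw_corr_in = unname(fin["corr"]),
    powerlaw_corr_out = unname(fout["corr"])
  )
}
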