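# Independent oracle implementations used to cross-check the package's
# computations. Deliberately written from first principles (plug-in
# entropies, brute-force concordance counting, explicit observed/expected
# survival tables) rather than reusing package internals.

# plug-in entropy (bits) of an empirical discrete distribution
oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# MI via the entropy identity I(X;Y) = H(X) + H(Y) - H(X,Y)
oracle_mi <- function(x, y) {
  oracle_entropy(x) + oracle_entropy(y) -
    oracle_entropy(paste(x, y, sep = "|"))
}

# CMI from first principles: ascending sort of the modulator (assumes no
# ties), first/last floor(f*n) patients, entropy-based MI per stratum
oracle_cmi <- function(a_bin, b_raw, risk, fraction = 0.35) {
  stopifnot(!anyDuplicated(b_raw))   # tie-free so no tie-break needed
  n <- length(b_raw)
  k <- floor(fraction * n)
  ord <- order(b_raw)
  lo <- ord[seq_len(k)]
  hi <- ord[seq.int(n - k + 1, n)]
  oracle_mi(a_bin[hi], risk[hi]) - oracle_mi(a_bin[lo], risk[lo])
}

# AUC by brute force over all label-discordant pairs (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
  conc / (length(pos) * length(neg))
}

# two-group log-rank by explicit iteration over distinct event times:
# observed and expected events per group plus the hypergeometric variance
oracle_logrank <- function(time, event, group) {
  g <- as.character(group)
  lv <- sort(unique(g))
  stopifnot(length(lv) == 2)
  times <- sort(unique(time[event == 1]))
  obs <- exp1 <- v <- 0
  obs_tab <- stats::setNames(c(0, 0), lv)
  exp_tab <- stats::setNames(c(0, 0), lv)
  for (t in times) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    d_tot <- sum(event == 1 & time == t)
    n1 <- sum(at_risk & g == lv[1])
    d1 <- sum(event == 1 & time == t & g == lv[1])
    e1 <- d_tot * n1 / n_tot
    obs_tab[1] <- obs_tab[1] + d1
    obs_tab[2] <- obs_tab[2] + (d_tot - d1)
    exp_tab[1] <- exp_tab[1] + e1
    exp_tab[2] <- exp_tab[2] + (d_tot - e1)
    obs <- obs + d1
    exp1 <- exp1 + e1
    if (n_tot > 1) {
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  chi2 <- if (v > 0) (obs - exp1)^2 / v else 0
  list(observed = obs_tab, expected = exp_tab, chi2 = chi2,
       p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# Welch two-sample t-test p-value from the textbook formulas
oracle_welch_p <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  tt <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(tt), df)
}

# random simple digraph as an edge tibble over nodes "n1".."nn"
rand_digraph <- function(n, p = 0.3) {
  nodes <- paste0("n", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  tibble::tibble(modulator = pairs$from[keep], dependent = pairs$to[keep])
}

# exact maximum-matching size of a digraph edge table via the subset-DP
# verification routine (independent of the augmenting-path implementation)
oracle_matching_size <- function(edges, nodes) {
  if (nrow(edges) == 0) return(0L)
  bonemet:::cpp_dp_matching_size(
    length(nodes),
    match(edges$modulator, nodes) - 1L,
    match(edges$dependent, nodes) - 1L
  )
}

# small labelled clinical table builder
clin <- function(...) {
  d <- tibble::tribble(...)
  names(d) <- c("patient_id", "time", "event")
  d
}
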