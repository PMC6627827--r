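test_that("mutual information matches hand values and the entropy oracle", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)

  # 2x2 table [[30,10],[10,30]]
  x <- rep(c(0, 0, 1, 1), c(30, 10, 10, 30))
  y <- rep(c(0, 1, 0, 1), c(30, 10, 10, 30))
  expect_equal(mutual_information(x, y), oracle_mi(x, y), tolerance = 1e-12)

  expect_error(mutual_information(c(0, 1), c(0, 1, 0)), "equal length")
  expect_error(mutual_information(c(0, 2, 1), c(0, 1, 0)), "binary")
})

test_that("mutual information is symmetric and non-negative on random tables", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(4:60, 1)
    x <- rbinom(n, 1, runif(1, 0.1, 0.9))
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    mi <- mutual_information(x, y)
    expect_gte(mi, 0)
    expect_equal(mi, mutual_information(y, x), tolerance = 1e-12)
    expect_equal(mi, oracle_mi(x, y), tolerance = 1e-9)
  }
})

test_that("cmi_pair recovers its construction and matches the oracle", {
  # independence everywhere -> CMI near 0
  set.seed(21)
  n <- 1000
  a <- rbinom(n, 1, 0.5)
  b <- rnorm(n)
  r <- rbinom(n, 1, 0.4)
  expect_lt(abs(cmi_pair(a, b, r)$cmi), 0.02)

  # a == risk in the high stratum, independent in the low stratum:
  # CMI approaches 1 bit
  b2 <- seq_len(n)           # deterministic strata, no ties
  k <- floor(0.35 * n)
  hi <- seq.int(n - k + 1, n)
  a2 <- rbinom(n, 1, 0.5)
  r2 <- rbinom(n, 1, 0.5)
  a2[hi] <- r2[hi]
  res <- cmi_pair(a2, b2, r2)
  expect_equal(res$n_high, k)
  expect_equal(res$n_low, k)
  expect_gt(res$cmi, 0.9)

  # oracle equivalence on planted synthetic pairs (tie-free b)
  set.seed(22)
  for (i in 1:20) {
    m <- 400
    b3 <- rnorm(m)
    r3 <- rbinom(m, 1, 0.35)
    a3 <- ifelse(b3 > median(b3), rbinom(m, 1, 0.3 + 0.4 * r3),
                 rbinom(m, 1, 0.5))
    expect_equal(cmi_pair(a3, b3, r3)$cmi, oracle_cmi(a3, b3, r3),
                 tolerance = 1e-12)
  }

  expect_error(cmi_pair(a, b, r, fraction = 0.6), "fraction")
  expect_error(cmi_pair(c(0, 1, 0, 1), c(1, 2, 3, 4), c(0, 1, 0, 1)),
               "stratum too small")
})

test_that("cmi is asymmetric on a directionally planted pair", {
  set.seed(23)
  n <- 2000
  b <- rnorm(n)
  r <- rbinom(n, 1, 0.4)
  a_bin <- ifelse(b > median(b), rbinom(n, 1, 0.15 + 0.6 * r), rbinom(n, 1, 0.5))
  a_raw <- rnorm(n, mean = 2 * a_bin - 1, sd = 0.6)
  b_bin <- as.numeric(b > median(b))
  fwd <- cmi_pair(a_bin, b, r)$cmi
  rev <- cmi_pair(b_bin, a_raw, r)$cmi
  expect_gt(fwd, 0.05)
  expect_gt(fwd, abs(rev) * 2)
})

test_that("permutation p-values follow the pseudocount formula", {
  # strong planted signal beats all random permutations
  set.seed(31)
  n <- 600
  b <- seq_len(n)
  k <- floor(0.35 * n)
  r <- rbinom(n, 1, 0.5)
  a <- rbinom(n, 1, 0.5)
  a[seq.int(n - k + 1, n)] <- r[seq.int(n - k + 1, n)]
  res <- cmi_permutation_test(a, b, r, n_perm = 1000, seed = 4)
  expect_equal(res$p_value, 1 / 1001)

  # constant dependent gene: CMI exactly 0, p at the top of its range
  res0 <- cmi_permutation_test(rep(0, n), b, r, n_perm = 200, seed = 4)
  expect_equal(res0$cmi, 0)
  expect_equal(res0$p_value, 1)
})

test_that("permutation p-values are invariant to joint patient relabeling", {
  set.seed(32)
  n <- 300
  a <- rbinom(n, 1, 0.5)
  b <- rnorm(n)
  r <- rbinom(n, 1, 0.4)
  p1 <- cmi_permutation_test(a, b, r, n_perm = 100, seed = 9)$p_value
  perm <- sample.int(n)
  p2 <- cmi_permutation_test(a[perm], b[perm], r[perm],
                             n_perm = 100, seed = 9)$p_value
  # same joint distribution; p-values are equal in distribution and, with a
  # tie-free b, the observed CMI is identical
  expect_equal(cmi_pair(a, b, r)$cmi, cmi_pair(a[perm], b[perm], r[perm])$cmi,
               tolerance = 1e-12)
  expect_lt(abs(p1 - p2), 0.1)
})

test_that("build_network filters by significance and is reproducible", {
  cfg <- synth_config(n_genes = 40, n_patients = 300, n_planted_pairs = 6,
                      effect_size = 0.6, seed = 13)
  coh <- simulate_cohort(cfg)
  lab <- label_risk(coh$clinical)
  m <- bonemet:::as_expr_matrix(coh$expression)
  bin <- binarize_expression(m)
  cand <- candidate_pairs(rownames(m), coh$scaffold)

  net1 <- build_network(cand, bin, m, lab, n_perm = 100, seed = 17)
  net2 <- build_network(cand, bin, m, lab, n_perm = 100, seed = 17)
  expect_identical(net1$edges, net2$edges)
  expect_true(all(net1$edges$p_value < 0.05))
  expect_equal(nrow(net1$tests), nrow(cand))
  expect_setequal(net1$nodes,
                  unique(c(net1$edges$modulator, net1$edges$dependent)))

  # alpha = 0 can admit no edge
  expect_warning(
    net0 <- build_network(cand[1:10, ], bin, m, lab, alpha = 0,
                          n_perm = 50, seed = 1),
    "no significant"
  )
  expect_equal(nrow(net0$edges), 0)
})

test_that("network_stats reports exact degree means and a regression-oracle fit", {
  cycle <- tibble::tibble(modulator = c("a", "b", "c"),
                          dependent = c("b", "c", "a"))
  st <- network_stats(cycle)
  expect_equal(st$mean_in_degree, 1)
  expect_equal(st$mean_out_degree, 1)

  star <- tibble::tibble(modulator = rep("hub", 4),
                         dependent = paste0("leaf", 1:4))
  st2 <- network_stats(star)
  expect_equal(st2$mean_out_degree, 4 / 5)
  # fewer than 3 distinct degree values: fit undefined
  expect_true(is.na(st2$powerlaw_r2_out))

  # scale-free-ish synthetic network: R^2 equals an independent log-log fit
  set.seed(51)
  deg_pool <- rep(paste0("n", 1:40), times = pmax(1, rpois(40, c(rep(8, 5), rep(1, 35)))))
  edges <- tibble::tibble(modulator = sample(deg_pool, 150, replace = TRUE),
                          dependent = sample(paste0("n", 1:40), 150, replace = TRUE))
  edges <- edges[edges$modulator != edges$dependent, ]
  edges <- dplyr::distinct(edges)
  st3 <- network_stats(edges)
  out_deg <- table(edges$modulator)
  tab <- table(as.numeric(out_deg))
  fit <- lm(log10(as.numeric(tab)) ~ log10(as.numeric(names(tab))))
  expect_equal(st3$powerlaw_r2_out, summary(fit)$r.squared, tolerance = 1e-9)
})
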