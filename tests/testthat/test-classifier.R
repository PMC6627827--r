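fit_toy <- function(n_hi = 10, n_lo = 14, n_genes = 6, seed = 81) {
  set.seed(seed)
  lab <- tibble::tibble(
    patient_id = sprintf("p%03d", seq_len(n_hi + n_lo)),
    time = 1, event = 1L,
    label = c(rep("high", n_hi), rep("low", n_lo)),
    risk = c(rep(1, n_hi), rep(0, n_lo))
  )
  m <- matrix(rnorm((n_hi + n_lo) * n_genes), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)), lab$patient_id))
  m[, lab$risk == 1] <- m[, lab$risk == 1] + 0.8
  list(m = m, lab = lab)
}

test_that("centroids are class means with the exact midpoint/weight identities", {
  d <- fit_toy()
  fit <- fit_centroid(d$m, d$lab, rownames(d$m))
  hi <- d$lab$patient_id[d$lab$risk == 1]
  lo <- d$lab$patient_id[d$lab$risk == 0]
  expect_equal(fit$c_plus, rowMeans(d$m[, hi]), tolerance = 1e-12)
  expect_equal(fit$c_minus, rowMeans(d$m[, lo]), tolerance = 1e-12)
  expect_identical(fit$c_mid, (fit$c_plus + fit$c_minus) / 2)
  expect_identical(fit$w, fit$c_plus - fit$c_minus)
  expect_equal(fit$n_plus + fit$n_minus, nrow(d$lab))

  # one patient per class: centroids equal those patients' vectors
  lab1 <- d$lab[c(1, nrow(d$lab)), ]
  fit1 <- fit_centroid(d$m, lab1, rownames(d$m))
  expect_equal(fit1$c_plus, d$m[, lab1$patient_id[1]])
  expect_equal(fit1$c_minus, d$m[, lab1$patient_id[2]])
})

test_that("swapping class labels negates w and keeps c_mid", {
  d <- fit_toy(seed = 82)
  fit <- fit_centroid(d$m, d$lab, rownames(d$m))
  flipped <- d$lab
  flipped$risk <- 1 - flipped$risk
  flipped$label <- ifelse(flipped$label == "high", "low", "high")
  fit2 <- fit_centroid(d$m, flipped, rownames(d$m))
  expect_equal(fit2$w, -fit$w, tolerance = 1e-12)
  expect_equal(fit2$c_mid, fit$c_mid, tolerance = 1e-12)
})

test_that("gamma equals the Euclidean distance-difference identity", {
  d <- fit_toy(seed = 83)
  fit <- fit_centroid(d$m, d$lab, rownames(d$m))
  set.seed(84)
  samples <- matrix(rnorm(1000 * nrow(d$m), sd = 2), nrow(d$m),
                    dimnames = list(rownames(d$m), sprintf("s%04d", 1:1000)))
  pred <- predict(fit, samples)
  for (i in seq_len(ncol(samples))) {
    s <- samples[, i]
    ident <- (sum((s - fit$c_minus)^2) - sum((s - fit$c_plus)^2)) / 2
    expect_equal(pred$gamma[i], ident, tolerance = 1e-9)
  }
  # sign(gamma) is the nearest-centroid rule
  d_plus <- colSums((samples - fit$c_plus)^2)
  d_minus <- colSums((samples - fit$c_minus)^2)
  expect_equal(pred$predicted_label, as.integer(d_plus < d_minus))
})

test_that("boundary cases follow the decision rule", {
  d <- fit_toy(seed = 85)
  fit <- fit_centroid(d$m, d$lab, rownames(d$m))

  mid <- matrix(fit$c_mid, ncol = 1,
                dimnames = list(fit$genes, "midpoint"))
  p_mid <- predict(fit, mid)
  expect_equal(p_mid$gamma, 0, tolerance = 1e-12)
  expect_equal(p_mid$predicted_label, 0L)   # gamma = 0 -> negative class

  plus <- matrix(fit$c_plus, ncol = 1, dimnames = list(fit$genes, "cp"))
  p_plus <- predict(fit, plus)
  expect_equal(p_plus$gamma, sum(fit$w^2) / 2, tolerance = 1e-12)
  expect_equal(p_plus$predicted_label, 1L)
})

test_that("gamma is translation invariant", {
  d <- fit_toy(seed = 86)
  fit <- fit_centroid(d$m, d$lab, rownames(d$m))
  shift <- rnorm(nrow(d$m))
  fit_shift <- fit_centroid(d$m + shift, d$lab, rownames(d$m))
  s <- matrix(rnorm(nrow(d$m)), ncol = 1, dimnames = list(fit$genes, "x"))
  expect_equal(predict(fit, s)$gamma,
               predict(fit_shift, s + shift)$gamma, tolerance = 1e-9)
})

test_that("degenerate fits and inputs raise errors", {
  d <- fit_toy()
  lab_one <- d$lab
  lab_one$risk <- 1
  lab_one$label <- "high"
  expect_error(fit_centroid(d$m, lab_one, rownames(d$m)), "non-empty")
  expect_error(fit_centroid(d$m, d$lab, c("g1", "nope")), "nope")
  expect_error(fit_centroid(d$m, d$lab, character(0)), "empty")
  fit <- fit_centroid(d$m, d$lab, rownames(d$m))
  expect_error(predict(fit, d$m[-1, ]), "missing")

  # identical centroids: gamma identically 0, all predictions negative
  m_same <- d$m
  m_same[] <- rep(rnorm(nrow(d$m)), ncol(d$m))
  fit_same <- fit_centroid(m_same, d$lab, rownames(d$m))
  pr <- predict(fit_same, d$m)
  expect_true(all(abs(pr$gamma) < 1e-9))
  expect_true(all(pr$predicted_label == 0L))
})
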