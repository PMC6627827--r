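#' Configuration for the synthetic bone-metastasis cohort generator
#'
#' Bundles and validates every knob of the simulator: cohort dimensions, the
#' protein-protein interaction (PPI) scaffold model, the planted
#' modulator-dependent structure, the latent 5-year risk model, and the
#' survival/censoring model. The defaults emulate the study design the
#' pipeline targets: an 855-patient breast-cancer cohort split 380/189/286
#' into training/test/independent sets, a sparse scale-free PPI scaffold, and
#' a moderate planted conditional effect.
#'
#' @param n_genes Number of genes (simulated symbols `G0001`, `G0002`, ...).
#' @param n_patients Number of patients (`P0001`, ...).
#' @param scaffold_model `"barabasi_albert"` (scale-free, preferential
#'   attachment) or `"erdos_renyi"` (uniform random).
#' @param scaffold_param Attachment count `m` (Barabási–Albert) or edge
#'   probability `p` (Erdős–Rényi).
#' @param n_planted_pairs Number of vertex-disjoint scaffold edges on which a
#'   directed modulator -> dependent conditional effect is planted.
#' @param effect_size Shift in high-risk probability for patients in the
#'   active stratum of the modulator whose dependent gene is above its median;
#'   in `[0, 1]` and `baseline_risk + effect_size <= 1`.
#' @param active_stratum Which modulator stratum carries the effect:
#'   `"high"` (above the modulator's median) or `"low"`.
#' @param baseline_risk Probability of the high-risk label absent any planted
#'   effect.
#' @param followup_scale Mean (years) of the exponential follow-up tail for
#'   low-risk patients; high-risk event times use mean `followup_scale / 3`
#'   truncated to the 5-year window.
#' @param censor_rate Probability that a low-risk patient's record is
#'   censored rather than followed to a late event.
#' @param split_fractions Length-3 numeric, train/test/independent fractions
#'   summing to 1.
#' @param seed Integer master seed; everything the generator emits is a
#'   deterministic function of the configuration including this seed.
#'
#' @return A validated list of class `"synth_config"`.
#' @examples
#' cfg <- synth_config(n_genes = 30, n_patients = 120, seed = 7)
#' @export
synth_config <- function(n_genes = 200L,
                         n_patients = 855L,
                         scaffold_model = c("barabasi_albert", "erdos_renyi"),
                         scaffold_param = 2,
                         n_planted_pairs = 20L,
                         effect_size = 0.5,
                         active_stratum = c("high", "low"),
                         baseline_risk = 0.15,
                         followup_scale = 5,
                         censor_rate = 0.3,
                         split_fractions = c(380, 189, 286) / 855,
                         seed = 1L) {
  scaffold_model <- match.arg(scaffold_model)
  active_stratum <- match.arg(active_stratum)
  stopifnot(n_genes >= 4, n_patients >= 2, n_planted_pairs >= 0)
  probs <- c(effect_size, baseline_risk, censor_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("effect_size, baseline_risk and censor_rate must lie in [0, 1]")
  }
  if (baseline_risk + effect_size > 1) {
    abort("baseline_risk + effect_size must not exceed 1")
  }
  if (length(split_fractions) != 3 || any(split_fractions < 0) ||
      abs(sum(split_fractions) - 1) > 1e-9) {
    abort("split_fractions must be 3 non-negative numbers summing to 1")
  }
  if (scaffold_model == "barabasi_albert") {
    if (scaffold_param < 1 || scaffold_param >= n_genes ||
        scaffold_param != round(scaffold_param)) {
      abort("for barabasi_albert, scaffold_param must be an integer in [1, n_genes)")
    }
  } else if (scaffold_param < 0 || scaffold_param > 1) {
    abort("for erdos_renyi, scaffold_param must be a probability")
  }
  if (followup_scale <= 0) abort("followup_scale must be positive")
  structure(
    list(
      n_genes = as.integer(n_genes), n_patients = as.integer(n_patients),
      scaffold_model = scaffold_model, scaffold_param = scaffold_param,
      n_planted_pairs = as.integer(n_planted_pairs),
      effect_size = effect_size, active_stratum = active_stratum,
      baseline_risk = baseline_risk, followup_scale = followup_scale,
      censor_rate = censor_rate, split_fractions = split_fractions,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))
patient_ids <- function(n) sprintf("P%04d", seq_len(n))

#' Generate an undirected PPI-like scaffold
#'
#' Stands in for a curated protein-protein interaction reference: the
#' candidate gene dependency pairs downstream are restricted to its edges.
#' `"barabasi_albert"` grows a scale-free graph by preferential attachment
#' (`m` seed vertices, each newcomer attaching `m` edges to distinct existing
#' vertices, so the graph has exactly `(n - m) * m` edges); `"erdos_renyi"`
#' draws each of the `choose(n, 2)` possible edges independently with
#' probability `p`.
#'
#' @param cfg A [synth_config()].
#' @return A tibble with columns `from`, `to` (gene symbols), one row per
#'   undirected edge, deterministic given `cfg$seed`.
#' @examples
#' simulate_scaffold(synth_config(n_genes = 10, scaffold_param = 2, seed = 1))
#' @export
simulate_scaffold <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  genes <- gene_ids(cfg$n_genes)
  with_seed(derive_seed(cfg$seed, 101L), {
    if (cfg$scaffold_model == "barabasi_albert") {
      el <- ba_edge_list(cfg$n_genes, as.integer(cfg$scaffold_param))
    } else {
      el <- er_edge_list(cfg$n_genes, cfg$scaffold_param)
    }
  })
  tibble::tibble(from = genes[el[, 1]], to = genes[el[, 2]])
}

# Preferential attachment over integer vertex ids: start from m isolated seed
# vertices; vertex v (v > m) attaches m edges to distinct targets sampled
# proportionally to current degree (seed targets 1..m for the first newcomer).
ba_edge_list <- function(n, m) {
  from <- integer((n - m) * m)
  to <- integer((n - m) * m)
  repeated <- integer(0)        # vertex multiset, multiplicity = degree
  targets <- seq_len(m)
  k <- 0L
  for (v in seq.int(m + 1L, n)) {
    from[k + seq_len(m)] <- v
    to[k + seq_len(m)] <- targets
    k <- k + m
    repeated <- c(repeated, targets, rep.int(v, m))
    # sample m *distinct* vertices, degree-proportional, by rejection
    picked <- integer(0)
    while (length(picked) < m) {
      cand <- repeated[sample.int(length(repeated), 1L)]
      if (!cand %in% picked) picked <- c(picked, cand)
    }
    targets <- picked
  }
  cbind(pmin(from, to), pmax(from, to))
}

er_edge_list <- function(n, p) {
  if (p <= 0 || n < 2) return(matrix(integer(0), ncol = 2))
  pairs <- utils::combn(n, 2)
  keep <- runif(ncol(pairs)) < p
  t(pairs[, keep, drop = FALSE])
}

#' Simulate an expression cohort with planted conditional dependencies
#'
#' Draws continuous expression for every gene from a two-component Gaussian
#' mixture (components at -1 and +1, sd 0.6, mixing 1/2), so each gene's
#' median split is non-degenerate. On `n_planted_pairs` vertex-disjoint
#' scaffold edges a directed modulator -> dependent dependency is planted in
#' two layers:
#'
#' 1. *Marginal layer.* The latent 5-year high-risk label is drawn from a
#'    logistic model in the modulator states,
#'    `logit P(high) = logit(baseline_risk + effect_size/2) +
#'    1.5 * effect_size * sum_i (1[B_i active] - 1/2)`, so each modulator is
#'    itself (mildly) risk-associated — mirroring real driver genes, which
#'    are differentially expressed as well as upstream.
#' 2. *Conditional layer.* Within the active stratum of each modulator
#'    (patients above — or below, per `active_stratum` — its median), the
#'    dependent gene's mixture component is redrawn given the risk label so
#'    that `P(high | A above median) - P(high | A below median) =
#'    effect_size` exactly (Bayes inversion around the stratum's realized
#'    risk rate, clamped to (0, 1)); outside the active stratum, and for
#'    every unplanted gene, expression is independent of risk. With
#'    `effect_size = 0` the cohort is exactly null.
#'
#' Because planted pairs are vertex-disjoint and each pair only touches its
#' own dependent gene, pairs do not interfere: every pair carries its full
#' conditional contrast regardless of `n_planted_pairs`.
#'
#' Follow-up times are then drawn conditional on the latent label so that the
#' emitted time/event columns always reproduce the label under the 5-year
#' rule: high-risk patients get an observed event in (0, 5] years, low-risk
#' patients survive event-free past 5 years and are then either censored
#' (probability `censor_rate`) or followed to a late event.
#'
#' @param cfg A [synth_config()].
#' @param scaffold Optional scaffold tibble from [simulate_scaffold()] with
#'   the same config; generated on the fly when omitted.
#' @return A list of class `"synth_cohort"`: `expression` (tibble, `gene`
#'   column + one column per patient), `clinical` (tibble `patient_id`,
#'   `time` in years, `event`), `truth` (tibble `modulator`, `dependent`,
#'   `effect_size`), `scaffold`, and `config`.
#' @examples
#' cfg <- synth_config(n_genes = 30, n_patients = 100, n_planted_pairs = 3,
#'                     seed = 2)
#' coh <- simulate_cohort(cfg)
#' coh$truth
#' @export
simulate_cohort <- function(cfg, scaffold = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(scaffold)) scaffold <- simulate_scaffold(cfg)
  if (cfg$n_planted_pairs > nrow(scaffold)) {
    abort("n_planted_pairs exceeds the number of scaffold edges")
  }
  genes <- gene_ids(cfg$n_genes)
  pats <- patient_ids(cfg$n_patients)
  with_seed(derive_seed(cfg$seed, 202L), {
    # expression: bimodal per gene, i.i.d. across patients
    comp <- matrix(rbinom(cfg$n_genes * cfg$n_patients, 1L, 0.5),
                   cfg$n_genes, cfg$n_patients)
    expr <- matrix(rnorm(cfg$n_genes * cfg$n_patients,
                         mean = ifelse(comp == 1L, 1, -1), sd = 0.6),
                   cfg$n_genes, cfg$n_patients,
                   dimnames = list(genes, pats))

    truth <- plant_pairs(scaffold, cfg$n_planted_pairs, cfg$effect_size)

    above <- expr > apply(expr, 1, median)   # gene x patient median indicator
    active <- function(b_gene) {
      if (cfg$active_stratum == "high") above[b_gene, ] else !above[b_gene, ]
    }

    # marginal layer: logistic risk in the modulator activity states
    lp <- stats::qlogis(min(max(cfg$baseline_risk + cfg$effect_size / 2,
                                1e-6), 1 - 1e-6))
    for (i in seq_len(nrow(truth))) {
      lp <- lp + 1.5 * truth$effect_size[i] * (active(truth$modulator[i]) - 0.5)
    }
    label <- rbinom(cfg$n_patients, 1L, stats::plogis(lp))

    # conditional layer: redraw each dependent gene inside its modulator's
    # active stratum so the risk contrast across A's median equals the
    # planted effect size
    for (i in seq_len(nrow(truth))) {
      e <- truth$effect_size[i]
      if (e == 0) next
      act <- active(truth$modulator[i])
      pi1 <- mean(label[act])
      pi0 <- mean(label[!act])
      if (!is.finite(pi1) || pi1 <= 0 || pi1 >= 1 || !is.finite(pi0)) next
      # centre the contrast on the inactive stratum's rate: the reverse
      # orientation then sees symmetric risk contrasts (+/- e/2) in the two
      # strata of A, so the planted dependency stays directionally
      # asymmetric. The centre is pulled toward the active stratum's rate
      # just enough to keep the Bayes inversion feasible.
      ctr <- min(max(pi0, pi1 - e / 2 + 0.02), pi1 + e / 2 - 0.02)
      p1 <- min(ctr + e / 2, 1 - 1e-3)
      p0 <- max(ctr - e / 2, 1e-3)
      odds <- (1 - pi1) / pi1
      r1 <- p1 / (1 - p1) * odds
      r0 <- p0 / (1 - p0) * odds
      a0 <- min(max((1 - r0) / (r1 - r0), 0), 1)   # P(A comp high | low risk)
      a1 <- min(max(r1 * a0, 0), 1)                # P(A comp high | high risk)
      n_act <- sum(act)
      new_comp <- rbinom(n_act, 1L, ifelse(label[act] == 1L, a1, a0))
      expr[truth$dependent[i], act] <-
        rnorm(n_act, mean = ifelse(new_comp == 1L, 1, -1), sd = 0.6)
      # rebalance the inactive stratum (independently of risk) so the
      # dependent gene's overall high-component frequency stays 1/2 and its
      # median split keeps tracking the mixture component
      w_act <- (pi1 - p0) / (p1 - p0)
      b <- min(max(1 - w_act, 0), 1)
      inact_comp <- rbinom(cfg$n_patients - n_act, 1L, b)
      expr[truth$dependent[i], !act] <-
        rnorm(cfg$n_patients - n_act, mean = ifelse(inact_comp == 1L, 1, -1),
              sd = 0.6)
    }

    # survival consistent with the latent 5-year label
    horizon <- 5
    scale_hi <- cfg$followup_scale / 3
    time <- numeric(cfg$n_patients)
    event <- integer(cfg$n_patients)
    hi <- label == 1L
    # truncated exponential on (0, horizon]
    u <- runif(sum(hi))
    time[hi] <- -scale_hi * log(1 - u * (1 - exp(-horizon / scale_hi)))
    event[hi] <- 1L
    lo <- !hi
    time[lo] <- horizon + rexp(sum(lo), rate = 1 / cfg$followup_scale)
    event[lo] <- rbinom(sum(lo), 1L, 1 - cfg$censor_rate)
  })
  structure(
    list(
      expression = expr_as_tibble(expr),
      clinical = tibble::tibble(patient_id = pats, time = time, event = event),
      truth = truth,
      scaffold = scaffold,
      config = cfg
    ),
    class = "synth_cohort"
  )
}

# Pick n vertex-disjoint scaffold edges and orient each one at random.
plant_pairs <- function(scaffold, n_pairs, effect_size) {
  if (n_pairs == 0L) {
    return(tibble::tibble(modulator = character(0), dependent = character(0),
                          effect_size = numeric(0)))
  }
  ord <- sample.int(nrow(scaffold))
  used <- character(0)
  rows <- integer(0)
  for (i in ord) {
    g <- c(scaffold$from[i], scaffold$to[i])
    if (!any(g %in% used)) {
      rows <- c(rows, i)
      used <- c(used, g)
      if (length(rows) == n_pairs) break
    }
  }
  if (length(rows) < n_pairs) {
    abort("scaffold does not contain enough vertex-disjoint edges to plant")
  }
  flip <- runif(n_pairs) < 0.5
  tibble::tibble(
    modulator = ifelse(flip, scaffold$to[rows], scaffold$from[rows]),
    dependent = ifelse(flip, scaffold$from[rows], scaffold$to[rows]),
    effect_size = effect_size
  )
}

#' Partition patients into training / test / independent sets
#'
#' Sizes are the largest-remainder apportionment of `fractions * n`, so
#' fractions chosen as cohort counts over the total reproduce those counts
#' exactly (e.g. `c(380, 189, 286) / 855` on 855 patients gives 380/189/286).
#' Assignment is a seeded uniform shuffle.
#'
#' @param clinical Data frame with a `patient_id` column.
#' @param fractions Length-3 non-negative numeric summing to 1
#'   (train, test, independent).
#' @param seed Integer seed for the shuffle.
#' @return A tibble `patient_id`, `split` (factor train/test/independent);
#'   a disjoint, exhaustive partition.
#' @export
split_cohort <- function(clinical, fractions = c(0.5, 0.25, 0.25), seed = 1L) {
  if (nrow(clinical) == 0) abort("cannot split an empty cohort")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    abort("fractions must be 3 non-negative numbers summing to 1")
  }
  n <- nrow(clinical)
  sizes <- floor(fractions * n)
  rem <- fractions * n - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    sizes[bump] <- sizes[bump] + 1L
  }
  lev <- c("train", "test", "independent")
  assign <- rep(lev, times = sizes)
  ord <- with_seed(derive_seed(seed, 303L), sample.int(n))
  tibble::tibble(
    patient_id = clinical$patient_id,
    split = factor(assign[ord], levels = lev)
  )
}
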