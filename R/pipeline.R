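#' Run the full bone-metastasis prediction pipeline
#'
#' Orchestrates every stage on one cohort: 5-year risk labelling,
#' train/test/independent splitting, median binarization (over all retained
#' patients), PPI-restricted candidate pairs, CMI dependency-network
#' inference with permutation-test edges (training patients), randomized
#' maximum-matching driver sampling, all-runs driver candidates, t-test
#' signature selection, centroid-classifier fitting (training patients), and
#' evaluation of the held-out splits by survival analysis (all patients,
#' grouped by predicted label) and AUC/accuracy/MCC (labelable patients).
#'
#' Defaults reproduce the study parameterization: 35% modulator strata,
#' edge threshold 0.05 with 1000 permutations, 500 matching runs, t-test
#' threshold 0.002, 5-year horizon.
#'
#' @param expression Expression data frame (`gene` column + patient columns)
#'   or matrix.
#' @param clinical Data frame `patient_id`, `time`, `event`.
#' @param scaffold PPI edge list data frame (`from`, `to`).
#' @param split Optional tibble `patient_id`, `split`
#'   (train/test/independent), e.g. from [split_cohort()]; computed from
#'   `split_fractions` when omitted.
#' @param split_fractions Train/test/independent fractions used when `split`
#'   is missing.
#' @param years_threshold,time_unit Passed to [label_risk()].
#' @param fraction,alpha,n_perm Passed to [build_network()].
#' @param runs Matching runs for [sample_driver_sets()].
#' @param t_threshold Passed to [select_signature()].
#' @param seed Master seed; every stochastic stage derives its own stream.
#' @param outdir Optional directory; when given, per-stage TSV/JSON
#'   artifacts and a reproducibility manifest are written there.
#' @param verbose Print per-stage progress.
#' @return A list of class `"bonemet_run"` with elements `labels`, `split`,
#'   `network`, `network_stats`, `driver_freq`, `driver_candidates`,
#'   `signature`, `model`, `predictions` (all patients, with split),
#'   `evaluation` (per held-out split: `survival`, `metrics`), and
#'   `manifest`.
#' @export
run_pipeline <- function(expression, clinical, scaffold,
                         split = NULL,
                         split_fractions = c(380, 189, 286) / 855,
                         years_threshold = 5, time_unit = "years",
                         fraction = 0.35, alpha = 0.05, n_perm = 1000L,
                         runs = 500L, t_threshold = 0.002,
                         seed = 1L, outdir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  expr_m <- as_expr_matrix(expression)

  say("labelling risk")
  labels <- run_stage("label_risk",
                      label_risk(clinical, years_threshold, time_unit))
  if (is.null(split)) {
    split <- run_stage("split_cohort",
                       split_cohort(clinical, split_fractions,
                                    derive_seed(seed, 1L)))
  }
  stopifnot(all(c("patient_id", "split") %in% names(split)))
  labels <- dplyr::left_join(labels, split, by = "patient_id")

  retained <- labels$patient_id[labels$label != "excluded"]
  train_ids <- labels$patient_id[labels$split == "train" &
                                   labels$label != "excluded"]

  say("binarizing expression")
  bin <- run_stage("binarize",
                   binarize_expression(expr_m[, retained, drop = FALSE]))

  say("candidate pairs")
  cand <- run_stage("candidate_pairs",
                    candidate_pairs(rownames(expr_m), scaffold))

  say("building dependency network (", nrow(cand), " candidate pairs)")
  train_labels <- labels[labels$patient_id %in% train_ids, ]
  net <- run_stage("network", build_network(
    cand, bin, expr_m[, train_ids, drop = FALSE], train_labels,
    alpha = alpha, n_perm = n_perm, fraction = fraction,
    seed = derive_seed(seed, 2L)
  ))
  if (nrow(net$edges) == 0) abort("stage 'network' produced no edges")
  nstats <- network_stats(net)

  say("sampling driver sets (", runs, " runs)")
  freq <- run_stage("drivers",
                    sample_driver_sets(net, runs = runs,
                                       seed = derive_seed(seed, 3L)))
  driver_cand <- select_candidates(freq)
  if (length(driver_cand) == 0) abort("stage 'drivers' produced no all-run candidates")

  say("selecting signature (", length(driver_cand), " candidates)")
  sig <- run_stage("select", select_signature(
    expr_m[, train_ids, drop = FALSE], train_labels, driver_cand,
    threshold = t_threshold
  ))
  if (nrow(sig) == 0) abort("stage 'select' produced an empty signature")

  say("fitting centroid classifier (", nrow(sig), " genes)")
  model <- run_stage("train", fit_centroid(
    expr_m[, train_ids, drop = FALSE], train_labels, sig
  ))

  say("predicting")
  preds <- run_stage("predict", predict(model, expr_m)) %>%
    dplyr::left_join(labels, by = "patient_id")

  say("evaluating")
  evaluation <- list()
  for (sp in c("train", "test", "independent")) {
    d <- preds[preds$split == sp & !is.na(preds$split), ]
    if (nrow(d) == 0) next
    surv <- if (length(unique(d$predicted_label)) == 2) {
      km_logrank(d, time = "time", event = "event", group = "predicted_label")
    } else {
      NULL
    }
    lab <- d[d$label != "excluded", ]
    metrics <- if (nrow(lab) > 0 && length(unique(lab$risk)) == 2) {
      classification_metrics(lab$risk, lab$predicted_label, lab$gamma)
    } else {
      NULL
    }
    evaluation[[sp]] <- list(survival = surv, metrics = metrics)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("bonemet")),
    seed = as.integer(seed),
    parameters = list(
      split_fractions = split_fractions, years_threshold = years_threshold,
      time_unit = time_unit, fraction = fraction, alpha = alpha,
      n_perm = as.integer(n_perm), runs = as.integer(runs),
      t_threshold = t_threshold
    ),
    counts = list(
      n_genes = nrow(expr_m), n_patients = ncol(expr_m),
      n_retained = length(retained),
      n_train = sum(split$split == "train"),
      n_test = sum(split$split == "test"),
      n_independent = sum(split$split == "independent"),
      n_candidate_pairs = nrow(cand),
      n_edges = nrow(net$edges), n_network_nodes = length(net$nodes),
      matching_size = attr(freq, "matching_size"),
      n_drivers_per_run = max(length(net$nodes) - attr(freq, "matching_size"), 1L),
      n_driver_candidates = length(driver_cand),
      n_signature_genes = nrow(sig)
    )
  )

  res <- structure(
    list(labels = labels, split = split, network = net,
         network_stats = nstats, driver_freq = freq,
         driver_candidates = driver_cand, signature = sig, model = model,
         predictions = preds, evaluation = evaluation, manifest = manifest),
    class = "bonemet_run"
  )
  if (!is.null(outdir)) write_run_artifacts(res, outdir)
  res
}

#' @export
print.bonemet_run <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("bonemet pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  cat("  network: ", cnt$n_edges, " edges / ", cnt$n_network_nodes,
      " nodes from ", cnt$n_candidate_pairs, " candidate pairs\n", sep = "")
  cat("  drivers: matching size ", cnt$matching_size, "; ",
      cnt$n_driver_candidates, " all-run driver candidates; signature of ",
      cnt$n_signature_genes, " genes\n", sep = "")
  for (sp in names(x$evaluation)) {
    ev <- x$evaluation[[sp]]
    auc <- if (!is.null(ev$metrics)) format(ev$metrics$auc, digits = 3) else "NA"
    mcc <- if (!is.null(ev$metrics)) format(ev$metrics$mcc, digits = 3) else "NA"
    p <- if (!is.null(ev$survival)) format(ev$survival$logrank_p, digits = 3) else "NA"
    cat("  ", sp, ": AUC = ", auc, ", MCC = ", mcc, ", log-rank p = ", p,
        "\n", sep = "")
  }
  invisible(x)
}

#' Write the per-stage artifacts and manifest of a pipeline run
#'
#' Emits plain TSV/JSON files so every stage can be inspected or re-used in
#' isolation: risk labels, split assignment, network edge list, driver
#' frequency table, signature, centroid model (JSON), predictions, and a
#' `manifest.json` carrying the seed, all parameters and per-stage counts
#' needed to reproduce the run.
#'
#' @param run A `bonemet_run` from [run_pipeline()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_run_artifacts <- function(run, outdir) {
  stopifnot(inherits(run, "bonemet_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_tsv(x, file.path(outdir, name))
  w(run$labels, "risk_labels.tsv")
  w(run$split, "split.tsv")
  w(run$network$edges, "network_edges.tsv")
  w(run$network$tests, "network_tests.tsv")
  w(run$network_stats, "network_stats.tsv")
  w(dplyr::mutate(tibble::as_tibble(run$driver_freq),
                  runs = attr(run$driver_freq, "runs")),
    "driver_frequency.tsv")
  w(tibble::tibble(gene = run$driver_candidates), "driver_candidates.tsv")
  w(tibble::as_tibble(run$signature), "signature.tsv")
  w(run$predictions, "predictions.tsv")
  m <- run$model
  jsonlite::write_json(
    list(genes = m$genes, c_plus = unname(m$c_plus),
         c_minus = unname(m$c_minus), c_mid = unname(m$c_mid),
         w = unname(m$w), n_plus = m$n_plus, n_minus = m$n_minus),
    file.path(outdir, "centroid_model.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
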