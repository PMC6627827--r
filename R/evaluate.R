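# Evaluation of predicted risk groups: Kaplan-Meier curves with the log-rank
# test (via the survival package), rank-based AUC, accuracy and MCC.

#' Kaplan-Meier comparison of two predicted risk groups
#'
#' Fits the product-limit survival estimator per group and tests the
#' difference with the two-group log-rank statistic (chi-square, 1 df).
#' When no events occur in either group the statistic is undefined and the
#' conventional `chi2 = 0`, `p = 1` is reported.
#'
#' @param data Data frame with one row per patient.
#' @param time,event,group Column names (strings) for follow-up time, the
#'   0/1 event indicator, and the group assignment (exactly two distinct
#'   non-missing values).
#' @return A list of class `"survival_comparison"`: `curves` (tibble
#'   `group`, `time`, `surv`, `n_risk`, `n_event`), `logrank_chi2`,
#'   `logrank_p`, `observed` and `expected` event counts per group, `n` per
#'   group. Has an [autoplot()] method.
#' @export
km_logrank <- function(data, time = "time", event = "event", group = "group") {
  need <- c(time, event, group)
  if (!all(need %in% names(data))) {
    abort(paste0("data must contain columns: ", paste(need, collapse = ", ")))
  }
  d <- data.frame(
    time = as.numeric(data[[time]]),
    event = as.integer(data[[event]]),
    group = as.factor(as.character(data[[group]]))
  )
  d <- d[!is.na(d$group), , drop = FALSE]
  if (nlevels(droplevels(d$group)) != 2) {
    abort("exactly two non-empty groups are required")
  }
  d$group <- droplevels(d$group)
  if (any(d$time < 0)) abort("times must be non-negative")

  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- tibble::tibble(
    group = sub("^group=", "", strata),
    time = fit$time, surv = fit$surv,
    n_risk = fit$n.risk, n_event = fit$n.event
  )

  if (sum(d$event) == 0) {
    chi2 <- 0
    p <- 1
    obs <- exp_ <- stats::setNames(c(0, 0), levels(d$group))
  } else {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    chi2 <- unname(sd_$chisq)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
    obs <- stats::setNames(sd_$obs, levels(d$group))
    exp_ <- stats::setNames(sd_$exp, levels(d$group))
  }
  structure(
    list(curves = curves, logrank_chi2 = chi2, logrank_p = p,
         observed = obs, expected = exp_,
         n = table(d$group)),
    class = "survival_comparison"
  )
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat("Two-group survival comparison (log-rank): chi2 = ",
      format(x$logrank_chi2, digits = 4), ", p = ",
      format(x$logrank_p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney) of continuous scores
#'
#' Probability that a randomly chosen positive scores above a randomly
#' chosen negative, with ties counted half — computed from average ranks.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (1 = positive class).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) abort("labels must be binary (0/1)")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present to compute AUC")
  r <- rank(scores)   # average ranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matthews correlation coefficient from confusion counts
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' balanced correlation between predicted and true binary labels; when any
#' factor of the denominator is zero, MCC is 0 by convention.
#'
#' @param tp,fp,fn,tn Non-negative confusion-matrix counts.
#' @return MCC in `[-1, 1]`.
#' @examples
#' mcc_score(tp = 50, fp = 10, fn = 5, tn = 35)
#' @export
mcc_score <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0)) abort("confusion counts must be non-negative")
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Classification metrics of risk predictions
#'
#' Confusion counts, accuracy and MCC from predicted labels, plus the
#' rank-based AUC when continuous scores are supplied.
#'
#' @param truth Binary true labels (1 = high risk).
#' @param predicted Binary predicted labels.
#' @param scores Optional continuous scores (e.g. centroid gamma) for AUC;
#'   without them AUC is `NA`.
#' @return A one-row tibble: `auc`, `accuracy`, `mcc`, `tp`, `fp`, `tn`,
#'   `fn`, `n`.
#' @export
classification_metrics <- function(truth, predicted, scores = NULL) {
  truth <- as.numeric(truth)
  predicted <- as.numeric(predicted)
  if (length(truth) != length(predicted)) abort("length mismatch")
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    abort("truth and predicted must be binary (0/1)")
  }
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == 0 & predicted == 1)
  tn <- sum(truth == 0 & predicted == 0)
  fn <- sum(truth == 1 & predicted == 0)
  tibble::tibble(
    auc = if (is.null(scores)) NA_real_ else auc_score(scores, truth),
    accuracy = (tp + tn) / length(truth),
    mcc = mcc_score(tp, fp, fn, tn),
    tp = tp, fp = fp, tn = tn, fn = fn, n = length(truth)
  )
}
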