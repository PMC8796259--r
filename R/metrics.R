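#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Computes AUC as the normalized Mann-Whitney U from mid-ranks, which
#' handles ties by counting them 0.5 — the probability that a random case
#' scores above a random control.
#'
#' @param prob Predicted scores or probabilities.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(prob, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("AUC needs both classes")
  r <- rank(prob, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metric panel for one evaluation
#'
#' AUC by the Mann-Whitney rank formulation with tie correction; sensitivity,
#' specificity, PPV and NPV from the confusion matrix at `threshold`
#' (prediction positive when `prob >= threshold`); Gini = 2*AUC - 1;
#' log-loss with probabilities clipped at 1e-7; and mean squared error.
#'
#' @param prob Predicted probabilities.
#' @param labels Binary labels (0/1), both classes present.
#' @param threshold Decision threshold for the confusion-matrix metrics.
#' @return A one-row data.frame: auc, sensitivity, specificity, ppv, npv,
#'   gini, log_loss, mse, threshold.
#' @export
compute_metrics <- function(prob, labels, threshold = 0.5) {
  if (length(unique(labels)) < 2) stopf("metrics need both classes in labels")
  auc <- auc_mann_whitney(prob, labels)
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  pc <- clip01(prob)
  data.frame(
    auc = auc,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    gini = 2 * auc - 1,
    log_loss = -mean(labels * log(pc) + (1 - labels) * log(1 - pc)),
    mse = mean((prob - labels)^2),
    threshold = threshold
  )
}

#' Youden-J-optimal decision threshold
#'
#' Scans the unique predicted probabilities as candidate thresholds and
#' returns the one maximizing Youden's J = sensitivity + specificity - 1.
#' Intended to be computed on the validation partition and then frozen for
#' the test partition. Ties take the lowest such threshold.
#'
#' @param prob Validation probabilities.
#' @param labels Validation labels (0/1).
#' @return The selected threshold.
#' @export
youden_threshold <- function(prob, labels) {
  if (length(unique(labels)) < 2) stopf("threshold selection needs both classes")
  cand <- sort(unique(prob))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  j <- vapply(cand, function(t) {
    sum(prob >= t & labels == 1) / n1 + sum(prob < t & labels == 0) / n0 - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Aggregate metric panels over repeated runs
#'
#' Stacks per-repeat metric rows and appends mean and SD rows, mirroring a
#' mean +/- SD report over five shuffled repeats.
#'
#' @param reports A list of (or a data.frame stacking) one-row results from
#'   [compute_metrics()]; at least 2 repeats.
#' @return A `metrics_report`: list with `per_repeat` (one row per repeat),
#'   `summary` (rows `mean` and `sd`), and `n_repeats`.
#' @export
aggregate_metrics <- function(reports) {
  if (is.data.frame(reports)) {
    per <- reports
  } else {
    per <- do.call(rbind, reports)
  }
  if (nrow(per) < 2) stopf("aggregation needs at least 2 repeats")
  per$repeat_id <- seq_len(nrow(per))
  num <- setdiff(names(per), "repeat_id")
  summary <- rbind(
    data.frame(stat = "mean", t(colMeans(per[num]))),
    data.frame(stat = "sd", t(apply(per[num], 2, stats::sd)))
  )
  structure(list(per_repeat = per, summary = summary, n_repeats = nrow(per)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  m <- x$summary[x$summary$stat == "mean", ]
  s <- x$summary[x$summary$stat == "sd", ]
  cat(sprintf("<metrics_report> %d repeats%s\n", x$n_repeats,
              if (!is.null(x$control)) paste0(" [", x$control, " control]") else ""))
  cat(sprintf("  AUC %.3f+/-%.3f | sens %.3f | spec %.3f | Gini %.3f | log-loss %.3f | MSE %.3f\n",
              m$auc, s$auc, m$sensitivity, m$specificity, m$gini, m$log_loss, m$mse))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' Serializes the per-repeat rows and the mean/SD summary deterministically
#' (fixed column order, full precision), so re-running an identical
#' experiment reproduces the file byte for byte.
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(
    list(n_repeats = report$n_repeats,
         control = report$control,
         per_repeat = report$per_repeat,
         summary = report$summary),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
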