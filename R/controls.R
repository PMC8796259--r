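#' Run the repeated CNN train/evaluate cycle
#'
#' The workhorse evaluation loop: for each of `n_repeats` stratified
#' 64/16/20 split plans, trains the CNN, picks the Youden-J-optimal decision
#' threshold on the validation partition, freezes it, and computes the test
#' metric panel. Per-repeat panels are aggregated to mean +/- SD. The
#' "best-performance" model — highest validation AUC across repeats — is
#' returned for downstream saliency analysis.
#'
#' If the feature count is smaller than the configured kernel width, the
#' kernel (and stride) shrink to fit so that degenerate, very small feature
#' sets remain trainable.
#'
#' @param X Encoded matrix, samples x SNPs.
#' @param labels Binary labels for all rows.
#' @param n_repeats Number of shuffled repeats (default 5).
#' @param config A [cnn_config()]; per-repeat seeds are derived from
#'   `config$seed` via [stage_seed()].
#' @param seed Master seed for the split plans.
#' @param keep_models Keep every repeat's model (default only the best).
#' @return A list: `report` (a `metrics_report`), `best_model`, `best_repeat`,
#'   `val_auc` (per repeat), `plans`, and optionally `models`.
#' @export
run_cnn_pipeline <- function(X, labels, n_repeats = 5L, config = cnn_config(),
                             seed = 1L, keep_models = FALSE) {
  if (ncol(X) < config$kernel_size) {
    config$kernel_size <- as.integer(ncol(X))
    config$stride <- 1L
  }
  plans <- make_splits(labels, n_repeats = n_repeats, seed = seed)
  rows <- vector("list", n_repeats)
  models <- vector("list", n_repeats)
  val_auc <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    cfg <- config
    cfg$seed <- stage_seed(config$seed, 100L + r)
    model <- cnn_train(X, labels, plans[[r]], cfg)
    p_val <- cnn_predict(model, X[plans[[r]]$validation, , drop = FALSE])
    thr <- youden_threshold(p_val, labels[plans[[r]]$validation])
    val_auc[r] <- auc_mann_whitney(p_val, labels[plans[[r]]$validation])
    p_test <- cnn_predict(model, X[plans[[r]]$test, , drop = FALSE])
    rows[[r]] <- compute_metrics(p_test, labels[plans[[r]]$test], thr)
    models[[r]] <- model
  }
  report <- aggregate_metrics(rows)
  best <- which.max(val_auc)
  out <- list(report = report, best_model = models[[best]], best_repeat = best,
              val_auc = val_auc, plans = plans)
  if (keep_models) out$models <- models
  out
}

#' Null-SNP negative control
#'
#' Full train/evaluate cycle restricted to the non-significant SNP subset
#' (reference-GWAS `p >= 0.99`). On synthetic data whose control SNPs are
#' truly null, the mean test AUC is expected near 0.5 — the check that
#' feature selection, not the classifier machinery, carries the signal.
#'
#' @param cohort A `cohort`.
#' @param harmonized Harmonized summary statistics ([harmonize_stats()]).
#' @param n_repeats,config,seed Passed to [run_cnn_pipeline()].
#' @return As [run_cnn_pipeline()], with `report$control = "null_snps"` and
#'   the control `feature_set` attached.
#' @export
run_control_null_snps <- function(cohort, harmonized, n_repeats = 5L,
                                  config = cnn_config(), seed = 1L) {
  fs <- select_features(harmonized, control = TRUE)
  X <- encode_genotypes(cohort, fs)
  res <- run_cnn_pipeline(X, cohort$samples$status, n_repeats = n_repeats,
                          config = config, seed = seed)
  res$report$control <- "null_snps"
  res$features <- fs
  res
}

#' Index-parity negative control
#'
#' Replaces the phenotype label with the parity of the registration index
#' (odd vs even) — a phenotype without heritability — and runs the full
#' cycle on the disease-associated feature set. The genotype matrix is
#' untouched; only labels change. Expected mean AUC is about 0.5.
#'
#' @param X Encoded matrix of the disease-associated feature set.
#' @param registration_index 1-based registration order of each sample.
#' @param n_repeats,config,seed Passed to [run_cnn_pipeline()].
#' @return As [run_cnn_pipeline()], with `report$control = "parity"` and the
#'   parity labels attached as `labels`.
#' @export
run_control_parity <- function(X, registration_index, n_repeats = 5L,
                               config = cnn_config(), seed = 1L) {
  labels <- as.integer(registration_index %% 2 == 1)
  res <- run_cnn_pipeline(X, labels, n_repeats = n_repeats, config = config,
                          seed = seed)
  res$report$control <- "parity"
  res$labels <- labels
  res
}

#' 1:1 propensity-score matching on age and sex
#'
#' Estimates the propensity by a logistic regression of status on age and
#' sex, then matches each case to the nearest unmatched control on the logit
#' scale (greedy nearest-neighbor, without replacement, cases processed in
#' seeded random order) within a caliper of 0.2 SD of the logit. Warns when
#' more than 20% of cases find no control within the caliper.
#'
#' @param cohort A `cohort` with age and sex covariates.
#' @param seed Seed for the case processing order.
#' @param caliper_sd Caliper width in logit SD units (default 0.2).
#' @return A list: `cohort` (the matched sub-cohort, cases then their matched
#'   controls), `pairs` (case_id, control_id, distance), `n_unmatched`.
#' @export
propensity_match <- function(cohort, seed = 1L, caliper_sd = 0.2) {
  s <- cohort$samples
  if (is.null(s$age) || is.null(s$sex)) stopf("cohort lacks age/sex covariates")
  fit <- stats::glm(status ~ age + sex, data = s, family = stats::binomial())
  logit <- as.vector(stats::predict(fit, type = "link"))
  caliper <- caliper_sd * stats::sd(logit)
  cases <- which(s$status == 1)
  controls <- which(s$status == 0)
  set.seed(seed)
  cases <- sample(cases)
  available <- rep(TRUE, length(controls))
  ctl_logit <- logit[controls]
  pair_case <- pair_control <- integer(0)
  dist <- numeric(0)
  for (i in cases) {
    d <- abs(ctl_logit - logit[i])
    d[!available] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= caliper) {
      pair_case <- c(pair_case, i)
      pair_control <- c(pair_control, controls[j])
      dist <- c(dist, d[j])
      available[j] <- FALSE
    }
  }
  n_unmatched <- length(cases) - length(pair_case)
  if (n_unmatched > 0.2 * length(cases)) {
    warnf("propensity matching left %d of %d cases unmatched (caliper %.3f)",
          n_unmatched, length(cases), caliper)
  }
  sel <- c(pair_case, pair_control)
  matched <- structure(
    list(samples = s[sel, , drop = FALSE],
         variants = cohort$variants,
         genotypes = cohort$genotypes[sel, , drop = FALSE]),
    class = "cohort"
  )
  rownames(matched$samples) <- NULL
  list(
    cohort = matched,
    pairs = data.frame(case_id = s$sample_id[pair_case],
                       control_id = s$sample_id[pair_control],
                       distance = dist, stringsAsFactors = FALSE),
    n_unmatched = n_unmatched
  )
}
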