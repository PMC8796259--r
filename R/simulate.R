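#' Specify the variant panel of a simulated cohort
#'
#' Builds the per-SNP specification table used by [sim_config()]. Each variant
#' carries a population minor-allele frequency, a per-minor-allele log odds
#' ratio on disease liability (0 for null SNPs), and an optional
#' linkage-disequilibrium block membership.
#'
#' @param rsid Variant identifiers (unique).
#' @param chrom Chromosome labels.
#' @param bp 1-based base-pair positions, strictly increasing within a
#'   chromosome.
#' @param maf Population minor-allele frequencies in (0, 0.5].
#' @param log_or Per-minor-allele log odds ratios (default all 0).
#' @param block_id Integer LD-block labels; `NA` for SNPs outside any block.
#' @param a1,a2 Minor and major allele characters. If `NULL`, unambiguous
#'   pairs (never A/T or C/G) are assigned deterministically from the rsid
#'   order so that a cohort and an independently simulated reference share
#'   alleles.
#' @return A `data.frame` with one row per variant.
#' @export
variant_table <- function(rsid, chrom, bp, maf, log_or = 0, block_id = NA_integer_,
                          a1 = NULL, a2 = NULL) {
  n <- length(rsid)
  if (anyDuplicated(rsid)) stopf("duplicate rsid in variant table")
  if (any(maf <= 0 | maf > 0.5)) stopf("maf must lie in (0, 0.5] for polymorphic sites")
  chrom <- rep_len(as.character(chrom), n)
  bp <- rep_len(as.integer(bp), n)
  for (ch in unique(chrom)) {
    pos <- bp[chrom == ch]
    if (any(diff(pos) <= 0)) stopf("positions must be strictly increasing within chromosome %s", ch)
  }
  if (is.null(a1) || is.null(a2)) {
    # deterministic, strand-unambiguous allele pairs keyed on panel order
    pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"), ncol = 2, byrow = TRUE)
    sel <- ((seq_len(n) - 1L) %% 4L) + 1L
    a1 <- pairs[sel, 1]
    a2 <- pairs[sel, 2]
  }
  data.frame(
    rsid = as.character(rsid), chrom = chrom, bp = bp,
    maf = rep_len(maf, n), log_or = rep_len(log_or, n),
    block_id = rep_len(as.integer(block_id), n),
    a1 = rep_len(toupper(a1), n), a2 = rep_len(toupper(a2), n),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic case-control genotype cohort
#'
#' Collects everything the generator needs: the variant panel, case/control
#' quotas, the disease-model intercept, LD strength within blocks, a
#' missing-call rate, and the covariate model for age and sex.
#'
#' Disease status follows a prospective additive logistic model,
#' `P(case | g) = logistic(b0 + sum_i log_or_i * g_i)`, with `g_i` the
#' minor-allele count; case and control quotas are then filled by rejection
#' sampling conditional on status. When `baseline_log_odds` is `NULL` the
#' intercept is set so that population prevalence is approximately 5%,
#' `qlogis(0.05) - sum(2 * maf * log_or)`, which keeps rejection sampling
#' efficient.
#'
#' @param variants A variant specification from [variant_table()].
#' @param n_cases,n_controls Positive sample quotas per class.
#' @param baseline_log_odds Intercept of the disease model, or `NULL` for the
#'   5%-prevalence default.
#' @param ld_block_r Target pairwise latent-Gaussian correlation within each
#'   LD block, in `[0, 1)`.
#' @param missing_rate Probability a genotype call is missing, in `[0, 1)`.
#' @param covariate_model List with `age_case`/`age_control` (mean, sd) and
#'   `p_male_case`/`p_male_control`. Defaults mirror a retrospective AF
#'   ablation cohort: cases younger (50.4 +/- 7.9 vs 55.6 +/- 8.6 years) and
#'   more often male (80.5% vs 45.5%). Covariates do not feed the genotype
#'   model; they exist for propensity matching.
#' @param seed Random seed for the generator.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(variants, n_cases = 872, n_controls = 5486,
                       baseline_log_odds = NULL, ld_block_r = 0,
                       missing_rate = 0.01, covariate_model = NULL, seed = 1L) {
  if (!is_count(n_cases) || !is_count(n_controls)) stopf("n_cases and n_controls must be positive counts")
  if (ld_block_r < 0 || ld_block_r >= 1) stopf("ld_block_r must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must lie in [0, 1)")
  if (is.null(baseline_log_odds)) {
    baseline_log_odds <- stats::qlogis(0.05) - sum(2 * variants$maf * variants$log_or)
  }
  covariate_model <- covariate_model %||% list(
    age_case = c(mean = 50.4, sd = 7.9),
    age_control = c(mean = 55.6, sd = 8.6),
    p_male_case = 0.805,
    p_male_control = 0.455
  )
  structure(
    list(
      variants = variants, n_cases = as.integer(n_cases),
      n_controls = as.integer(n_controls),
      baseline_log_odds = baseline_log_odds, ld_block_r = ld_block_r,
      missing_rate = missing_rate, covariate_model = covariate_model,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Demo cohort configuration with planted effects
#'
#' Convenience wrapper producing the package's standard synthetic study
#' design: `n_snps` SNPs on a single synthetic chromosome with a chosen
#' number of causal SNPs whose odds ratios are drawn log-uniformly from
#' `or_range` and whose minor-allele frequencies are uniform on `maf_range`;
#' the remaining SNPs are null. Causal positions are spread over the panel.
#'
#' @param n_snps Total SNP count.
#' @param n_causal Number of causal SNPs.
#' @param n_cases,n_controls Class quotas (defaults 872 / 5486).
#' @param or_range Odds-ratio range for causal SNPs; draws are uniform in
#'   log-OR over `[log(or_range[1]), log(or_range[2])]`.
#' @param maf_range Minor-allele-frequency range, uniform draws.
#' @param effect_scale Multiplier applied to all causal log-ORs (used for
#'   liability-variance sweeps).
#' @param ld_block_r,missing_rate,seed Passed to [sim_config()].
#' @return A `sim_config` object.
#' @export
demo_config <- function(n_snps = 2000, n_causal = 20, n_cases = 872,
                        n_controls = 5486, or_range = c(0.4, 2.0),
                        maf_range = c(0.1, 0.5), effect_scale = 1,
                        ld_block_r = 0, missing_rate = 0.01, seed = 1L) {
  set.seed(stage_seed(seed, 17L))
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  log_or <- numeric(n_snps)
  causal <- if (n_causal > 0) {
    idx <- sort(sample.int(n_snps, n_causal))
    log_or[idx] <- effect_scale *
      stats::runif(n_causal, log(or_range[1]), log(or_range[2]))
    idx
  } else integer(0)
  variants <- variant_table(
    rsid = sprintf("rs%06d", seq_len(n_snps)),
    chrom = "1",
    bp = seq_len(n_snps) * 5000L,
    maf = maf, log_or = log_or
  )
  cfg <- sim_config(variants, n_cases = n_cases, n_controls = n_controls,
                    ld_block_r = ld_block_r, missing_rate = missing_rate,
                    seed = seed)
  cfg$causal_index <- causal
  cfg
}

# Genotype draw for a chunk of samples under the latent-Gaussian copula:
# each SNP's genotype comes from thresholding a standard-normal latent at its
# Hardy-Weinberg genotype quantiles; SNPs sharing a block_id share a common
# factor with loading sqrt(r), which induces pairwise latent correlation r.
draw_genotypes <- function(n, variants, ld_block_r) {
  p <- nrow(variants)
  z <- matrix(stats::rnorm(n * p), n, p)
  if (ld_block_r > 0) {
    blocks <- variants$block_id
    for (b in unique(blocks[!is.na(blocks)])) {
      cols <- which(!is.na(blocks) & blocks == b)
      if (length(cols) > 1) {
        common <- stats::rnorm(n)
        z[, cols] <- sqrt(ld_block_r) * common +
          sqrt(1 - ld_block_r) * z[, cols]
      }
    }
  }
  q <- variants$maf
  t0 <- stats::qnorm((1 - q)^2)   # below: homozygous major (0 copies)
  t1 <- stats::qnorm(1 - q^2)     # above: homozygous minor (2 copies)
  g <- matrix(0L, n, p)
  g <- g + (z > rep(t0, each = n)) + (z > rep(t1, each = n))
  storage.mode(g) <- "integer"
  g
}

#' Simulate a case-control genotype cohort
#'
#' Draws genotypes from Hardy-Weinberg haplotype frequencies (with a
#' latent-Gaussian copula inducing LD within blocks), assigns disease status
#' from the additive logistic model, and fills the case and control quotas by
#' rejection sampling conditional on status. Missing calls are set
#' independently at the configured rate. `registration_index` records the
#' 1-based generation (acceptance) order of each sample.
#'
#' @param config A [sim_config()] object.
#' @param max_attempts Cap on total candidate draws before the generator
#'   aborts (guards against a pathological intercept); default
#'   `500 * (n_cases + n_controls)`.
#' @return An object of class `cohort`: a list with `samples` (sample_id,
#'   status, registration_index, age, sex), `variants` (rsid, chrom, bp,
#'   minor_allele, major_allele, maf observed), and `genotypes`, an integer
#'   matrix of minor-allele counts in \{0, 1, 2\} with `NA` for missing calls.
#'   The ground truth (true log-ORs, block ids, seed) is attached as
#'   `attr(, "truth")`.
#' @export
simulate_cohort <- function(config, max_attempts = NULL) {
  stopifnot(inherits(config, "sim_config"))
  v <- config$variants
  n_cases <- config$n_cases
  n_controls <- config$n_controls
  n_total <- n_cases + n_controls
  max_attempts <- max_attempts %||% (500 * n_total)

  set.seed(config$seed)
  geno <- matrix(NA_integer_, n_total, nrow(v))
  status <- integer(n_total)
  got_cases <- 0L
  got_controls <- 0L
  drawn <- 0L
  filled <- 0L
  cases_seen <- 0L
  beta <- v$log_or
  chunk <- max(1000L, min(20000L, n_total))

  while ((got_cases < n_cases || got_controls < n_controls) && drawn < max_attempts) {
    g <- draw_genotypes(chunk, v, config$ld_block_r)
    drawn <- drawn + chunk
    eta <- config$baseline_log_odds + as.vector(g %*% beta)
    y <- stats::rbinom(chunk, 1L, stats::plogis(eta))
    cases_seen <- cases_seen + sum(y)
    for (i in seq_len(chunk)) {
      if (y[i] == 1L) {
        if (got_cases < n_cases) {
          got_cases <- got_cases + 1L
          filled <- filled + 1L
          geno[filled, ] <- g[i, ]
          status[filled] <- 1L
        }
      } else if (got_controls < n_controls) {
        got_controls <- got_controls + 1L
        filled <- filled + 1L
        geno[filled, ] <- g[i, ]
        status[filled] <- 0L
      }
      if (got_cases == n_cases && got_controls == n_controls) break
    }
  }
  if (got_cases < n_cases || got_controls < n_controls) {
    stopf(paste0(
      "case/control quota unreachable within %d draws: achieved prevalence %.4f ",
      "(have %d/%d cases, %d/%d controls); adjust baseline_log_odds"),
      drawn, cases_seen / max(drawn, 1),
      got_cases, n_cases, got_controls, n_controls)
  }

  if (config$missing_rate > 0) {
    miss <- stats::runif(length(geno)) < config$missing_rate
    geno[miss] <- NA_integer_
  }

  cm <- config$covariate_model
  age <- numeric(n_total)
  sex <- character(n_total)
  is_case <- status == 1L
  age[is_case] <- stats::rnorm(sum(is_case), cm$age_case[["mean"]], cm$age_case[["sd"]])
  age[!is_case] <- stats::rnorm(sum(!is_case), cm$age_control[["mean"]], cm$age_control[["sd"]])
  sex[is_case] <- ifelse(stats::runif(sum(is_case)) < cm$p_male_case, "M", "F")
  sex[!is_case] <- ifelse(stats::runif(sum(!is_case)) < cm$p_male_control, "M", "F")

  samples <- data.frame(
    sample_id = sprintf("S%06d", seq_len(n_total)),
    status = status,
    registration_index = seq_len(n_total),
    age = round(age, 2),
    sex = sex,
    stringsAsFactors = FALSE
  )
  obs_maf <- colMeans(geno, na.rm = TRUE) / 2
  variants <- data.frame(
    rsid = v$rsid, chrom = v$chrom, bp = v$bp,
    minor_allele = v$a1, major_allele = v$a2,
    maf = obs_maf,
    stringsAsFactors = FALSE
  )
  rownames(geno) <- samples$sample_id
  colnames(geno) <- variants$rsid
  out <- structure(
    list(samples = samples, variants = variants, genotypes = geno),
    class = "cohort"
  )
  attr(out, "truth") <- list(
    log_or = stats::setNames(v$log_or, v$rsid),
    block_id = stats::setNames(v$block_id, v$rsid),
    maf = stats::setNames(v$maf, v$rsid),
    baseline_log_odds = config$baseline_log_odds,
    seed = config$seed
  )
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d samples (%d cases / %d controls), %d variants, %.2f%% missing calls\n",
    nrow(x$samples), sum(x$samples$status == 1), sum(x$samples$status == 0),
    nrow(x$variants), 100 * mean(is.na(x$genotypes))
  ))
  invisible(x)
}

#' Simulate reference GWAS summary statistics
#'
#' Draws an independent reference cohort from the same variant panel (same
#' MAFs, effects, and LD), runs the per-SNP logistic association scan on it,
#' and returns its odds-ratio/p-value table in the summary-statistics layout
#' used for feature selection and PRS weights. Null SNPs receive p-values
#' uniform on (0, 1) in expectation, so a non-significant "p >= 0.99" subset
#' exists.
#'
#' @param config The [sim_config()] of the target study (supplies the panel).
#' @param n_ref_cases,n_ref_controls Reference-cohort quotas.
#' @param seed Seed for the reference draw.
#' @param source_label Free-text provenance label stored on the table.
#' @return A `summary_stats` data.frame (rsid, chrom, bp, effect_allele,
#'   other_allele, odds_ratio, p_value) whose effect allele is the panel's
#'   minor allele.
#' @export
simulate_summary_stats <- function(config, n_ref_cases = 3000,
                                   n_ref_controls = 3000, seed = 100L,
                                   source_label = "simulated reference GWAS") {
  stopifnot(inherits(config, "sim_config"))
  ref_cfg <- config
  ref_cfg$n_cases <- as.integer(n_ref_cases)
  ref_cfg$n_controls <- as.integer(n_ref_controls)
  ref_cfg$seed <- as.integer(seed)
  ref <- simulate_cohort(ref_cfg)
  scan <- assoc_scan(ref)
  out <- data.frame(
    rsid = scan$rsid,
    chrom = ref$variants$chrom[match(scan$rsid, ref$variants$rsid)],
    bp = ref$variants$bp[match(scan$rsid, ref$variants$rsid)],
    effect_allele = scan$minor_allele,
    other_allele = scan$major_allele,
    odds_ratio = scan$odds_ratio,
    p_value = scan$p_value,
    stringsAsFactors = FALSE
  )
  attr(out, "source_label") <- source_label
  class(out) <- c("summary_stats", "data.frame")
  out
}
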