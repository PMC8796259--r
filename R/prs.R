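#' Greedy p-value-ordered LD clumping
#'
#' Builds a polygenic-risk-score model: candidates are harmonized SNPs with
#' `p < threshold`, processed in ascending p-value order (ties broken by
#' chromosome, position, then rsid, so the greedy order is total and
#' invariant to input row order). Each round retains the best remaining SNP
#' as an index SNP and removes all remaining SNPs on the same chromosome
#' within `clump_window_bp` of it (index-centered, inclusive) whose squared
#' Pearson correlation of genotype codes with the index exceeds `clump_r2`.
#' The LD reference is the supplied cohort (by convention its training
#' partition). Weights are the harmonized per-minor-allele log odds ratios.
#'
#' @param stats Harmonized `summary_stats` (see [harmonize_stats()]).
#' @param cohort A `cohort` supplying the LD reference genotypes.
#' @param clump_r2 Squared-correlation threshold (default 0.1).
#' @param clump_window_bp Distance window around the index SNP (default
#'   250000, i.e. +/- 250 kb inclusive).
#' @param threshold P-value cut-off defining the candidate set.
#' @param ld_samples Optional row indices of the cohort to use as the LD
#'   reference (e.g. a training partition); default all samples.
#' @return A `prs_model`: list with `retained` (rsid, chrom, bp, p_value,
#'   weight), `clump_r2`, `clump_window_bp`, `threshold`.
#' @export
prs_clump <- function(stats, cohort, clump_r2 = 0.1, clump_window_bp = 250000,
                      threshold = 1e-3, ld_samples = NULL) {
  if (!is.null(stats$flag)) stats <- stats[stats$flag %in% c("match", "flipped"), ]
  cand <- stats[stats$p_value < threshold, , drop = FALSE]
  cand <- cand[cand$rsid %in% cohort$variants$rsid, , drop = FALSE]
  if (nrow(cand) == 0) stopf("no clumping candidates at threshold %s", format(threshold))
  chrom_num <- suppressWarnings(as.integer(as.character(cand$chrom)))
  chrom_rank <- ifelse(is.na(chrom_num), .Machine$integer.max, chrom_num)
  cand <- cand[order(cand$p_value, chrom_rank, cand$bp, cand$rsid), , drop = FALSE]

  g <- cohort$genotypes[, match(cand$rsid, cohort$variants$rsid), drop = FALSE]
  if (!is.null(ld_samples)) g <- g[ld_samples, , drop = FALSE]
  storage.mode(g) <- "double"

  alive <- rep(TRUE, nrow(cand))
  retained <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    retained <- c(retained, i)
    alive[i] <- FALSE
    near <- which(alive &
                    cand$chrom == cand$chrom[i] &
                    abs(cand$bp - cand$bp[i]) <= clump_window_bp)
    if (length(near)) {
      r <- suppressWarnings(
        stats::cor(g[, i], g[, near, drop = FALSE], use = "pairwise.complete.obs")
      )
      r[is.na(r)] <- 0
      alive[near[as.vector(r)^2 > clump_r2]] <- FALSE
    }
  }
  keep <- cand[retained, , drop = FALSE]
  structure(
    list(
      retained = data.frame(rsid = keep$rsid, chrom = keep$chrom, bp = keep$bp,
                            p_value = keep$p_value,
                            weight = log(keep$odds_ratio),
                            stringsAsFactors = FALSE),
      clump_r2 = clump_r2, clump_window_bp = clump_window_bp,
      threshold = threshold
    ),
    class = "prs_model"
  )
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("<prs_model> %d index SNPs (p < %s, r2 <= %.2f within %d bp)\n",
              nrow(x$retained), format(x$threshold), x$clump_r2,
              x$clump_window_bp))
  invisible(x)
}

#' Score samples with a polygenic risk score
#'
#' The weighted allele sum `PRS_m = sum_i weight_i * g_mi` over the model's
#' retained SNPs, with `g` the minor-allele count. Missing genotypes
#' contribute `weight_i * 2 * maf_i` (mean imputation from the cohort's
#' observed allele frequency), the standard scoring behavior.
#'
#' @param model A `prs_model`.
#' @param cohort A `cohort`; every retained SNP must be present.
#' @return A data.frame (sample_id, score, status).
#' @export
prs_score <- function(model, cohort) {
  cols <- match(model$retained$rsid, cohort$variants$rsid)
  if (anyNA(cols)) {
    stopf("retained SNP absent from cohort: %s",
          model$retained$rsid[which(is.na(cols))[1]])
  }
  g <- cohort$genotypes[, cols, drop = FALSE]
  storage.mode(g) <- "double"
  maf <- colMeans(g, na.rm = TRUE) / 2
  for (j in seq_along(cols)) {
    miss <- is.na(g[, j])
    if (any(miss)) g[miss, j] <- 2 * maf[j]
  }
  data.frame(
    sample_id = cohort$samples$sample_id,
    score = as.vector(g %*% model$retained$weight),
    status = cohort$samples$status,
    stringsAsFactors = FALSE
  )
}
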