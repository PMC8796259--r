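#' Per-SNP case-control association scan
#'
#' For every variant, fits a single-predictor logistic regression of disease
#' status on minor-allele count (missing calls excluded) and reports the
#' odds ratio `exp(beta)`, its Wald 95% confidence interval, and the Wald
#' p-value. Degenerate columns — monomorphic sites, or fits showing complete
#' separation / non-convergence — fall back to the allelic 2x2 cross-product
#' odds ratio with a Haldane-Anscombe 0.5 correction and a two-sided Fisher
#' exact p-value; such rows are flagged `method = "fisher"`.
#'
#' No covariate adjustment and no multiple-testing correction are applied
#' here; thresholds are the business of feature selection downstream.
#'
#' @param cohort A `cohort` object.
#' @param min_nonmissing Minimum non-missing genotype count per variant
#'   (default 10); variants below it are an error, per the scan contract.
#' @return A data.frame of per-variant statistics: rsid, alleles, pooled MAF,
#'   `beta` (log-OR), `se`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `method`.
#' @export
assoc_scan <- function(cohort, min_nonmissing = 10) {
  stopifnot(inherits(cohort, "cohort"))
  y <- cohort$samples$status
  if (length(unique(y)) < 2) stopf("association scan needs both cases and controls")
  g <- cohort$genotypes
  p <- ncol(g)
  beta <- se <- pval <- maf <- numeric(p)
  method <- character(p)

  for (j in seq_len(p)) {
    x <- g[, j]
    ok <- !is.na(x)
    if (sum(ok) < min_nonmissing) {
      stopf("variant %s has fewer than %d non-missing calls", colnames(g)[j], min_nonmissing)
    }
    xs <- as.numeric(x[ok])
    ys <- y[ok]
    f <- mean(xs) / 2
    maf[j] <- min(f, 1 - f)
    fit_ok <- FALSE
    if (stats::var(xs) > 0) {
      X <- cbind(1, xs)
      fit <- suppressWarnings(stats::glm.fit(X, ys, family = stats::binomial()))
      b <- fit$coefficients[2]
      if (fit$converged && is.finite(b) && abs(b) < 15) {
        w <- fit$weights
        xtwx <- crossprod(X * sqrt(w))
        V <- tryCatch(solve(xtwx), error = function(e) NULL)
        if (!is.null(V) && is.finite(V[2, 2]) && V[2, 2] > 0) {
          beta[j] <- b
          se[j] <- sqrt(V[2, 2])
          pval[j] <- 2 * stats::pnorm(-abs(b / se[j]))
          method[j] <- "wald"
          fit_ok <- TRUE
        }
      }
    }
    if (!fit_ok) {
      # allelic 2x2 fallback: minor vs major allele counts by status
      a <- sum(xs[ys == 1])              # minor alleles in cases
      b2 <- 2 * sum(ys == 1) - a         # major alleles in cases
      c2 <- sum(xs[ys == 0])             # minor alleles in controls
      d <- 2 * sum(ys == 0) - c2
      tab <- matrix(c(a, b2, c2, d), 2, 2, byrow = TRUE)
      pval[j] <- stats::fisher.test(round(tab))$p.value
      if (any(tab == 0)) tab <- tab + 0.5
      beta[j] <- log((tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
      se[j] <- sqrt(sum(1 / tab))
      method[j] <- "fisher"
    }
  }
  pval <- pmin(pmax(pval, .Machine$double.xmin), 1)
  out <- data.frame(
    rsid = cohort$variants$rsid,
    chrom = cohort$variants$chrom,
    bp = cohort$variants$bp,
    minor_allele = cohort$variants$minor_allele,
    major_allele = cohort$variants$major_allele,
    maf = maf,
    beta = beta,
    se = se,
    odds_ratio = exp(beta),
    ci_low = exp(beta - 1.959964 * se),
    ci_high = exp(beta + 1.959964 * se),
    p_value = pval,
    method = method,
    stringsAsFactors = FALSE
  )
  out
}

#' Manhattan-plot table
#'
#' Plot-ready per-SNP table of genomic coordinates and `-log10(p)`. Row order
#' is preserved from the input scan (which is itself in the cohort's genomic
#' order).
#'
#' @param stats An [assoc_scan()] result (needs rsid, chrom, bp, p_value).
#' @return A data.frame (rsid, chrom, bp, neg_log10_p).
#' @export
manhattan_table <- function(stats) {
  if (nrow(stats) == 0) stopf("empty association table")
  data.frame(
    rsid = stats$rsid,
    chrom = stats$chrom,
    bp = stats$bp,
    neg_log10_p = -log10(stats$p_value),
    stringsAsFactors = FALSE
  )
}
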