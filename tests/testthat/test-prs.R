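# cohort with controllable LD between chosen column pairs: overwrite genotype
# columns with copies (r2 ~ 1) or independent draws (r2 ~ 0)
clumping_fixture <- function(p_values, bp, r2_pairs = list(), n = 400,
                             seed = 1) {
  n_snps <- length(p_values)
  coh <- tiny_cohort(n_cases = n / 2, n_controls = n / 2, n_snps = n_snps,
                     missing_rate = 0, seed = seed)
  coh$variants$bp <- as.integer(bp)
  for (pr in r2_pairs) {
    coh$genotypes[, pr[2]] <- coh$genotypes[, pr[1]]
    if (length(pr) == 3 && pr[3] < 1) {
      flip <- sample(n, round((1 - pr[3]) * n / 2))
      coh$genotypes[flip, pr[2]] <- sample(0:2, length(flip), TRUE)
    }
  }
  st <- data.frame(rsid = coh$variants$rsid, chrom = coh$variants$chrom,
                   bp = coh$variants$bp,
                   effect_allele = coh$variants$minor_allele,
                   other_allele = coh$variants$major_allele,
                   odds_ratio = exp(runif(n_snps, -0.3, 0.3)),
                   p_value = p_values, flag = "match",
                   stringsAsFactors = FALSE)
  class(st) <- c("summary_stats", "data.frame")
  list(cohort = coh, stats = st)
}

test_that("greedy clumping follows the hand-executed oracle", {
  # 3 SNPs within one window; SNP1-SNP2 correlated, SNP3 independent
  set.seed(2)
  fx <- clumping_fixture(p_values = c(1e-10, 1e-8, 1e-3),
                         bp = c(10000, 60000, 110000),
                         r2_pairs = list(c(1, 2)))
  m <- prs_clump(fx$stats, fx$cohort, clump_r2 = 0.1,
                 clump_window_bp = 250000, threshold = 0.05)
  expect_setequal(m$retained$rsid, c("rs000001", "rs000003"))
})

test_that("SNPs outside the distance window are retained despite high r2", {
  set.seed(3)
  fx <- clumping_fixture(p_values = c(1e-10, 1e-8),
                         bp = c(10000, 310000),       # 300 kb apart
                         r2_pairs = list(c(1, 2)))    # r2 ~ 1
  m <- prs_clump(fx$stats, fx$cohort, clump_r2 = 0.1,
                 clump_window_bp = 250000, threshold = 0.05)
  expect_setequal(m$retained$rsid, c("rs000001", "rs000002"))
})

test_that("mutually uncorrelated candidates are all retained", {
  set.seed(4)
  fx <- clumping_fixture(p_values = rep(1e-4, 10),
                         bp = (1:10) * 10000)
  m <- prs_clump(fx$stats, fx$cohort, threshold = 0.05)
  expect_equal(nrow(m$retained), 10)
})

test_that("clumping is invariant to input row order", {
  set.seed(5)
  fx <- clumping_fixture(p_values = c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2),
                         bp = (1:5) * 50000,
                         r2_pairs = list(c(1, 3), c(2, 4)))
  m1 <- prs_clump(fx$stats, fx$cohort, threshold = 0.05)
  shuffled <- fx$stats[c(4, 1, 5, 3, 2), ]
  m2 <- prs_clump(shuffled, fx$cohort, threshold = 0.05)
  expect_equal(m1$retained, m2$retained)
})

test_that("clumped model satisfies all pairwise constraints (brute force)", {
  set.seed(6)
  n_snps <- 20
  fx <- clumping_fixture(p_values = 10^runif(n_snps, -8, -2),
                         bp = (1:n_snps) * 40000,
                         r2_pairs = list(c(1, 2), c(5, 6, 0.8), c(10, 12)))
  m <- prs_clump(fx$stats, fx$cohort, clump_r2 = 0.1,
                 clump_window_bp = 250000, threshold = 0.05)
  kept <- m$retained
  g <- fx$cohort$genotypes[, match(kept$rsid, fx$cohort$variants$rsid), drop = FALSE]
  # exhaustive pairwise validity check
  if (nrow(kept) > 1) {
    for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
      if (kept$chrom[i] == kept$chrom[j] &&
          abs(kept$bp[i] - kept$bp[j]) <= 250000) {
        expect_lte(cor(g[, i], g[, j])^2, 0.1)
      }
    }
  }
  # p-optimality: every removed candidate is within window+r2 of a retained
  # SNP with smaller or equal p
  removed <- setdiff(fx$stats$rsid, kept$rsid)
  g_all <- fx$cohort$genotypes
  for (r in removed) {
    ri <- match(r, fx$cohort$variants$rsid)
    ok <- FALSE
    for (k in seq_len(nrow(kept))) {
      ki <- match(kept$rsid[k], fx$cohort$variants$rsid)
      if (fx$stats$chrom[ri] == kept$chrom[k] &&
          abs(fx$stats$bp[ri] - kept$bp[k]) <= 250000 &&
          cor(g_all[, ri], g_all[, ki])^2 > 0.1 &&
          kept$p_value[k] <= fx$stats$p_value[match(r, fx$stats$rsid)]) {
        ok <- TRUE
        break
      }
    }
    expect_true(ok, label = sprintf("removed SNP %s justified", r))
  }
})

test_that("empty candidate sets fail naming the threshold", {
  set.seed(7)
  fx <- clumping_fixture(p_values = rep(0.5, 3), bp = (1:3) * 1000)
  expect_error(prs_clump(fx$stats, fx$cohort, threshold = 1e-8), "1e-08")
})

test_that("PRS scoring is the weighted allele sum with mean imputation", {
  coh <- tiny_cohort(n_cases = 3, n_controls = 3, n_snps = 1,
                     missing_rate = 0, seed = 1)
  coh$genotypes[, 1] <- c(0L, 1L, 2L, 0L, 1L, 2L)
  model <- structure(list(
    retained = data.frame(rsid = "rs000001", chrom = "1", bp = 1000L,
                          p_value = 1e-5, weight = log(2),
                          stringsAsFactors = FALSE),
    clump_r2 = 0.1, clump_window_bp = 250000, threshold = 1e-3
  ), class = "prs_model")
  sc <- prs_score(model, coh)
  expect_equal(sc$score, log(2) * c(0, 1, 2, 0, 1, 2), tolerance = 1e-12)

  # zero weights give zero scores
  model0 <- model
  model0$retained$weight <- 0
  expect_true(all(prs_score(model0, coh)$score == 0))

  # missing genotype contributes weight * 2 * maf
  coh$genotypes[1, 1] <- NA
  maf <- mean(coh$genotypes[, 1], na.rm = TRUE) / 2
  sc2 <- prs_score(model, coh)
  expect_equal(sc2$score[1], log(2) * 2 * maf, tolerance = 1e-12)
})

test_that("allele flip with negated weight preserves score differences", {
  coh <- tiny_cohort(n_cases = 20, n_controls = 20, n_snps = 2,
                     missing_rate = 0, seed = 9)
  model <- structure(list(
    retained = data.frame(rsid = c("rs000001", "rs000002"), chrom = "1",
                          bp = c(1000L, 2000L), p_value = 1e-5,
                          weight = c(0.4, -0.2), stringsAsFactors = FALSE),
    clump_r2 = 0.1, clump_window_bp = 250000, threshold = 1e-3
  ), class = "prs_model")
  s1 <- prs_score(model, coh)$score
  coh2 <- coh
  coh2$genotypes[, 1] <- 2L - coh$genotypes[, 1]
  model2 <- model
  model2$retained$weight[1] <- -model$retained$weight[1]
  s2 <- prs_score(model2, coh2)$score
  expect_equal(s1 - mean(s1), s2 - mean(s2), tolerance = 1e-12)
})

test_that("scoring fails when a retained SNP is absent from the cohort", {
  coh <- tiny_cohort(n_cases = 5, n_controls = 5, n_snps = 1, seed = 1)
  model <- structure(list(
    retained = data.frame(rsid = "rsGONE", chrom = "1", bp = 1L,
                          p_value = 0.5, weight = 1, stringsAsFactors = FALSE),
    clump_r2 = 0.1, clump_window_bp = 250000, threshold = 1
  ), class = "prs_model")
  expect_error(prs_score(model, coh), "rsGONE")
})
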