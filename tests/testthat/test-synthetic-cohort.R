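test_that("null model is symmetric: no case-control MAF difference", {
  coh <- tiny_cohort(n_cases = 500, n_controls = 500, n_snps = 40,
                     missing_rate = 0, seed = 11)
  g <- coh$genotypes
  case <- coh$samples$status == 1
  diff <- colMeans(g[case, ]) / 2 - colMeans(g[!case, ]) / 2
  # binomial SE of a MAF difference at n = 500 per arm, maf 0.3
  se <- sqrt(2 * 0.3 * 0.7 / (2 * 500))
  expect_lt(max(abs(diff)), 5 * se)
  expect_lt(abs(mean(diff)), se)
})

test_that("cohort honors quotas, codes, and registration order", {
  coh <- tiny_cohort(n_cases = 80, n_controls = 220, n_snps = 20, seed = 2)
  expect_equal(sum(coh$samples$status == 1), 80)
  expect_equal(sum(coh$samples$status == 0), 220)
  expect_true(all(coh$genotypes %in% c(0L, 1L, 2L, NA)))
  expect_equal(coh$samples$registration_index, 1:300)
  expect_equal(dim(coh$genotypes), c(300, 20))
})

test_that("identical config and seed give identical cohorts", {
  c1 <- tiny_cohort(seed = 7)
  c2 <- tiny_cohort(seed = 7)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$samples, c2$samples)
  c3 <- tiny_cohort(seed = 8)
  expect_false(identical(c1$genotypes, c3$genotypes))
})

test_that("null LD-free SNPs sit at Hardy-Weinberg frequencies", {
  maf <- c(0.1, 0.25, 0.4, 0.5)
  coh <- tiny_cohort(n_cases = 500, n_controls = 4500, n_snps = 4,
                     maf = maf, missing_rate = 0, seed = 13)
  n <- 5000
  for (j in seq_along(maf)) {
    q <- maf[j]
    expected <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    counts <- tabulate(coh$genotypes[, j] + 1L, nbins = 3)
    for (k in 1:3) {
      se <- sqrt(n * expected[k] * (1 - expected[k]))
      expect_lt(abs(counts[k] - n * expected[k]), 3 * se,
                label = sprintf("genotype %d of SNP %d deviates", k - 1, j))
    }
  }
})

test_that("effect direction shifts case MAF the right way", {
  lo <- c(0.6, -0.6, rep(0, 8))
  coh <- tiny_cohort(n_cases = 600, n_controls = 600, n_snps = 10,
                     log_or = lo, missing_rate = 0, seed = 5)
  g <- coh$genotypes
  case <- coh$samples$status == 1
  d <- colMeans(g[case, ]) - colMeans(g[!case, ])
  expect_gt(d[1], 0)
  expect_lt(d[2], 0)
})

test_that("LD copula matches a brute-force Monte-Carlo oracle", {
  r <- 0.8
  q <- c(0.3, 0.3)
  coh <- tiny_cohort(n_cases = 500, n_controls = 4500, n_snps = 2, maf = q,
                     missing_rate = 0, ld_block_r = r, block_id = c(1L, 1L),
                     seed = 17)
  obs_r2 <- cor(coh$genotypes[, 1], coh$genotypes[, 2])^2

  # independent Monte-Carlo oracle of the same copula: latent equicorrelated
  # bivariate normal thresholded at Hardy-Weinberg genotype quantiles
  set.seed(99)
  n <- 1e6
  common <- rnorm(n)
  z1 <- sqrt(r) * common + sqrt(1 - r) * rnorm(n)
  z2 <- sqrt(r) * common + sqrt(1 - r) * rnorm(n)
  thr <- function(z, q) (z > qnorm((1 - q)^2)) + (z > qnorm(1 - q^2))
  oracle_r2 <- cor(thr(z1, q[1]), thr(z2, q[2]))^2
  expect_lt(abs(obs_r2 - oracle_r2), 0.1)
})

test_that("pathological intercept fails naming the achieved prevalence", {
  cfg <- sim_config(tiny_variants(5), n_cases = 50, n_controls = 50,
                    baseline_log_odds = -30, seed = 1)
  expect_error(simulate_cohort(cfg, max_attempts = 5000),
               "quota unreachable.*prevalence")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(variant_table("rs1", "1", 100L, maf = 0.7), "maf")
  expect_error(variant_table(c("rs1", "rs2"), "1", c(200L, 100L), maf = 0.3),
               "strictly increasing")
  expect_error(sim_config(tiny_variants(3), n_cases = 0), "positive")
  expect_error(sim_config(tiny_variants(3), missing_rate = 1), "missing_rate")
  expect_error(sim_config(tiny_variants(3), ld_block_r = 1), "ld_block_r")
})

test_that("simulated summary stats are deterministic and null-calibrated", {
  cfg <- sim_config(tiny_variants(400), n_cases = 100, n_controls = 300,
                    missing_rate = 0, seed = 3)
  s1 <- simulate_summary_stats(cfg, 400, 1200, seed = 5)
  s2 <- simulate_summary_stats(cfg, 400, 1200, seed = 5)
  expect_identical(s1, s2)
  # all-null panel: p-values roughly uniform, so about 1% reach p >= 0.99
  frac <- mean(s1$p_value >= 0.99)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / 400) + 0.005)
})

test_that("a strong planted effect reaches genome-wide significance in a large reference", {
  lo <- numeric(30); lo[7] <- log(2.01)
  cfg <- sim_config(tiny_variants(30, maf = rep(0.42, 30), log_or = lo),
                    n_cases = 100, n_controls = 300, missing_rate = 0, seed = 9)
  ss <- simulate_summary_stats(cfg, 2500, 2500, seed = 31)
  expect_lt(ss$p_value[7], 5e-8)
  expect_gt(min(ss$p_value[-7]), 5e-8)
})

test_that("association scan recovers a planted protective OR within its CI", {
  lo <- numeric(10); lo[3] <- log(0.42)
  coh <- tiny_cohort(n_cases = 1500, n_controls = 1500, n_snps = 10,
                     maf = rep(0.476, 10), log_or = lo, missing_rate = 0,
                     seed = 23)
  scan <- assoc_scan(coh)
  expect_lt(scan$ci_low[3], 0.42)
  expect_gt(scan$ci_high[3], 0.42)
})
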