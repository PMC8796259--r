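# Shared fixtures: small cohorts and feature sets built in code.

tiny_variants <- function(n_snps = 50, maf = NULL, log_or = NULL,
                          block_id = NA_integer_) {
  variant_table(
    rsid = sprintf("rs%06d", seq_len(n_snps)),
    chrom = "1",
    bp = seq_len(n_snps) * 1000L,
    maf = maf %||% rep(0.3, n_snps),
    log_or = log_or %||% numeric(n_snps),
    block_id = block_id
  )
}

tiny_cohort <- function(n_cases = 100, n_controls = 300, n_snps = 50,
                        maf = NULL, log_or = NULL, missing_rate = 0.01,
                        ld_block_r = 0, block_id = NA_integer_, seed = 1L) {
  cfg <- sim_config(
    tiny_variants(n_snps, maf, log_or, block_id),
    n_cases = n_cases, n_controls = n_controls,
    ld_block_r = ld_block_r, missing_rate = missing_rate, seed = seed
  )
  simulate_cohort(cfg)
}

# a feature set covering every variant of a cohort, in genomic order
all_features <- function(cohort) {
  v <- cohort$variants
  ord <- genomic_order(v$chrom, v$bp, v$rsid)
  structure(
    list(threshold = 1,
         rsid = v$rsid[ord],
         table = data.frame(rsid = v$rsid[ord], chrom = v$chrom[ord],
                            bp = v$bp[ord], p_value = NA_real_,
                            odds_ratio = NA_real_, flag = "match",
                            stringsAsFactors = FALSE)),
    class = "feature_set"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast training settings for tests that only need a functioning model
fast_cnn <- function(seed = 1L, n_filters = 8L, fc_units = 16L,
                     max_epochs = 40L, patience = 6L, ...) {
  cnn_config(n_filters = n_filters, fc_units = fc_units,
             max_epochs = max_epochs, patience = patience, seed = seed, ...)
}
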