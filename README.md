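# cnngwas

Can a convolutional neural network classify disease status from genotypes
alone, using a SNP panel preselected from external GWAS summary statistics?
`cnngwas` implements that question end to end for case-control cohorts, in
plain R, with a synthetic-cohort generator so every stage is testable
against known ground truth — the real cohorts this design emulates are
access-restricted.

The pipeline:

1. **Simulate** (or read) a case-control genotype cohort: Hardy–Weinberg
   genotypes with tunable LD blocks (latent-Gaussian copula), disease status
   from an additive logistic model
   `P(case | g) = logit⁻¹(β₀ + Σᵢ βᵢ gᵢ)`, case/control quotas filled by
   rejection sampling, MCAR missing calls, and age/sex covariates.
2. **Select features**: harmonize external summary statistics to the cohort
   (allele matching, OR flipping, ambiguous-SNP dropping) and keep SNPs with
   `p < t` for a threshold grid down to genome-wide significance — plus the
   non-significant control set `p ≥ 0.99`.
3. **Encode** genotypes additively per minor allele:
   `X ∈ {−1, 0, 1, 2}` (missing = −1), columns in genomic order.
4. **Classify** with a small 1D CNN (conv → flatten → dropout → dense →
   logistic), trained with Adam, class weights, early stopping; evaluated
   over five repeated stratified 64/16/20 splits with a Youden-J threshold
   frozen on validation. Baselines: MC-dropout CNN, lasso, ridge, logistic
   regression.
5. **Explain** with Grad-CAM: per-patient, per-SNP saliency
   `L_u = ReLU(Σ_k α_k A^k_u)`, `α_k = mean_u ∂y/∂A^k_u`, max-normalized
   per-SNP means, compared against the cohort's own logistic association
   scan.
6. **Check** with negative controls (null-SNP subset, registration-index
   parity labels), propensity matching, and a clumped polygenic risk score
   (`r² > 0.1` removed within ±250 kb of each index SNP).

The CNN, its training loop, and Grad-CAM are implemented in the package
itself (vectorized matrix algebra over BLAS); standard statistics go through
`stats` and `glmnet`.

## Worked example

```r
library(cnngwas)

# a 6358-sample cohort (872 cases / 5486 controls), 2000 SNPs, 20 causal
cfg    <- demo_config(seed = 1)
cohort <- simulate_cohort(cfg)
cohort
#> <cohort> 6358 samples (872 cases / 5486 controls), 2000 variants, 1.00% missing calls

# reference GWAS summary statistics from an independent simulated cohort
stats <- simulate_summary_stats(cfg, n_ref_cases = 3000, n_ref_controls = 3000,
                                seed = 101)
harmonized <- harmonize_stats(cohort, stats)
features   <- select_features(harmonized, threshold = 1e-5)
features
#> <feature_set> 16 SNPs at threshold 1e-05

X   <- encode_genotypes(cohort, features)
res <- run_cnn_pipeline(X, cohort$samples$status, n_repeats = 5,
                        config = cnn_config(seed = 42), seed = 7)
res$report
#> <metrics_report> 5 repeats
#>   AUC 0.806+/-0.018 | sens 0.700 | spec 0.751 | Gini 0.611 | log-loss 0.521 | MSE 0.172

# negative control: parity of the registration index is not predictable
parity <- run_control_parity(X, cohort$samples$registration_index,
                             n_repeats = 5, config = cnn_config(seed = 43),
                             seed = 8)
parity$report
#> <metrics_report> 5 repeats [parity control]
#>   AUC 0.493+/-0.014 | sens 0.363 | spec 0.618 | Gini -0.013 | log-loss 0.695 | MSE 0.251
```

The selected panel carries real signal (mean test AUC ≈ 0.81 across five
shuffled repeats), while the same machinery applied to a heritability-free
pseudo-label sits at chance (≈ 0.49) — the two numbers that matter when
arguing the classifier learns genetics rather than artifacts. Saliency,
PRS, and the null-SNP control follow the same pattern; `run_experiment()`
runs the whole panel of thresholds, controls, saliency, and PRS in one call
and `write_experiment()` serializes the reports and a reproducibility
manifest. A thin CLI over these functions lives at `inst/cli/cnngwas.R`
(verbs `simulate` and `run`).

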