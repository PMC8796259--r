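---
title: "Methods: CNN classification of case-control genotypes with GWAS-guided feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNN classification of case-control genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cnngwas)
```

## The problem

Genome-wide association studies (GWAS) identify individual SNPs associated
with a polygenic disease, but single-SNP statistics discard the cumulative,
possibly interacting contribution of many moderately associated loci. This
package studies a two-stage alternative: select a SNP panel from *external*
GWAS summary statistics at a p-value threshold, then train a small
one-dimensional convolutional neural network (CNN) on additively encoded
genotypes to classify case versus control status directly. Per-SNP Grad-CAM
saliency then attributes the trained network's prediction back to loci, and
a conventional polygenic risk score (PRS) serves as the comparison baseline.

Real disease cohorts of this kind are access-restricted, so the package is
built around a synthetic cohort generator with known ground truth: every
downstream claim (signal recovery, negative controls, attribution) is
testable against planted effects.

## The generative model

Genotypes are drawn per SNP from Hardy–Weinberg proportions at the
configured minor-allele frequency $q$: a standard-normal latent $z$ is
thresholded at $\Phi^{-1}((1-q)^2)$ and $\Phi^{-1}(1-q^2)$, giving 0/1/2
minor-allele counts. SNPs sharing an LD block draw their latents from an
equicorrelated Gaussian (a one-factor copula with loading $\sqrt{r}$), which
induces a tunable pairwise genotype correlation without phased haplotype
machinery; the implied genotype $r^2$ is validated in tests against an
independent Monte-Carlo oracle of the same copula.

Disease status follows a prospective additive logistic model,

$$P(\text{case}\mid g) = \mathrm{logit}^{-1}\Big(\beta_0 + \sum_i \beta_i\, g_i\Big),$$

with $\beta_i$ the per-minor-allele log odds ratio. Case and control quotas
are filled by rejection sampling conditional on the drawn status, matching
the retrospective case-control design of the studies this emulates. The
default intercept sets population prevalence to roughly 5%
($\beta_0 = \mathrm{logit}(0.05) - \sum_i 2 q_i \beta_i$), which keeps
rejection sampling efficient; it is configurable, and a pathological
intercept aborts with the achieved prevalence in the message.

Defaults mirror the emulated study design: 872 cases and 5486 controls;
2,000 SNPs of which 20 are causal with odds ratios drawn log-uniformly from
0.4–2.0 and MAFs uniform on 0.10–0.50 (the published per-locus MAF/OR
spectrum spans MAF 13–50% and OR 0.32–2.01); age
$\sim N(50.4, 7.9^2)$ for cases and $N(55.6, 8.6^2)$ for controls, and
male proportions 80.5% / 45.5%. Covariates never feed the genotype model —
they exist solely for the propensity-matching stage. Missing calls are
missing-completely-at-random at 1% by default; no published missing-call
rate exists for the emulated chip data, so this is a placeholder chosen
once.

What the generator does **not** emulate: recombination-map LD decay,
population structure and admixture, genotyping batch effects,
informative missingness, and imputation uncertainty. Tests passing on this
generator therefore validate the pipeline's machinery and calibration, not
robustness to those real-data complications.

## Feature selection and encoding

External summary statistics are matched to the cohort on rsid (the emulated
chips share rsid namespaces; positions are used only for ordering). Effect
alleles are aligned to the cohort minor allele: matching alleles keep their
odds ratio, swapped alleles invert it, strand-ambiguous pairs (A/T, C/G)
are dropped rather than frequency-resolved, and unmatched rsids are
dropped; all four outcomes are flagged per variant. Feature sets retain
SNPs with $p < t$ (strict) for a threshold grid from $5\times10^{-8}$ to
$10^{-3}$, plus the non-significant control rule $p \ge 0.99$, and are
ordered genomically — column order is genomic position throughout, which is
what makes a convolution over the SNP axis meaningful.

Genotypes enter the model as raw additive codes: homozygous minor 2,
heterozygous 1, homozygous major 0, missing −1, with no standardization and
no imputation. The minor allele is designated from the pooled case+control
frequency of the analysis cohort itself, ties at exactly 0.5 broken
lexicographically.

## The classifier

Architecture: input $N \times 1$ → 1D convolution (32 filters, width 4,
stride 1, ReLU) → flatten → dropout 0.5 → dense 64 (ReLU) → single logistic
output. Training minimizes class-weighted binary cross-entropy
(inverse-frequency weights by default, toggleable) with Adam at learning
rate $10^{-3}$, batch 64, at most 200 epochs, early stopping on validation
loss with patience 10 and best-epoch weight restoration. These sizes are
conventional small-model choices, all exposed in `cnn_config()`; they are
this package's own defaults, not claims about any prior model's
unpublished architecture. All randomness (initialization, shuffling,
dropout) derives from `config$seed`, so training is bit-reproducible.

Evaluation uses repeated stratified splits: per repeat, a stratified 20%
test set is held out and the remainder split 80/20 into train/validation —
64/16/20 overall with the case fraction preserved in each partition. The
decision threshold for sensitivity/specificity is the Youden-J optimum on
the validation partition, frozen before touching the test set. Metrics:
Mann–Whitney AUC with tie correction, sensitivity, specificity, PPV, NPV,
Gini ($= 2\cdot\mathrm{AUC}-1$), log-loss (probabilities clipped at
$10^{-7}$ — declared, not hidden), and MSE, reported per repeat and as
mean ± SD. Baselines under identical splits: the CNN with Monte-Carlo
dropout 0.5 at inference (100 passes; a Bayesian approximation), lasso and
ridge logistic regression (glmnet, penalty chosen by validation log-loss),
and unpenalized logistic regression (falling back to a tiny ridge penalty,
flagged, when underdetermined).

When a feature set is narrower than the kernel (e.g. a $5\times10^{-8}$
panel with three SNPs), the pipeline wrapper shrinks the kernel to the
feature count rather than aborting the experiment; `cnn_train()` itself
still rejects $N < k$ as a contract violation.

## Grad-CAM saliency and its resolution

For each patient, with $A^k_u$ the activation of conv filter $k$ at
position $u$ and $y$ the **pre-sigmoid** case score (gradients at the
logit avoid saturation): $\alpha_k = \frac{1}{L}\sum_u \partial y /
\partial A^k_u$, $L_u = \mathrm{ReLU}\big(\sum_k \alpha_k A^k_u\big)$, and
$L$ is upsampled from conv length to SNP length by linear interpolation at
the window centers. The per-SNP mean over patients (true cases by default,
mirroring a case-attribution analysis) is max-normalized so the top SNP
scores exactly 1.

A point that matters for validation: Grad-CAM attributes at the resolution
of the conv feature map. With kernel width $k$ and stride 1, a single
causal SNP excites the $k$ windows covering it, and which of those windows
the trained network leans on is arbitrary — so the interpolated peak can
land up to $k-1$ SNPs away from the causal locus. We observe exactly this
with the default width-4 kernel: a planted-signal experiment recovers the
locus to within 2 SNPs, but not reliably to exact top rank. The SNP-exact
rank-recovery experiment therefore uses `kernel_size = 1`, whose feature
map is in one-to-one correspondence with loci; the width-4 neighborhood
behavior is asserted separately. For the same reason the recovery
experiment uses a narrower, slower-trained network (8 filters, 16 dense
units, dropout 0.2, learning rate $5\times10^{-4}$, patience 30) at
3000/3000 samples: the full-width default with dropout 0.5 fails to train
at all on a 501-SNP input carrying a single moderate signal (it collapses
to the base rate, leaving a dead, all-zero saliency map), and an
attribution check presupposes a trained model. With ~500 mostly-null
inputs the race is between memorizing the training set and finding one
sparse signal; less capacity and smaller steps let the signal win. Because
stochastic optimization of so sparse a signal still occasionally collapses,
fits support random restarts (`n_restarts` in `cnn_config()`): several
seeded initializations, keeping the one with the lowest best validation
loss — the neural-network analogue of `kmeans`' `nstart`. The recovery
experiment uses three restarts. A decoupled L2 penalty on the weight
matrices (`weight_decay`, default 0) is also available; it raises the
saliency margin of a recovered SNP but, pushed hard, collapses training
before the sparse signal emerges.

Even so, exact top-rank recovery of a *single* moderate-effect SNP is not
guaranteed, and that is a property of Grad-CAM rather than of this
implementation: $\alpha_k$ averages gradients over **all** conv positions,
so one informative position among 500 contributes $1/501$ of each filter
weight, and with `kernel_size = 1` the shared conv features reduce each
patient's map to a single learned scalar function of the genotype —
per-SNP mean saliency then ranks SNPs by their case genotype distribution
passed through that function. When residual memorization noise makes the
function non-monotone, a null SNP can take the top rank even though the
planted SNP's case-frequency enrichment dwarfs null sampling noise. The
planted SNP reliably lands in the top 5% of saliency; its *exact* top rank
holds in most but not all training repeats.

Saliency is compared with the cohort's own association scan as the Pearson
correlation between max-normalized mean saliency and $-\log_{10} p$
(capped at 30 to bound genome-wide-significant values; whether to cap is a
judgment call, declared here), plus the overlap between the top-5%
saliency set and threshold-passing SNPs.

## Association scan and PRS

The scan fits one logistic regression of status on minor-allele count per
SNP (missing excluded, no covariates, no multiplicity correction —
thresholds are applied downstream) and reports Wald odds ratios, 95% CIs
and p-values; Wald rather than profile likelihood for speed and
determinism. Degenerate columns — monomorphic or separated — fall back to
the allelic 2×2 cross-product OR with Haldane–Anscombe correction and a
two-sided Fisher exact p.

The PRS baseline clumps harmonized SNPs greedily in ascending p order
(ties broken by position then rsid, making the result order-invariant):
each index SNP removes same-chromosome neighbors within ±250 kb whose
genotype $r^2$ exceeds 0.1, with the analysis cohort as LD reference.
Scores are the weighted minor-allele sums with log-OR weights; missing
genotypes contribute $2\,\mathrm{MAF}\cdot w$ (mean imputation), matching
standard scoring behavior.

## Negative controls

Two controls check that the signal lives where it should. The null-SNP
control re-runs the full pipeline on the $p \ge 0.99$ feature set; with
truly null control SNPs its mean AUC should sit in [0.45, 0.55]. The
parity control replaces the phenotype with the parity of the registration
index — a phenotype with no heritability — on the disease-associated
feature set; consecutive indices split exactly in half and mean AUC should
be ≈ 0.5. Propensity matching (logistic propensity on age and sex, greedy
1:1 nearest-neighbor on the logit within a 0.2-SD caliper, without
replacement) addresses the class-imbalance concern separately.

## Numerical and design choices

- Stage seeds derive from one master seed as
  $(\text{seed} + 7919\,s) \bmod (2^{31}-1)$; every stochastic stage is
  independently seeded and the whole experiment replays byte-identically.
- Log-loss clipping $\varepsilon = 10^{-7}$; AUC ties at 0.5 via mid-ranks;
  Youden ties take the lowest threshold; zero-variance saliency or
  association vectors make the correlation "undefined", never NaN.
- Problem sizes in the test suite are chosen to keep the full suite in the
  tens of minutes on one CPU: unit tests run cohorts of a few hundred
  samples; the calibration and control experiments run the full 872/5486
  design with 2,000 SNPs; the saliency-recovery experiment runs 3000/3000
  with 501 SNPs; sweeps use 400/1200 with 300 SNPs.
- The logistic-scan estimate of a *marginal* per-SNP log-OR is attenuated
  relative to the *conditional* planted effect when many other causal SNPs
  contribute liability (non-collapsibility of the odds ratio). Calibration
  experiments therefore plant moderate total liability so the attenuation
  stays well inside sampling noise; this is a property of marginal
  case-control scans generally, not of this implementation.

## Known limitations

The CNN is trained on CPU in plain R; it is adequate for panels of order
$10^2$–$10^3$ SNPs and thousands of samples, not for half-million-SNP
inputs. The generator's LD blocks are exchangeable within a block rather
than distance-decaying. Saliency scores carry no significance calibration —
they rank, they do not test. PRS evaluation reuses the analysis cohort as
its own LD reference, which is standard but optimistic relative to an
external reference panel.
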