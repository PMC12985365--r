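---
title: "Detecting polygenic gene-environment interaction with pgsxe: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting polygenic gene-environment interaction with pgsxe: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsxe)
```

## The problem

Single-variant gene-environment interaction (G×E) tests are chronically
underpowered: individual interaction effects on complex traits are tiny, and
genome-wide multiplicity is severe. An alternative is to aggregate: build a
polygenic score (PGS) from genome-wide per-variant summary statistics and
test a single *PGS×E* interaction term,

$$Y_i = \beta_0 + \beta_{PGS}\,PGS_i + \beta_E E_i +
        \beta_{PGS \times E}\, PGS_i \, E_i + \boldsymbol{\beta}_C^T
        \mathbf{C}_i + \epsilon_i,$$

where $E_i$ is a continuous exposure (the motivating application is BMI
against serum cardiometabolic biomarkers) and $\mathbf{C}_i$ are covariates.
The PGS main effect is always retained — dropping it inflates the type I
error of the interaction term. When genetic principal components are among
the covariates, exposure-by-gPC product terms belong in
$\mathbf{C}_i$ as well; pooled-ancestry interaction tests are otherwise
vulnerable to structure-induced false positives.

Three PGS flavours differ only in the genome-wide scan supplying their
weights:

* **mPGS** — marginal (main-effect) scan: OLS of $Y$ on dosage plus
  covariates, per variant.
* **iPGS** — interaction scan: OLS of $Y$ on dosage, exposure, their
  product, and covariates; the weight is the per-variant interaction
  coefficient $\beta_{G\times E}$.
* **vPGS** — variance scan: tests whether a variant changes trait
  *variability* rather than its mean, a signature of unmodeled interaction
  that needs no measured exposure at all.

## The variance scans

The default variance test is the deviation regression model (DRM). With
genotype groups $k \in \{0,1,2\}$ (dosages rounded) and group medians
$\tilde{Y}_k$, it regresses the absolute deviations
$Z_i = |Y_i - \tilde{Y}_{k(i)}|$ on additive genotype:
$Z_i = \beta_0 + \beta_{Gv} G_i + \boldsymbol{\beta}_C^T \mathbf{C}_i +
\epsilon_i$. Medians rather than means make the statistic robust to mean
effects and skew; the test is exactly invariant to adding a constant to
$Y$.

The alternative is a quantile-integral estimator: with quantile-regression
slopes $\beta_\tau$ of $Y$ on $G$, the quantity $\beta_{1-\tau} -
\beta_\tau$ isolates scale (variance) effects, since location effects
shift all quantiles equally and cancel. Aggregating,
$$\beta_{QI} = \int_0^{0.5} (\beta_{1-\tau} - \beta_\tau)\, d\tau,$$
approximated by the trapezoid rule on the grid $\tau \in \{0.05, 0.10,
\ldots, 0.45\}$ (a single-point grid falls back to the rectangle rule over
$(0, 0.5)$). Inference uses a case-resampling bootstrap (default 100
draws) of the integrated statistic; the original rank-score machinery of
the quantile-integral literature is deliberately not reimplemented, since
the estimator — not its specialized inference — is what the score pipeline
consumes. Quantile regressions are fit with `quantreg`.

## Score construction and threshold optimization

Scan estimates become weights by pruning and thresholding: greedy LD
clumping (radius 250 kb, $r^2 \le 0.1$, index variants by ascending
p-value) followed by retaining estimates with $p$ strictly below a cutoff.
The cutoff grid runs 0.05, 0.01, 0.005, ... down to $5\times10^{-8}$,
alternating $5\times10^{-k}$ / $1\times10^{-k}$ anchors. Because the goal
is interaction detection, the cutoff is *not* chosen by predictive $R^2$:
each candidate PGS is carried into the PGS×E model on a held-out
optimization subset (10% of samples), and the cutoff minimizing the
interaction p-value wins. Ties go to the more stringent cutoff (fewer
variants). The winning score is then refit once in the fully held-out
testing subset (20%); the 70/10/20 split is drawn once per run with sizes
within one sample of the exact fractions. Note the selected optimization
p-value is a minimum over correlated fits and is biased downward; only the
testing-subset fit is reported as evidence.

Weights transfer across datasets by chromosomal location: a variant whose
counted/non-counted alleles are reversed in the target panel keeps its
weight with the sign flipped; variants absent from the target or carrying a
different allele pair are dropped (with a reported count); if more than
5,000 variants survive, the 5,000 smallest source p-values are kept.
Strand-ambiguous variants (A/T, C/G) and duplicated IDs are excluded before
any scoring. Reported interaction coefficients are standardized to
$SD_Y / SD_{PGS} / SD_E$ units using testing-subset standard deviations, so
they are invariant to affine rescaling of score, exposure and outcome.

## The simulation engine

`run_scenario()` implements a replicate protocol for type-I-error and
power evaluation. One genotype matrix per scenario: $N = 10{,}000$ samples
by $M = 100$ independent variants, dosages Binomial$(2, \mathrm{MAF})$
with MAF $\sim U(0.01, 0.5)$. Per replicate:

1. **Exposure.** On a latent standard-normal scale,
   $E = \sqrt{\sigma^2_{GE}}\, g + \sqrt{1 - \sigma^2_{GE}}\, z$ with $g$
   a standardized random-weighted genetic score, giving gene-environment
   correlation with exposure variance share $\sigma^2_{GE}$ (0 or 0.1).
   Classical measurement error follows:
   $E^{meas} = \sqrt{ICC_E}\, E + \sqrt{1 - ICC_E}\,\xi$, so the squared
   true-measured correlation equals $ICC_E$. Non-normal exposures are
   produced by a Gaussian copula: $F^{-1}_{\Gamma(\alpha,\theta)}(\Phi(z))$
   applied identically to true and measured values after the correlation
   and error steps, preserving ranks exactly. The two gamma laws used in
   the shipped scenarios are $\Gamma(1,1)$ (mean 1, SD 1) and
   $\Gamma(4, 0.5)$ (mean 2, SD 1).
2. **Phenotype.** $Y = g_{main} + e_{main} + g \times e + \epsilon$, with
   main-effect weights $b$ and interaction weights $c$ drawn independently
   standard-normal over all $M$ variants (all variants causal; the draws
   are uncorrelated by construction). Dosages are standardized per column
   before forming genetic contributions so variance shares hold at any
   MAF; association testing always uses raw 0/1/2 coding. Each structural
   component is rescaled empirically to its exact variance share
   ($\sigma^2_G$, $\sigma^2_E$, $\sigma^2_{G\times E}$) and the residual is
   drawn with variance $1 - \sum \sigma^2$, giving Var$(Y) \approx 1$.
   The phenotype is generated from the error-free exposure; analysis sees
   only the error-added one — measurement error must attenuate the
   analyst's view, not the data-generating process. The exposure is
   mean-centered before forming interaction products (a flag allows
   non-centered products, which reproduces the severe vPGS power loss seen
   with nonnegative exposures whose products are collinear with main
   effects). The optional nonlinear exposure effect replaces $e$ with the
   standardized $e^2$ at the same variance share — the minimal
   nonlinearity producing spurious interaction when the mean model is
   misspecified.
3. **Protocol.** Random 70/30 train/test split; marginal, interaction and
   DRM scans in training; weights by the simple $p < 0.05$ rule (no
   clumping — the variants are independent); PGSs as weighted dosage sums;
   the PGS×E model in the testing subset; rejection at $\alpha = 0.05$
   tallied over replicates as $f$, with $SE = \sqrt{f(1-f)/P}$ and 95% CI
   $f \pm 1.96\,SE$.

Per-replicate seeds are pre-drawn from the scenario seed, so every result
is bit-reproducible and replicates are order-independent. The
quantile-integral scan can be switched on per scenario (`include_qi`),
but the DRM is the default vPGS source in simulation: running bootstrap
quantile regressions for every variant in every replicate costs orders of
magnitude more than the closed-form scans while testing the same
vPGS pathway, and the DRM is the variance model the simulation design is
built around. The shipped scenario runs use 500 replicates for
type-I-error conditions and 200 for power conditions; the originally
reported designs (5,000/500) are available by setting `n_replicates`.

What the simulations deliberately omit: population structure, relatedness,
linkage disequilibrium (scenario variants are independent), sparsity of
causal effects, binary outcomes, and non-classical (differential)
measurement error. Passing calibration here shows the pipeline's
statistics behave as designed under the generative model — not that real
biobank analyses are free of confounding these features can introduce.

## The toy biobank

`simulate_toy_biobank()` generates the fixture for end-to-end pipeline
tests: LD-blocked genotypes, a heritable BMI-like exposure (mean 27,
SD 4, heritability 0.2), standard covariates (sex, age, age², age×sex, ten
genetic PCs simulated as pure noise — they carry no structure, they only
exercise the model plumbing), biomarkers with planted PGS×E structure, and
deliberately planted strand-ambiguous and duplicate-ID variants so the QC
filters are exercised. LD uses a haplotype-copy model — within a block all
variants share one allele frequency and each haplotype copies a block
anchor allele with probability $\sqrt{r}$ — so within-block dosage
correlation equals the configured $r$ (default 0.9) in expectation at any
MAF, unlike latent-Gaussian threshold constructions whose realized dosage
correlation is attenuated.

The planted interaction acts through a standardized genetic score, so its
coefficient is directly in standardized units. For parameter-recovery
experiments the interaction is concentrated on three index variants in
distinct LD blocks with a standardized coefficient of 0.1: per-variant
training-scan signal-to-noise is then about 5 at $n_{train} = 7{,}000$, so
weight-estimation noise attenuates the recovered coefficient by only a few
percent. A dense, weak architecture (the generator's default for ordinary
pipeline tests) would attenuate the recovered value substantially through
noisy weights — informative about realistic PGS behaviour, but a poor
yardstick for testing that the pipeline chain is *correct*.

## Numerical design

* All OLS scans run through a vectorized Frisch–Waugh–Lovell engine: the
  outcome and dosage columns are residualized once against the shared
  covariate design (orthonormal QR basis), leaving per-variant problems
  of dimension one (marginal, DRM) or two (interaction) solved in closed
  form. Coefficients, model-based SEs, and HC0/HC1 sandwich SEs are
  algebraically identical to full per-variant regressions — the
  partitioned-sandwich identity is exact, not asymptotic — and the test
  suite verifies agreement with `lm()` and `sandwich::vcovHC()` to 1e-8.
* Monomorphic dosages, constant exposures, and single-genotype-group
  variants are flagged non-estimable and carry the sentinel p-value 1 plus
  an `estimable = FALSE` column: they can never pass a threshold, and no
  row is ever silently dropped.
* Thresholding uses strict inequality ($p <$ cutoff) everywhere.
* PGS decile binning breaks ties by stable sample order, for determinism.
* The effective number of correlated outcomes uses the eigenvalue rule
  $\sum_j \left[ \mathbf{1}(\lambda_j \ge 1) + (\lambda_j - \lfloor
  \lambda_j \rfloor) \right]$ on the outcome correlation spectrum, which
  reproduces the independence limit (count) and the degeneracy limit (1);
  eigenvalues are rounded to 10 decimals first so exact-integer spectra
  are not perturbed by floating-point noise. The Bonferroni level is the
  base $\alpha$ divided by this count.
* Statin-treated lipid values are divided by 0.749 (total cholesterol),
  0.684 (LDL-C) and 0.719 (ApoB). Biomarker cleaning supports a 5-SD rule
  (set to missing, after optional log transform) and an
  average-repeats / drop-negatives / impute-zeros-with-half-minimum /
  5-IQR rule; BMI cleaning averages repeats, applies the 5-IQR rule, then
  drops values below 10 kg/m².

## A small worked example

```{r example, eval = FALSE}
sc <- simulation_scenario(sigma2_GxE = 0.01, n_replicates = 100, seed = 1)
res <- run_scenario(sc)
res
```

Typical behaviour at these settings: the iPGS rejects in roughly 60–80% of
replicates, the DRM-based vPGS in 10–20%, and the mPGS stays near the
nominal 5% — the marginal score aggregates main effects, which are
uninformative about interaction when main and interaction weights are
uncorrelated.

## Known limitations

* Scans are OLS-only: no mixed models, no relatedness correction, no
  binary outcomes.
* The quantile-integral p-value is bootstrap-based and therefore granular
  at small bootstrap counts; it is intended for targeted follow-up, not
  for genome-wide scanning inside tight loops.
* Threshold optimization returns the minimum of correlated p-values;
  treat the optimization-subset trace as model selection, never as
  inference.
* Gene-environment correlation in the simulator is linear on the latent
  scale; more exotic dependence (e.g., interaction-driven G-E coupling)
  is not modeled.
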