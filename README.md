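# pgsxe

Polygenic score by environment (PGS×E) interaction testing — score
construction, evaluation, and simulation-based calibration.

## The problem

Per-variant gene-environment interaction effects on complex traits are too
small to detect reliably one variant at a time. `pgsxe` implements the
aggregated alternative: build a polygenic score (PGS) from genome-wide
per-variant summary statistics, then test a single interaction between the
score and a continuous exposure,

```
Y = b0 + b_PGS * PGS + b_E * E + b_PGSxE * PGS*E + b_C' C + e
```

with the PGS main effect always retained (omitting it inflates type I
error) and exposure-by-genetic-PC product terms included whenever genetic
PCs are among the covariates. The motivating setting is a biobank analysis
of BMI as the exposure against serum cardiometabolic biomarkers.

Three score types are supported, differing only in the genome-wide scan
that supplies their weights:

| score | training scan | weight |
|-------|---------------|--------|
| mPGS  | marginal (main-effect) GWAS | per-variant `b_G` |
| iPGS  | genome-wide interaction scan (G, E, G×E + covariates) | per-variant `b_GxE` |
| vPGS  | variance-QTL scan: deviation regression model (`Z = |Y - median_by_genotype|` on dosage) or a quantile-integral estimator `∫(b_(1-tau) - b_tau) dtau` | per-variant `b_Gv` |

Scores are built by pruning and thresholding (greedy clumping, 250 kb /
r² 0.1; cutoff grid 0.05 down to 5e-8), with the cutoff chosen to minimize
the PGS×E interaction p-value in a held-out optimization subset (70/10/20
training/optimization/testing split) and the final model fit in the fully
held-out testing subset. Cross-dataset weight transfer handles allele-order
sign flips, drops mismatches, and caps at the top 5,000 variants by
p-value. A simulation engine (normal or Gaussian-copula gamma exposures,
gene-environment correlation, exposure measurement error, exact phenotype
variance shares) supports type-I-error and power studies, and an
LD-blocked toy-biobank generator supports end-to-end pipeline tests.

## Worked example

A power scenario with 1% of phenotypic variance from G×E, 10% each from G
and E main effects:

```r
library(pgsxe)
sc  <- simulation_scenario(sigma2_G = 0.1, sigma2_E = 0.1,
                           sigma2_GxE = 0.01, n_replicates = 100, seed = 7)
run_scenario(sc)
#> scenario: N=10000 M=100 s2G=0.1 s2E=0.1 s2GxE=0.01 s2GE=0 ICC=1 dist=normal P=100
#>   mPGS     rejection 0.1200 (0.0563-0.1837)
#>   iPGS     rejection 0.7700 (0.6875-0.8525)
#>   vPGS_drm rejection 0.2100 (0.1302-0.2898)
```

Interpretation: at this effect size the interaction-trained score detects
the planted PGS×E signal in 77% of replicates, the variance score (which
never sees the exposure during training) in 21%, and the marginal score —
whose weights aggregate main effects uncorrelated with the interaction
weights — trails at 12%. Each rate is reported with the binomial standard
error `sqrt(f(1-f)/P)` and its 95% CI.

The full biobank-style pipeline on generated data:

```r
tb  <- simulate_toy_biobank(toy_biobank_config(n_samples = 5000,
                                               interaction_variants = 3),
                            seed = 1)
res <- run_biobank_pipeline(
  tb$genotypes, tb$samples,
  config = list(outcomes = c("bm1", "bm2"), exposure = "exposure",
                covariates = c("sex", "age", "age2", "age_sex",
                               paste0("gPC", 1:10)),
                exposure_products = paste0("gPC", 1:10)))
res$fits$bm1$iPGS$fit
#> PGS-by-exposure interaction fit (n = 1000 )
#>               estimate      se        p
#> (Intercept)  -1.318850  1.5030 0.380459
#> pgs         -28.818979 12.8826 0.025509 *
#> e             0.040065  0.0123 0.001186 **
#> pgs:e         1.010851  0.4785 0.034893 *
#> standardized beta_PGSxE: 0.06959 (SD_Y per SD_PGS per SD_E)
```

The toy biobank plants a standardized interaction of 0.05 on `bm1` (and
none on `bm2`); the testing-subset fit recovers it (0.070 ± 0.033,
p = 0.035) on the raw BMI-like exposure scale — the raw `pgs:e`
coefficient depends on the units of score and exposure, the standardized
one does not.

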