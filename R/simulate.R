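#' Define a simulation scenario
#'
#' Collects every generative parameter of one simulation condition: sample
#' and variant counts, the variance fractions of the phenotype attributable
#' to genetic main effects (`sigma2_G`), exposure main effects (`sigma2_E`)
#' and their interaction (`sigma2_GxE`); the fraction of exposure variance
#' explained by genotype (`sigma2_GE`, gene-environment correlation); the
#' intraclass correlation of the measured exposure (`icc_E`, lower means
#' more measurement error); the exposure marginal distribution; and the
#' replicate count.
#'
#' @param n_samples,n_variants dataset dimensions (default 10,000 x 100).
#' @param maf_range minor-allele-frequency range, a subinterval of (0, 0.5].
#' @param sigma2_G,sigma2_E,sigma2_GxE phenotype variance fractions in
#'   \[0, 1); their sum must be < 1.
#' @param sigma2_GE exposure variance fraction explained by genotype.
#' @param icc_E fraction of measured-exposure variance explained by the true
#'   exposure, in (0, 1\].
#' @param exposure_dist `"normal"` or `"gamma"`.
#' @param gamma_shape,gamma_scale gamma parameters used when
#'   `exposure_dist = "gamma"`; the defaults (1, 1) give mean 1 and SD 1.
#' @param nonlinear_E if `TRUE` the exposure main effect on the phenotype is
#'   quadratic (standardized e^2) rather than linear.
#' @param center_products if `TRUE` (default) the exposure is mean-centered
#'   before forming G-by-E products, both in generation and in the
#'   interaction scan.
#' @param n_replicates number of independent exposure/phenotype replicates.
#' @param train_fraction fraction of samples assigned to training (the rest
#'   is the testing set).
#' @param alpha nominal significance level for the PGS-by-E test.
#' @param include_qi also run the quantile-integral variance scan per
#'   replicate (slow; the deviation regression model remains the vPGS
#'   source).
#' @param seed integer root seed.
#' @return A list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_samples = 10000L, n_variants = 100L,
                                maf_range = c(0.01, 0.5),
                                sigma2_G = 0.1, sigma2_E = 0.1,
                                sigma2_GxE = 0, sigma2_GE = 0,
                                icc_E = 1, exposure_dist = c("normal", "gamma"),
                                gamma_shape = 1, gamma_scale = 1,
                                nonlinear_E = FALSE, center_products = TRUE,
                                n_replicates = 500L, train_fraction = 0.7,
                                alpha = 0.05, include_qi = FALSE, seed = 1L) {
  exposure_dist <- match.arg(exposure_dist)
  if (sigma2_G + sigma2_E + sigma2_GxE >= 1) {
    stop("variance fractions sigma2_G + sigma2_E + sigma2_GxE must sum to < 1")
  }
  if (sigma2_GE >= 1 || sigma2_GE < 0) stop("sigma2_GE must lie in [0, 1)")
  if (icc_E <= 0 || icc_E > 1) stop("icc_E must lie in (0, 1]")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must be a subinterval of (0, 0.5]")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    maf_range = maf_range, sigma2_G = sigma2_G, sigma2_E = sigma2_E,
    sigma2_GxE = sigma2_GxE, sigma2_GE = sigma2_GE, icc_E = icc_E,
    exposure_dist = exposure_dist, gamma_shape = gamma_shape,
    gamma_scale = gamma_scale, nonlinear_E = nonlinear_E,
    center_products = center_products, n_replicates = as.integer(n_replicates),
    train_fraction = train_fraction, alpha = alpha,
    include_qi = include_qi, seed = as.integer(seed)
  ), class = "simulation_scenario")
}

#' Simulate independent biallelic genotypes
#'
#' Draws per-variant minor allele frequencies uniformly from `maf_range` and
#' genotypes from Binomial(2, MAF), giving independent variants in
#' Hardy-Weinberg proportions.
#'
#' @param n,m sample and variant counts.
#' @param maf_range MAF range, a subinterval of (0, 0.5].
#' @param seed integer seed.
#' @return A [genotype_dataset()] with alleles assigned arbitrarily (effect
#'   allele "A", other allele "G") and realized MAFs stored in metadata.
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.01, 0.5), seed = 1L) {
  if (n < 1 || m < 1) stop("n and m must be >= 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must be a subinterval of (0, 0.5]")
  }
  set.seed(seed)
  maf <- stats::runif(m, maf_range[1], maf_range[2])
  dos <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  variants <- data.frame(
    id = paste0("sim", seq_len(m)),
    chrom = "1",
    pos = seq_len(m) * 1000000L,  # spaced beyond any clumping radius
    effect_allele = "A", other_allele = "G",
    maf = maf, info = 1,
    stringsAsFactors = FALSE
  )
  genotype_dataset(dos, variants)
}

#' Gaussian-copula transform to gamma marginals
#'
#' Maps standard-normal values to gamma-distributed values by the
#' normal-to-anything construction: probabilities via the standard normal
#' CDF, then the gamma quantile function. The map is strictly increasing, so
#' rank order (and hence copula dependence) is preserved exactly.
#'
#' @param z numeric vector of (approximately standard normal) values.
#' @param shape,scale gamma parameters (both > 0).
#' @return Nonnegative values with Gamma(shape, scale) marginals when `z` is
#'   standard normal.
#' @export
gamma_copula_transform <- function(z, shape, scale) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  if (any(!is.finite(z))) stop("non-finite values in input")
  stats::qgamma(stats::pnorm(z), shape = shape, scale = scale)
}

# standardize columns of a dosage matrix (mean 0, unit variance); columns
# with zero variance are left at 0
.standardize_cols <- function(G) {
  mu <- colMeans(G)
  Gc <- sweep(G, 2L, mu)
  sd <- sqrt(colMeans(Gc^2))
  sd[sd == 0] <- 1
  sweep(Gc, 2L, sd, "/")
}

# scale a vector to an exact sample variance (denominator n), preserving mean 0
.scale_to_var <- function(x, v) {
  if (v == 0) return(rep(0, length(x)))
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) stop("cannot scale a constant component to positive variance")
  x * sqrt(v) / s
}

#' Simulate an exposure with gene-environment correlation and measurement
#' error
#'
#' On the latent standard-normal scale the true exposure is
#' `sqrt(sigma2_GE) * g + sqrt(1 - sigma2_GE) * z`, where `g` is a
#' standardized weighted sum of standardized dosages (weights drawn
#' standard-normal) and `z` is independent noise. The measured exposure adds
#' classical measurement error, `sqrt(icc_E) * e_true + sqrt(1 - icc_E) * xi`,
#' so the squared correlation between true and measured exposure equals
#' `icc_E`. A gamma marginal, when requested, is imposed by applying the same
#' copula map to both the true and measured exposure after the correlation
#' and error steps.
#'
#' @param G dosage matrix or [genotype_dataset()].
#' @param sigma2_GE exposure variance fraction explained by genotype, in
#'   \[0, 1).
#' @param icc_E intraclass correlation in (0, 1\].
#' @param exposure_dist `"normal"` or `"gamma"`.
#' @param gamma_shape,gamma_scale gamma parameters.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A list of class `exposure_panel` with elements `e_true` (used to
#'   generate phenotypes) and `e_measured` (used in analysis).
#' @export
simulate_exposure <- function(G, sigma2_GE = 0, icc_E = 1,
                              exposure_dist = c("normal", "gamma"),
                              gamma_shape = 1, gamma_scale = 1, seed = NULL) {
  exposure_dist <- match.arg(exposure_dist)
  if (sigma2_GE >= 1 || sigma2_GE < 0) stop("sigma2_GE must lie in [0, 1)")
  if (icc_E <= 0 || icc_E > 1) stop("icc_E must lie in (0, 1]")
  if (inherits(G, "genotype_dataset")) G <- G$dosages
  n <- nrow(G)
  if (!is.null(seed)) set.seed(seed)
  e_true <- stats::rnorm(n)
  if (sigma2_GE > 0) {
    u <- stats::rnorm(ncol(G))
    gscore <- .standardize_cols(G) %*% u
    gscore <- as.numeric(scale(gscore))
    e_true <- sqrt(sigma2_GE) * gscore + sqrt(1 - sigma2_GE) * e_true
  }
  if (icc_E < 1) {
    e_measured <- sqrt(icc_E) * e_true + sqrt(1 - icc_E) * stats::rnorm(n)
  } else {
    e_measured <- e_true
  }
  if (exposure_dist == "gamma") {
    e_true <- gamma_copula_transform(e_true, gamma_shape, gamma_scale)
    e_measured <- gamma_copula_transform(e_measured, gamma_shape, gamma_scale)
  }
  structure(list(e_true = as.numeric(e_true), e_measured = as.numeric(e_measured)),
            class = "exposure_panel")
}

#' Simulate a phenotype with genetic, exposure, and interaction components
#'
#' Builds `y = g_main + e_main + gxe + noise` where `g_main` is a weighted
#' sum of standardized dosages (weights `b` standard-normal over all
#' variants), `e_main` is the (optionally quadratic) true exposure, and
#' `gxe` is an independently weighted genetic score (`c` standard-normal)
#' multiplied elementwise by the mean-centered true exposure. Each
#' structural component is rescaled empirically so its realized variance
#' share equals the requested fraction exactly; residual noise is drawn with
#' variance `1 - sigma2_G - sigma2_E - sigma2_GxE`, so Var(y) is ~1.
#'
#' @param G dosage matrix or [genotype_dataset()].
#' @param e_true per-sample true exposure on the analysis scale (possibly
#'   gamma-transformed).
#' @param scenario a [simulation_scenario()] supplying the variance
#'   fractions and flags.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A list of class `phenotype_set`: `y`, the per-variant main-effect
#'   weights `b` and interaction weights `c`, and the realized variance
#'   shares.
#' @export
simulate_phenotype <- function(G, e_true, scenario, seed = NULL) {
  if (inherits(G, "genotype_dataset")) G <- G$dosages
  if (nrow(G) != length(e_true)) stop("dimension mismatch between G and e_true")
  s2 <- c(G = scenario$sigma2_G, E = scenario$sigma2_E, GxE = scenario$sigma2_GxE)
  if (sum(s2) >= 1) stop("variance fractions must sum to < 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(G); m <- ncol(G)
  Gstd <- .standardize_cols(G)
  b <- stats::rnorm(m)
  cc <- stats::rnorm(m)
  g_main <- .scale_to_var(as.numeric(Gstd %*% b), s2["G"])
  f_e <- if (scenario$nonlinear_E) {
    as.numeric(scale(e_true^2))
  } else {
    e_true
  }
  e_main <- .scale_to_var(f_e, s2["E"])
  e_prod <- if (isTRUE(scenario$center_products)) e_true - mean(e_true) else e_true
  gxe <- .scale_to_var(as.numeric(Gstd %*% cc) * e_prod, s2["GxE"])
  noise <- stats::rnorm(n, sd = sqrt(1 - sum(s2)))
  y <- g_main + e_main + gxe + noise
  structure(list(
    y = y, b = b, c = cc,
    realized = c(G = stats::var(g_main), E = stats::var(e_main),
                 GxE = stats::var(gxe))
  ), class = "phenotype_set")
}

#' Configuration for the toy-biobank generator
#'
#' @param n_samples sample count.
#' @param n_blocks,block_size LD structure: variants come in `n_blocks`
#'   independent blocks of `block_size` variants with within-block latent
#'   correlation `block_r`.
#' @param block_r within-block latent allelic correlation in \[0, 1).
#' @param maf_range MAF range.
#' @param exposure_h2 heritability of the BMI-like exposure.
#' @param exposure_mean,exposure_sd exposure location/scale (BMI-like
#'   defaults).
#' @param biomarkers named list describing each outcome; each element is a
#'   list with `sigma2_G`, `sigma2_E`, `beta_pgsxe` (standardized
#'   PGS-by-exposure interaction coefficient planted through the
#'   interaction genetic score; 0 for a null biomarker).
#' @param interaction_variants number of variants carrying the planted
#'   interaction. 0 (default) spreads it over the same dense causal score
#'   as the main effects; k > 0 concentrates it on the first variant of
#'   each of the first k LD blocks (a sparse architecture whose weights the
#'   training scans can estimate precisely, keeping pipeline attenuation of
#'   the planted coefficient small).
#' @param n_ambiguous number of planted strand-ambiguous (A/T or C/G)
#'   variants.
#' @param n_duplicate_ids number of planted duplicated variant IDs.
#' @return A list of class `toy_biobank_config`.
#' @export
toy_biobank_config <- function(n_samples = 2000L, n_blocks = 10L,
                               block_size = 10L, block_r = 0.9,
                               maf_range = c(0.05, 0.5),
                               exposure_h2 = 0.2,
                               exposure_mean = 27, exposure_sd = 4,
                               biomarkers = list(
                                 bm1 = list(sigma2_G = 0.15, sigma2_E = 0.05,
                                            beta_pgsxe = 0.05),
                                 bm2 = list(sigma2_G = 0.15, sigma2_E = 0.05,
                                            beta_pgsxe = 0)
                               ),
                               interaction_variants = 0L,
                               n_ambiguous = 2L, n_duplicate_ids = 2L) {
  if (block_size < 1 || n_blocks < 1) stop("block dimensions must be >= 1")
  if (interaction_variants > n_blocks) {
    stop("interaction_variants cannot exceed the block count")
  }
  structure(as.list(environment()), class = "toy_biobank_config")
}

#' Simulate an LD-structured toy biobank
#'
#' Generates a small biobank-like dataset for end-to-end pipeline tests:
#' genotypes with block-diagonal LD, a heritable BMI-like exposure,
#' covariates (sex, age, age^2, age-by-sex, ten genetic PCs simulated as
#' noise), and biomarkers carrying a planted PGS-by-exposure interaction of
#' known standardized size. Strand-ambiguous variants and duplicated variant
#' IDs are planted so that variant filters are exercised.
#'
#' LD uses a haplotype-copy model: variants within a block share one allele
#' frequency (as in a tight haplotype block) and each of a sample's two
#' haplotypes copies a block anchor allele with probability `sqrt(block_r)`,
#' drawing a fresh allele otherwise — giving pairwise within-block dosage
#' correlation `block_r` in expectation at any MAF.
#'
#' The planted interaction acts through the per-sample causal genetic score:
#' `y = sqrt(s2G) * gs + sqrt(s2E) * e_std + beta_pgsxe * gs * e_std + noise`
#' with `gs` and `e_std` standardized, so `beta_pgsxe` is directly the
#' standardized interaction coefficient (SD_Y per SD_score per SD_E).
#'
#' @param config a [toy_biobank_config()].
#' @param seed integer seed.
#' @return A list with elements `genotypes` (a [genotype_dataset()]),
#'   `samples` (data frame: sample_id, exposure, covariates, biomarkers),
#'   and `truth` (per-biomarker planted parameters and the causal weights).
#' @export
simulate_toy_biobank <- function(config = toy_biobank_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_samples
  m <- config$n_blocks * config$block_size
  if (config$block_size > m) stop("block size exceeds variant count")
  block_maf <- stats::runif(config$n_blocks, config$maf_range[1],
                            config$maf_range[2])
  maf <- rep(block_maf, each = config$block_size)
  copy_p <- sqrt(config$block_r)
  dos <- matrix(0, n, m)
  for (b in seq_len(config$n_blocks)) {
    cols <- ((b - 1L) * config$block_size + 1L):(b * config$block_size)
    p <- block_maf[b]
    for (hap in 1:2) {
      anchor <- stats::rbinom(n, 1L, p)
      fresh <- matrix(stats::rbinom(n * length(cols), 1L, p), n)
      copied <- matrix(stats::runif(n * length(cols)) < copy_p, n)
      dos[, cols] <- dos[, cols] + ifelse(copied, anchor, fresh)
    }
  }
  alleles_pool <- c("A", "C", "G", "T")
  effect <- sample(alleles_pool, m, replace = TRUE)
  other <- vapply(effect, function(a) sample(setdiff(alleles_pool, a), 1L),
                  character(1), USE.NAMES = FALSE)
  ids <- paste0("rs", seq_len(m))
  # plant strand-ambiguous pairs and duplicate IDs outside the blocks that
  # carry the causal interaction signal used by parameter-recovery tests
  n_protect <- max(1L, config$interaction_variants) * config$block_size
  safe <- setdiff(seq_len(m), seq_len(n_protect))
  if (config$n_ambiguous > 0L) {
    amb <- sample(safe, config$n_ambiguous)
    effect[amb] <- c("A", "C")[(seq_along(amb) %% 2L) + 1L]
    other[amb] <- c("T", "G")[(seq_along(amb) %% 2L) + 1L]
    safe <- setdiff(safe, amb)
  }
  if (config$n_duplicate_ids > 0L) {
    dup <- sample(safe, config$n_duplicate_ids)
    ids[dup] <- ids[dup[1L]]
  }
  variants <- data.frame(
    id = ids, chrom = as.character(rep(seq_len(config$n_blocks),
                                       each = config$block_size)),
    pos = rep(seq_len(config$block_size) * 10000L, config$n_blocks),
    effect_allele = effect, other_allele = other,
    maf = pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2), info = 1,
    stringsAsFactors = FALSE
  )
  geno <- genotype_dataset(dos, variants)

  Gstd <- .standardize_cols(dos)
  causal_w <- stats::rnorm(m)
  gs <- as.numeric(scale(Gstd %*% causal_w))
  k <- config$interaction_variants
  if (k > 0L) {
    int_idx <- ((seq_len(k) - 1L) * config$block_size) + 1L
    gs_int <- as.numeric(scale(rowSums(Gstd[, int_idx, drop = FALSE])))
  } else {
    int_idx <- integer(0)
    gs_int <- gs
  }

  # heritable exposure on the BMI scale
  e_lat <- sqrt(config$exposure_h2) * as.numeric(scale(Gstd %*% stats::rnorm(m))) +
    sqrt(1 - config$exposure_h2) * stats::rnorm(n)
  exposure <- config$exposure_mean + config$exposure_sd * e_lat
  e_std <- as.numeric(scale(exposure))

  sex <- stats::rbinom(n, 1L, 0.5)
  age <- round(stats::runif(n, 40, 69))
  gpcs <- matrix(stats::rnorm(n * 10L), n, 10L,
                 dimnames = list(NULL, paste0("gPC", 1:10)))
  samples <- data.frame(sample_id = geno$sample_ids, exposure = exposure,
                        sex = sex, age = age, age2 = age^2,
                        age_sex = age * sex, stringsAsFactors = FALSE)
  samples <- cbind(samples, as.data.frame(gpcs))

  truth <- list(causal_weights = causal_w, interaction_variants = int_idx,
                biomarkers = list())
  for (nm in names(config$biomarkers)) {
    bm <- config$biomarkers[[nm]]
    s2 <- bm$sigma2_G + bm$sigma2_E
    if (s2 >= 1) stop("biomarker ", nm, ": variance fractions must sum to < 1")
    y <- sqrt(bm$sigma2_G) * gs + sqrt(bm$sigma2_E) * e_std +
      bm$beta_pgsxe * gs_int * (e_std - mean(e_std)) +
      stats::rnorm(n, sd = sqrt(max(1 - s2 - bm$beta_pgsxe^2, 0.05)))
    samples[[nm]] <- y
    truth$biomarkers[[nm]] <- bm
  }
  list(genotypes = geno, samples = samples, truth = truth)
}
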