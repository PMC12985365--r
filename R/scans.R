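#' Describe a scan model for pipeline mode
#'
#' Names the outcome, exposure and covariate columns of a sample table, plus
#' the options each genome-wide scan should use. Exposure-by-covariate
#' product terms (typically exposure-by-genetic-PC, which guard pooled
#' interaction analyses against population structure) are listed by
#' covariate name.
#'
#' @param outcome outcome column name.
#' @param exposure exposure column name (required for the interaction scan).
#' @param covariates character vector of covariate column names.
#' @param robust_se use heteroscedasticity-robust (sandwich) standard
#'   errors in the interaction scan.
#' @param center_exposure mean-center the exposure before products.
#' @param exposure_products covariate names to interact with the exposure.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(outcome, exposure = NULL, covariates = character(),
                       robust_se = FALSE, center_exposure = TRUE,
                       exposure_products = character()) {
  if (anyDuplicated(covariates)) stop("covariate names must be unique")
  if (length(exposure_products) > 0 &&
      !all(exposure_products %in% covariates)) {
    stop("exposure_products must reference declared covariates")
  }
  structure(list(outcome = outcome, exposure = exposure,
                 covariates = covariates, robust_se = robust_se,
                 center_exposure = center_exposure,
                 exposure_products = exposure_products),
            class = "model_spec")
}

# orthonormal basis of the adjustment design [1, C]; returns list(Q, p)
.adjust_basis <- function(n, covariates = NULL) {
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    storage.mode(C) <- "double"
    X <- cbind(X, C)
  }
  qrX <- qr(X)
  list(Q = qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE], p = qrX$rank)
}

.residualize_on <- function(X, Q) X - Q %*% crossprod(Q, X)

.as_dosage_matrix <- function(G) {
  if (inherits(G, "genotype_dataset")) G$dosages else as.matrix(G)
}

.variant_meta <- function(G, m) {
  if (inherits(G, "genotype_dataset")) {
    G$variants[, c("id", "effect_allele", "other_allele")]
  } else {
    ids <- colnames(G)
    if (is.null(ids)) ids <- paste0("v", seq_len(m))
    data.frame(id = ids, effect_allele = NA_character_,
               other_allele = NA_character_, stringsAsFactors = FALSE)
  }
}

# assemble a scan_result, flagging non-estimable rows with the p = 1 sentinel
.finish_scan <- function(meta, beta, se, df, n, scan_type, estimable,
                         p = NULL) {
  beta[!estimable] <- NA_real_
  se[!estimable] <- NA_real_
  if (is.null(p)) {
    p <- 2 * stats::pt(-abs(beta / se), df)
  }
  p[!estimable] <- 1
  scan_result(meta$id, meta$effect_allele, meta$other_allele,
              beta, se, p, n, scan_type, estimable)
}

#' Genome-wide marginal (main-effect) scan
#'
#' Fits, for each variant, the linear model `y ~ dosage + covariates` and
#' reports the dosage coefficient (the genetic main effect), its standard
#' error, and p-value. All variants are fit jointly by residualizing the
#' outcome and every dosage column on the covariate design, which yields
#' coefficients identical to per-variant least squares.
#'
#' @param G dosage matrix (samples x variants) or [genotype_dataset()].
#' @param y numeric outcome.
#' @param covariates optional numeric matrix / data frame of covariates.
#' @param robust_se use HC sandwich standard errors instead of model-based.
#' @param hc_type small-sample correction for robust SEs.
#' @return A [scan_result()] with `scan_type = "marginal"`.
#' @export
marginal_scan <- function(G, y, covariates = NULL, robust_se = FALSE,
                          hc_type = c("HC0", "HC1")) {
  hc_type <- match.arg(hc_type)
  dos <- .as_dosage_matrix(G)
  n <- nrow(dos); m <- ncol(dos)
  stopifnot(length(y) == n)
  adj <- .adjust_basis(n, covariates)
  yr <- .residualize_on(cbind(y), adj$Q)[, 1L]
  Gr <- .residualize_on(dos, adj$Q)
  sxx <- colSums(Gr^2)
  estimable <- sxx > n * 1e-12
  sxx[!estimable] <- NA_real_
  sxy <- colSums(Gr * yr)
  beta <- sxy / sxx
  df <- n - adj$p - 1L
  if (robust_se) {
    R <- yr - sweep(Gr, 2L, beta, "*")  # full-model residuals via FWL
    meat <- colSums((R * Gr)^2)
    v <- meat / sxx^2
    if (hc_type == "HC1") v <- v * n / df
    se <- sqrt(v)
  } else {
    rss <- pmax(sum(yr^2) - beta * sxy, 0)
    se <- sqrt(rss / df / sxx)
  }
  .finish_scan(.variant_meta(G, m), beta, se, df, n, "marginal", estimable)
}

#' Genome-wide interaction scan
#'
#' Fits, for each variant, `y ~ dosage + e + dosage:e + covariates`
#' (optionally plus exposure-by-covariate products) and reports the
#' interaction coefficient. Sandwich (HC) standard errors are available via
#' `robust_se`, matching the convention of running interaction scans with
#' robust inference. The exposure is mean-centered before forming products
#' when `center_exposure` is `TRUE`.
#'
#' @inheritParams marginal_scan
#' @param e numeric exposure.
#' @param center_exposure mean-center the exposure first (default `TRUE`).
#' @param exposure_products optional matrix of extra adjustment columns
#'   formed as exposure-by-covariate products (passed pre-built), or column
#'   indices/names of `covariates` to interact with the exposure.
#' @return A [scan_result()] with `scan_type = "interaction"` carrying the
#'   per-variant G-by-E coefficient.
#' @export
interaction_scan <- function(G, y, e, covariates = NULL, robust_se = FALSE,
                             hc_type = c("HC0", "HC1"),
                             center_exposure = TRUE,
                             exposure_products = NULL) {
  hc_type <- match.arg(hc_type)
  dos <- .as_dosage_matrix(G)
  n <- nrow(dos); m <- ncol(dos)
  stopifnot(length(y) == n, length(e) == n)
  if (center_exposure) e <- e - mean(e)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(exposure_products)) {
    ep <- if (is.matrix(exposure_products)) exposure_products
          else C[, exposure_products, drop = FALSE] * e
    C <- cbind(C, ep)
  }
  adj <- .adjust_basis(n, cbind(C, e))
  yr <- .residualize_on(cbind(y), adj$Q)[, 1L]
  Gr <- .residualize_on(dos, adj$Q)
  Wr <- .residualize_on(dos * e, adj$Q)
  a <- colSums(Gr^2); bb <- colSums(Gr * Wr); cc <- colSums(Wr^2)
  u <- colSums(Gr * yr); v <- colSums(Wr * yr)
  D <- a * cc - bb^2
  estimable <- a > n * 1e-12 & D > n * a * 1e-12
  D[!estimable] <- NA_real_
  beta_g <- (cc * u - bb * v) / D
  beta_w <- (a * v - bb * u) / D
  df <- n - adj$p - 2L
  if (robust_se) {
    R <- yr - sweep(Gr, 2L, beta_g, "*") - sweep(Wr, 2L, beta_w, "*")
    m11 <- colSums((R * Gr)^2)
    m12 <- colSums(R^2 * Gr * Wr)
    m22 <- colSums((R * Wr)^2)
    vw <- (bb^2 * m11 - 2 * a * bb * m12 + a^2 * m22) / D^2
    if (hc_type == "HC1") vw <- vw * n / df
    se <- sqrt(vw)
  } else {
    rss <- pmax(sum(yr^2) - beta_g * u - beta_w * v, 0)
    se <- sqrt(rss / df * a / D)
  }
  .finish_scan(.variant_meta(G, m), beta_w, se, df, n, "interaction",
               estimable)
}

#' Genome-wide variance scan: deviation regression model
#'
#' For each variant, genotype dosages are rounded to groups {0, 1, 2}, the
#' per-group phenotype median is computed, and each individual's absolute
#' deviation from its genotype-group median is regressed on the additive
#' genotype coding (plus covariates). The genotype coefficient estimates the
#' change in phenotype variability per allele; it is sensitive to unmodeled
#' interactions without requiring the exposure to be measured.
#'
#' @inheritParams marginal_scan
#' @return A [scan_result()] with `scan_type = "variance_drm"`.
#' @export
drm_scan <- function(G, y, covariates = NULL) {
  dos <- .as_dosage_matrix(G)
  n <- nrow(dos); m <- ncol(dos)
  stopifnot(length(y) == n)
  grp <- round(dos)
  grp[grp < 0] <- 0; grp[grp > 2] <- 2
  Z <- matrix(NA_real_, n, m)
  estimable <- logical(m)
  fast_median <- function(x) {
    nx <- length(x)
    half <- (nx + 1L) %/% 2L
    if (nx %% 2L == 1L) sort.int(x, partial = half)[half]
    else mean(sort.int(x, partial = c(half, half + 1L))[c(half, half + 1L)])
  }
  for (j in seq_len(m)) {
    g <- grp[, j]
    meds <- rep(NA_real_, 3L)
    n_groups <- 0L
    for (k in 0:2) {
      idx <- g == k
      if (any(idx)) {
        meds[k + 1L] <- fast_median(y[idx])
        n_groups <- n_groups + 1L
      }
    }
    estimable[j] <- n_groups >= 2L
    Z[, j] <- abs(y - meds[g + 1L])
  }
  adj <- .adjust_basis(n, covariates)
  Zr <- .residualize_on(Z, adj$Q)
  Gr <- .residualize_on(grp, adj$Q)
  sxx <- colSums(Gr^2)
  estimable <- estimable & sxx > n * 1e-12
  sxx[!estimable] <- NA_real_
  sxy <- colSums(Gr * Zr)
  beta <- sxy / sxx
  df <- n - adj$p - 1L
  rss <- pmax(colSums(Zr^2) - beta * sxy, 0)
  se <- sqrt(rss / df / sxx)
  .finish_scan(.variant_meta(G, m), beta, se, df, n, "variance_drm",
               estimable)
}

#' Genome-wide variance scan: quantile-integral model
#'
#' For each variant and each quantile level tau in `tau_grid`, quantile
#' regressions of the outcome on genotype (plus covariates) are fit at tau
#' and 1 - tau; the difference of the two genotype slopes measures how the
#' genotype effect diverges between upper and lower quantiles — a variance
#' (scale) effect. The differences are aggregated over the grid by the
#' trapezoid rule, approximating the integral of `beta_(1-tau) - beta_tau`
#' over tau in (0, 0.5). With a single grid point the rectangle rule over
#' (0, 0.5) is used. Inference is by case-resampling bootstrap of the
#' integrated statistic.
#'
#' @inheritParams marginal_scan
#' @param tau_grid quantile levels, strictly inside (0, 0.5).
#' @param n_boot bootstrap replicates for the p-value (0 skips inference;
#'   SE and p are then `NA` and the sentinel 1 is not applied).
#' @param seed optional seed for the bootstrap resampling.
#' @return A [scan_result()] with `scan_type = "variance_qi"`.
#' @export
quantile_integral_scan <- function(G, y, covariates = NULL,
                                   tau_grid = seq(0.05, 0.45, by = 0.05),
                                   n_boot = 100L, seed = NULL) {
  if (length(tau_grid) == 0L || any(tau_grid <= 0) || any(tau_grid >= 0.5)) {
    stop("tau_grid must be non-empty and strictly inside (0, 0.5)")
  }
  dos <- .as_dosage_matrix(G)
  n <- nrow(dos); m <- ncol(dos)
  stopifnot(length(y) == n)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(seed)) set.seed(seed)
  taus <- sort(tau_grid)

  qi_one <- function(g, y, C) {
    X <- if (is.null(C)) cbind(1, g) else cbind(1, g, C)
    d <- vapply(taus, function(tau) {
      # discrete dosages often give non-unique LP solutions; any vertex of
      # the optimum is acceptable for the integrated difference
      lo <- suppressWarnings(quantreg::rq.fit.br(X, y, tau = tau))$coefficients[2L]
      hi <- suppressWarnings(quantreg::rq.fit.br(X, y, tau = 1 - tau))$coefficients[2L]
      hi - lo
    }, numeric(1))
    if (length(taus) == 1L) return(d * 0.5)
    sum(diff(taus) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
  }

  beta <- numeric(m); se <- rep(NA_real_, m); p <- rep(NA_real_, m)
  estimable <- logical(m)
  boot_idx <- if (n_boot > 0L) {
    matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  } else NULL
  for (j in seq_len(m)) {
    g <- dos[, j]
    if (stats::var(g) < 1e-12) next
    estimable[j] <- TRUE
    beta[j] <- qi_one(g, y, C)
    if (n_boot > 0L) {
      bstat <- vapply(seq_len(n_boot), function(b) {
        idx <- boot_idx[, b]
        qi_one(g[idx], y[idx], if (is.null(C)) NULL else C[idx, , drop = FALSE])
      }, numeric(1))
      se[j] <- stats::sd(bstat)
      p[j] <- 2 * stats::pnorm(-abs(beta[j] / se[j]))
    }
  }
  beta[!estimable] <- NA_real_
  p[!estimable] <- 1
  scan_result(.variant_meta(G, m)$id, .variant_meta(G, m)$effect_allele,
              .variant_meta(G, m)$other_allele, beta, se, p, n,
              "variance_qi", estimable)
}

#' Filter variants on MAF and imputation quality
#'
#' Standard pre-scan variant QC: keep common variants (minor allele
#' frequency above `maf_min`) with imputation info score above `info_min`.
#' Variants with missing info are kept (assumed genotyped).
#'
#' @param geno a [genotype_dataset()].
#' @param maf_min MAF threshold (default 0.01, i.e. MAF > 1%).
#' @param info_min info-score threshold (default 0.5).
#' @return A filtered [genotype_dataset()].
#' @export
filter_variants <- function(geno, maf_min = 0.01, info_min = 0.5) {
  keep <- geno$variants$maf > maf_min &
    (is.na(geno$variants$info) | geno$variants$info > info_min)
  geno[, which(keep)]
}
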