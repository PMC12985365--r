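#' Fit the PGS-by-exposure interaction model
#'
#' Ordinary least squares for
#' `y = b0 + b_PGS * pgs + b_E * e + b_PGSxE * pgs * e + b_C' C + error`.
#' The PGS main effect is always included: omitting it is known to inflate
#' the type I error of the interaction test. Alongside the raw interaction
#' coefficient the fit reports a standardized version in SD(y) per SD(pgs)
#' per SD(e) units, `beta * sd(pgs) * sd(e) / sd(y)`, which is invariant to
#' affine rescaling of the three inputs.
#'
#' @param pgs numeric polygenic score.
#' @param e numeric exposure.
#' @param y numeric outcome.
#' @param covariates optional covariate matrix / data frame (include
#'   exposure-by-genetic-PC products here when genetic PCs are present).
#' @param robust_se use an HC sandwich covariance for inference.
#' @param hc_type sandwich small-sample correction.
#' @param add_e2 add a squared-exposure main-effect term (sensitivity to
#'   nonlinear exposure-outcome relationships).
#' @param add_pgs2 add a squared-PGS term.
#' @param extra_pgs optional second PGS included as a main effect only
#'   (e.g. adding an mPGS main effect when testing an iPGS interaction).
#' @param replace_e optional vector replacing the exposure (e.g. an
#'   exposure polygenic score); the interaction is then `pgs * replace_e`.
#' @return A list of class `interaction_fit`: `coefficients` (matrix with
#'   rows `(Intercept)`, `pgs`, `e`, `pgs:e`, ... and columns estimate, se,
#'   p), `beta_pgsxe_std`, `n`, and `options`.
#' @export
fit_pgsxe <- function(pgs, e, y, covariates = NULL, robust_se = FALSE,
                      hc_type = c("HC0", "HC1"), add_e2 = FALSE,
                      add_pgs2 = FALSE, extra_pgs = NULL, replace_e = NULL) {
  hc_type <- match.arg(hc_type)
  if (!is.null(replace_e)) e <- replace_e
  if (stats::sd(pgs) == 0 || stats::sd(e) == 0) {
    stop("degenerate design: constant pgs or exposure")
  }
  X <- cbind(`(Intercept)` = 1, pgs = pgs, e = e, `pgs:e` = pgs * e)
  if (add_e2) X <- cbind(X, `e2` = e^2)
  if (add_pgs2) X <- cbind(X, `pgs2` = pgs^2)
  if (!is.null(extra_pgs)) X <- cbind(X, `pgs_extra` = extra_pgs)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (is.null(colnames(C))) colnames(C) <- paste0("C", seq_len(ncol(C)))
    X <- cbind(X, C)
  }
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]; yy <- y[keep]
  n <- nrow(X)
  fit <- stats::lm.fit(X, yy)
  if (fit$rank < ncol(X)) stop("degenerate design: rank-deficient model matrix")
  coefs <- fit$coefficients
  res <- fit$residuals
  df <- n - ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  if (robust_se) {
    meat <- crossprod(X * res)
    V <- XtXinv %*% meat %*% XtXinv
    if (hc_type == "HC1") V <- V * n / df
  } else {
    V <- XtXinv * sum(res^2) / df
  }
  se <- sqrt(diag(V))
  pvals <- 2 * stats::pt(-abs(coefs / se), df)
  cm <- cbind(estimate = coefs, se = se, p = pvals)
  rownames(cm) <- colnames(X)
  sd_pgs <- stats::sd(pgs[keep]); sd_e <- stats::sd(e[keep]); sd_y <- stats::sd(yy)
  structure(list(
    coefficients = cm,
    beta_pgsxe_std = unname(cm["pgs:e", "estimate"] * sd_pgs * sd_e / sd_y),
    se_pgsxe_std = unname(cm["pgs:e", "se"] * sd_pgs * sd_e / sd_y),
    p_pgsxe = unname(cm["pgs:e", "p"]),
    n = n,
    options = list(robust_se = robust_se, hc_type = hc_type, add_e2 = add_e2,
                   add_pgs2 = add_pgs2, extra_pgs = !is.null(extra_pgs),
                   replace_e = !is.null(replace_e))
  ), class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("PGS-by-exposure interaction fit (n =", x$n, ")\n")
  stats::printCoefmat(x$coefficients[1:4, , drop = FALSE], P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("standardized beta_PGSxE:", format(x$beta_pgsxe_std, digits = 4),
      "(SD_Y per SD_PGS per SD_E)\n")
  invisible(x)
}

#' Exposure effects stratified by PGS quantile bin
#'
#' Bins samples by PGS quantiles (deciles by default; ties broken by stable
#' sample order) and, within each bin, fits a covariate-adjusted OLS slope
#' of the outcome on the exposure. A fanning pattern of slopes across bins
#' is the visual signature of a PGS-by-exposure interaction.
#'
#' @inheritParams fit_pgsxe
#' @param n_bins number of quantile bins (default 10).
#' @return Data frame: bin, n, slope, se, ci_low, ci_high.
#' @export
decile_stratified_effects <- function(pgs, e, y, covariates = NULL,
                                      n_bins = 10L) {
  n <- length(pgs)
  # stable-order tie-break: rank on (pgs, original index)
  ord <- order(pgs, seq_len(n))
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) / (n / n_bins))
  bin[bin > n_bins] <- n_bins
  p_cov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  out <- data.frame(bin = seq_len(n_bins), n = NA_integer_,
                    slope = NA_real_, se = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_)
  for (b in seq_len(n_bins)) {
    idx <- which(bin == b)
    if (length(idx) < p_cov + 3L) {
      stop("too few samples in PGS bin ", b, " (n = ", length(idx), ")")
    }
    X <- cbind(1, e = e[idx])
    if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates)[idx, , drop = FALSE])
    fit <- stats::lm.fit(X, y[idx])
    df <- length(idx) - ncol(X)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(diag(XtXinv) * sum(fit$residuals^2) / df)[2L]
    out$n[b] <- length(idx)
    out$slope[b] <- fit$coefficients[2L]
    out$se[b] <- se
    out$ci_low[b] <- out$slope[b] - 1.96 * se
    out$ci_high[b] <- out$slope[b] + 1.96 * se
  }
  out
}

#' Contrast exposure effects in the top PGS stratum versus the rest
#'
#' Splits samples at the `1 - top_fraction` PGS quantile and fits
#' covariate-adjusted exposure slopes in each stratum, reporting the
#' percent difference `100 * (slope_top - slope_rest) / slope_rest`.
#'
#' @inheritParams fit_pgsxe
#' @param top_fraction fraction of samples in the top stratum (default 0.1,
#'   the top decile).
#' @return A list: `slope_top`, `slope_rest` (each with `se`),
#'   `percent_difference` (`NA` with `undefined = TRUE` when the reference
#'   slope is indistinguishable from zero).
#' @export
top_fraction_contrast <- function(pgs, e, y, covariates = NULL,
                                  top_fraction = 0.1) {
  n <- length(pgs)
  ord <- order(pgs, seq_len(n))
  n_top <- max(1L, round(n * top_fraction))
  top <- logical(n)
  top[ord[(n - n_top + 1L):n]] <- TRUE
  slope_of <- function(idx) {
    X <- cbind(1, e = e[idx])
    if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates)[idx, , drop = FALSE])
    fit <- stats::lm.fit(X, y[idx])
    df <- length(idx) - ncol(X)
    se <- sqrt(diag(chol2inv(chol(crossprod(X)))) * sum(fit$residuals^2) / df)[2L]
    c(slope = unname(fit$coefficients[2L]), se = unname(se))
  }
  st <- slope_of(which(top)); sr <- slope_of(which(!top))
  undefined <- abs(sr["slope"]) < 2 * sr["se"]
  pct <- if (undefined) NA_real_ else
    100 * (st["slope"] - sr["slope"]) / sr["slope"]
  list(slope_top = st, slope_rest = sr,
       percent_difference = unname(pct), undefined = unname(undefined))
}

#' Summarize a set of replicate p-values into a rejection rate
#'
#' The fraction `f` of p-values below `alpha`, with the binomial standard
#' error `sqrt(f * (1 - f) / P)` and the 95% confidence interval
#' `f +/- 1.96 * SE` truncated to \[0, 1\].
#'
#' @param p_values numeric vector of per-replicate p-values.
#' @param alpha significance level (default 0.05).
#' @return A list of class `rejection_summary`: `f`, `P`, `se`, `ci_low`,
#'   `ci_high`, `alpha`.
#' @export
rejection_summary <- function(p_values, alpha = 0.05) {
  p_values <- p_values[!is.na(p_values)]
  P <- length(p_values)
  if (P < 1L) stop("no p-values supplied")
  f <- mean(p_values < alpha)
  se <- sqrt(f * (1 - f) / P)
  structure(list(f = f, P = P, se = se,
                 ci_low = max(0, f - 1.96 * se),
                 ci_high = min(1, f + 1.96 * se),
                 alpha = alpha),
            class = "rejection_summary")
}

#' @export
print.rejection_summary <- function(x, ...) {
  cat(sprintf("rejection rate %.4f (95%% CI %.4f-%.4f) over %d replicates at alpha = %g\n",
              x$f, x$ci_low, x$ci_high, x$P, x$alpha))
  invisible(x)
}

#' Clean a biomarker column
#'
#' Two cleaning conventions are supported. `mode = "ukb"`: optional log
#' transform, then values more than 5 standard deviations from the mean are
#' set to missing. `mode = "aou"`: repeated measures are averaged within
#' person, negative values are removed, zeros are imputed with half the
#' minimum non-zero value, and values more than 5 interquartile ranges from
#' the median are removed.
#'
#' @param values numeric vector of biomarker measurements.
#' @param mode `"ukb"` or `"aou"`.
#' @param log_transform log-transform first (ukb mode; applied to positive
#'   values).
#' @param person_id grouping vector for within-person averaging (aou mode);
#'   defaults to one measurement per person.
#' @return Cleaned numeric vector (ukb mode: same length, outliers `NA`;
#'   aou mode: one value per person, named by person, outliers dropped).
#' @export
preprocess_biomarker <- function(values, mode = c("ukb", "aou"),
                                 log_transform = FALSE, person_id = NULL) {
  mode <- match.arg(mode)
  if (all(is.na(values))) stop("all values missing")
  if (mode == "ukb") {
    x <- values
    if (log_transform) x <- log(x)
    mu <- mean(x, na.rm = TRUE); sdv <- stats::sd(x, na.rm = TRUE)
    if (sdv > 0) x[!is.na(x) & abs(x - mu) > 5 * sdv] <- NA_real_
    return(x)
  }
  if (is.null(person_id)) person_id <- seq_along(values)
  x <- tapply(values, person_id, mean, na.rm = TRUE)
  x <- stats::setNames(as.numeric(x), names(x))
  x <- x[!is.na(x) & x >= 0]
  nz <- x[x > 0]
  if (length(nz) > 0L) x[x == 0] <- min(nz) / 2
  med <- stats::median(x); iqr <- stats::IQR(x)
  if (iqr > 0) x <- x[abs(x - med) <= 5 * iqr]
  x
}

.statin_divisors <- c(total_cholesterol = 0.749, ldl_c = 0.684, apob = 0.719)

#' Adjust lipid biomarkers for statin use
#'
#' In statin users, total cholesterol, LDL cholesterol and apolipoprotein B
#' are divided by empirically estimated adjustment factors (0.749, 0.684
#' and 0.719 respectively) to approximate the untreated value; non-users
#' are unchanged.
#'
#' @param value numeric biomarker value(s).
#' @param biomarker one of `"total_cholesterol"`, `"ldl_c"`, `"apob"`.
#' @param statin_user logical flag(s), recycled against `value`.
#' @return Adjusted values.
#' @export
statin_adjust <- function(value, biomarker, statin_user) {
  if (!biomarker %in% names(.statin_divisors)) {
    stop("no statin adjustment defined for biomarker: ", biomarker)
  }
  ifelse(statin_user, value / .statin_divisors[[biomarker]], value)
}

#' Clean a BMI exposure column
#'
#' Averages repeated measures within person, removes values more than 5
#' interquartile ranges from the median, then removes values below 10
#' kg/m^2 (physiologically implausible), and optionally mean-centers the
#' result for interaction analyses.
#'
#' @param values numeric BMI measurements (kg/m^2).
#' @param person_id grouping vector for within-person averaging.
#' @param center mean-center the cleaned values.
#' @return Cleaned (named, one per person) numeric vector.
#' @export
preprocess_bmi <- function(values, person_id = NULL, center = FALSE) {
  if (is.null(person_id)) person_id <- seq_along(values)
  x <- tapply(values, person_id, mean, na.rm = TRUE)
  x <- stats::setNames(as.numeric(x), names(x))
  x <- x[!is.na(x)]
  med <- stats::median(x); iqr <- stats::IQR(x)
  if (iqr > 0) x <- x[abs(x - med) <= 5 * iqr]
  x <- x[x >= 10]
  if (center) x <- x - mean(x)
  x
}

#' Effective number of independent outcomes
#'
#' Eigenvalue-based reduction of a set of correlated outcomes to an
#' effective test count, for Bonferroni correction: each eigenvalue of the
#' outcome correlation matrix contributes `1` if it is at least 1 plus its
#' fractional part otherwise (Li-and-Ji-style). Independent outcomes give
#' the full count; perfectly correlated outcomes give 1.
#'
#' @param outcomes numeric matrix / data frame, one column per outcome.
#' @return Effective test count (numeric scalar); attribute `eigenvalues`
#'   carries the spectrum.
#' @export
effective_tests <- function(outcomes) {
  X <- as.matrix(outcomes)
  if (ncol(X) < 2L) stop("need at least two outcomes")
  cc <- stats::complete.cases(X)
  if (sum(cc) < 3L) stop("too few complete cases to estimate correlations")
  R <- stats::cor(X[cc, , drop = FALSE])
  if (any(!is.finite(R))) stop("correlation matrix not estimable (constant outcome?)")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  ev <- round(ev, 10)  # guard floor() against numerical noise at integers
  meff <- sum(ifelse(ev >= 1, 1, 0) + (ev - floor(ev)))
  attr(meff, "eigenvalues") <- ev
  meff
}
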