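test_that("the PGSxE fit matches the normal-equations oracle to 1e-8", {
  set.seed(61)
  n <- 500
  pgs <- rnorm(n); e <- rnorm(n); y <- rnorm(n)
  C <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  fit <- fit_pgsxe(pgs, e, y, covariates = C)
  o <- ols_oracle(cbind(pgs = pgs, e = e, pe = pgs * e, C), y, col = 3)
  expect_equal(fit$coefficients["pgs:e", "estimate"], o$beta, tolerance = 1e-8)
  expect_equal(fit$coefficients["pgs:e", "se"], o$se, tolerance = 1e-8)
  expect_equal(fit$p_pgsxe, o$p, tolerance = 1e-8)

  # robust covariance agrees with the sandwich package
  fr <- fit_pgsxe(pgs, e, y, covariates = C, robust_se = TRUE)
  f <- lm(y ~ pgs + e + I(pgs * e) + C)
  expect_equal(fr$coefficients["pgs:e", "se"],
               sqrt(sandwich::vcovHC(f, type = "HC0")[4, 4]),
               tolerance = 1e-8)
})

test_that("a planted standardized interaction is recovered within 2 SE", {
  set.seed(62)
  n <- 10000
  pgs <- rnorm(n); e <- rnorm(n)
  y <- 0.2 * pgs * e + rnorm(n)
  fit <- fit_pgsxe(pgs, e, y)
  expect_lt(abs(fit$beta_pgsxe_std - 0.2), 2 * fit$se_pgsxe_std)
})

test_that("the standardized interaction estimate is scale-invariant", {
  set.seed(63)
  n <- 1000
  pgs <- rnorm(n); e <- rnorm(n); y <- 0.1 * pgs * e + rnorm(n)
  base <- fit_pgsxe(pgs, e, y)
  resc <- fit_pgsxe(pgs * 10, e, y)
  expect_equal(resc$beta_pgsxe_std, base$beta_pgsxe_std, tolerance = 1e-10)
  expect_equal(resc$coefficients["pgs:e", "estimate"],
               base$coefficients["pgs:e", "estimate"] / 10, tolerance = 1e-10)
  # invariance extends to e and y rescaling
  resc2 <- fit_pgsxe(pgs, e * 3, y * 2)
  expect_equal(resc2$beta_pgsxe_std, base$beta_pgsxe_std, tolerance = 1e-10)
  expect_error(fit_pgsxe(rep(1, n), e, y), "degenerate")
})

test_that("permuted PGS nulls reject at the nominal rate", {
  set.seed(64)
  n <- 800; reps <- 200
  pv <- vapply(seq_len(reps), function(i) {
    pgs <- rnorm(n); e <- rnorm(n)
    y <- 0.3 * pgs + 0.3 * e + rnorm(n)
    fit_pgsxe(sample(pgs), e, y)$p_pgsxe
  }, numeric(1))
  f <- mean(pv < 0.05)
  expect_lt(abs(f - 0.05), 1.96 * sqrt(0.05 * 0.95 / reps) + 1e-9)
})

test_that("sensitivity options add the documented model terms", {
  set.seed(65)
  n <- 300
  pgs <- rnorm(n); e <- rnorm(n); y <- rnorm(n)
  f1 <- fit_pgsxe(pgs, e, y, add_e2 = TRUE, add_pgs2 = TRUE)
  expect_true(all(c("e2", "pgs2") %in% rownames(f1$coefficients)))
  f2 <- fit_pgsxe(pgs, e, y, extra_pgs = rnorm(n))
  expect_true("pgs_extra" %in% rownames(f2$coefficients))
  e2 <- rnorm(n)
  f3 <- fit_pgsxe(pgs, e, y, replace_e = e2)
  o <- ols_oracle(cbind(pgs, e2, pgs * e2), y, col = 3)
  expect_equal(f3$coefficients["pgs:e", "estimate"], o$beta, tolerance = 1e-10)
})

test_that("decile-stratified slopes fan out under a planted interaction", {
  set.seed(66)
  n <- 5000
  pgs <- rnorm(n); e <- rnorm(n)
  y <- 0.2 * e + 0.3 * pgs * e + rnorm(n)
  tab <- decile_stratified_effects(pgs, e, y)
  expect_equal(nrow(tab), 10L)
  expect_equal(sum(tab$n), n)
  expect_gt(tab$slope[10], tab$slope[1])
  # monotone trend in expectation: top decile slope ~ 0.2 + 0.3*E[pgs|top]
  expect_gt(tab$slope[10], 0.2)
  expect_lt(tab$slope[1], 0.2)

  # single bin degenerates to the overall adjusted slope
  one <- decile_stratified_effects(pgs, e, y, n_bins = 1L)
  o <- ols_oracle(cbind(e), y, col = 1)
  expect_equal(one$slope[1], o$beta, tolerance = 1e-10)

  expect_error(decile_stratified_effects(rnorm(15), rnorm(15), rnorm(15),
                                         covariates = matrix(rnorm(15)),
                                         n_bins = 10),
               "bin")
})

test_that("flat slopes arise without interaction and the top contrast is near zero", {
  set.seed(67)
  n <- 6000
  pgs <- rnorm(n); e <- rnorm(n)
  y <- 0.3 * e + rnorm(n)
  tab <- decile_stratified_effects(pgs, e, y)
  # joint z-test of slope differences from the pooled mean: nominal behavior
  z <- (tab$slope - mean(tab$slope)) / tab$se
  expect_lt(max(abs(z)), 4)

  tc <- top_fraction_contrast(pgs, e, y)
  expect_false(tc$undefined)
  expect_lt(abs(tc$percent_difference), 35)
})

test_that("top-fraction contrast matches the planted analytic expectation", {
  set.seed(68)
  n <- 50000
  pgs <- rnorm(n); e <- rnorm(n)
  beta_e <- 0.3; beta_int <- 0.1
  y <- beta_e * e + beta_int * pgs * e + rnorm(n)
  tc <- top_fraction_contrast(pgs, e, y, top_fraction = 0.1)
  # slope in a stratum is beta_e + beta_int * E[pgs | stratum];
  # for the top decile of a standard normal E[pgs] = dnorm(q90)/0.1
  q90 <- qnorm(0.9)
  m_top <- dnorm(q90) / 0.1
  m_rest <- -dnorm(q90) / 0.9
  expected <- 100 * (beta_int * (m_top - m_rest)) / (beta_e + beta_int * m_rest)
  expect_lt(abs(tc$percent_difference - expected), 12)

  # half split is the median split
  tc5 <- top_fraction_contrast(pgs, e, y, top_fraction = 0.5)
  expect_gt(tc5$slope_top["slope"], tc5$slope_rest["slope"])
})

test_that("rejection summary reproduces the closed-form SE and CI arithmetic", {
  rs <- rejection_summary(rep(1, 10))
  expect_equal(rs$f, 0)
  expect_equal(rs$se, 0)

  # f = 0.05 over 5000 replicates
  p <- c(rep(0.01, 250), rep(0.5, 4750))
  rs2 <- rejection_summary(p)
  expect_equal(rs2$f, 0.05)
  expect_equal(rs2$se, sqrt(0.05 * 0.95 / 5000))
  expect_equal(rs2$se, 0.00308, tolerance = 1e-3)

  # f = 0.5 over 100 replicates: CI (0.402, 0.598)
  rs3 <- rejection_summary(c(rep(0.01, 50), rep(0.5, 50)))
  expect_equal(rs3$ci_low, 0.5 - 1.96 * sqrt(0.25 / 100))
  expect_equal(rs3$ci_high, 0.5 + 1.96 * sqrt(0.25 / 100))
  expect_equal(round(c(rs3$ci_low, rs3$ci_high), 3), c(0.402, 0.598))

  expect_error(rejection_summary(numeric(0)), "no p-values")
})

test_that("biomarker cleaning applies the 5-SD, zero-imputation and 5-IQR rules", {
  # ukb mode: a 10-SD outlier is blanked
  set.seed(69)
  x <- rnorm(1000)
  x[1] <- mean(x[-1]) + 10 * sd(x[-1])
  out <- preprocess_biomarker(x, mode = "ukb")
  expect_true(is.na(out[1]))
  expect_equal(out[-1], x[-1])

  # clean values pass through unchanged
  expect_equal(preprocess_biomarker(x[-1], mode = "ukb"), x[-1])

  # log transform precedes the outlier rule
  y <- exp(rnorm(100))
  expect_equal(preprocess_biomarker(y, mode = "ukb", log_transform = TRUE),
               log(y))

  # aou mode: zeros imputed with half of minimum non-zero
  out2 <- preprocess_biomarker(c(0, 2, 4), mode = "aou")
  expect_equal(unname(sort(out2)), c(1, 2, 4))
  # negatives removed; repeats averaged within person
  out3 <- preprocess_biomarker(c(-1, 10, 12), mode = "aou",
                               person_id = c("a", "b", "b"))
  expect_equal(unname(out3), 11)
  expect_error(preprocess_biomarker(c(NA, NA)), "missing")
})

test_that("statin adjustment divides by the published factors for users only", {
  expect_equal(statin_adjust(6.0, "total_cholesterol", TRUE), 6.0 / 0.749)
  expect_equal(statin_adjust(3.0, "ldl_c", FALSE), 3.0)
  expect_equal(statin_adjust(1.0, "apob", TRUE), 1.0 / 0.719)
  expect_equal(statin_adjust(1.0, "apob", TRUE), 1.391, tolerance = 1e-3)
  expect_equal(statin_adjust(6.0, "total_cholesterol", TRUE), 8.011,
               tolerance = 1e-3)
  expect_error(statin_adjust(5, "hdl", TRUE), "hdl")
})

test_that("BMI cleaning averages repeats, drops 5-IQR outliers then values < 10", {
  # {9.5, 25}: the 5-IQR band is wide with two values, so only the < 10
  # rule fires
  expect_equal(unname(preprocess_bmi(c(9.5, 25))), 25)
  # repeated measures averaged within person
  expect_equal(unname(preprocess_bmi(c(24, 26), person_id = c("a", "a"))), 25)
  # an extreme value among many tight inliers falls to the 5-IQR rule
  vals <- c(24, 26, 25, 24.5, 25.5, 24.8, 25.2, 26.5, 23.5, 200)
  out <- preprocess_bmi(vals)
  expect_equal(length(out), 9L)
  expect_false(200 %in% out)
  centered <- preprocess_bmi(c(20, 30), center = TRUE)
  expect_equal(unname(centered), c(-5, 5))
})

test_that("effective test counts hit the independence and degeneracy limits", {
  set.seed(70)
  X <- matrix(rnorm(20000 * 20), ncol = 20)
  expect_equal(as.numeric(effective_tests(X)), 20, tolerance = 0.5)

  base <- rnorm(500)
  Xc <- matrix(rep(base, 6), ncol = 6)
  expect_equal(as.numeric(effective_tests(Xc)), 1)

  # two exactly-orthogonal perfectly-correlated blocks of 3:
  # eigenvalues {3, 3, 0, ...}
  b1 <- rnorm(500)
  b2 <- residuals(lm(rnorm(500) ~ b1))
  Xb <- cbind(b1, b1, b1, b2, b2, b2)
  expect_equal(as.numeric(effective_tests(Xb)), 2)
  ev <- attr(effective_tests(Xb), "eigenvalues")
  expect_equal(ev[1:2], c(3, 3), tolerance = 1e-8)

  expect_error(effective_tests(matrix(rnorm(10), ncol = 1)), "two outcomes")
})
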