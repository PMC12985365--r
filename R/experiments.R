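#' Run one simulation scenario end to end
#'
#' Implements the replicate protocol of the simulation study. A single
#' genotype dataset is generated per scenario; then, per replicate: an
#' exposure (with optional gene-environment correlation, measurement error,
#' and gamma marginal) and a phenotype (with the scenario's variance
#' components) are simulated; samples are split 70/30 into training and
#' testing; marginal, interaction and deviation-regression scans are run in
#' training; scan estimates are converted to PGS weights by the simple
#' p < 0.05 thresholding rule (clumping is unnecessary for independent
#' variants); and each PGS is tested for PGS-by-exposure interaction in the
#' testing subset. Rejection rates at the scenario's alpha summarize type I
#' error (when `sigma2_GxE = 0`) or power.
#'
#' Analysis always uses the measured exposure; the phenotype is generated
#' from the true exposure, so measurement error attenuates the analyst's
#' view only. The variance scan never sees the exposure.
#'
#' Per-replicate randomness derives from the scenario seed through a
#' pre-drawn seed sequence, so results are bit-reproducible and replicates
#' are independent of execution order.
#'
#' @param scenario a [simulation_scenario()].
#' @param keep_pvalues retain the per-replicate p-value matrix (default
#'   `TRUE`).
#' @return A list of class `scenario_result`: `scenario`, `summaries` (one
#'   [rejection_summary()] per PGS type: mPGS, iPGS, vPGS_drm, and
#'   vPGS_qi when `include_qi`), and `p_values` (replicates x types).
#' @export
run_scenario <- function(scenario, keep_pvalues = TRUE) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  geno <- simulate_genotypes(scenario$n_samples, scenario$n_variants,
                             scenario$maf_range, seed = scenario$seed)
  dos <- geno$dosages
  n <- nrow(dos)
  set.seed(scenario$seed)
  rep_seeds <- sample.int(2147483646L, scenario$n_replicates)
  types <- c("mPGS", "iPGS", "vPGS_drm")
  if (scenario$include_qi) types <- c(types, "vPGS_qi")
  P <- scenario$n_replicates
  pmat <- matrix(NA_real_, P, length(types), dimnames = list(NULL, types))
  n_train <- round(n * scenario$train_fraction)

  for (r in seq_len(P)) {
    set.seed(rep_seeds[r])
    panel <- simulate_exposure(dos, scenario$sigma2_GE, scenario$icc_E,
                               scenario$exposure_dist, scenario$gamma_shape,
                               scenario$gamma_scale)
    phen <- simulate_phenotype(dos, panel$e_true, scenario)
    idx <- sample.int(n)
    tr <- idx[seq_len(n_train)]
    te <- idx[(n_train + 1L):n]
    G_tr <- dos[tr, , drop = FALSE]
    y_tr <- phen$y[tr]
    scans <- list(
      mPGS = marginal_scan(G_tr, y_tr),
      iPGS = interaction_scan(G_tr, y_tr, panel$e_measured[tr],
                              center_exposure = scenario$center_products),
      vPGS_drm = drm_scan(G_tr, y_tr)
    )
    if (scenario$include_qi) {
      scans$vPGS_qi <- quantile_integral_scan(G_tr, y_tr, n_boot = 100L)
    }
    for (ty in types) {
      wt <- threshold_weights(scans[[ty]], 0.05, variants = geno$variants)
      if (nrow(wt) == 0L) { pmat[r, ty] <- 1; next }
      pgs <- as.numeric(dos[te, wt$id, drop = FALSE] %*% wt$weight)
      if (stats::sd(pgs) == 0) { pmat[r, ty] <- 1; next }
      fit <- fit_pgsxe(pgs, panel$e_measured[te], phen$y[te])
      pmat[r, ty] <- fit$p_pgsxe
    }
  }
  summaries <- lapply(as.data.frame(pmat), rejection_summary,
                      alpha = scenario$alpha)
  structure(list(scenario = scenario, summaries = summaries,
                 p_values = if (keep_pvalues) pmat else NULL),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("scenario: N=%d M=%d s2G=%g s2E=%g s2GxE=%g s2GE=%g ICC=%g dist=%s P=%d\n",
              s$n_samples, s$n_variants, s$sigma2_G, s$sigma2_E, s$sigma2_GxE,
              s$sigma2_GE, s$icc_E, s$exposure_dist, s$n_replicates))
  for (ty in names(x$summaries)) {
    z <- x$summaries[[ty]]
    cat(sprintf("  %-8s rejection %.4f (%.4f-%.4f)\n", ty, z$f, z$ci_low, z$ci_high))
  }
  invisible(x)
}

#' Run a grid of simulation scenarios
#'
#' Runs each scenario in turn; failures are caught and logged with their
#' parameters while the remaining scenarios continue.
#'
#' @param scenarios list of [simulation_scenario()] objects (optionally
#'   named).
#' @return A list of class `scenario_grid_result`: `results` (per-scenario
#'   `scenario_result` or `NULL` on failure), `table` (tidy data frame, one
#'   row per scenario x PGS type), `failures` (messages).
#' @export
run_scenario_grid <- function(scenarios) {
  if (is.null(names(scenarios))) {
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  }
  results <- vector("list", length(scenarios))
  names(results) <- names(scenarios)
  failures <- character(0)
  rows <- list()
  for (nm in names(scenarios)) {
    res <- tryCatch(run_scenario(scenarios[[nm]], keep_pvalues = FALSE),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[nm] <- conditionMessage(res)
      next
    }
    results[[nm]] <- res
    s <- scenarios[[nm]]
    for (ty in names(res$summaries)) {
      z <- res$summaries[[ty]]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = nm, pgs_type = ty, sigma2_GxE = s$sigma2_GxE,
        sigma2_G = s$sigma2_G, sigma2_E = s$sigma2_E,
        sigma2_GE = s$sigma2_GE, icc_E = s$icc_E,
        exposure_dist = s$exposure_dist, nonlinear_E = s$nonlinear_E,
        rejection = z$f, se = z$se, ci_low = z$ci_low, ci_high = z$ci_high,
        P = z$P, stringsAsFactors = FALSE)
    }
  }
  structure(list(results = results,
                 table = do.call(rbind, rows),
                 failures = failures),
            class = "scenario_grid_result")
}

#' Plot rejection rates from a scenario grid
#'
#' Power / type-I-error plot with 95% confidence-interval error bars, one
#' line per PGS type, faceted by exposure distribution and measurement
#' error when those vary. Requires ggplot2.
#'
#' @param grid_result a [run_scenario_grid()] result.
#' @param x variable mapped to the x axis (default `"sigma2_GxE"`).
#' @return A ggplot object.
#' @export
plot_scenario_grid <- function(grid_result, x = "sigma2_GxE") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  tab <- grid_result$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data[[x]], y = .data$rejection,
                                    colour = .data$pgs_type)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.001)) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0,
                           position = ggplot2::position_dodge(width = 0.001)) +
    ggplot2::facet_grid(icc_E ~ exposure_dist, labeller = ggplot2::label_both) +
    ggplot2::labs(x = x, y = "PGSxE rejection rate", colour = "PGS type") +
    ggplot2::theme_bw()
}

#' Run the full biobank PGS-by-exposure pipeline
#'
#' End-to-end protocol on tabular biobank-style data: variant QC (MAF,
#' imputation info, strand-ambiguous alleles, duplicated IDs), a 70/10/20
#' training/optimization/testing split, three genome-wide scans in the
#' training subset per outcome, pruning-and-thresholding score construction
#' over a p-value grid with LD clumping, threshold selection on the
#' optimization subset by maximal interaction significance, a final
#' PGS-by-exposure fit in the held-out testing subset, and a Bonferroni
#' level from the effective number of correlated outcomes.
#'
#' @param geno a [genotype_dataset()].
#' @param samples data frame with `sample_id`, the exposure, covariates and
#'   outcome columns named in `config`.
#' @param config list with elements: `outcomes` (character), `exposure`
#'   (column name), `covariates` (character), `exposure_products`
#'   (covariate names to interact with the exposure, e.g. genetic PCs),
#'   and optionally `grid`, `r2_cut` (0.1), `radius_kb` (250), `maf_min`
#'   (0.01), `info_min` (0.5), `alpha` (0.05), `robust_se` (FALSE),
#'   `vgwas_method` ("drm" or "qi"), `pgs_types` (subset of
#'   `c("mPGS", "iPGS", "vPGS")`), `seed` (1).
#' @return A list of class `pipeline_result`: `fits` (per outcome, per PGS
#'   type: threshold, trace, weights, testing-subset [fit_pgsxe()] result),
#'   `split`, `alpha_bonferroni`, `n_effective_tests`, `variants_used`.
#' @export
run_biobank_pipeline <- function(geno, samples, config) {
  defaults <- list(grid = default_threshold_grid(), r2_cut = 0.1,
                   radius_kb = 250, maf_min = 0.01, info_min = 0.5,
                   alpha = 0.05, robust_se = FALSE, vgwas_method = "drm",
                   pgs_types = c("mPGS", "iPGS", "vPGS"),
                   exposure_products = character(), covariates = character(),
                   seed = 1L)
  config <- utils::modifyList(defaults, config)
  for (field in c("outcomes", "exposure")) {
    if (is.null(config[[field]])) stop("config error: missing '", field, "'")
  }
  needed <- c(config$exposure, config$covariates, config$outcomes)
  absent <- setdiff(needed, names(samples))
  if (length(absent) > 0L) {
    stop("config error: column(s) not in sample table: ",
         paste(absent, collapse = ", "))
  }
  samples <- samples[match(geno$sample_ids, samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop("sample table does not cover all genotyped samples")

  # variant QC
  geno_f <- filter_variants(geno, config$maf_min, config$info_min)
  keep_meta <- exclude_ambiguous_and_duplicates(geno_f$variants)
  geno_f <- geno_f[, match(keep_meta$id, geno_f$variants$id)]

  split <- split_samples(geno$sample_ids, c(0.7, 0.1, 0.2), seed = config$seed)
  subsets <- split(split$sample_id, split$subset)
  stopifnot(!any(duplicated(unlist(subsets))))  # leakage guard
  idx <- lapply(subsets, match, geno$sample_ids)

  e_all <- samples[[config$exposure]]
  C_all <- if (length(config$covariates) > 0) {
    as.matrix(samples[, config$covariates, drop = FALSE])
  } else NULL
  # exposure-by-covariate products for interaction scans and PGSxE fits
  ep_cols <- config$exposure_products
  make_fit_covs <- function(rows) {
    C <- if (is.null(C_all)) NULL else C_all[rows, , drop = FALSE]
    if (length(ep_cols) > 0) {
      ep <- C_all[rows, ep_cols, drop = FALSE] *
        (e_all[rows] - mean(e_all[rows]))
      colnames(ep) <- paste0("e_x_", ep_cols)
      C <- cbind(C, ep)
    }
    C
  }

  tr <- idx$training; op <- idx$optimization; te <- idx$testing
  geno_tr <- geno_f[tr, ]; geno_op <- geno_f[op, ]; geno_te <- geno_f[te, ]

  fits <- list()
  for (outcome in config$outcomes) {
    y <- samples[[outcome]]
    C_tr <- if (is.null(C_all)) NULL else C_all[tr, , drop = FALSE]
    scans <- list()
    if ("mPGS" %in% config$pgs_types) {
      scans$mPGS <- marginal_scan(geno_tr, y[tr], covariates = C_tr)
    }
    if ("iPGS" %in% config$pgs_types) {
      scans$iPGS <- interaction_scan(
        geno_tr, y[tr], e_all[tr], covariates = C_tr,
        robust_se = config$robust_se, center_exposure = TRUE,
        exposure_products = if (length(ep_cols) > 0) ep_cols else NULL)
    }
    if ("vPGS" %in% config$pgs_types) {
      scans$vPGS <- if (config$vgwas_method == "qi") {
        quantile_integral_scan(geno_tr, y[tr], covariates = C_tr)
      } else {
        drm_scan(geno_tr, y[tr], covariates = C_tr)
      }
    }
    fits[[outcome]] <- list()
    for (ty in names(scans)) {
      cell <- tryCatch({
        opt <- optimize_threshold(
          scans[[ty]], grid = config$grid,
          geno_opt = geno_op, y_opt = y[op], e_opt = e_all[op],
          covariates = make_fit_covs(op),
          ld_ref = geno_tr, variants = geno_f$variants,
          robust_se = config$robust_se
        )
        pgs_te <- compute_pgs(geno_te, opt$weights)
        final <- fit_pgsxe(pgs_te, e_all[te], y[te],
                           covariates = make_fit_covs(te),
                           robust_se = config$robust_se)
        list(threshold = opt$threshold, trace = opt$trace,
             weights = opt$weights, fit = final)
      }, error = function(e) list(fit = NULL, error = conditionMessage(e)))
      fits[[outcome]][[ty]] <- cell
    }
  }
  n_eff <- if (length(config$outcomes) >= 2L) {
    effective_tests(samples[tr, config$outcomes, drop = FALSE])
  } else 1
  structure(list(fits = fits, split = split,
                 n_effective_tests = as.numeric(n_eff),
                 alpha_bonferroni = config$alpha / as.numeric(n_eff),
                 variants_used = geno_f$variants$id,
                 config = config),
            class = "pipeline_result")
}
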