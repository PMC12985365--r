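#' Default p-value threshold grid for pruning-and-thresholding
#'
#' The grid runs from 0.05 down to 5e-8 (the conventional genome-wide
#' significance level), alternating 5x10^-k and 1x10^-k anchors.
#'
#' @return Strictly decreasing numeric vector of cutoffs in (0, 1).
#' @export
default_threshold_grid <- function() {
  c(5e-2, 1e-2, 5e-3, 1e-3, 5e-4, 1e-4, 5e-5, 1e-5, 5e-6, 1e-6, 5e-7,
    1e-7, 5e-8)
}

#' Convert scan results to PGS weights by p-value thresholding
#'
#' Variants with scan p-value strictly below the cutoff keep their
#' regression estimate as the PGS weight; all other weights are zero (and
#' therefore omitted from the table). Non-estimable rows carry the sentinel
#' p = 1 and can never be selected.
#'
#' @param scan a [scan_result()].
#' @param p_cut p-value cutoff (strict inequality).
#' @param variants optional variant metadata (data frame with id, chrom,
#'   pos) used to fill positional columns; otherwise `NA`.
#' @return A [weight_table()].
#' @export
threshold_weights <- function(scan, p_cut, variants = NULL) {
  keep <- !is.na(scan$p) & scan$p < p_cut & scan$estimable
  sel <- scan[keep, , drop = FALSE]
  chrom <- rep(NA_character_, nrow(sel)); pos <- rep(NA_integer_, nrow(sel))
  if (!is.null(variants)) {
    idx <- match(sel$id, variants$id)
    chrom <- variants$chrom[idx]
    pos <- variants$pos[idx]
  }
  weight_table(sel$id, chrom, pos, sel$effect_allele, sel$other_allele,
               sel$beta, sel$p, p_cut)
}

#' Drop strand-ambiguous variants and duplicated IDs
#'
#' Removes variants whose allele pair is strand-ambiguous ({A,T} or {C,G} —
#' indistinguishable between strands) and every copy of any duplicated
#' variant ID.
#'
#' @param variants data frame with columns `id`, `effect_allele`,
#'   `other_allele`.
#' @return The filtered data frame (attribute `n_removed` records the drop
#'   count).
#' @export
exclude_ambiguous_and_duplicates <- function(variants) {
  ea <- toupper(variants$effect_allele)
  oa <- toupper(variants$other_allele)
  ambiguous <- (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
  dup <- variants$id %in% variants$id[duplicated(variants$id)]
  keep <- !ambiguous & !dup
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Greedy LD clumping of scan results
#'
#' Repeatedly selects the most significant unclaimed variant as an index
#' variant and discards unclaimed variants on the same chromosome within
#' `radius_kb` whose squared dosage correlation with the index exceeds
#' `r2_cut`. Returns index-variant IDs in selection order.
#'
#' @param scan a [scan_result()] (non-estimable rows are ignored).
#' @param ld_ref a [genotype_dataset()] providing dosages and positions for
#'   every scan variant (typically a held-out LD reference subset).
#' @param r2_cut squared-correlation threshold (default 0.1).
#' @param radius_kb clumping radius in kilobases (default 250).
#' @return Character vector of selected variant IDs.
#' @export
clump <- function(scan, ld_ref, r2_cut = 0.1, radius_kb = 250) {
  usable <- scan[scan$estimable, , drop = FALSE]
  idx <- match(usable$id, ld_ref$variants$id)
  if (anyNA(idx)) {
    stop("variants absent from LD reference: ",
         paste(usable$id[is.na(idx)], collapse = ", "))
  }
  meta <- ld_ref$variants[idx, ]
  dos <- ld_ref$dosages[, idx, drop = FALSE]
  radius <- radius_kb * 1000
  ord <- order(usable$p)
  claimed <- rep(FALSE, nrow(usable))
  selected <- character(0)
  for (i in ord) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    selected <- c(selected, usable$id[i])
    near <- which(!claimed & meta$chrom == meta$chrom[i] &
                    abs(meta$pos - meta$pos[i]) <= radius)
    if (length(near) > 0L) {
      r <- suppressWarnings(stats::cor(dos[, i], dos[, near, drop = FALSE]))
      r[is.na(r)] <- 0
      claimed[near[r[1, ]^2 > r2_cut]] <- TRUE
    }
  }
  selected
}

#' Compute polygenic scores as weighted dosage sums
#'
#' `score_i = sum_j w_j * dosage_ij` over the weight-table variants. Every
#' weight-table variant must be present in the genotype data with matching
#' alleles in the same orientation; run [harmonize_weights()] first when
#' scoring a different dataset.
#'
#' @param geno a [genotype_dataset()].
#' @param weights a [weight_table()].
#' @return Numeric vector of per-sample scores (all zero for an empty
#'   weight table).
#' @export
compute_pgs <- function(geno, weights) {
  if (nrow(weights) == 0L) {
    return(stats::setNames(rep(0, length(geno$sample_ids)), geno$sample_ids))
  }
  idx <- match(weights$id, geno$variants$id)
  if (anyNA(idx)) {
    stop("weight variants missing from genotypes: ",
         paste(weights$id[is.na(idx)], collapse = ", "))
  }
  tgt <- geno$variants[idx, ]
  same <- toupper(tgt$effect_allele) == weights$effect_allele &
    toupper(tgt$other_allele) == weights$other_allele
  if (!all(same)) {
    stop("allele mismatch (unharmonized weights) for: ",
         paste(weights$id[!same], collapse = ", "))
  }
  scores <- as.numeric(geno$dosages[, idx, drop = FALSE] %*% weights$weight)
  stats::setNames(scores, geno$sample_ids)
}

#' Harmonize PGS weights to a target variant panel
#'
#' Matches weight-table variants to the target panel by chromosomal
#' location (chrom, pos, unordered allele pair). Variants found with the
#' same allele orientation keep their weight; variants found with reversed
#' effect/other alleles have their weight sign-flipped and alleles swapped
#' to the target orientation; variants absent from the target, or present
#' with a different allele pair, are dropped. If more than `max_variants`
#' rows survive, only the `max_variants` with the smallest source p-values
#' are kept.
#'
#' @param weights a [weight_table()].
#' @param target variant metadata data frame (id, chrom, pos,
#'   effect_allele, other_allele).
#' @param max_variants cap on surviving variants (default 5000).
#' @return A [weight_table()] in target orientation; attribute `n_dropped`
#'   reports how many rows were dropped for non-matching.
#' @export
harmonize_weights <- function(weights, target, max_variants = 5000L) {
  if (nrow(weights) == 0L) return(weights)
  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  tk <- key(target$chrom, target$pos)
  idx <- match(key(weights$chrom, weights$pos), tk)
  found <- !is.na(idx)
  w_ea <- weights$effect_allele; w_oa <- weights$other_allele
  t_ea <- toupper(target$effect_allele[idx]); t_oa <- toupper(target$other_allele[idx])
  same <- found & t_ea == w_ea & t_oa == w_oa
  flip <- found & t_ea == w_oa & t_oa == w_ea
  keep <- same | flip
  out <- weights[keep, , drop = FALSE]
  midx <- idx[keep]
  out$id <- target$id[midx]  # adopt target IDs (location is the join key)
  out$effect_allele <- toupper(target$effect_allele[midx])
  out$other_allele <- toupper(target$other_allele[midx])
  out$weight <- ifelse(flip[keep], -out$weight, out$weight)
  n_dropped <- nrow(weights) - nrow(out)
  if (nrow(out) > max_variants) {
    out <- out[order(out$p)[seq_len(max_variants)], , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("weight_table", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Select the p-value threshold maximizing interaction significance
#'
#' For each cutoff in the grid: clump the scan against the LD reference,
#' keep clumped variants passing the cutoff, score the optimization
#' subset, and fit the PGS-by-exposure interaction model. The chosen cutoff
#' minimizes the interaction p-value; ties go to the more stringent cutoff
#' (fewer variants). Cutoffs yielding an empty score are recorded with
#' `NA` and skipped.
#'
#' @param scan a [scan_result()] from the training subset.
#' @param grid p-value cutoffs (default [default_threshold_grid()]).
#' @param geno_opt [genotype_dataset()] for the optimization subset.
#' @param y_opt,e_opt outcome and exposure in the optimization subset.
#' @param covariates optional covariate matrix for the optimization fits.
#' @param ld_ref LD reference [genotype_dataset()]; `NULL` skips clumping
#'   (appropriate for independent variants).
#' @param variants variant metadata used to build weight tables.
#' @param ... further options passed to [fit_pgsxe()].
#' @return A list: `threshold` (chosen cutoff), `weights` (the winning
#'   [weight_table()]), and `trace` (data frame: cutoff, n_variants, beta,
#'   se, p).
#' @export
optimize_threshold <- function(scan, grid = default_threshold_grid(),
                               geno_opt, y_opt, e_opt, covariates = NULL,
                               ld_ref = NULL, variants = NULL, ...) {
  grid <- sort(grid, decreasing = TRUE)
  if (is.null(variants) && inherits(geno_opt, "genotype_dataset")) {
    variants <- geno_opt$variants
  }
  keep_ids <- if (!is.null(ld_ref)) clump(scan, ld_ref) else
    scan$id[scan$estimable]
  scan_kept <- scan[scan$id %in% keep_ids, , drop = FALSE]
  trace <- data.frame(cutoff = grid, n_variants = 0L, beta = NA_real_,
                      se = NA_real_, p = NA_real_)
  tables <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    wt <- threshold_weights(scan_kept, grid[k], variants = variants)
    trace$n_variants[k] <- nrow(wt)
    if (nrow(wt) == 0L) next
    pgs <- compute_pgs(geno_opt, wt)
    if (stats::sd(pgs) == 0) next
    fit <- fit_pgsxe(pgs, e_opt, y_opt, covariates = covariates, ...)
    trace$beta[k] <- fit$coefficients["pgs:e", "estimate"]
    trace$se[k] <- fit$coefficients["pgs:e", "se"]
    trace$p[k] <- fit$coefficients["pgs:e", "p"]
    tables[[k]] <- wt
  }
  if (all(is.na(trace$p))) stop("no variants survive any threshold")
  # ties broken toward the more stringent (smaller) cutoff: pick the last
  # index among minima since the grid is ordered decreasing
  minp <- min(trace$p, na.rm = TRUE)
  best <- max(which(!is.na(trace$p) & trace$p == minp))
  list(threshold = grid[best], weights = tables[[best]], trace = trace)
}
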