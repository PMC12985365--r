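# Shared fixtures and independent oracles used across test files.

# tiny genotype dataset with hand-set dosages
tiny_geno <- function() {
  genotype_dataset(
    dosages = matrix(c(0, 1, 2, 2, 1, 0), nrow = 3),
    variants = data.frame(
      id = c("v1", "v2"), chrom = c("1", "1"), pos = c(1000L, 500000L),
      effect_allele = c("A", "C"), other_allele = c("G", "T"),
      maf = c(0.5, 0.5), info = c(1, 1), stringsAsFactors = FALSE
    ),
    sample_ids = c("s1", "s2", "s3")
  )
}

# independent normal-equations OLS oracle: full solve of X'X b = X'y with
# model-based covariance; returns estimate and se for one column of interest
ols_oracle <- function(X, y, col) {
  X <- cbind(1, X)
  y <- as.numeric(y)
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  V <- solve(XtX) * sum(res^2) / df
  j <- col + 1L
  list(beta = b[j], se = sqrt(V[j, j]),
       p = 2 * pt(-abs(b[j] / sqrt(V[j, j])), df))
}

# brute-force clumping oracle: literal restatement of the greedy rule
clump_oracle <- function(scan, ld_ref, r2_cut = 0.1, radius_kb = 250) {
  usable <- scan[scan$estimable, , drop = FALSE]
  idx <- match(usable$id, ld_ref$variants$id)
  meta <- ld_ref$variants[idx, ]
  dos <- ld_ref$dosages[, idx, drop = FALSE]
  remaining <- seq_len(nrow(usable))
  out <- character(0)
  while (length(remaining) > 0L) {
    i <- remaining[which.min(usable$p[remaining])]
    out <- c(out, usable$id[i])
    remaining <- setdiff(remaining, i)
    drop <- vapply(remaining, function(j) {
      meta$chrom[j] == meta$chrom[i] &&
        abs(meta$pos[j] - meta$pos[i]) <= radius_kb * 1000 &&
        isTRUE(cor(dos[, i], dos[, j])^2 > r2_cut)
    }, logical(1))
    remaining <- remaining[!drop]
  }
  out
}

# deterministic scan_result builder for scoring tests
fake_scan <- function(ids, p, beta = seq_along(ids),
                      scan_type = "marginal", ea = "A", oa = "G") {
  scan_result(ids, rep(ea, length.out = length(ids)),
              rep(oa, length.out = length(ids)),
              beta, rep(0.1, length(ids)), p, 100L, scan_type)
}
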