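test_that("the default threshold grid is strictly decreasing from 0.05 to 5e-8", {
  g <- default_threshold_grid()
  expect_true(all(diff(g) < 0))
  expect_equal(g[1], 0.05)
  expect_equal(g[length(g)], 5e-8)
  expect_true(all(g > 0 & g < 1))
})

test_that("thresholding keeps estimates strictly below the cutoff", {
  s <- fake_scan(c("a", "b"), p = c(0.01, 0.06), beta = c(0.5, 0.7))
  w <- threshold_weights(s, 0.05)
  expect_equal(w$id, "a")
  expect_equal(w$weight, 0.5)
  expect_equal(w$threshold, 0.05)

  # p exactly at the cutoff is excluded (strict inequality)
  s2 <- fake_scan("c", p = 0.05)
  expect_equal(nrow(threshold_weights(s2, 0.05)), 0L)

  # all above cutoff: empty table
  expect_equal(nrow(threshold_weights(fake_scan(c("a", "b"), p = c(0.9, 0.6)),
                                      0.05)), 0L)
})

test_that("thresholding equals a brute-force filter on a simulated scan", {
  set.seed(51)
  g <- simulate_genotypes(500, 40, seed = 51)
  y <- rnorm(500)
  s <- marginal_scan(g, y)
  w <- threshold_weights(s, 0.05, variants = g$variants)
  manual <- s$id[!is.na(s$p) & s$p < 0.05 & s$estimable & s$beta != 0]
  expect_setequal(w$id, manual)
  expect_equal(w$weight, s$beta[match(w$id, s$id)])
  # positional metadata filled from the variant table
  expect_equal(w$pos, g$variants$pos[match(w$id, g$variants$id)])
})

test_that("non-estimable scan rows can never enter a weight table", {
  s <- scan_result(c("a", "b"), "A", "G", c(0.5, NA), c(0.1, NA),
                   c(1e-10, 1), 100L, "marginal", estimable = c(TRUE, FALSE))
  w <- threshold_weights(s, 0.05)
  expect_equal(w$id, "a")
})

test_that("strand-ambiguous variants and duplicated IDs are excluded", {
  v <- data.frame(
    id = c("rs1", "rs2", "rs3", "rs3", "rs4", "rs5"),
    effect_allele = c("A", "A", "C", "G", "C", "G"),
    other_allele = c("T", "G", "T", "A", "G", "C"),
    stringsAsFactors = FALSE
  )
  out <- exclude_ambiguous_and_duplicates(v)
  # rs1 (A/T) ambiguous; rs4, rs5 (C/G, G/C) ambiguous; both rs3 copies dropped
  expect_equal(out$id, "rs2")
  expect_equal(attr(out, "n_removed"), 5L)
})

test_that("clumping keeps uncorrelated variants and prunes by p within LD", {
  g <- simulate_genotypes(800, 6, seed = 52)  # positions 1 Mb apart: no LD
  s <- fake_scan(g$variants$id, p = runif(6, 1e-6, 1e-3))
  expect_setequal(clump(s, g), s$id)

  # duplicate a column to force r2 = 1 at 1 kb distance
  g2 <- g
  g2$dosages[, 2] <- g2$dosages[, 1]
  g2$variants$pos[2] <- g2$variants$pos[1] + 1000L
  s2 <- fake_scan(g2$variants$id,
                  p = c(1e-8, 1e-4, rep(0.5, 4)))
  sel <- clump(s2, g2)
  expect_true(g2$variants$id[1] %in% sel)
  expect_false(g2$variants$id[2] %in% sel)
})

test_that("clumping matches an exhaustive oracle on an LD-block fixture", {
  tb <- simulate_toy_biobank(toy_biobank_config(n_samples = 600, n_blocks = 2,
                                                block_size = 5,
                                                n_ambiguous = 0,
                                                n_duplicate_ids = 0),
                             seed = 53)
  g <- tb$genotypes
  set.seed(54)
  s <- fake_scan(g$variants$id, p = runif(10, 1e-8, 0.05))
  expect_identical(clump(s, g), clump_oracle(s, g))
  # post-hoc invariant: no two selected variants in radius share r2 > cutoff
  sel <- clump(s, g)
  idx <- match(sel, g$variants$id)
  for (i in seq_along(idx)) for (j in seq_len(i - 1L)) {
    same_chrom <- g$variants$chrom[idx[i]] == g$variants$chrom[idx[j]]
    near <- abs(g$variants$pos[idx[i]] - g$variants$pos[idx[j]]) <= 250000
    if (same_chrom && near) {
      expect_lte(cor(g$dosages[, idx[i]], g$dosages[, idx[j]])^2, 0.1)
    }
  }
  expect_error(clump(fake_scan("ghost", 0.01), g), "ghost")
})

test_that("PGS computation is the hand-checkable weighted dosage sum", {
  g <- genotype_dataset(
    matrix(c(0, 1, 2, 2, 1, 0), nrow = 3),
    data.frame(id = c("v1", "v2"), chrom = "1", pos = c(100L, 200L),
               effect_allele = c("A", "C"), other_allele = c("G", "T"),
               maf = 0.5, info = 1)
  )
  w <- weight_table(c("v1", "v2"), "1", c(100L, 200L), c("A", "C"),
                    c("G", "T"), weight = c(0.5, -1), p = c(0.01, 0.01))
  expect_equal(unname(compute_pgs(g, w)), c(-2, -0.5, 1))

  # empty weights give all-zero scores; linearity in the weight vector
  expect_equal(unname(compute_pgs(g, w[0, ])), c(0, 0, 0))
  w1 <- w; w1$weight <- c(0.5, 0)
  w2 <- w; w2$weight <- c(0, -1)
  expect_equal(compute_pgs(g, w),
               compute_pgs(g, w1) + compute_pgs(g, w2))

  # allele mismatch is an error, never a silent skip
  wbad <- w; wbad$effect_allele <- c("G", "C"); wbad$other_allele <- c("A", "T")
  expect_error(compute_pgs(g, wbad), "v1")
})

test_that("harmonization flips reversed alleles, drops mismatches, caps by p", {
  w <- weight_table(paste0("v", 1:4), "1", c(100L, 200L, 300L, 400L),
                    effect_allele = c("A", "A", "A", "A"),
                    other_allele = c("G", "G", "G", "G"),
                    weight = c(0.3, 0.2, -0.1, 0.4),
                    p = c(1e-8, 1e-6, 1e-4, 1e-2))
  target <- data.frame(
    id = c("t1", "t2", "t3"),
    chrom = "1", pos = c(100L, 200L, 300L),
    effect_allele = c("G", "A", "A"), other_allele = c("A", "G", "C"),
    stringsAsFactors = FALSE
  )
  h <- harmonize_weights(w, target)
  # v1 reversed orientation: sign flip, target orientation adopted
  expect_equal(h$weight[h$id == "t1"], -0.3)
  expect_equal(h$effect_allele[h$id == "t1"], "G")
  # v2 same orientation: unchanged
  expect_equal(h$weight[h$id == "t2"], 0.2)
  # v3 allele mismatch (A/G vs A/C) and v4 absent: dropped
  expect_equal(nrow(h), 2L)
  expect_equal(attr(h, "n_dropped"), 2L)

  # cap: keep the max_variants smallest p-values
  h2 <- harmonize_weights(w, target, max_variants = 1L)
  expect_equal(h2$id, "t1")
})

test_that("harmonization is an involution under double allele flips", {
  w <- weight_table("v1", "1", 100L, "A", "G", weight = 0.3, p = 0.01)
  flipped_target <- data.frame(id = "v1", chrom = "1", pos = 100L,
                               effect_allele = "G", other_allele = "A")
  original_target <- data.frame(id = "v1", chrom = "1", pos = 100L,
                                effect_allele = "A", other_allele = "G")
  once <- harmonize_weights(w, flipped_target)
  twice <- harmonize_weights(once, original_target)
  expect_equal(twice$weight, w$weight)
  expect_equal(twice$effect_allele, w$effect_allele)
  # idempotence on a matching panel
  expect_equal(harmonize_weights(w, original_target)$weight, w$weight)
})

test_that("threshold optimization picks the cutoff minimizing interaction p", {
  set.seed(55)
  n <- 4000
  g <- simulate_genotypes(n, 30, seed = 55)
  dos <- g$dosages
  e <- rnorm(n)
  # interaction concentrated in 3 variants with very strong training signal
  gs <- scale(dos[, 1] + dos[, 2] + dos[, 3])[, 1]
  y <- 0.1 * gs + 0.25 * gs * e + rnorm(n)
  tr <- 1:3000; op <- 3001:4000
  scan <- interaction_scan(g[tr, ], y[tr], e[tr])
  opt <- optimize_threshold(scan, geno_opt = g[op, ], y_opt = y[op],
                            e_opt = e[op], variants = g$variants)
  # the chosen table contains the causal trio
  expect_true(all(g$variants$id[1:3] %in% opt$weights$id))
  # trace agrees with per-cutoff oracle refits
  for (k in which(!is.na(opt$trace$p))[1:3]) {
    wt <- threshold_weights(scan, opt$trace$cutoff[k], variants = g$variants)
    pgs <- compute_pgs(g[op, ], wt)
    f <- lm(y[op] ~ pgs * e[op])
    expect_equal(opt$trace$p[k], summary(f)$coefficients[4, 4],
                 tolerance = 1e-8)
  }
  expect_equal(opt$trace$p[opt$trace$cutoff == opt$threshold],
               min(opt$trace$p, na.rm = TRUE))

  # one-cutoff grid returns that cutoff; hopeless scans error out
  opt1 <- optimize_threshold(scan, grid = 0.05, geno_opt = g[op, ],
                             y_opt = y[op], e_opt = e[op],
                             variants = g$variants)
  expect_equal(opt1$threshold, 0.05)
  null_scan <- fake_scan(g$variants$id, p = rep(0.99, 30))
  expect_error(optimize_threshold(null_scan, geno_opt = g[op, ],
                                  y_opt = y[op], e_opt = e[op],
                                  variants = g$variants),
               "no variants survive")
})

test_that("optimization trace is bit-reproducible for fixed inputs", {
  set.seed(56)
  g <- simulate_genotypes(1000, 10, seed = 56)
  e <- rnorm(1000)
  y <- 0.2 * scale(g$dosages[, 1])[, 1] * e + rnorm(1000)
  scan <- interaction_scan(g[1:700, ], y[1:700], e[1:700])
  run <- function() optimize_threshold(scan, grid = c(0.5, 0.05),
                                       geno_opt = g[701:1000, ],
                                       y_opt = y[701:1000],
                                       e_opt = e[701:1000],
                                       variants = g$variants)
  expect_identical(run()$trace, run()$trace)
})
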