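#' Construct a genotype dataset
#'
#' Bundles an N x M additive dosage matrix with per-variant metadata and
#' sample identifiers. Dosages count copies of the effect allele and must lie
#' in \[0, 2\] (hard-called genotypes are 0/1/2; imputed dosages may be
#' fractional).
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants data frame with columns `id`, `chrom`, `pos` (1-based),
#'   `effect_allele`, `other_allele`, `maf`, and optionally `info`
#'   (imputation quality in \[0, 1\]).
#' @param sample_ids character vector of length `nrow(dosages)`.
#' @return An object of class `genotype_dataset`: a list with elements
#'   `dosages`, `variants`, `sample_ids`.
#' @export
genotype_dataset <- function(dosages, variants, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  required <- c("id", "chrom", "pos", "effect_allele", "other_allele", "maf")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0L) {
    stop("variant metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"info" %in% names(variants)) variants$info <- NA_real_
  if (nrow(variants) != ncol(dosages)) {
    stop("variant metadata rows (", nrow(variants), ") != dosage columns (",
         ncol(dosages), ")")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  if (length(sample_ids) != nrow(dosages)) {
    stop("sample_ids length != dosage rows")
  }
  bad <- which(dosages < 0 | dosages > 2, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("dosage outside [0, 2] for variant ", variants$id[bad[1L, 2L]],
         " (sample ", sample_ids[bad[1L, 1L]], ")")
  }
  colnames(dosages) <- variants$id
  rownames(dosages) <- sample_ids
  structure(
    list(dosages = dosages, variants = variants, sample_ids = as.character(sample_ids)),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

#' Subset a genotype dataset by samples and/or variants
#'
#' @param x a `genotype_dataset`.
#' @param i sample index (integer, logical, or sample id character vector).
#' @param j variant index (integer, logical, or variant id character vector).
#' @param ... unused.
#' @return A `genotype_dataset` restricted to the selected rows/columns.
#' @export
`[.genotype_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (is.character(j)) j <- match(j, x$variants$id)
  genotype_dataset(
    x$dosages[i, j, drop = FALSE],
    x$variants[j, , drop = FALSE],
    x$sample_ids[i]
  )
}

# ---------------------------------------------------------------------------
# Tabular readers/writers. TSV is the canonical dialect: tab-separated,
# header row, "." for missing values.

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(df, path) {
  df_out <- df
  for (nm in names(df_out)) {
    if (is.numeric(df_out[[nm]])) {
      df_out[[nm]] <- ifelse(is.na(df_out[[nm]]), ".",
                             format(df_out[[nm]], digits = 17, trim = TRUE,
                                    scientific = NA))
    } else {
      df_out[[nm]] <- ifelse(is.na(df_out[[nm]]), ".", as.character(df_out[[nm]]))
    }
  }
  utils::write.table(df_out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read genotypes from disk
#'
#' The TSV layout stores dosages with one sample per row (first column
#' `sample_id`, one column per variant) and variant metadata in a sidecar
#' file `<path>.variants.tsv` with columns id, chrom, pos, effect_allele,
#' other_allele, maf, info. The VCF path converts `DS` (preferred) or `GT`
#' fields of biallelic records to effect-allele dosage of the ALT allele.
#'
#' @param path genotype file path.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "vcf") return(.read_genotypes_vcf(path))
  sidecar <- paste0(path, ".variants.tsv")
  if (!file.exists(sidecar)) {
    stop("missing variant sidecar file: ", sidecar)
  }
  geno <- .read_tsv(path)
  variants <- .read_tsv(sidecar)
  if (!"sample_id" %in% names(geno)) stop("genotype TSV must have a sample_id column")
  sample_ids <- as.character(geno$sample_id)
  # index-based selection: variant IDs may legitimately be duplicated
  dos <- as.matrix(geno[, -match("sample_id", names(geno)), drop = FALSE])
  storage.mode(dos) <- "double"
  genotype_dataset(dos, variants, sample_ids)
}

.read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", lines[1L]), "\t")[[1L]]
  if (length(header) < 10L) stop("VCF has no sample columns")
  sample_ids <- header[-(1:9)]
  body <- lines[-1L]
  n <- length(sample_ids)
  m <- length(body)
  dos <- matrix(NA_real_, n, m)
  meta <- data.frame(id = character(m), chrom = character(m), pos = integer(m),
                     effect_allele = character(m), other_allele = character(m),
                     maf = NA_real_, info = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    f <- strsplit(body[j], "\t")[[1L]]
    fmt <- strsplit(f[9L], ":")[[1L]]
    ds_idx <- match("DS", fmt)
    gt_idx <- match("GT", fmt)
    vals <- vapply(f[-(1:9)], function(cell) {
      parts <- strsplit(cell, ":")[[1L]]
      if (!is.na(ds_idx)) return(as.numeric(parts[ds_idx]))
      gt <- parts[gt_idx]
      alleles <- strsplit(gt, "[/|]")[[1L]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == "1")
    }, numeric(1), USE.NAMES = FALSE)
    dos[, j] <- vals
    meta$id[j] <- f[3L]
    meta$chrom[j] <- f[1L]
    meta$pos[j] <- as.integer(f[2L])
    meta$other_allele[j] <- f[4L]
    meta$effect_allele[j] <- f[5L]
    meta$maf[j] <- min(mean(vals, na.rm = TRUE) / 2, 1 - mean(vals, na.rm = TRUE) / 2)
  }
  genotype_dataset(dos, meta, sample_ids)
}

#' Write genotypes (dosage TSV plus variant sidecar)
#'
#' @param geno a [genotype_dataset()].
#' @param path output path; the sidecar is written to `<path>.variants.tsv`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(sample_id = geno$sample_ids, stringsAsFactors = FALSE)
  dos <- as.data.frame(geno$dosages)
  names(dos) <- geno$variants$id
  .write_tsv(cbind(df, dos), path)
  .write_tsv(geno$variants[, c("id", "chrom", "pos", "effect_allele",
                               "other_allele", "maf", "info")],
             paste0(path, ".variants.tsv"))
  invisible(path)
}

.scan_types <- c("marginal", "interaction", "variance_drm", "variance_qi")

#' Construct a scan result table
#'
#' One row per variant tested, holding the focal coefficient of the scan
#' (genetic main effect, G-by-E interaction, or variance effect), its
#' standard error and p-value. Variants that could not be fit (for example a
#' monomorphic dosage column) are kept with `estimable = FALSE`, `NA`
#' estimate, and the sentinel p-value 1 so downstream thresholding never
#' selects them.
#'
#' @param id,effect_allele,other_allele variant identity columns.
#' @param beta,se,p estimate, standard error and p-value of the focal term.
#' @param n samples used per variant.
#' @param scan_type one of `"marginal"`, `"interaction"`, `"variance_drm"`,
#'   `"variance_qi"`.
#' @param estimable logical; defaults to `!is.na(beta)`.
#' @return A data frame of class `scan_result`.
#' @export
scan_result <- function(id, effect_allele, other_allele, beta, se, p, n,
                        scan_type, estimable = !is.na(beta)) {
  scan_type <- match.arg(scan_type, .scan_types)
  out <- data.frame(
    id = as.character(id),
    effect_allele = as.character(effect_allele),
    other_allele = as.character(other_allele),
    beta = as.numeric(beta),
    se = as.numeric(se),
    p = as.numeric(p),
    n = as.integer(n),
    scan_type = scan_type,
    estimable = as.logical(estimable),
    stringsAsFactors = FALSE
  )
  if (any(out$p < 0 | out$p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Write / read a scan result TSV
#'
#' @param scan a [scan_result()].
#' @param path file path.
#' @return `read_scan` returns a `scan_result`; `write_scan` returns `path`.
#' @export
write_scan <- function(scan, path) {
  .write_tsv(as.data.frame(scan), path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  df <- .read_tsv(path)
  if (nrow(df) == 0L) {
    out <- data.frame(id = character(), effect_allele = character(),
                      other_allele = character(), beta = numeric(),
                      se = numeric(), p = numeric(), n = integer(),
                      scan_type = character(), estimable = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("scan_result", "data.frame")
    return(out)
  }
  bad <- setdiff(unique(df$scan_type), .scan_types)
  if (length(bad) > 0L) {
    stop("unknown scan_type tag(s): ", paste(bad, collapse = ", "))
  }
  df$estimable <- as.logical(df$estimable)
  scan_result(df$id, df$effect_allele, df$other_allele, df$beta, df$se,
              df$p, df$n, df$scan_type[1L], df$estimable)
}

#' Construct a PGS weight table
#'
#' The scoring-file layout carries variant identity (id, chrom, pos,
#' alleles), the signed weight applied per copy of the effect allele, the
#' source scan p-value, and the p-value threshold that produced the table.
#' Zero-weight rows are dropped.
#'
#' @param id,chrom,pos,effect_allele,other_allele variant identity.
#' @param weight signed per-allele weight.
#' @param p source scan p-value.
#' @param threshold p-value cutoff used to build the table (scalar, recycled).
#' @return A data frame of class `weight_table`.
#' @export
weight_table <- function(id, chrom, pos, effect_allele, other_allele,
                         weight, p, threshold = NA_real_) {
  out <- data.frame(
    id = as.character(id), chrom = as.character(chrom), pos = as.integer(pos),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    weight = as.numeric(weight), p = as.numeric(p),
    threshold = rep(as.numeric(threshold), length.out = length(id)),
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$weight) & out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("weight_table", "data.frame")
  out
}

#' Write / read a PGS weight table TSV
#'
#' @param weights a [weight_table()].
#' @param path file path.
#' @return `read_weights` returns a `weight_table`; `write_weights` returns
#'   `path`.
#' @export
write_weights <- function(weights, path) {
  .write_tsv(as.data.frame(weights), path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- .read_tsv(path)
  required <- c("id", "chrom", "pos", "effect_allele", "other_allele", "weight", "p")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("weight file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"threshold" %in% names(df)) df$threshold <- NA_real_
  weight_table(df$id, df$chrom, df$pos, df$effect_allele, df$other_allele,
               df$weight, df$p, df$threshold)
}

#' Randomly split samples into analysis subsets
#'
#' Partitions samples into labelled subsets (by default training 70%,
#' optimization 10%, testing 20%) with subset sizes within one sample of
#' `N * fraction`, deterministically under a fixed seed. Two-way splits
#' (e.g. 70/30 train/test, as used in the simulation study) are requested by
#' passing two fractions/labels.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param fractions positive fractions summing to 1, one per subset.
#' @param seed integer RNG seed.
#' @param labels subset labels; defaults to training/optimization/testing
#'   (or training/testing for a two-way split).
#' @return A data frame of class `split_assignment` with columns
#'   `sample_id`, `subset`.
#' @export
split_samples <- function(sample_ids, fractions = c(0.7, 0.1, 0.2), seed,
                          labels = NULL) {
  if (any(fractions <= 0)) stop("all fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  k <- length(fractions)
  if (is.null(labels)) {
    labels <- if (k == 2L) c("training", "testing")
              else if (k == 3L) c("training", "optimization", "testing")
              else paste0("subset", seq_len(k))
  }
  if (length(labels) != k) stop("labels length must match fractions")
  n <- length(sample_ids)
  sizes <- floor(n * fractions)
  # distribute the rounding remainder to the largest fractional parts
  rem <- n - sum(sizes)
  if (rem > 0L) {
    frac_part <- n * fractions - sizes
    sizes[order(frac_part, decreasing = TRUE)[seq_len(rem)]] <-
      sizes[order(frac_part, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  perm <- withr_seed_sample(seed, n)
  subset <- rep(labels, times = sizes)[order(perm)]
  out <- data.frame(sample_id = as.character(sample_ids), subset = subset,
                    stringsAsFactors = FALSE)
  class(out) <- c("split_assignment", "data.frame")
  out
}

# draw a permutation of 1..n under a local seed without disturbing the
# caller's RNG stream
withr_seed_sample <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(n)
}

#' Write / read a split assignment TSV
#'
#' @param split a [split_samples()] result.
#' @param path file path.
#' @return `read_split` returns a `split_assignment`; `write_split` returns
#'   `path`.
#' @export
write_split <- function(split, path) .write_tsv(as.data.frame(split), path)

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- .read_tsv(path)
  class(df) <- c("split_assignment", "data.frame")
  df
}
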