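#' Median-ratio size factors
#'
#' For each sample, the size factor is the median over reference genes of the
#' ratio of the gene's count to its geometric mean across samples. Reference
#' genes are those with a positive count in every sample. Factors are exactly
#' equivariant: scaling one sample's counts by `c` scales its factor by `c`.
#'
#' @param gene_counts genes x samples count matrix (raw counts; fractional
#'   values allowed).
#' @param genes optional subset of gene ids to use as the reference pool.
#' @return List of class `"tecoex_sf"`: `size_factors` (named, positive),
#'   `reference_genes`.
#' @export
median_ratio_size_factors <- function(gene_counts, genes = NULL) {
  m <- as.matrix(gene_counts)
  if (ncol(m) < 2L) stop("need at least 2 samples")
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  eligible <- rowSums(m > 0) == ncol(m)
  if (!any(eligible)) stop("no gene is positive in every sample")
  me <- m[eligible, , drop = FALSE]
  geomean <- exp(rowMeans(log(me)))
  ratios <- me / geomean
  sf <- apply(ratios, 2, median)
  structure(list(size_factors = sf, reference_genes = rownames(me)),
            class = "tecoex_sf")
}

#' Two-step DEGES size factors
#'
#' Differentially-expressed-genes elimination strategy: (1) median-ratio
#' factors on all eligible genes; (2) rank genes by a between-group one-way
#' F-statistic on step-1-normalized `log2(x + 1)` counts (by across-sample
#' variance when only one group is given), drop the top `drop_fraction`, and
#' recompute median-ratio factors on the remainder, which becomes the
#' recorded reference gene set. With `drop_fraction = 0` the result equals
#' one-step median-ratio.
#'
#' @inheritParams median_ratio_size_factors
#' @param sample_groups factor/character of group (tissue) per sample.
#' @param drop_fraction fraction of genes flagged as potentially DE and
#'   eliminated before the second pass (default 0.3).
#' @return List of class `"tecoex_sf"` with `size_factors`,
#'   `reference_genes`, and `step1` (the one-step factors).
#' @export
deges_size_factors <- function(gene_counts, sample_groups = NULL,
                               drop_fraction = 0.3) {
  m <- as.matrix(gene_counts)
  step1 <- median_ratio_size_factors(m)
  if (drop_fraction <= 0) {
    step1$step1 <- step1$size_factors
    return(step1)
  }
  norm1 <- sweep(m, 2, step1$size_factors, `/`)
  lg <- log2(norm1 + 1)
  stat <- if (!is.null(sample_groups) &&
              length(unique(sample_groups)) >= 2L) {
    .row_f_stat(lg, factor(sample_groups))
  } else {
    apply(lg, 1, var)
  }
  stat[is.na(stat)] <- 0
  n_drop <- floor(drop_fraction * nrow(m))
  drop <- rownames(m)[order(stat, decreasing = TRUE)][seq_len(n_drop)]
  keep <- setdiff(rownames(m), drop)
  if (!length(keep)) stop("drop_fraction eliminated every gene")
  out <- median_ratio_size_factors(m, genes = keep)
  out$step1 <- step1$size_factors
  out
}

# vectorized one-way ANOVA F statistic per matrix row
.row_f_stat <- function(m, groups) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups); n <- ncol(m)
  if (k < 2L || n <= k) return(rep(NA_real_, nrow(m)))
  gm <- rowMeans(m)
  ssb <- 0; ssw <- 0
  for (lev in levels(groups)) {
    cols <- which(groups == lev)
    mu <- rowMeans(m[, cols, drop = FALSE])
    ssb <- ssb + length(cols) * (mu - gm)^2
    ssw <- ssw + rowSums((m[, cols, drop = FALSE] - mu)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Apply size factors to a count matrix
#'
#' Divides each sample's column by its factor. Size factors estimated from
#' gene counts are applied unchanged to TE count matrices of the same
#' samples.
#'
#' @param counts features x samples matrix.
#' @param sf a `tecoex_sf` object or named numeric vector of factors.
#' @return Normalized matrix (stage `normalized`).
#' @export
normalize_counts <- function(counts, sf) {
  f <- if (inherits(sf, "tecoex_sf")) sf$size_factors else sf
  m <- as.matrix(counts)
  if (!all(colnames(m) %in% names(f)))
    stop("missing size factor for some samples")
  sweep(m, 2, f[colnames(m)], `/`)
}

#' Effective library size
#'
#' Sum of all normalized counts per sample; used downstream as a covariate in
#' the L1HS-gene linear models.
#'
#' @param normalized normalized matrix (genes, or genes plus TEs).
#' @return Named numeric vector.
#' @export
effective_library_size <- function(normalized) colSums(as.matrix(normalized))

#' Log2 transform of normalized counts
#'
#' `log2(x + pseudocount)`; monotone, zeros map to 0 at the default
#' pseudocount of 1. Stands in for a variance-stabilizing transform;
#' downstream correlation analyses are rank-robust to this choice.
#'
#' @param normalized normalized matrix.
#' @param pseudocount added before the log (default 1).
#' @return Matrix of log2 values (stage `log2`).
#' @export
log_transform <- function(normalized, pseudocount = 1) {
  m <- as.matrix(normalized)
  if (any(m < 0)) stop("negative values cannot be log-transformed")
  log2(m + pseudocount)
}
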