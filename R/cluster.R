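#' Select top-variance features
#'
#' Locus-level features with fewer than `min_count_filter` raw counts in
#' every sample are removed first, X/Y-chromosome features are excluded, then
#' the `n` features with the largest across-sample variance of the log2
#' values are kept (ties broken by feature id, lexicographically, for
#' determinism).
#'
#' @param log2_matrix features x samples matrix of log2 values.
#' @param n number of features to keep (default 150).
#' @param feature_chroms optional named chromosome per feature, used for the
#'   X/Y exclusion.
#' @param exclude_chroms chromosome names to exclude (default X and Y).
#' @param raw_counts optional raw count matrix (same features) used for the
#'   minimum-count filter.
#' @param min_count_filter features must reach this many raw counts in at
#'   least one sample (default 5).
#' @return Character vector of `n` feature ids.
#' @export
select_top_variance <- function(log2_matrix, n = 150L, feature_chroms = NULL,
                                exclude_chroms = c("chrX", "chrY", "X", "Y"),
                                raw_counts = NULL, min_count_filter = 5) {
  m <- as.matrix(log2_matrix)
  keep <- rownames(m)
  if (!is.null(raw_counts)) {
    rc <- as.matrix(raw_counts)
    ok <- rownames(rc)[apply(rc, 1, max) >= min_count_filter]
    keep <- intersect(keep, ok)
  }
  if (!is.null(feature_chroms))
    keep <- keep[!(feature_chroms[keep] %in% exclude_chroms)]
  if (length(keep) < n)
    stop("only ", length(keep), " eligible features; ", n, " requested")
  v <- apply(m[keep, , drop = FALSE], 1, var)
  keep[order(-v, keep)][seq_len(n)]
}

#' UPGMA clustering of samples
#'
#' Euclidean distances between sample columns, average-linkage (UPGMA)
#' agglomeration, tree cut into `k` clusters. Deterministic: no randomness is
#' involved.
#'
#' @param matrix features x samples matrix (typically the selected
#'   top-variance log2 submatrix).
#' @param k number of clusters.
#' @param zscore z-score each feature across samples before computing
#'   distances.
#' @return Named integer vector of cluster ids per sample.
#' @export
upgma_cluster <- function(matrix, k, zscore = FALSE) {
  m <- as.matrix(matrix)
  if (k > ncol(m)) stop("k exceeds the number of samples")
  if (zscore) {
    sds <- apply(m, 1, sd)
    m <- (m - rowMeans(m)) / ifelse(sds > 0, sds, 1)
  }
  hc <- hclust(dist(t(m)), method = "average")
  cutree(hc, k = k)
}

#' Majority group label per cluster
#'
#' @param clusters named cluster ids per sample.
#' @param truth named true group labels per sample.
#' @return Character vector: majority label per cluster id (ties broken by
#'   label order).
#' @export
majority_labels <- function(clusters, truth) {
  truth <- truth[names(clusters)]
  vapply(split(truth, clusters),
         function(x) names(sort(table(x), decreasing = TRUE))[1], "")
}

#' Normalized mutual information between two partitions
#'
#' Mutual information normalized by the arithmetic mean of the two partition
#' entropies (the `sqrt` variant divides by the geometric mean instead).
#' Symmetric, invariant to label renaming, and 0 whenever either partition
#' is a single cluster.
#'
#' @param labels,truth_labels two partitions of the same samples (any label
#'   type; matched by position, or by names when both are named).
#' @param normalization `"mean"` (default) or `"sqrt"`.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(labels, truth_labels, normalization = c("mean", "sqrt")) {
  normalization <- match.arg(normalization)
  if (!length(labels) || length(labels) != length(truth_labels))
    stop("partitions must be non-empty and of equal length")
  if (!is.null(names(labels)) && !is.null(names(truth_labels)))
    truth_labels <- truth_labels[names(labels)]
  tab <- table(labels, truth_labels)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / (pi_[row(pij)[nz]] * pj[col(pij)[nz]])))
  hu <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hv <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  denom <- if (normalization == "mean") (hu + hv) / 2 else sqrt(hu * hv)
  if (denom == 0) return(0)
  max(0, min(1, mi / denom))
}

#' Permutation baseline for the clustering NMI
#'
#' Mean NMI between the true labels and labels permuted without replacement
#' (shuffled) and resampled with replacement, over `reps` repetitions.
#'
#' @param truth_labels true group labels.
#' @param reps number of permutations (default 100).
#' @param seed optional seed for reproducibility.
#' @return Named numeric: `without_replacement`, `with_replacement`.
#' @export
permutation_baseline <- function(truth_labels, reps = 100L, seed = NULL) {
  if (reps <= 0) stop("reps must be positive")
  if (!is.null(seed)) set.seed(seed)
  wo <- mean(vapply(seq_len(reps), function(i)
    nmi(sample(truth_labels), truth_labels), 0))
  wi <- mean(vapply(seq_len(reps), function(i)
    nmi(sample(truth_labels, replace = TRUE), truth_labels), 0))
  c(without_replacement = wo, with_replacement = wi)
}

#' Cluster samples and score against true tissue labels
#'
#' Feature selection ([select_top_variance()]), UPGMA clustering at `k`,
#' majority labeling and NMI scoring in one call.
#'
#' @inheritParams select_top_variance
#' @inheritParams upgma_cluster
#' @param truth named true group label per sample.
#' @param k number of clusters (default: number of distinct true groups).
#' @return List of class `"tecoex_clustering"`: `clusters`, `majority`,
#'   `nmi`, `features`.
#' @export
evaluate_clustering <- function(log2_matrix, truth, k = length(unique(truth)),
                                n = 150L, feature_chroms = NULL,
                                raw_counts = NULL, min_count_filter = 5,
                                zscore = FALSE) {
  feats <- select_top_variance(log2_matrix, n = n,
                               feature_chroms = feature_chroms,
                               raw_counts = raw_counts,
                               min_count_filter = min_count_filter)
  cl <- upgma_cluster(log2_matrix[feats, , drop = FALSE], k = k,
                      zscore = zscore)
  structure(list(clusters = cl, majority = majority_labels(cl, truth),
                 nmi = nmi(cl, truth[names(cl)]), features = feats),
            class = "tecoex_clustering")
}
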