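#' Signed soft-thresholded adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta` on Pearson correlations of feature
#' profiles, so perfectly anti-correlated features get adjacency 0 and the
#' soft power suppresses weak, noise-level correlations.
#'
#' @param log2_matrix features x samples matrix; features with zero variance
#'   are an error.
#' @param beta soft power (default 14).
#' @return Symmetric adjacency matrix in `[0, 1]` with unit diagonal;
#'   attribute `"beta"`.
#' @export
signed_adjacency <- function(log2_matrix, beta = 14) {
  m <- as.matrix(log2_matrix)
  if (ncol(m) < 3L) stop("need at least 3 samples")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) stop("zero-variance features: ",
                          paste(head(rownames(m)[sds == 0]), collapse = ", "))
  a <- ((1 + cor(t(m))) / 2)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Soft-power selection by scale-free topology fit
#'
#' For each candidate power, computes the adjacency, bins the connectivity
#' distribution, and fits `log10 p(k) ~ log10 k`. Returns the smallest power
#' whose fit reaches `target_r2` with a negative slope; otherwise the
#' candidate with the best fit; falls back to 14 (with a warning) when no
#' fit is defined, e.g. when all correlations are about 0.
#'
#' @inheritParams signed_adjacency
#' @param candidate_powers powers to try.
#' @param target_r2 fit threshold (default 0.8).
#' @param n_bins connectivity histogram bins (default 10).
#' @return Selected power; attribute `"fit"` holds per-candidate R-squared.
#' @export
soft_power_selection <- function(log2_matrix, candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                                 target_r2 = 0.8, n_bins = 10L) {
  if (!length(candidate_powers)) stop("no candidate powers")
  r2 <- vapply(candidate_powers, function(b) {
    a <- signed_adjacency(log2_matrix, beta = b)
    k <- rowSums(a) - 1
    if (sd(k) == 0) return(NA_real_)
    br <- cut(k, breaks = n_bins)
    pk <- tapply(k, br, length) / length(k)
    km2 <- tapply(k, br, mean)
    ok <- !is.na(pk) & pk > 0 & km2 > 0
    if (sum(ok) < 3L) return(NA_real_)
    fit <- lm(log10(pk[ok]) ~ log10(km2[ok]))
    r2v <- summary(fit)$r.squared
    if (coef(fit)[2] >= 0) 0 else r2v
  }, 0)
  if (all(is.na(r2))) {
    warning("scale-free fit undefined for all candidates; falling back to 14")
    out <- 14
  } else if (any(!is.na(r2) & r2 >= target_r2)) {
    out <- min(candidate_powers[!is.na(r2) & r2 >= target_r2])
  } else {
    out <- candidate_powers[which.max(r2)]
  }
  attr(out, "fit") <- setNames(r2, candidate_powers)
  out
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu` and the sum over `u` excluding `i` and `j`;
#' `TOM_ii = 1`. Bounded in `[0, 1]`: 0 off-diagonal for an edgeless graph,
#' identically 1 for a complete graph. `1 - TOM` is the module-detection
#' dissimilarity.
#'
#' @param adjacency output of [signed_adjacency()].
#' @return TOM matrix.
#' @export
tom <- function(adjacency) {
  a <- as.matrix(adjacency)
  k <- rowSums(a) - diag(a)
  shared <- a %*% a - 2 * a            # sum over u != i,j of a_iu a_uj (diag 1)
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  t_ <- num / den
  diag(t_) <- 1
  pmin(pmax(t_, 0), 1)
}

#' Consensus TOM across tissues
#'
#' Component-wise minimum of per-tissue TOMs: an edge is only as strong as
#' its weakest tissue, so consensus modules are shared across all tissues.
#'
#' @param tom_by_tissue named list of TOM matrices over identical features.
#' @return Consensus matrix.
#' @export
consensus_tom <- function(tom_by_tissue) {
  if (!length(tom_by_tissue)) stop("empty TOM list")
  ref <- tom_by_tissue[[1]]
  for (t_ in tom_by_tissue[-1]) {
    if (!identical(dimnames(t_), dimnames(ref)))
      stop("mismatched feature sets across tissues")
    ref <- pmin(ref, t_)
  }
  ref
}

#' Detect modules on a (consensus) TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, static cut at
#' `cut_height`; clusters smaller than `min_module_size` become unassigned
#' (module 0). Modules are renumbered 1, 2, ... by decreasing size.
#'
#' @param ctom TOM or consensus TOM.
#' @param min_module_size smallest retained module (default 30).
#' @param cut_height static tree-cut height on the dissimilarity (default
#'   0.995).
#' @return Named integer vector: feature -> module id (0 = unassigned).
#' @export
detect_modules <- function(ctom, min_module_size = 30L, cut_height = 0.995) {
  d <- stats::as.dist(1 - as.matrix(ctom))
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  out <- integer(length(cl))
  names(out) <- names(cl)
  keep <- keep[order(-sizes[keep])]
  for (i in seq_along(keep)) out[cl == as.integer(keep[i])] <- i
  out
}

#' Module eigengene
#'
#' First principal component of the standardized member submatrix (features
#' z-scored across samples), returned as a unit-norm sample profile oriented
#' so that its mean correlation with the members is non-negative.
#'
#' @param log2_matrix features x samples matrix.
#' @param module_features ids of the module's members (>= 2).
#' @return Named numeric sample profile, unit norm.
#' @export
eigengene <- function(log2_matrix, module_features) {
  m <- as.matrix(log2_matrix)[module_features, , drop = FALSE]
  if (nrow(m) < 2L) stop("eigengene needs at least 2 member features")
  if (ncol(m) < 3L) stop("eigengene needs at least 3 samples")
  sds <- apply(m, 1, sd)
  if (all(sds == 0)) stop("degenerate module: all members have zero variance")
  z <- (m - rowMeans(m)) / ifelse(sds > 0, sds, 1)
  sv <- svd(t(z), nu = 1, nv = 0)
  e <- sv$u[, 1]
  names(e) <- colnames(m)
  cors <- suppressWarnings(cor(e, t(m)))
  if (mean(cors, na.rm = TRUE) < 0) e <- -e
  e
}

#' Eigengenes for every module
#'
#' @param log2_matrix features x samples matrix.
#' @param modules feature -> module assignment from [detect_modules()].
#' @return samples x modules matrix of eigengene profiles (module 0 skipped).
#' @export
module_eigengenes <- function(log2_matrix, modules) {
  ids <- sort(setdiff(unique(modules), 0L))
  out <- sapply(ids, function(i)
    eigengene(log2_matrix, names(modules)[modules == i]))
  colnames(out) <- paste0("M", ids)
  rownames(out) <- colnames(log2_matrix)
  out
}

#' Module membership (kME)
#'
#' Correlation of each feature's profile with each module eigengene.
#'
#' @param log2_matrix features x samples matrix.
#' @param eigengenes samples x modules matrix from [module_eigengenes()].
#' @return features x modules matrix of correlations in `[-1, 1]`.
#' @export
module_membership <- function(log2_matrix, eigengenes) {
  cor(t(as.matrix(log2_matrix)), eigengenes)
}

#' Cross-tissue module screens
#'
#' Given consensus module assignments and per-tissue expression matrices:
#' (a) strict members have kME above `kme_threshold` with their own module's
#' eigengene in every tissue; (b) anti-correlated module pairs have
#' eigengene correlation below `anticor_threshold` in every tissue; (c) TE
#' modules contain more than `te_module_min` TE features, and core TE
#' modules are those whose members are mostly TE features.
#'
#' @param modules feature -> module id.
#' @param mats_by_tissue named list of features x samples log2 matrices
#'   (identical feature sets).
#' @param te_features character vector naming the TE features.
#' @param kme_threshold strict-membership cutoff (default 0.6).
#' @param anticor_threshold anti-correlation cutoff (default -0.7).
#' @param te_module_min TE-feature count above which a module is a TE module
#'   (default 10).
#' @return List: `strict_members`, `anticorrelated_pairs` (data frame),
#'   `te_modules`, `core_te_modules`, `eigengenes` (per tissue), `kme` (per
#'   tissue).
#' @export
module_screens <- function(modules, mats_by_tissue, te_features = character(0),
                           kme_threshold = 0.6, anticor_threshold = -0.7,
                           te_module_min = 10L) {
  ids <- sort(setdiff(unique(modules), 0L))
  egs <- lapply(mats_by_tissue, module_eigengenes, modules = modules)
  kmes <- lapply(names(mats_by_tissue), function(t_)
    module_membership(mats_by_tissue[[t_]], egs[[t_]]))
  names(kmes) <- names(mats_by_tissue)

  own_col <- paste0("M", modules)
  assigned <- names(modules)[modules != 0L]
  strict <- assigned
  for (t_ in names(kmes)) {
    km <- kmes[[t_]]
    ok <- km[cbind(assigned, own_col[match(assigned, names(modules))])] >
      kme_threshold
    strict <- intersect(strict, assigned[ok])
  }

  pairs <- list()
  if (length(ids) >= 2L) {
    cm <- lapply(egs, cor)
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      vals <- vapply(cm, function(x) x[i, j], 0)
      if (all(vals < anticor_threshold))
        pairs[[length(pairs) + 1L]] <- data.frame(
          module_a = ids[i], module_b = ids[j],
          max_cor = max(vals), stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(module_a = integer(0), module_b = integer(0),
               max_cor = numeric(0))

  n_te <- vapply(ids, function(i)
    sum(names(modules)[modules == i] %in% te_features), 0L)
  n_all <- vapply(ids, function(i) sum(modules == i), 0L)
  te_mods <- ids[n_te > te_module_min]
  core <- ids[n_te > te_module_min & n_te > n_all / 2]

  list(strict_members = strict, anticorrelated_pairs = pairs,
       te_modules = te_mods, core_te_modules = core,
       eigengenes = egs, kme = kmes)
}

#' Per-tissue consensus network analysis
#'
#' Convenience wrapper: per-tissue signed adjacency and TOM, consensus TOM,
#' module detection, and module screens.
#'
#' @param mats_by_tissue named list of features x samples log2 matrices.
#' @param beta soft power (default 14).
#' @param min_module_size,cut_height passed to [detect_modules()].
#' @param te_features,kme_threshold,anticor_threshold,te_module_min passed to
#'   [module_screens()].
#' @return List: `modules`, `consensus`, `toms`, `screens`.
#' @export
consensus_network <- function(mats_by_tissue, beta = 14,
                              min_module_size = 30L, cut_height = 0.995,
                              te_features = character(0),
                              kme_threshold = 0.6, anticor_threshold = -0.7,
                              te_module_min = 10L) {
  toms <- lapply(mats_by_tissue, function(m) tom(signed_adjacency(m, beta)))
  cons <- consensus_tom(toms)
  modules <- detect_modules(cons, min_module_size, cut_height)
  screens <- module_screens(modules, mats_by_tissue, te_features,
                            kme_threshold, anticor_threshold, te_module_min)
  list(modules = modules, consensus = cons, toms = toms, screens = screens)
}
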