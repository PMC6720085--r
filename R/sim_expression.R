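#' Simulate ground-truth expression with planted factor structure
#'
#' Draws per-sample latent factor values (tissue mean plus unit Gaussian
#' noise), assigns every feature (gene or TE locus) to a feature group (gene
#' groups from `config$gene_groups`; each TE locus belongs to its family
#' group), and sets the expected fragment count of feature `f` in sample `s`
#' to `exp(baseline_f + sum_k loading_{group(f),k} * factor_{s,k})`, rescaled
#' so each sample's expected total (genes + autonomous TE + read-through)
#' equals `frag_reads_per_sample`. Counts are drawn negative-binomially later,
#' by [draw_counts()] or [simulate_alignments()].
#'
#' Expected read-through (pre-mRNA/retained-intron) fragments per gene are
#' `retention_fraction` times the gene's mature expected fragments.
#'
#' @param config a [sim_config()] object.
#' @param annotation output of [simulate_annotation()].
#' @return A list of class `"tecoex_truth"`: `samples` (sample/tissue table),
#'   `true_locus_abundance` (locus x sample expected fragments),
#'   `true_gene_abundance`, `retention_reads` (gene x sample expected
#'   read-through fragments), `factor_values` (sample x factor),
#'   `feature_group`, `module_membership` (feature -> planted factor index, 0
#'   = background).
#' @export
simulate_expression <- function(config, annotation) {
  validate_sim_config(config)
  set.seed(.sub_seed(config$seed, 1L))
  n_fac <- .n_factors(config)
  n_samp <- config$n_tissues * config$n_samples_per_tissue
  tissues <- rep(sprintf("tissue%02d", seq_len(config$n_tissues)),
                 each = config$n_samples_per_tissue)
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n_samp)),
    tissue = tissues, stringsAsFactors = FALSE
  )

  mu <- matrix(0, config$n_tissues, n_fac)
  if (!is.null(config$tissue_factor_means)) {
    m <- as.matrix(config$tissue_factor_means)
    mu[, seq_len(ncol(m))] <- m[rep(seq_len(nrow(m)),
                                    length.out = config$n_tissues), ]
  }
  fac <- mu[match(tissues, sprintf("tissue%02d", seq_len(config$n_tissues))), ,
            drop = FALSE] +
    matrix(rnorm(n_samp * n_fac), n_samp, n_fac)
  rownames(fac) <- samples$sample_id
  colnames(fac) <- sprintf("factor%d", seq_len(n_fac))

  gene_ids <- annotation$genes$genes$gene_id
  locus_ids <- annotation$te$locus_id
  group <- c(.gene_group_labels(config, gene_ids),
             setNames(annotation$te$family, locus_ids))

  load_mat <- matrix(0, length(group), n_fac,
                     dimnames = list(names(group), colnames(fac)))
  for (g in names(config$factor_loadings)) {
    v <- config$factor_loadings[[g]]
    rows <- names(group)[group == g]
    if (length(rows))
      load_mat[rows, seq_along(v)] <- matrix(v, length(rows), length(v),
                                             byrow = TRUE)
  }

  baseline <- rnorm(length(group), config$baseline_log_mean,
                    config$baseline_log_sd)
  names(baseline) <- names(group)
  log_mu <- baseline + load_mat %*% t(fac)   # feature x sample
  expected <- exp(log_mu)

  gene_e <- expected[gene_ids, , drop = FALSE]
  locus_e <- expected[locus_ids, , drop = FALSE]
  retention_e <- config$retention_fraction * gene_e
  totals <- colSums(gene_e) + colSums(locus_e) + colSums(retention_e)
  scale <- config$frag_reads_per_sample / totals
  gene_e <- sweep(gene_e, 2, scale, `*`)
  locus_e <- sweep(locus_e, 2, scale, `*`)
  retention_e <- sweep(retention_e, 2, scale, `*`)

  membership <- apply(load_mat, 1, function(r)
    if (all(r == 0)) 0L else which.max(abs(r)))

  structure(
    list(samples = samples,
         true_locus_abundance = locus_e,
         true_gene_abundance = gene_e,
         retention_reads = retention_e,
         factor_values = fac,
         feature_group = group,
         module_membership = membership,
         config = config),
    class = "tecoex_truth"
  )
}

.gene_group_labels <- function(config, gene_ids) {
  group <- rep("background", length(gene_ids))
  gg <- config$gene_groups
  if (!is.null(gg)) {
    if (sum(gg) > length(gene_ids))
      stop("gene_groups assign more genes than simulated")
    group[seq_len(sum(gg))] <- rep(names(gg), gg)
  }
  setNames(group, gene_ids)
}

#' Draw negative-binomial counts from ground-truth expectations
#'
#' Counts have mean `mu` (the expected abundances in `truth`) and variance
#' `mu + mu^2 / nb_dispersion`.
#'
#' @param truth a `tecoex_truth` object.
#' @param config the matching [sim_config()].
#' @param seed_offset integer added to the derived seed so separate draws can
#'   be made reproducibly distinct.
#' @return List of matrices `locus_counts`, `gene_counts`,
#'   `retention_counts`.
#' @export
draw_counts <- function(truth, config = truth$config, seed_offset = 2L) {
  set.seed(.sub_seed(config$seed, seed_offset))
  draw <- function(mu) {
    out <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                          size = config$nb_dispersion),
                  nrow(mu), ncol(mu), dimnames = dimnames(mu))
    out
  }
  list(locus_counts = draw(truth$true_locus_abundance),
       gene_counts = draw(truth$true_gene_abundance),
       retention_counts = draw(truth$retention_reads))
}
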