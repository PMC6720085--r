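#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_annotation()], [simulate_expression()] and
#' [simulate_alignments()]. The defaults describe a small poly-A RNA-seq
#' experiment over a toy genome: 48-nt single-end fragments, multi-mapped
#' reads arising from sequence-similar TE copies, and pre-mRNA/retained-intron
#' read-through at a per-gene fraction `retention_fraction`.
#'
#' @param n_chromosomes number of toy chromosomes.
#' @param chrom_length length of each chromosome in bases.
#' @param n_genes total number of genes placed across chromosomes.
#' @param exons_per_gene exons per gene.
#' @param exon_length exon length in bases.
#' @param intron_length intron length in bases.
#' @param n_te_families number of TE families.
#' @param loci_per_family copies per family.
#' @param te_length TE consensus length in bases; scalar or one per family.
#' @param family_divergence per-base substitution probability applied to each
#'   copy relative to the family consensus; scalar or one per family.
#' @param te_context_fractions named fractions (`intronic`, `exonic`,
#'   `intergenic`) of each family's copies placed in each genomic context.
#' @param read_len sequenced fragment length in bases (single-end).
#' @param frag_reads_per_sample expected total fragments per sample.
#' @param retention_fraction expected pre-mRNA/retained-intron read-through
#'   fragments per gene, as a fraction of the gene's mature-transcript
#'   fragments; in `[0, 1]`.
#' @param n_samples_per_tissue samples per tissue.
#' @param n_tissues number of tissues.
#' @param factor_loadings named list mapping a feature group (a TE family name
#'   or a gene group name) to its numeric loadings on the latent factors;
#'   groups absent from the list load 0 on every factor.
#' @param gene_groups named integer vector assigning the first
#'   `sum(gene_groups)` genes to named groups (e.g. `c(kzfp = 10, immune =
#'   10)`); remaining genes form group `"background"`.
#' @param tissue_factor_means optional `n_tissues x n_factors` matrix of
#'   per-tissue factor means (0 when `NULL`); per-sample factor values are
#'   drawn `N(mean, 1)`.
#' @param baseline_log_mean,baseline_log_sd per-feature baseline
#'   log-abundance distribution.
#' @param nb_dispersion negative-binomial size parameter; counts have mean
#'   `mu` and variance `mu + mu^2 / nb_dispersion`.
#' @param intergenic_gap minimum gap in bases between a gene boundary and the
#'   nearest intergenic TE (kept above the 1000-base intergenic threshold).
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_chromosomes = 1L,
                       chrom_length = 100000L,
                       n_genes = 4L,
                       exons_per_gene = 3L,
                       exon_length = 200L,
                       intron_length = 1500L,
                       n_te_families = 2L,
                       loci_per_family = 3L,
                       te_length = 300L,
                       family_divergence = 0.1,
                       te_context_fractions = c(intronic = 0.3, exonic = 0,
                                                intergenic = 0.7),
                       read_len = 48L,
                       frag_reads_per_sample = 20000L,
                       retention_fraction = 0.3,
                       n_samples_per_tissue = 4L,
                       n_tissues = 2L,
                       factor_loadings = list(),
                       gene_groups = NULL,
                       tissue_factor_means = NULL,
                       baseline_log_mean = log(50),
                       baseline_log_sd = 0.7,
                       nb_dispersion = 10,
                       intergenic_gap = 1500L,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    n_te_families = as.integer(n_te_families),
    loci_per_family = as.integer(loci_per_family),
    te_length = as.integer(te_length),
    family_divergence = family_divergence,
    te_context_fractions = te_context_fractions,
    read_len = as.integer(read_len),
    frag_reads_per_sample = as.integer(frag_reads_per_sample),
    retention_fraction = retention_fraction,
    n_samples_per_tissue = as.integer(n_samples_per_tissue),
    n_tissues = as.integer(n_tissues),
    factor_loadings = factor_loadings,
    gene_groups = gene_groups,
    tissue_factor_means = tissue_factor_means,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    nb_dispersion = nb_dispersion,
    intergenic_gap = as.integer(intergenic_gap),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config a `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- c("n_chromosomes", "chrom_length", "exons_per_gene", "exon_length",
              "intron_length", "n_te_families", "loci_per_family", "read_len",
              "frag_reads_per_sample", "n_samples_per_tissue", "n_tissues")
  for (f in counts) {
    if (any(config[[f]] <= 0L)) stop("sim_config: '", f, "' must be positive")
  }
  if (config$n_genes < 0L) stop("sim_config: 'n_genes' must be >= 0")
  if (any(config$te_length <= 0L)) stop("sim_config: 'te_length' must be positive")
  if (any(config$retention_fraction < 0 | config$retention_fraction > 1))
    stop("sim_config: 'retention_fraction' must be in [0, 1]")
  if (any(config$family_divergence < 0 | config$family_divergence > 1))
    stop("sim_config: 'family_divergence' must be in [0, 1]")
  if (config$nb_dispersion <= 0) stop("sim_config: 'nb_dispersion' must be > 0")
  fr <- config$te_context_fractions
  if (is.null(names(fr)) ||
      !all(names(fr) %in% c("intronic", "exonic", "intergenic")))
    stop("sim_config: 'te_context_fractions' must be named intronic/exonic/intergenic")
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    stop("sim_config: 'te_context_fractions' must be non-negative and sum to 1")
  if (length(config$factor_loadings)) {
    vals <- unlist(config$factor_loadings)
    if (any(!is.finite(vals))) stop("sim_config: non-finite factor loadings")
  }
  if (config$exon_length < config$read_len)
    stop("sim_config: exons shorter than read_len cannot emit contained fragments")
  invisible(config)
}

# number of latent factors implied by the loadings (>= 1)
.n_factors <- function(config) {
  n <- max(c(1L, vapply(config$factor_loadings, length, 1L)))
  if (!is.null(config$tissue_factor_means)) n <- max(n, ncol(config$tissue_factor_means))
  n
}

# per-family vectors, recycled from scalars
.family_vec <- function(x, n) {
  if (length(x) == 1L) rep(x, n) else {
    if (length(x) != n) stop("per-family parameter has wrong length")
    x
  }
}
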