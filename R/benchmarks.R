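# Self-contained evaluation scenarios with known ground truth. Each builds
# its synthetic inputs, runs the package's own machinery, and returns the
# measured quantities; tests and scripts/acceptance.R both call these.

#' KZFP x TE family pair universe
#'
#' Builds a family co-expression screen over `n_kzfp` KZFP-like genes and
#' `n_family_expr` TE families, a binding-enrichment table covering
#' `n_family_bound` of those families, and reports the size of the shared
#' universe the association test runs on.
#'
#' @param seed integer seed.
#' @param n_kzfp,n_family_expr,n_family_bound universe dimensions (defaults:
#'   221 assayed KZFPs, 979 expressed families, 909 shared families).
#' @param n_per_tissue,n_tissues samples per tissue and tissue count.
#' @return List: `universe_size`, `n_kzfp`, `n_family`, `fisher_p`.
#' @export
bench_pair_universe <- function(seed = 1, n_kzfp = 221L,
                                n_family_expr = 979L, n_family_bound = 909L,
                                n_per_tissue = 10L, n_tissues = 2L) {
  set.seed(.sub_seed(seed, 11L))
  n <- n_per_tissue * n_tissues
  kz <- matrix(rnorm(n_kzfp * n), n_kzfp, n,
               dimnames = list(sprintf("ZNF%04d", seq_len(n_kzfp)),
                               sprintf("s%03d", seq_len(n))))
  te <- matrix(rnorm(n_family_expr * n), n_family_expr, n,
               dimnames = list(sprintf("FAM%04d", seq_len(n_family_expr)),
                               colnames(kz)))
  tissue <- rep(sprintf("t%d", seq_len(n_tissues)), each = n_per_tissue)
  scr <- pairwise_family_screen(kz, te, tissue, min_samples = 8L)
  enr <- expand.grid(kzfp = rownames(kz),
                     family = rownames(te)[seq_len(n_family_bound)],
                     stringsAsFactors = FALSE)
  enr$score <- stats::runif(nrow(enr), 0, 2)
  ov <- binding_overlap_family(scr, enr, min_tissues = 1L)
  list(universe_size = ov$universe_size, n_kzfp = ov$n_kzfp,
       n_family = ov$n_family, fisher_p = ov$p_value)
}

#' Correction-formula unit suite
#'
#' Evaluates the flanking-depth discount on its three canonical regimes (no
#' intron signal, half discount, zero-out) and on random depth triples,
#' verifying the corrected count always lies in `[0, raw]`.
#'
#' @param seed integer seed.
#' @param n_random number of random triples (default 10000).
#' @return List: the three canonical corrected values and
#'   `fraction_in_bounds` over the random triples.
#' @export
bench_correction_formula <- function(seed = 1, n_random = 10000L) {
  set.seed(.sub_seed(seed, 12L))
  cte <- runif(n_random, 0, 1000)
  rte <- runif(n_random, 1e-6, 2)
  out <- correct_te_count(cte, rte, runif(n_random, 0, 3),
                          runif(n_random, 0, 3))
  list(
    no_discount = correct_te_count(100, 0.1, 0, 0),
    half_discount = correct_te_count(100, 0.1, 0.05, 0.05),
    zero_out = correct_te_count(100, 0.1, 0.15, 0.15),
    fraction_in_bounds = mean(out >= 0 & out <= cte + 1e-12)
  )
}

#' EM versus direct maximum likelihood on small problems
#'
#' Enumerates every two-locus fragment configuration up to `max_frag`
#' fragments and samples three-locus configurations, solves each by direct
#' likelihood maximization over the abundance simplex (coarse grid plus
#' Nelder-Mead/BFGS polish -- independent of the EM iteration), and
#' compares EM expected counts at convergence. Configurations whose ML
#' counts are not unique (flat likelihood ridges) are compared on
#' log-likelihood only.
#'
#' @param seed integer seed (used for the three-locus sampling).
#' @param max_frag fragment budget per configuration (default 20).
#' @param n_three number of sampled three-locus configurations.
#' @return List: `max_count_diff` (worst per-locus count difference on
#'   identifiable configurations), `max_loglik_deficit` (worst EM
#'   log-likelihood shortfall), `n_configs`, `n_identifiable`.
#' @export
bench_em_ml <- function(seed = 1, max_frag = 20L, n_three = 60L) {
  set.seed(.sub_seed(seed, 13L))
  max_diff <- 0; max_ll_def <- 0; n_cfg <- 0L; n_ident <- 0L

  eval_config <- function(sets, n) {
    keep <- n > 0
    sets <- sets[keep]; n <- n[keep]
    if (!length(sets)) return(NULL)
    loci <- sort(unique(unlist(sets)))
    frag_class <- rep(seq_along(sets), n)
    pairs <- data.table::data.table(
      fragment_id = rep(sprintf("f%04d", seq_along(frag_class)),
                        lengths(sets)[frag_class]),
      locus_id = unlist(sets[frag_class])
    )
    fit <- em_assign(pairs, loci = loci, tol = 1e-9, max_iter = 20000L)
    oracle <- .ml_direct(sets, n, loci)
    ll_em <- sum(n * log(vapply(sets, function(s)
      sum(fit$pi[match(s, loci)]), 0)))
    n_cfg <<- n_cfg + 1L
    max_ll_def <<- max(max_ll_def, oracle$loglik - ll_em)
    # multi-start probe for ML-count uniqueness
    alts <- lapply(seq_along(loci), function(k) {
      p0 <- rep(0.05 / max(length(loci) - 1, 1), length(loci)); p0[k] <- 0.95
      .ml_direct(sets, n, loci, start_pi = p0)$counts
    })
    spread <- max(vapply(alts, function(x) max(abs(x - oracle$counts)), 0))
    if (spread < 1e-4) {
      n_ident <<- n_ident + 1L
      max_diff <<- max(max_diff, max(abs(fit$counts - oracle$counts)))
    }
    NULL
  }

  two_sets <- list("A", "B", c("A", "B"))
  for (na in 0:max_frag) for (nb in 0:(max_frag - na))
    for (nab in 0:(max_frag - na - nb)) {
      if (na + nb + nab == 0) next
      eval_config(two_sets, c(na, nb, nab))
    }
  three_sets <- list("A", "B", "C", c("A", "B"), c("A", "C"), c("B", "C"),
                     c("A", "B", "C"))
  for (i in seq_len(n_three)) {
    n <- as.vector(rmultinom(1, sample(5:max_frag, 1), rep(1 / 7, 7)))
    eval_config(three_sets, n)
  }
  list(max_count_diff = max_diff, max_loglik_deficit = max_ll_def,
       n_configs = n_cfg, n_identifiable = n_ident)
}

# direct likelihood maximization used as the EM oracle inside bench_em_ml
.ml_direct <- function(sets, n, loci, start_pi = NULL) {
  k <- length(loci)
  memb <- lapply(sets, function(s) match(s, loci))
  ll <- function(pi) sum(n * log(vapply(memb, function(m) sum(pi[m]), 0)))
  best_pi <- rep(1 / k, k); best_ll <- ll(best_pi)
  if (k == 2) {
    for (a in seq(0.02, 0.98, by = 0.02)) {
      v <- ll(c(a, 1 - a))
      if (v > best_ll) { best_ll <- v; best_pi <- c(a, 1 - a) }
    }
  } else if (k >= 3) {
    for (a in seq(0.05, 0.9, by = 0.05))
      for (b in seq(0.05, max(0.95 - a, 0.05) + 1e-9, by = 0.05)) {
      p <- c(a, b, 1 - a - b)
      v <- ll(p)
      if (v > best_ll) { best_ll <- v; best_pi <- p }
    }
  }
  if (k > 1) {
    obj <- function(theta) {
      pi <- exp(c(theta, 0)); pi <- pi / sum(pi); -ll(pi)
    }
    start <- if (is.null(start_pi)) best_pi else start_pi
    par0 <- log(pmax(start[-k], 1e-8) / max(start[k], 1e-8))
    opt <- if (length(par0) == 1L)
      optim(par0, obj, method = "BFGS",
            control = list(maxit = 5000, reltol = 1e-14))
    else optim(par0, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    pi <- exp(c(opt$par, 0)); pi <- pi / sum(pi)
    if (ll(pi) >= best_ll - 1e-9) { best_pi <- pi; best_ll <- max(best_ll, ll(pi)) }
  }
  counts <- setNames(numeric(k), loci)
  for (i in seq_along(memb)) {
    denom <- sum(best_pi[memb[[i]]])
    counts[memb[[i]]] <- counts[memb[[i]]] + n[i] * best_pi[memb[[i]]] / denom
  }
  list(pi = best_pi, loglik = best_ll, counts = counts)
}

#' Mappability-bias scenario
#'
#' 200 intergenic TE loci of equal true abundance in 20 families whose
#' divergence grades from 0 (fully multi-mapping) to 0.25 (uniquely
#' mappable). Quantifies the same simulated alignments in unique-only and EM
#' modes and correlates per-locus `log2(count + 1)` with uniquely-mappable
#' length: unique-only counting under-counts poorly-mappable copies
#' (positive association), EM assignment does not.
#'
#' @param seed integer seed.
#' @param n_families,loci_per_family locus layout (20 x 10 = 200 loci).
#' @param reads_per_sample,n_samples sequencing effort.
#' @return List: `unique_cor`, `unique_p`, `em_cor`, `em_p`, `n_loci`.
#' @export
bench_mappability_bias <- function(seed = 1, n_families = 20L,
                                   loci_per_family = 10L,
                                   reads_per_sample = 20000L,
                                   n_samples = 3L) {
  cfg <- sim_config(
    seed = .sub_seed(seed, 14L), n_genes = 0L,
    n_te_families = n_families, loci_per_family = loci_per_family,
    te_length = 300L,
    family_divergence = seq(0, 0.25, length.out = n_families),
    te_context_fractions = c(intronic = 0, exonic = 0, intergenic = 1),
    chrom_length = 120000L, n_tissues = 1L,
    n_samples_per_tissue = n_samples,
    frag_reads_per_sample = reads_per_sample,
    baseline_log_sd = 0, nb_dispersion = 100
  )
  ann <- simulate_annotation(cfg)
  truth <- simulate_expression(cfg, ann)
  al <- simulate_alignments(truth, ann, cfg)
  ctx <- classify_te_context(ann$te, ann$genes)
  em <- quantify_te(al$alignments, ctx, mode = "em")
  uo <- quantify_te(al$alignments, ctx, mode = "unique")
  ml <- mappable_length(ann$te, ann$genome, k = cfg$read_len)
  r_u <- mappability_bias_test(uo$counts, ml)
  r_e <- mappability_bias_test(em$counts, ml)
  list(unique_cor = r_u$cor, unique_p = r_u$p_value,
       em_cor = r_e$cor, em_p = r_e$p_value, n_loci = r_u$n)
}

# geometry for the retention scenarios: genes whose single intron hosts a
# full-length (2 kb) TE; `intron_length` sets how roomy the flanks are
.retention_cfg <- function(seed, n_genes, retention_fraction, reads,
                           intron_length = 2800L, baseline_log_sd = 0.7) {
  sim_config(
    seed = seed, n_genes = n_genes, exons_per_gene = 2L,
    exon_length = 200L, intron_length = intron_length,
    n_te_families = 1L, loci_per_family = n_genes, te_length = 2000L,
    family_divergence = 0.2,
    te_context_fractions = c(intronic = 1, exonic = 0, intergenic = 0),
    retention_fraction = retention_fraction,
    n_tissues = 1L, n_samples_per_tissue = 1L,
    frag_reads_per_sample = reads,
    baseline_log_sd = baseline_log_sd,
    chrom_length = n_genes * (intron_length + 4000L) + 4000L
  )
}

#' Retention-correction recovery
#'
#' Two scenarios on intronic full-length TEs. (a) Read-through only: TE
#' loci with zero autonomous transcription under strong intron retention;
#' reports the fraction of locus/sample counts whose corrected value falls
#' below 5% of the raw EM count. (b) Autonomous plus read-through: reports,
#' per seed, total corrected count over total true autonomous fragments;
#' the mean over seeds estimates the corrector's recovery of autonomous
#' expression.
#'
#' @param seed integer seed.
#' @param n_seeds_recovery replicate simulations for scenario (b).
#' @return List: `fraction_below_5pct` (a), `recovery_ratio_mean` and
#'   `recovery_ratios` (b).
#' @export
bench_retention_recovery <- function(seed = 1, n_seeds_recovery = 50L) {
  # (a) read-through only: tight flanks, the common full-length-TE case
  cfg <- .retention_cfg(.sub_seed(seed, 15L), n_genes = 10L,
                        retention_fraction = 0.5, reads = 40000L,
                        intron_length = 2400L)
  ann <- simulate_annotation(cfg)
  truth <- simulate_expression(cfg, ann)
  truth$true_locus_abundance[] <- 0   # no autonomous TE transcription
  al <- simulate_alignments(truth, ann, cfg)
  ctx <- classify_te_context(ann$te, ann$genes)
  q <- quantify_te(al$alignments, ctx, ann$genes, mode = "em")
  corr <- apply_counting_policy(q$counts, ctx, al$alignments,
                                read_len = cfg$read_len)
  nz <- q$counts > 0
  frac_below <- mean(corr$counts[nz] < 0.05 * q$counts[nz])

  # (b) autonomous + read-through, across seeds
  ratios <- vapply(seq_len(n_seeds_recovery), function(i) {
    cfg_i <- .retention_cfg(.sub_seed(seed, 100L + i), n_genes = 5L,
                            retention_fraction = 0.3, reads = 15000L,
                            intron_length = 3200L, baseline_log_sd = 0.4)
    ann_i <- simulate_annotation(cfg_i)
    truth_i <- simulate_expression(cfg_i, ann_i)
    al_i <- simulate_alignments(truth_i, ann_i, cfg_i)
    ctx_i <- classify_te_context(ann_i$te, ann_i$genes)
    q_i <- quantify_te(al_i$alignments, ctx_i, ann_i$genes, mode = "em")
    corr_i <- apply_counting_policy(q_i$counts, ctx_i, al_i$alignments,
                                    read_len = cfg_i$read_len)
    sum(corr_i$counts) / sum(al_i$counts$locus_counts)
  }, 0)
  list(fraction_below_5pct = frac_below,
       recovery_ratio_mean = mean(ratios),
       recovery_ratios = ratios)
}

#' DEGES size-factor recovery
#'
#' Counts with known per-sample sequencing depths and 30% of genes planted
#' 4-fold up in one group. Reports the worst relative error (vs the known
#' depths, both rescaled to geometric mean 1) of the two-step DEGES factors
#' and of plain one-step median-ratio factors.
#'
#' @param seed integer seed.
#' @param n_genes number of genes (default 2000).
#' @return List: `deges_max_rel_error`, `onestep_max_rel_error`.
#' @export
bench_deges <- function(seed = 1, n_genes = 2000L) {
  set.seed(.sub_seed(seed, 16L))
  depths <- c(1, 1.5, 0.7, 1.2, 2, 0.9)
  mu <- stats::rexp(n_genes, 1 / 100)
  m <- sapply(depths, function(d) stats::rpois(n_genes, mu * d))
  dimnames(m) <- list(sprintf("g%05d", seq_len(n_genes)),
                      sprintf("s%02d", seq_along(depths)))
  groups <- rep(c("g1", "g2"), each = 3)
  de <- seq_len(round(0.3 * n_genes))
  m[de, 1:3] <- m[de, 1:3] * 4L

  norm1 <- function(f) f / exp(mean(log(f)))
  truth <- norm1(depths)
  two <- norm1(deges_size_factors(m, groups, drop_fraction = 0.3)$size_factors)
  one <- norm1(median_ratio_size_factors(m)$size_factors)
  list(deges_max_rel_error = max(abs(two - truth) / truth),
       onestep_max_rel_error = max(abs(one - truth) / truth))
}

#' Tissue-clustering recovery
#'
#' Three tissues with distinct planted factor means over 200 intergenic TE
#' loci; UPGMA at k = 3 on the top-150-variance loci of the log2 counts is
#' scored by NMI against the true tissues, alongside the 100-permutation
#' baseline.
#'
#' @param seed integer seed.
#' @param n_per_tissue samples per tissue (default 20, i.e. 60 samples, large
#'   enough that the small-sample bias of NMI between random partitions stays
#'   low).
#' @return List: `nmi`, `perm_nmi_without`, `perm_nmi_with`, `n_samples`.
#' @export
bench_clustering <- function(seed = 1, n_per_tissue = 20L) {
  cfg <- sim_config(
    seed = .sub_seed(seed, 17L), n_genes = 2L, n_te_families = 8L,
    loci_per_family = 25L, te_length = 200L, family_divergence = 0.25,
    te_context_fractions = c(intronic = 0, exonic = 0, intergenic = 1),
    chrom_length = 400000L, n_tissues = 3L,
    n_samples_per_tissue = n_per_tissue,
    factor_loadings = list(FAM01 = c(0.5, 0), FAM02 = c(0, 0.5),
                           FAM03 = c(-0.5, 0), FAM04 = c(0, -0.5)),
    tissue_factor_means = rbind(c(0, 0), c(8, 0), c(0, 8)),
    frag_reads_per_sample = 60000L
  )
  ann <- simulate_annotation(cfg)
  truth <- simulate_expression(cfg, ann)
  counts <- draw_counts(truth, cfg)$locus_counts
  lab <- setNames(truth$samples$tissue, truth$samples$sample_id)
  res <- evaluate_clustering(log_transform(counts), lab, k = 3L, n = 150L,
                             raw_counts = counts)
  base <- permutation_baseline(unname(lab), reps = 100L,
                               seed = .sub_seed(seed, 18L))
  list(nmi = res$nmi,
       perm_nmi_without = base[["without_replacement"]],
       perm_nmi_with = base[["with_replacement"]],
       n_samples = length(lab))
}

#' Consensus-network block recovery
#'
#' Two tissues x 50 samples x 300 features in two planted 150-feature
#' blocks (within-block correlation 0.9, between 0). Builds the signed
#' power-14 consensus TOM, detects modules, and reports the Rand index
#' against the planted split and the worst eigengene-factor correlation.
#'
#' @param seed integer seed.
#' @param n_per_block,n_samples layout (150 x 2 features, 50 samples per
#'   tissue).
#' @return List: `rand_index`, `eigengene_factor_cor`, `n_modules`.
#' @export
bench_network <- function(seed = 1, n_per_block = 150L, n_samples = 50L) {
  set.seed(.sub_seed(seed, 19L))
  feat <- c(sprintf("blk1_%03d", seq_len(n_per_block)),
            sprintf("blk2_%03d", seq_len(n_per_block)))
  factors <- list()
  mk <- function(t_) {
    f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
    factors[[t_]] <<- cbind(f1, f2)
    m <- rbind(
      t(vapply(seq_len(n_per_block),
               function(i) 3 * f1 + rnorm(n_samples), numeric(n_samples))),
      t(vapply(seq_len(n_per_block),
               function(i) 3 * f2 + rnorm(n_samples), numeric(n_samples)))
    )
    dimnames(m) <- list(feat, sprintf("%s_s%03d", t_, seq_len(n_samples)))
    m
  }
  mats <- list(t1 = mk("t1"), t2 = mk("t2"))
  net <- consensus_network(mats, beta = 14, min_module_size = 30L)

  truth <- rep(1:2, each = n_per_block)
  mods <- net$modules[feat]
  pairs <- utils::combn(length(feat), 2L)
  same_t <- truth[pairs[1, ]] == truth[pairs[2, ]]
  same_m <- mods[pairs[1, ]] == mods[pairs[2, ]]
  rand <- mean(same_t == same_m)

  cors <- vapply(1:2, function(b) {
    blk <- feat[truth == b]
    mod <- as.integer(names(which.max(table(mods[blk]))))
    if (mod == 0) return(0)
    eg <- eigengene(mats$t1, names(mods)[mods == mod])
    abs(cor(eg, factors$t1[, b]))
  }, 0)
  list(rand_index = rand, eigengene_factor_cor = min(cors),
       n_modules = length(setdiff(unique(mods), 0L)))
}

#' Screen calibration: FDR, power and AICc covariate recovery
#'
#' (a) Repeated family screens with 1000 null pairs and 50 pairs planted at
#' r = 0.6 (n = 50 samples): empirical FDR (false discoveries over
#' discoveries at q < 0.05) and power on the planted pairs, averaged over
#' replicates. (b) AICc all-subsets selection at n = 100 with three active
#' covariates out of four and residual SD half the signal SD: fraction of
#' replicates recovering exactly the active set.
#'
#' @param seed integer seed.
#' @param n_reps_fdr,n_reps_aicc replicate counts.
#' @return List: `fdr`, `power`, `aicc_recovery`, `n_null`, `n_planted`.
#' @export
bench_screen_calibration <- function(seed = 1, n_reps_fdr = 30L,
                                     n_reps_aicc = 150L) {
  set.seed(.sub_seed(seed, 20L))
  n_kz <- 21L; n_fam <- 50L; n <- 50L; r <- 0.6
  planted <- data.frame(kz = rep(seq_len(n_kz), length.out = 50L),
                        fam = seq_len(50L))
  fdr <- numeric(n_reps_fdr); pow <- numeric(n_reps_fdr)
  for (i in seq_len(n_reps_fdr)) {
    kz <- matrix(rnorm(n_kz * n), n_kz, n,
                 dimnames = list(sprintf("Z%02d", seq_len(n_kz)),
                                 sprintf("s%03d", seq_len(n))))
    te <- matrix(rnorm(n_fam * n), n_fam, n,
                 dimnames = list(sprintf("F%02d", seq_len(n_fam)),
                                 colnames(kz)))
    for (j in seq_len(nrow(planted))) {
      zk <- scale(kz[planted$kz[j], ])[, 1]
      te[planted$fam[j], ] <- r * zk + sqrt(1 - r^2) * rnorm(n)
    }
    scr <- pairwise_family_screen(kz, te, rep("t1", n))
    res <- scr$result
    key <- paste(res$predictor, res$response)
    pkey <- paste(sprintf("Z%02d", planted$kz), sprintf("F%02d", planted$fam))
    is_planted <- key %in% pkey
    disc <- res$significant
    fdr[i] <- sum(disc & !is_planted) / max(sum(disc), 1L)
    pow[i] <- mean(res$significant[is_planted])
  }

  hits <- 0L
  for (i in seq_len(n_reps_aicc)) {
    n2 <- 100L
    gene <- rnorm(n2)
    covs <- data.frame(lib = rnorm(n2), batch = rnorm(n2), rad = rnorm(n2),
                       n1 = rnorm(n2))
    signal <- gene + 0.8 * covs$lib + 0.8 * covs$batch + 0.8 * covs$rad
    y <- signal + rnorm(n2, 0, sd(signal) / 2)
    gm <- matrix(gene, 1, n2, dimnames = list("G", sprintf("s%03d", 1:n2)))
    scr <- l1hs_gene_screen(gm, setNames(y, colnames(gm)), covs,
                            rep("t1", n2), q_threshold = 0.5,
                            min_tissues = 1L)
    sel <- sort(strsplit(scr$result$covariates, "+", fixed = TRUE)[[1]])
    if (identical(sel, c("batch", "lib", "rad"))) hits <- hits + 1L
  }
  list(fdr = mean(fdr), power = mean(pow),
       aicc_recovery = hits / n_reps_aicc,
       n_null = n_kz * n_fam - 50L, n_planted = 50L)
}
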