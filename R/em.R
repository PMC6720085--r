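#' Ingest alignments into per-fragment TE candidate sets
#'
#' Intersects every alignment with the TE annotation (an alignment hits a
#' locus when they overlap by at least one base). Alignments overlapping a
#' gene exon but no TE locus are removed from the candidate set; fragments
#' whose every alignment is exonic non-TE are excluded, as are fragments with
#' multiplicity above `multimap_cap`.
#'
#' @param aln alignment `data.table` (from [read_alignments()] or the
#'   `alignments` element of [simulate_alignments()]), for one sample.
#' @param te TE locus table.
#' @param genes optional [gene_models()] object used for the exon filter.
#' @param multimap_cap maximum multiplicity (default 200).
#' @return A list of class `"tecoex_alnsets"`: `pairs` (`data.table` of
#'   unique `fragment_id`/`locus_id` candidates), `multiplicity` (named
#'   integer per fragment), and `stats` (fragments ingested, dropped at the
#'   cap, removed as exonic-only).
#' @export
ingest_alignments <- function(aln, te, genes = NULL, multimap_cap = 200L) {
  aln <- data.table::as.data.table(aln)
  if (!nrow(aln))
    return(structure(list(pairs = data.table::data.table(
      fragment_id = character(0), locus_id = character(0)),
      multiplicity = integer(0),
      stats = list(n_ingested = 0L, n_dropped_cap = 0L, n_exonic_only = 0L)),
      class = "tecoex_alnsets"))
  if (!"nh" %in% names(aln)) aln[, nh := 1L]
  aln[is.na(nh), nh := 1L]
  over <- aln$nh > multimap_cap
  n_cap <- length(unique(aln$fragment_id[over]))
  aln <- aln[!over]

  aln_gr <- GenomicRanges::GRanges(aln$chrom,
                                   IRanges::IRanges(aln$pos0 + 1L,
                                                    aln$pos0 + aln$width))
  te_gr <- .gr0(te[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(aln_gr, te_gr, ignore.strand = TRUE)
  te_hit <- rep(FALSE, nrow(aln))
  te_hit[unique(S4Vectors::queryHits(hits))] <- TRUE

  exon_hit <- rep(FALSE, nrow(aln))
  if (!is.null(genes) && nrow(genes$exons)) {
    ex_gr <- .gr0(genes$exons[, c("chrom", "start", "end")])
    exon_hit <- IRanges::overlapsAny(aln_gr, ex_gr, ignore.strand = TRUE)
  }
  # an alignment landing in an exon without touching a TE contributes no
  # candidate; fragments whose alignments are all exonic non-TE drop out here
  frag_has_te <- unique(aln$fragment_id[te_hit])
  no_te <- setdiff(unique(aln$fragment_id), frag_has_te)
  all_exonic <- tapply(exon_hit, aln$fragment_id, all)
  n_exonic_only <- sum(all_exonic[no_te], na.rm = TRUE)

  pairs <- data.table::data.table(
    fragment_id = aln$fragment_id[S4Vectors::queryHits(hits)],
    locus_id = te$locus_id[S4Vectors::subjectHits(hits)]
  )
  pairs <- unique(pairs)
  mult <- aln[fragment_id %in% frag_has_te,
              .(nh = max(nh, .N)), by = fragment_id]
  structure(
    list(pairs = pairs,
         multiplicity = setNames(mult$nh, mult$fragment_id),
         stats = list(n_ingested = length(frag_has_te),
                      n_dropped_cap = n_cap,
                      n_exonic_only = n_exonic_only)),
    class = "tecoex_alnsets"
  )
}

#' EM assignment of multi-mapped fragments to TE loci
#'
#' Multinomial-mixture model: fragment `i` with candidate loci `A_i` and
#' locus abundances `pi`; the E-step gives weights
#' `w_il = pi_l / sum(pi_l', l' in A_i)` and the M-step sets
#' `pi_l` proportional to `sum_i w_il`. Initialization is uniform; iteration
#' stops when the largest per-locus count change falls below `tol` or after
#' `max_iter` iterations. Returned counts are the summed weights, so total
#' mass equals the number of fragments exactly.
#'
#' @param alnsets a `tecoex_alnsets` object, or a `data.table` of
#'   `fragment_id`/`locus_id` candidate pairs.
#' @param loci optional character vector fixing the locus universe (loci
#'   without candidate fragments receive count 0).
#' @param tol convergence tolerance on per-locus counts (default 1e-3).
#' @param max_iter iteration cap (default 100).
#' @return A list of class `"tecoex_em"`: `counts` (named numeric),
#'   `pi` (relative abundances), `iterations`, `loglik` (trace of the
#'   observed-data log-likelihood, non-decreasing).
#' @export
em_assign <- function(alnsets, loci = NULL, tol = 1e-3, max_iter = 100L) {
  pairs <- if (inherits(alnsets, "tecoex_alnsets")) alnsets$pairs
           else data.table::as.data.table(alnsets)
  if (is.null(loci)) loci <- sort(unique(pairs$locus_id))
  counts0 <- setNames(numeric(length(loci)), loci)
  if (!nrow(pairs))
    return(structure(list(counts = counts0, pi = counts0, iterations = 0L,
                          loglik = numeric(0)), class = "tecoex_em"))

  # collapse fragments into equivalence classes by candidate-set signature
  pairs <- pairs[order(fragment_id, locus_id)]
  sig_by_frag <- pairs[, .(sig = paste(locus_id, collapse = "\r")),
                       by = fragment_id]
  cls <- sig_by_frag[, .(n = .N), by = sig]
  cls_loci <- strsplit(cls$sig, "\r", fixed = TRUE)
  long <- data.table::data.table(
    class_id = rep(seq_len(nrow(cls)), lengths(cls_loci)),
    locus = match(unlist(cls_loci), loci)
  )
  if (anyNA(long$locus)) stop("candidate locus outside the supplied universe")
  n_frag <- sum(cls$n)
  n_c <- cls$n

  pi <- rep(1 / length(loci), length(loci))
  counts <- setNames(rep(n_frag / length(loci), length(loci)), loci)
  loglik <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- pi[long$locus]
    denom <- rowsum(p, long$class_id)[, 1]
    loglik <- c(loglik, sum(n_c * log(denom)))
    w <- p / denom[long$class_id] * n_c[long$class_id]
    new_counts <- setNames(numeric(length(loci)), loci)
    agg <- rowsum(w, long$locus)
    new_counts[as.integer(rownames(agg))] <- agg[, 1]
    names(new_counts) <- loci
    delta <- max(abs(new_counts - counts))
    counts <- new_counts
    pi <- counts / n_frag
    if (delta < tol || iter >= max_iter) break
  }
  structure(list(counts = counts, pi = pi, iterations = iter,
                 loglik = loglik), class = "tecoex_em")
}

#' Unique-fragment locus counts
#'
#' Counts only fragments with alignment multiplicity 1 (single-best-alignment
#' semantics: any multi-mapped fragment is discarded entirely). Per-locus
#' unique counts never exceed the EM counts on the same data.
#'
#' @inheritParams em_assign
#' @param alnsets a `tecoex_alnsets` object from [ingest_alignments()].
#' @return Named numeric vector of per-locus counts.
#' @export
unique_only_counts <- function(alnsets, loci = NULL) {
  stopifnot(inherits(alnsets, "tecoex_alnsets"))
  uniq <- names(alnsets$multiplicity)[alnsets$multiplicity == 1L]
  pairs <- alnsets$pairs[fragment_id %in% uniq]
  if (is.null(loci)) loci <- sort(unique(alnsets$pairs$locus_id))
  tab <- table(factor(pairs$locus_id, levels = loci))
  setNames(as.numeric(tab), loci)
}

#' Aggregate locus counts to family counts
#'
#' Family count is the sum over the family's non-exonic loci; exonic loci
#' contribute nothing to the family level.
#'
#' @param locus_counts matrix (loci x samples) or named vector.
#' @param te TE table with `locus_id`, `family` and (optionally) `context`.
#' @return Matrix (families x samples) or named vector.
#' @export
aggregate_family <- function(locus_counts, te) {
  vec_in <- is.null(dim(locus_counts))
  m <- if (vec_in) matrix(locus_counts, ncol = 1,
                          dimnames = list(names(locus_counts), "s1"))
       else as.matrix(locus_counts)
  fam <- te$family[match(rownames(m), te$locus_id)]
  if (anyNA(fam)) stop("locus without a family in the TE table")
  w <- rep(1, nrow(m))
  if ("context" %in% names(te))
    w[te$context[match(rownames(m), te$locus_id)] == "exonic"] <- 0
  out <- rowsum(m * w, fam)
  if (vec_in) setNames(out[, 1], rownames(out)) else out
}

#' L1HS-style 5' end fragment count
#'
#' Sums, over fragments, the EM weight falling on candidate alignments that
#' overlap a 5' region. Regions are given in locus coordinates and are lifted
#' to the genome using the TE table (strand-aware: on minus-strand loci the
#' 5' window sits at the genomic end of the locus).
#'
#' @param alnsets `tecoex_alnsets` for one sample.
#' @param em fitted `tecoex_em` for the same sample.
#' @param regions output of [l1hs_five_prime_regions()].
#' @param te TE locus table with genomic coordinates and strand.
#' @param aln the raw alignment table for the sample (needed for alignment
#'   positions).
#' @return A single number: the summed 5'-end EM weight.
#' @export
count_l1hs_5prime <- function(alnsets, em, regions, te, aln) {
  if (!nrow(regions)) {
    warning("empty 5' region set; returning 0")
    return(0)
  }
  i <- match(regions$locus_id, te$locus_id)
  plus <- te$strand[i] != "-"
  gstart <- ifelse(plus, te$start[i] + regions$start,
                   te$end[i] - regions$end)
  gend <- ifelse(plus, te$start[i] + regions$end,
                 te$end[i] - regions$start)
  reg_gr <- GenomicRanges::GRanges(te$chrom[i],
                                   IRanges::IRanges(gstart + 1L, gend))
  aln <- data.table::as.data.table(aln)
  aln_gr <- GenomicRanges::GRanges(aln$chrom,
                                   IRanges::IRanges(aln$pos0 + 1L,
                                                    aln$pos0 + aln$width))
  in_region <- IRanges::overlapsAny(aln_gr, reg_gr, ignore.strand = TRUE)
  if (!any(in_region)) return(0)

  # locus of each in-region alignment
  te_gr <- .gr0(te[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(aln_gr[in_region], te_gr,
                                      ignore.strand = TRUE)
  touched <- unique(data.table::data.table(
    fragment_id = aln$fragment_id[in_region][S4Vectors::queryHits(hits)],
    locus_id = te$locus_id[S4Vectors::subjectHits(hits)]
  ))
  # EM weight of fragment on locus: pi_l / sum(pi over candidate set)
  pairs <- alnsets$pairs
  pv <- em$pi[pairs$locus_id]
  denom <- rowsum(pv, pairs$fragment_id)
  wtab <- data.table::data.table(
    fragment_id = pairs$fragment_id, locus_id = pairs$locus_id,
    w = pv / denom[pairs$fragment_id, 1]
  )
  hit_w <- merge(touched, wtab, by = c("fragment_id", "locus_id"))
  sum(hit_w$w)
}

#' Mappability-bias diagnostic
#'
#' Pearson correlation (with two-sided p-value) and regression slope between
#' per-locus `log2(count + 1)` -- counts summed across samples -- and the
#' uniquely-mappable length of each locus. Equal-abundance loci quantified
#' from uniquely mapped reads show a strong positive association (young,
#' poorly mappable copies lose reads), while EM-assigned counts should not.
#'
#' @param locus_counts matrix (loci x samples) or named vector of counts.
#' @param mappable_lengths named vector from [mappable_length()].
#' @param min_loci minimum number of loci (default 10).
#' @return List with `slope`, `cor`, `p_value`, `n`, `degenerate`.
#' @export
mappability_bias_test <- function(locus_counts, mappable_lengths,
                                  min_loci = 10L) {
  y <- if (is.null(dim(locus_counts))) locus_counts
       else rowSums(as.matrix(locus_counts))
  common <- intersect(names(y), names(mappable_lengths))
  if (length(common) < min_loci) stop("need at least ", min_loci, " loci")
  ylog <- log2(y[common] + 1)
  x <- as.numeric(mappable_lengths[common])
  if (sd(x) == 0 || sd(ylog) == 0)
    return(list(slope = NA_real_, cor = NA_real_, p_value = NA_real_,
                n = length(common), degenerate = TRUE))
  ct <- cor.test(x, ylog)
  list(slope = unname(coef(lm(ylog ~ x))[2]), cor = unname(ct$estimate),
       p_value = ct$p.value, n = length(common), degenerate = FALSE)
}

#' Quantify TE expression across samples
#'
#' Convenience wrapper running [ingest_alignments()] plus [em_assign()] (or
#' [unique_only_counts()]) per sample and assembling a loci x samples count
#' matrix.
#'
#' @param aln alignment table covering one or more samples (column
#'   `sample_id`).
#' @param te TE locus table.
#' @param genes optional [gene_models()] for the exon filter.
#' @param mode `"em"` or `"unique"`.
#' @param multimap_cap maximum multiplicity (default 200).
#' @return List: `counts` (loci x samples matrix, stage `raw_em` or
#'   `unique_only`), `qc` (per-sample ingestion stats), `fits` (per-sample
#'   `tecoex_em` fits, EM mode only), `alnsets` (per-sample candidate sets).
#' @export
quantify_te <- function(aln, te, genes = NULL, mode = c("em", "unique"),
                        multimap_cap = 200L) {
  mode <- match.arg(mode)
  aln <- data.table::as.data.table(aln)
  samples <- sort(unique(aln$sample_id))
  loci <- te$locus_id
  counts <- matrix(0, length(loci), length(samples),
                   dimnames = list(loci, samples))
  qc <- list(); fits <- list(); sets <- list()
  for (s in samples) {
    as_ <- ingest_alignments(aln[sample_id == s], te, genes, multimap_cap)
    sets[[s]] <- as_
    qc[[s]] <- as_$stats
    if (mode == "em") {
      fit <- em_assign(as_, loci = loci)
      fits[[s]] <- fit
      counts[, s] <- fit$counts
      qc[[s]]$em_iterations <- fit$iterations
    } else {
      counts[, s] <- unique_only_counts(as_, loci = loci)
    }
  }
  structure(list(counts = counts, qc = qc, fits = fits, alnsets = sets,
                 stage = if (mode == "em") "raw_em" else "unique_only"),
            class = "tecoex_quant")
}
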