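#' Read depth over an interval
#'
#' Depth in reads per effective base: `count / (length - read_len)`. The
#' effective length discounts the positions near the interval end where a
#' read of `read_len` bases can no longer start while staying inside.
#'
#' @param count number of reads mapped to the interval.
#' @param length interval length in bases; must exceed `read_len`.
#' @param read_len sequencing read length in bases.
#' @return `count / (length - read_len)`.
#' @export
read_depth <- function(count, length, read_len = 48L) {
  if (any(count < 0)) stop("count must be >= 0")
  if (any(length <= read_len))
    stop("depth undefined: interval length must exceed read_len")
  count / (length - read_len)
}

# fallback used inside the correction: intervals not longer than the read
# use plain count/length so the depth stays finite
.depth_fallback <- function(count, length, read_len) {
  ifelse(length > read_len, count / (length - read_len), count / length)
}

#' Discount a TE count by flanking-intron read depth
#'
#' Read-through (pre-mRNA or retained-intron) transcription covers a TE and
#' its flanking introns at similar depth, so the flank depth estimates the
#' read-through share of the TE's count:
#' `count' = count - count * (R_IL + R_IR) / (2 * R_TE)` when that ratio is
#' below 1, and 0 otherwise. The corrected count always lies in
#' `[0, count]`.
#'
#' @param count_te TE read count (EM-weighted).
#' @param r_te TE read depth from [read_depth()].
#' @param r_il,r_ir left/right flanking-intron read depths.
#' @return Corrected count(s); vectorized.
#' @export
correct_te_count <- function(count_te, r_te, r_il, r_ir) {
  ratio <- ifelse(r_te > 0, (r_il + r_ir) / (2 * r_te), 0)
  out <- ifelse(ratio < 1, count_te * (1 - ratio), 0)
  pmin(pmax(out, 0), count_te)
}

#' Per-sample flanking-intron fragment counts for intronic TEs
#'
#' A fragment contributes 1 to a flank count when at least one of its
#' alignments overlaps the flanking-intron interval (the intron portion left
#' or right of the TE, which by construction excludes the TE itself) by at
#' least one base -- regardless of its multiplicity, so multi-mapped
#' fragments are included.
#'
#' @param aln alignment table for one sample.
#' @param te contexted TE table from [classify_te_context()].
#' @return `data.table` with `locus_id`, `count_il`, `count_ir` (`NA` where
#'   the corresponding flank is absent).
#' @export
intron_counts <- function(aln, te) {
  intr <- te[te$context == "intronic", , drop = FALSE]
  out <- data.table::data.table(locus_id = intr$locus_id,
                                count_il = NA_real_, count_ir = NA_real_)
  if (!nrow(intr)) return(out)
  aln <- data.table::as.data.table(aln)
  aln_gr <- GenomicRanges::GRanges(aln$chrom,
                                   IRanges::IRanges(aln$pos0 + 1L,
                                                    aln$pos0 + aln$width))
  count_side <- function(starts, ends) {
    ok <- which(!is.na(starts) & ends > starts)
    res <- rep(NA_real_, nrow(intr))
    if (!length(ok)) return(res)
    gr <- GenomicRanges::GRanges(intr$chrom[ok],
                                 IRanges::IRanges(starts[ok] + 1L, ends[ok]))
    hits <- GenomicRanges::findOverlaps(aln_gr, gr, ignore.strand = TRUE)
    tab <- data.table::data.table(
      fragment_id = aln$fragment_id[S4Vectors::queryHits(hits)],
      side = S4Vectors::subjectHits(hits))
    tab <- unique(tab)
    cnt <- tab[, .N, by = side]
    res[ok] <- 0
    res[ok[cnt$side]] <- cnt$N
    res
  }
  out$count_il <- count_side(intr$left_intron_start, intr$left_intron_end)
  out$count_ir <- count_side(intr$right_intron_start, intr$right_intron_end)
  out
}

#' Apply the exonic/intronic/intergenic counting policy
#'
#' Intronic loci are discounted with [correct_te_count()] using the
#' flanking-intron depths of each sample; intergenic (and proximal) loci keep
#' their EM counts; exonic loci are zeroed and never contribute to family
#' counts. When only one flank exists, its depth stands in for both sides
#' (flagged). Counts may be fractional.
#'
#' @param locus_counts EM locus count matrix (loci x samples).
#' @param te contexted TE table from [classify_te_context()].
#' @param aln alignment table covering the same samples (column `sample_id`).
#' @param read_len read length in bases (default 48).
#' @return List: `counts` (corrected matrix, stage `corrected`), `report`
#'   (per locus: context, per-sample raw and corrected totals, depths of the
#'   maximally-corrected sample, `max_correction`, flags).
#' @export
apply_counting_policy <- function(locus_counts, te, aln, read_len = 48L) {
  if (!"context" %in% names(te)) stop("TE table has no context column")
  m <- as.matrix(locus_counts)
  idx <- match(rownames(m), te$locus_id)
  if (anyNA(idx)) stop("count matrix contains loci absent from the TE table")
  ctx <- te$context[idx]
  if (anyNA(ctx)) stop("missing context for some loci")
  corrected <- m
  corrected[ctx == "exonic", ] <- 0

  aln <- data.table::as.data.table(aln)
  samples <- colnames(m)
  intr_rows <- which(ctx == "intronic")
  rep_list <- list()
  if (length(intr_rows)) {
    tei <- te[idx[intr_rows], , drop = FALSE]
    len_te <- tei$end - tei$start
    len_il <- tei$left_intron_end - tei$left_intron_start
    len_ir <- tei$right_intron_end - tei$right_intron_start
    for (s in samples) {
      ic <- intron_counts(aln[sample_id == s], tei)
      stopifnot(identical(ic$locus_id, tei$locus_id))
      cil <- ic$count_il; cir <- ic$count_ir
      r_il <- .depth_fallback(cil, len_il, read_len)
      r_ir <- .depth_fallback(cir, len_ir, read_len)
      single <- is.na(r_il) | is.na(r_ir)
      r_il2 <- ifelse(is.na(r_il), r_ir, r_il)
      r_ir2 <- ifelse(is.na(r_ir), r_il, r_ir)
      none <- is.na(r_il2) & is.na(r_ir2)
      r_il2[none] <- 0; r_ir2[none] <- 0
      cte <- m[intr_rows, s]
      r_te <- .depth_fallback(cte, len_te, read_len)
      corrected[intr_rows, s] <- correct_te_count(cte, r_te, r_il2, r_ir2)
      rep_list[[s]] <- data.table::data.table(
        locus_id = tei$locus_id, sample_id = s, raw = cte,
        corrected = corrected[intr_rows, s],
        r_te = r_te, r_il = r_il2, r_ir = r_ir2,
        single_flank = single, no_flank = none
      )
    }
  }
  per_sample <- data.table::rbindlist(rep_list)
  report <- if (nrow(per_sample)) {
    per_sample[, .(
      context = "intronic",
      raw_total = sum(raw), corrected_total = sum(corrected),
      max_correction = max(raw - corrected),
      single_flank = any(single_flank), no_flank = any(no_flank)
    ), by = locus_id]
  } else {
    data.table::data.table(locus_id = character(0), context = character(0),
                           raw_total = numeric(0), corrected_total = numeric(0),
                           max_correction = numeric(0),
                           single_flank = logical(0), no_flank = logical(0))
  }
  list(counts = corrected, report = report, per_sample = per_sample,
       stage = "corrected")
}
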