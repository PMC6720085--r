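#' Simulate multi-mapped alignments from ground-truth expression
#'
#' Draws negative-binomial fragment counts from the expectations in `truth`
#' and emits single-end fragments of length `read_len`:
#' autonomous TE fragments start uniformly within the locus (and may run past
#' its end by at most `read_len - 1` bases), read-through fragments are
#' contained in an intron of their gene and tile it uniformly (covering any
#' embedded TE), and mature gene fragments are contained in an exon. Each
#' fragment is then reported at every genomic position whose sequence matches
#' it exactly on either strand; the number of such positions is the recorded
#' alignment multiplicity (NH). Fragments with multiplicity above
#' `multimap_cap` are dropped and tallied.
#'
#' @param truth a `tecoex_truth` object from [simulate_expression()].
#' @param annotation the matching `tecoex_annotation`.
#' @param config the matching [sim_config()].
#' @param out_dir optional directory; when given, one SAM file per sample is
#'   written (minimal header, FLAG 0/16, `NH:i:` multiplicity tag, secondary
#'   alignments flagged 0x100). Output is byte-identical under a fixed seed.
#' @param multimap_cap maximum reported multiplicity (default 200).
#' @param emit_gene_reads emit mature (exon-contained) gene fragments too.
#' @return A list of class `"tecoex_alignments"`: `alignments` (a
#'   `data.table` with `sample_id`, `fragment_id`, `chrom`, `pos0`, `width`,
#'   `strand`, `nh`, `origin`, `origin_id`), `counts` (the NB-drawn totals
#'   from [draw_counts()]), `n_dropped_cap` per sample, `sam_paths`.
#' @export
simulate_alignments <- function(truth, annotation, config = truth$config,
                                out_dir = NULL, multimap_cap = 200L,
                                emit_gene_reads = TRUE) {
  r <- config$read_len
  counts <- draw_counts(truth, config)
  set.seed(.sub_seed(config$seed, 3L))
  idx <- .kmer_index(annotation$genome, r)
  genome_chr <- setNames(as.character(annotation$genome),
                         names(annotation$genome))
  te <- annotation$te
  introns <- annotation$genes$introns
  exons <- annotation$genes$exons
  samples <- truth$samples$sample_id

  all_aln <- list(); n_dropped <- setNames(integer(length(samples)), samples)
  sam_paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sam_paths <- setNames(file.path(out_dir, paste0(samples, ".sam")), samples)
  }

  for (s in samples) {
    frs <- list()
    # autonomous TE fragments: start anywhere in [start, end)
    lc <- counts$locus_counts[, s]
    if (length(lc) && sum(lc) > 0) {
      li <- rep(seq_len(nrow(te)), lc)
      len <- te$end[li] - te$start[li]
      frs$te <- data.table::data.table(
        chrom = te$chrom[li],
        pos0 = te$start[li] + floor(runif(length(li)) * len),
        origin = "te", origin_id = te$locus_id[li]
      )
    }
    # read-through fragments: contained in an intron, uniform coverage
    rc_ <- setNames(counts$retention_counts[, s],
                    rownames(counts$retention_counts))
    if (length(rc_) && sum(rc_) > 0 && nrow(introns)) {
      for (g in names(rc_)[rc_ > 0]) {
        gi <- introns[introns$gene_id == g, , drop = FALSE]
        if (!nrow(gi)) next
        npos <- pmax(gi$end - gi$start - r + 1L, 0L)
        if (sum(npos) == 0L) next
        alloc <- as.vector(rmultinom(1L, rc_[g], prob = npos))
        ii <- rep(seq_len(nrow(gi)), alloc)
        frs[[paste0("ret_", g)]] <- data.table::data.table(
          chrom = gi$chrom[ii],
          pos0 = gi$start[ii] + floor(runif(length(ii)) * npos[ii]),
          origin = "retention", origin_id = g
        )
      }
    }
    # mature gene fragments: contained in an exon
    gc_ <- setNames(counts$gene_counts[, s], rownames(counts$gene_counts))
    if (emit_gene_reads && length(gc_) && sum(gc_) > 0 && nrow(exons)) {
      for (g in names(gc_)[gc_ > 0]) {
        ge <- exons[exons$gene_id == g, , drop = FALSE]
        npos <- pmax(ge$end - ge$start - r + 1L, 0L)
        if (sum(npos) == 0L) next
        alloc <- as.vector(rmultinom(1L, gc_[g], prob = npos))
        ii <- rep(seq_len(nrow(ge)), alloc)
        frs[[paste0("gene_", g)]] <- data.table::data.table(
          chrom = ge$chrom[ii],
          pos0 = ge$start[ii] + floor(runif(length(ii)) * npos[ii]),
          origin = "gene", origin_id = g
        )
      }
    }
    fr <- data.table::rbindlist(frs)
    if (!nrow(fr)) next
    fr[, fragment_id := sprintf("%s_f%07d", s, seq_len(.N))]
    fr[, seqs := substring(genome_chr[chrom], pos0 + 1L, pos0 + r)]
    fr[, flip := runif(.N) < 0.5]

    # exact-match alignment discovery on both strands
    fwd <- idx[fr[, .(kmer = seqs, fragment_id, flip)], nomatch = NULL,
               on = "kmer"]
    fwd[, strand := ifelse(flip, "-", "+")]
    rcq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(fr$seqs)))
    rev <- idx[data.table::data.table(kmer = rcq, fragment_id = fr$fragment_id,
                                      flip = fr$flip), nomatch = NULL,
               on = "kmer"]
    rev[, strand := ifelse(flip, "+", "-")]
    aln <- data.table::rbindlist(list(fwd, rev))[, .(fragment_id, chrom, pos0, strand)]
    aln[, nh := .N, by = fragment_id]
    over <- aln$nh > multimap_cap
    n_dropped[s] <- length(unique(aln$fragment_id[over]))
    aln <- aln[!over]
    aln <- merge(aln, fr[, .(fragment_id, origin, origin_id)],
                 by = "fragment_id", sort = FALSE)
    aln[, `:=`(sample_id = s, width = r)]
    data.table::setorder(aln, fragment_id, chrom, pos0)
    all_aln[[s]] <- aln
    if (!is.null(out_dir))
      .write_sam(aln, genome_chr, sam_paths[[s]], r)
  }

  aln <- data.table::rbindlist(all_aln)
  structure(
    list(alignments = aln, counts = counts, n_dropped_cap = n_dropped,
         sam_paths = sam_paths, read_len = r),
    class = "tecoex_alignments"
  )
}

# minimal SAM writer: FLAG 0/16 (+0x100 for secondary lines), NH tag
.write_sam <- function(aln, genome_chr, path, read_len) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome_chr),
                   nchar(genome_chr)))
  a <- data.table::copy(aln)
  a[, sec := seq_len(.N) > 1L, by = fragment_id]
  flag <- ifelse(a$strand == "-", 16L, 0L) + ifelse(a$sec, 256L, 0L)
  seqf <- substring(genome_chr[a$chrom], a$pos0 + 1L, a$pos0 + read_len)
  lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                   a$fragment_id, flag, a$chrom, a$pos0 + 1L, read_len,
                   seqf, a$nh)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an alignment file into the package's alignment table
#'
#' SAM files are converted with [Rsamtools::asBam()] and read with
#' [Rsamtools::scanBam()]; BAM files are read directly. Records missing the
#' NH tag are treated as having multiplicity 1; when the observed number of
#' records for a fragment exceeds its NH tag, the observed number is used.
#'
#' @param path SAM or BAM file path.
#' @param sample_id sample label attached to the records (default: file stem).
#' @return A `data.table` with columns `sample_id`, `fragment_id`, `chrom`,
#'   `pos0`, `width`, `strand`, `nh`.
#' @export
read_alignments <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth"), tag = "NH")
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  nh <- b$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(b$qname))
  dt <- data.table::data.table(
    sample_id = sample_id,
    fragment_id = b$qname[keep],
    chrom = as.character(b$rname[keep]),
    pos0 = b$pos[keep] - 1L,
    width = b$qwidth[keep],
    strand = ifelse(bitwAnd(b$flag[keep], 16L) > 0L, "-", "+"),
    nh = nh[keep]
  )
  dt[is.na(nh), nh := 1L]
  dt[, nh := pmax(nh, .N), by = fragment_id]
  dt[]
}
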