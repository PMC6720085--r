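#' Gene models from an exon table
#'
#' Orders exons per gene, derives introns as the gaps between consecutive
#' exons, and records each gene's span. All coordinates are 0-based half-open.
#'
#' @param exons data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `exon_rank`.
#' @return A list of class `"gene_models"` with data frames `exons`, `introns`
#'   (with `intron_rank`) and `genes` (spans).
#' @export
gene_models <- function(exons) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(exons))) stop("exon table must have columns: ",
                                        paste(req, collapse = ", "))
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (!"exon_rank" %in% names(exons))
    exons$exon_rank <- stats::ave(exons$start, exons$gene_id,
                                  FUN = seq_along)
  introns <- list(); genes <- list()
  for (gid in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == gid, , drop = FALSE]
    if (any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons within gene ", gid)
    genes[[gid]] <- data.frame(gene_id = gid, chrom = e$chrom[1],
                               start = min(e$start), end = max(e$end),
                               strand = e$strand[1], stringsAsFactors = FALSE)
    if (nrow(e) > 1L) {
      introns[[gid]] <- data.frame(
        gene_id = gid, chrom = e$chrom[1],
        start = e$end[-nrow(e)], end = e$start[-1], strand = e$strand[1],
        intron_rank = seq_len(nrow(e) - 1L), stringsAsFactors = FALSE
      )
    }
  }
  empty_introns <- data.frame(gene_id = character(0), chrom = character(0),
                              start = integer(0), end = integer(0),
                              strand = character(0), intron_rank = integer(0))
  structure(
    list(exons = exons,
         introns = if (length(introns)) do.call(rbind, c(introns, list(make.row.names = FALSE))) else empty_introns,
         genes = if (length(genes)) do.call(rbind, c(genes, list(make.row.names = FALSE))) else
           data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), strand = character(0))),
    class = "gene_models"
  )
}

#' Read gene models from a GTF file
#'
#' Keeps `exon` records (or all records when no `type` column is present) and
#' converts to the package's 0-based half-open convention.
#'
#' @param path GTF file path.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  df <- .df0(gr)
  gene_models(df[, c("gene_id", "chrom", "start", "end", "strand")])
}

#' Read a TE annotation from GTF or BED
#'
#' For GTF input the `gene_id` attribute is taken as the locus id; family is
#' parsed from ids of the form `family_dupNN` unless a `family` column is
#' present. BED input must have at least 6 columns (name = locus id).
#'
#' @param path file path ending in `.gtf` or `.bed`.
#' @return TE locus data frame (0-based half-open).
#' @export
read_te_loci <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:4] <- c("chrom", "start", "end", "locus_id")
    if (ncol(df) >= 6) names(df)[6] <- "strand" else df$strand <- "*"
    df <- df[, c("locus_id", "chrom", "start", "end", "strand")]
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- .df0(gr)
    df$locus_id <- df$gene_id
    df <- df[, c("locus_id", "chrom", "start", "end", "strand")]
  }
  df$family <- sub("_dup[0-9]+$", "", df$locus_id)
  df
}

#' Classify TE loci by genomic context
#'
#' Assigns each locus exactly one context: `exonic` if it overlaps any exon by
#' at least one base; otherwise `intronic` if it lies fully inside a gene span
#' (flanking intron intervals, i.e. the intron portions left and right of the
#' TE, are attached); otherwise `intergenic` when at least
#' `intergenic_distance` bases from every gene start/end, and `proximal` when
#' closer. Loci on chromosomes absent from the gene annotation namespace are
#' dropped with a warning (count in attribute `"n_dropped"`); with an empty
#' gene set all loci are intergenic at infinite distance.
#'
#' A TE contained in the introns of several genes is attached to the gene with
#' the smallest span and flagged `ambiguous_host`. A TE whose intron flank is
#' empty on one side (locus abuts the exon) is flagged `single_flank`.
#'
#' @param te TE locus data frame (`locus_id`, `chrom`, `start`, `end`, ...).
#' @param genes a [gene_models()] object.
#' @param intergenic_distance minimum distance in bases from any gene boundary
#'   for the `intergenic` label (default 1000).
#' @param chrom_universe optional character vector of valid chromosome names;
#'   defaults to chromosomes seen in `genes` plus those in `te` when the gene
#'   set is empty.
#' @return `te` with added columns `context`, `left_intron_start/end`,
#'   `right_intron_start/end`, `dist_to_nearest_gene`, `single_flank`,
#'   `ambiguous_host`.
#' @export
classify_te_context <- function(te, genes, intergenic_distance = 1000,
                                chrom_universe = NULL) {
  stopifnot(inherits(genes, "gene_models"))
  has_genes <- nrow(genes$genes) > 0L
  if (is.null(chrom_universe)) {
    chrom_universe <- if (has_genes) unique(c(genes$genes$chrom, te$chrom))
                      else unique(te$chrom)
  }
  bad <- !(te$chrom %in% chrom_universe)
  n_dropped <- sum(bad)
  if (n_dropped) {
    warning(n_dropped, " TE loci on unknown chromosomes dropped")
    te <- te[!bad, , drop = FALSE]
  }
  n <- nrow(te)
  te$context <- rep("intergenic", n)
  te$left_intron_start <- te$left_intron_end <- NA_integer_
  te$right_intron_start <- te$right_intron_end <- NA_integer_
  te$dist_to_nearest_gene <- rep(Inf, n)
  te$single_flank <- FALSE
  te$ambiguous_host <- FALSE
  if (!n) { attr(te, "n_dropped") <- n_dropped; return(te) }

  if (has_genes) {
    te_gr <- .gr0(te[, c("chrom", "start", "end")])
    ex_gr <- .gr0(genes$exons[, c("chrom", "start", "end")])
    sp_gr <- .gr0(genes$genes[, c("chrom", "start", "end")])
    exonic <- IRanges::overlapsAny(te_gr, ex_gr, ignore.strand = TRUE)
    inside <- GenomicRanges::findOverlaps(te_gr, sp_gr, type = "within",
                                          ignore.strand = TRUE)
    intronic_idx <- setdiff(unique(S4Vectors::queryHits(inside)), which(exonic))
    te$context[exonic] <- "exonic"
    te$context[intronic_idx] <- "intronic"

    # flanking intron portions for intronic loci
    if (length(intronic_idx)) {
      span_len <- genes$genes$end - genes$genes$start
      qh <- S4Vectors::queryHits(inside); sh <- S4Vectors::subjectHits(inside)
      for (i in intronic_idx) {
        hosts <- sh[qh == i]
        if (length(hosts) > 1L) {
          te$ambiguous_host[i] <- TRUE
          hosts <- hosts[which.min(span_len[hosts])]
        }
        gid <- genes$genes$gene_id[hosts]
        intr <- genes$introns[genes$introns$gene_id == gid, , drop = FALSE]
        hit <- which(intr$start <= te$start[i] & intr$end >= te$end[i])
        if (!length(hit)) next  # straddles an exon boundary yet exon-free: leave as is
        iv <- intr[hit[1L], ]
        if (te$start[i] > iv$start) {
          te$left_intron_start[i] <- iv$start
          te$left_intron_end[i] <- te$start[i]
        }
        if (te$end[i] < iv$end) {
          te$right_intron_start[i] <- te$end[i]
          te$right_intron_end[i] <- iv$end
        }
        te$single_flank[i] <- is.na(te$left_intron_start[i]) ||
          is.na(te$right_intron_start[i])
      }
    }

    outside <- setdiff(seq_len(n), c(which(exonic), intronic_idx))
    if (length(outside)) {
      d <- GenomicRanges::distanceToNearest(te_gr[outside], sp_gr,
                                            ignore.strand = TRUE)
      dist <- rep(Inf, length(outside))
      dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
      te$dist_to_nearest_gene[outside] <- dist
      te$context[outside] <- ifelse(dist >= intergenic_distance,
                                    "intergenic", "proximal")
    }
    te$dist_to_nearest_gene[te$context %in% c("exonic", "intronic")] <- 0
  }
  attr(te, "n_dropped") <- n_dropped
  te
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Distance-filtered intergenic locus sets
#'
#' Returns, for each distance threshold, the intergenic loci at least that far
#' from every gene boundary. Sets are nested: the subset at a larger threshold
#' is contained in the subset at any smaller one.
#'
#' @param te contexted TE table from [classify_te_context()].
#' @param thresholds distances in bases (default 1e3, 1e4, 1e5).
#' @return Named list of `locus_id` character vectors.
#' @export
distance_filtered_sets <- function(te, thresholds = c(1e3, 1e4, 1e5)) {
  if (!"context" %in% names(te)) stop("contexts not assigned; run classify_te_context()")
  ig <- te[te$context == "intergenic", , drop = FALSE]
  out <- lapply(thresholds, function(d)
    ig$locus_id[ig$dist_to_nearest_gene >= d])
  names(out) <- format(thresholds, scientific = FALSE, trim = TRUE)
  out
}

#' L1HS-style 5' end regions of TE loci
#'
#' Locally aligns each locus sequence against the first 300 bases of a family
#' consensus (match +1, mismatch -1, gap -2) and emits the locus-side aligned
#' span when the best local alignment reaches at least `min_identity` over at
#' least `min_aligned` aligned bases. 5'-truncated copies that lack the
#' consensus 5' end produce no region.
#'
#' @param locus_seqs named [Biostrings::DNAStringSet] of locus sequences in TE
#'   orientation (see [te_locus_seqs()]).
#' @param consensus consensus sequence (`DNAString` or character), >= 300
#'   bases.
#' @param five_prime_len length of the consensus 5' window (default 300).
#' @param min_identity minimum identity over aligned (non-gap) columns.
#' @param min_aligned minimum number of aligned bases.
#' @param min_score minimum local-alignment score (match +1, mismatch -1,
#'   gap -2); screens out the short chance alignments that unrelated
#'   sequence produces at the identity/length thresholds alone.
#' @return Data frame `locus_id`, `start`, `end` (0-based half-open within the
#'   locus), `consensus_offset`, `identity`, `aligned`.
#' @export
l1hs_five_prime_regions <- function(locus_seqs, consensus,
                                    five_prime_len = 300L,
                                    min_identity = 0.6, min_aligned = 50L,
                                    min_score = 30) {
  if (length(locus_seqs) == 0L) stop("empty locus sequence set")
  cons <- Biostrings::DNAString(as.character(consensus))
  if (length(cons) < five_prime_len)
    stop("consensus shorter than the 5' window (", five_prime_len, " bases)")
  head5 <- Biostrings::subseq(cons, 1L, five_prime_len)
  out <- list()
  for (i in seq_along(locus_seqs)) {
    if (Biostrings::width(locus_seqs)[i] == 0L) stop("empty locus sequence")
    aln <- Biostrings::pairwiseAlignment(
      locus_seqs[[i]], head5, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 0, gapExtension = 2
    )
    nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
    aligned <- nm + nmm
    if (aligned >= min_aligned && nm / aligned >= min_identity &&
        Biostrings::score(aln) >= min_score) {
      pstart <- start(Biostrings::pattern(aln)) - 1L
      pend <- end(Biostrings::pattern(aln))
      if (pend - pstart > five_prime_len) pend <- pstart + five_prime_len
      out[[length(out) + 1L]] <- data.frame(
        locus_id = names(locus_seqs)[i], start = pstart, end = pend,
        consensus_offset = start(Biostrings::subject(aln)) - 1L,
        identity = nm / aligned, aligned = aligned, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(locus_id = character(0), start = integer(0),
                      end = integer(0), consensus_offset = integer(0),
                      identity = numeric(0), aligned = integer(0)))
  do.call(rbind, out)
}
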