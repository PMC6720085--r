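# k-mer machinery shared by the mappability track and the exact-match
# alignment discovery of the read simulator.

# all genome k-mer start positions: data.table(kmer, chrom, pos0), keyed by kmer
.kmer_index <- function(genome, k) {
  if (k <= 0) stop("k must be positive")
  tabs <- lapply(names(genome), function(cc) {
    s <- as.character(genome[[cc]])
    n <- nchar(s) - k + 1L
    if (n < 1L) stop("k exceeds chromosome length for ", cc)
    data.table::data.table(
      kmer = substring(s, seq_len(n), seq_len(n) + k - 1L),
      chrom = cc, pos0 = seq_len(n) - 1L
    )
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, kmer)
  idx
}

#' Per-position unique-mappability track of a toy genome
#'
#' A position is uniquely mappable iff its k-mer, or the reverse complement of
#' its k-mer, occurs exactly once in the genome (both strands considered via
#' canonical k-mers). Positions within `k - 1` bases of a chromosome end have
#' no k-mer and are not mappable.
#'
#' @param genome a named [Biostrings::DNAStringSet] (or named character
#'   vector) of chromosome sequences.
#' @param k k-mer length in bases (default 48, the read length).
#' @return A `data.table` with columns `chrom`, `pos0` (0-based k-mer start)
#'   and logical `unique`.
#' @export
kmer_mappability <- function(genome, k = 48L) {
  idx <- .kmer_index(genome, k)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(idx$kmer)))
  canon <- pmin(idx$kmer, rc)
  cnt <- table(canon)
  idx$unique <- as.vector(cnt[canon]) == 1L
  idx[, c("chrom", "pos0", "unique")]
}

#' Uniquely-mappable length per TE locus
#'
#' Counts, inside each locus interval, the positions whose k-mer occurs
#' exactly once in the genome.
#'
#' @param te TE locus table (`locus_id`, `chrom`, `start`, `end`).
#' @param mappability output of [kmer_mappability()], or a genome to compute
#'   it from.
#' @param k k-mer length, used when `mappability` is a genome.
#' @return Named integer vector of mappable lengths, one per locus.
#' @export
mappable_length <- function(te, mappability, k = 48L) {
  if (!is.data.frame(mappability)) mappability <- kmer_mappability(mappability, k)
  mp <- data.table::as.data.table(mappability)[unique == TRUE]
  out <- integer(nrow(te))
  for (cc in unique(te$chrom)) {
    pos <- sort(mp[chrom == cc, pos0])
    rows <- which(te$chrom == cc)
    # count of unique positions in [start, end) via binary search
    out[rows] <- findInterval(te$end[rows] - 1L, pos) -
      findInterval(te$start[rows] - 1L, pos)
  }
  setNames(out, te$locus_id)
}
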