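# Internal coordinate convention: 0-based half-open [start, end).
# GRanges is 1-based inclusive; these two helpers are the only conversion points.

#' @noRd
.gr0 <- function(df, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
  keep <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(keep)) S4Vectors::mcols(gr) <- df[, keep, drop = FALSE]
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' @noRd
.df0 <- function(gr) {
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) out <- cbind(out, mc)
  rownames(out) <- NULL
  out
}

# seeds derived from a base seed stay below 2^31
.sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1000L + as.integer(offset) %% 1000L
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each base independently with probability p (to one of the 3 others)
.mutate_dna <- function(seq, p) {
  if (p <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < p)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    bases[hit] <- vapply(bases[hit], function(b) sample(setdiff(alt, b), 1L), "")
  }
  paste(bases, collapse = "")
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# cheap polynomial content hash over the deparsed object, for manifests
.param_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", h)
}
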