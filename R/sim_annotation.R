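#' Simulate a toy genome with gene models and TE loci
#'
#' Builds `n_chromosomes` random-sequence chromosomes, places multi-exon genes
#' and TE loci on them, and embeds each TE copy as a mutated version of its
#' family consensus so that copies of a low-divergence family are
#' near-identical (hence multi-mapping) while high-divergence copies are
#' effectively uniquely mappable. Each TE locus receives exactly one context:
#' `intronic` copies lie strictly inside one intron with non-empty flanks,
#' `exonic` copies lie inside an exon, and `intergenic` copies are at least
#' 1000 bases (the `intergenic_gap`) from every gene start/end.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `"tecoex_annotation"` with elements `genome`
#'   (a [Biostrings::DNAStringSet]), `genes` (a [gene_models()] object),
#'   `te` (TE locus table: `locus_id`, `chrom`, `start`, `end` in 0-based
#'   half-open coordinates, `strand`, `family`, `class`, `context`,
#'   `host_gene`, `host_intron`), `consensi` (family consensus sequences) and
#'   the `config`.
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(.sub_seed(config$seed, 0L))
  te_len <- .family_vec(config$te_length, config$n_te_families)
  divergence <- .family_vec(config$family_divergence, config$n_te_families)
  families <- sprintf("FAM%02d", seq_len(config$n_te_families))
  classes <- rep(c("LINE", "SINE", "LTR", "DNA"),
                 length.out = config$n_te_families)
  consensi <- setNames(
    vapply(te_len, .random_dna, ""),
    families
  )

  # context counts per family
  fr <- config$te_context_fractions[c("intronic", "exonic", "intergenic")]
  fr[is.na(fr)] <- 0
  n_int <- round(fr[["intronic"]] * config$loci_per_family)
  n_exo <- round(fr[["exonic"]] * config$loci_per_family)
  n_ig <- config$loci_per_family - n_int - n_exo
  if (n_ig < 0) stop("te_context_fractions round to more loci than available")
  if ((n_int > 0 || n_exo > 0) && config$n_genes == 0L)
    stop("placement error: intronic/exonic TEs requested but n_genes = 0")

  margin <- max(200L, config$read_len + 10L)
  span <- config$exons_per_gene * config$exon_length +
    (config$exons_per_gene - 1L) * config$intron_length
  gene_chrom <- if (config$n_genes > 0)
    rep(seq_len(config$n_chromosomes), length.out = config$n_genes) else integer(0)

  # lay genes left-to-right per chromosome
  exons <- list(); gene_tab <- list()
  cursor <- rep(margin, config$n_chromosomes)
  for (g in seq_len(config$n_genes)) {
    cc <- gene_chrom[g]
    gstart <- cursor[cc]
    gend <- gstart + span
    if (gend > config$chrom_length - margin)
      stop("placement error: chromosome ", cc, " too short for requested genes")
    gid <- sprintf("gene%04d", g)
    gstrand <- sample(c("+", "-"), 1L)
    ex_start <- gstart + (seq_len(config$exons_per_gene) - 1L) *
      (config$exon_length + config$intron_length)
    exons[[g]] <- data.frame(
      gene_id = gid, chrom = paste0("chr", cc),
      start = ex_start, end = ex_start + config$exon_length,
      strand = gstrand, exon_rank = seq_len(config$exons_per_gene),
      stringsAsFactors = FALSE
    )
    gene_tab[[g]] <- data.frame(gene_id = gid, chrom = paste0("chr", cc),
                                start = gstart, end = gend, strand = gstrand,
                                stringsAsFactors = FALSE)
    cursor[cc] <- gend + max(config$intergenic_gap, 1000L)
  }
  exons <- if (length(exons)) do.call(rbind, exons) else
    data.frame(gene_id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0), exon_rank = integer(0))
  genes <- gene_models(exons)

  # candidate host introns / exons (each hosts at most one TE)
  introns <- genes$introns
  exon_pool <- genes$exons
  intron_free <- rep(TRUE, nrow(introns))
  exon_free <- rep(TRUE, nrow(exon_pool))
  min_flank <- max(config$read_len + 2L, 100L)

  te <- list()
  for (f in seq_len(config$n_te_families)) {
    fam <- families[f]; tl <- te_len[f]
    contexts <- c(rep("intronic", n_int), rep("exonic", n_exo),
                  rep("intergenic", n_ig))
    for (i in seq_len(config$loci_per_family)) {
      ctx <- contexts[i]
      locus_id <- sprintf("%s_dup%d", fam, i)
      if (ctx == "intronic") {
        ok <- which(intron_free & (introns$end - introns$start) >= tl + 2L * min_flank)
        if (!length(ok))
          stop("placement error: no intron can host a ", tl, "-base TE")
        j <- if (length(ok) == 1L) ok else sample(ok, 1L)
        intron_free[j] <- FALSE
        slack <- (introns$end[j] - introns$start[j]) - tl - 2L * min_flank
        off <- min_flank + sample.int(slack + 1L, 1L) - 1L
        st <- introns$start[j] + off
        host <- introns$gene_id[j]; host_intron <- introns$intron_rank[j]
        cc <- introns$chrom[j]
      } else if (ctx == "exonic") {
        ok <- which(exon_free & (exon_pool$end - exon_pool$start) >= tl + 2L)
        if (!length(ok))
          stop("placement error: no exon can host a ", tl, "-base TE")
        j <- if (length(ok) == 1L) ok else sample(ok, 1L)
        exon_free[j] <- FALSE
        slack <- (exon_pool$end[j] - exon_pool$start[j]) - tl - 2L
        off <- 1L + sample.int(slack + 1L, 1L) - 1L
        st <- exon_pool$start[j] + off
        host <- exon_pool$gene_id[j]; host_intron <- NA_integer_
        cc <- exon_pool$chrom[j]
      } else {
        # intergenic: appended after the genes on a round-robin chromosome
        cc_i <- 1L + (length(te) %% config$n_chromosomes)
        st <- cursor[cc_i]
        if (st + tl > config$chrom_length - margin)
          stop("placement error: chromosome ", cc_i,
               " too short for requested intergenic TEs")
        cursor[cc_i] <- st + tl + 150L
        host <- NA_character_; host_intron <- NA_integer_
        cc <- paste0("chr", cc_i)
      }
      te[[length(te) + 1L]] <- data.frame(
        locus_id = locus_id, chrom = cc, start = st, end = st + tl,
        strand = sample(c("+", "-"), 1L), family = fam, class = classes[f],
        context = ctx, host_gene = host, host_intron = host_intron,
        stringsAsFactors = FALSE
      )
    }
  }
  te <- if (length(te)) do.call(rbind, te) else
    data.frame(locus_id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0), family = character(0),
               class = character(0), context = character(0),
               host_gene = character(0), host_intron = integer(0))

  # assemble sequences: random background, TE copies written over it
  genome <- setNames(
    vapply(seq_len(config$n_chromosomes), function(i)
      .random_dna(config$chrom_length), ""),
    paste0("chr", seq_len(config$n_chromosomes))
  )
  if (nrow(te)) {
    fam_idx <- match(te$family, families)
    for (i in seq_len(nrow(te))) {
      s <- .mutate_dna(consensi[[te$family[i]]], divergence[fam_idx[i]])
      if (te$strand[i] == "-") s <- .revcomp_chr(s)
      substr(genome[[te$chrom[i]]], te$start[i] + 1L, te$end[i]) <- s
    }
  }

  structure(
    list(genome = Biostrings::DNAStringSet(genome), genes = genes, te = te,
         consensi = Biostrings::DNAStringSet(consensi), config = config),
    class = "tecoex_annotation"
  )
}

#' Extract TE locus sequences from an annotation
#'
#' @param annotation a `tecoex_annotation` object (or any list with `genome`
#'   and `te` elements in the same layout).
#' @param oriented if `TRUE` (default), minus-strand loci are
#'   reverse-complemented so sequences read in TE orientation.
#' @return A named [Biostrings::DNAStringSet], one entry per locus.
#' @export
te_locus_seqs <- function(annotation, oriented = TRUE) {
  te <- annotation$te
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(te)), function(i) {
    as.character(Biostrings::subseq(annotation$genome[[te$chrom[i]]],
                                    te$start[i] + 1L, te$end[i]))
  }, ""))
  names(seqs) <- te$locus_id
  if (oriented) {
    neg <- te$strand == "-"
    if (any(neg)) seqs[neg] <- Biostrings::reverseComplement(seqs[neg])
  }
  seqs
}

#' Write a simulated annotation to standard files
#'
#' Writes the genome as FASTA, gene models as GTF (1-based inclusive), the TE
#' annotation as GTF and 6-column BED (0-based half-open), and the TE locus
#' table as TSV.
#'
#' @param annotation a `tecoex_annotation` object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_annotation <- function(annotation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gtf"),
    te_gtf = file.path(dir, "te.gtf"),
    te_bed = file.path(dir, "te.bed"),
    te_tsv = file.path(dir, "te_loci.tsv")
  )
  Biostrings::writeXStringSet(annotation$genome, paths[["genome"]])
  seqlens <- setNames(Biostrings::width(annotation$genome),
                      names(annotation$genome))
  ex <- .gr0(annotation$genes$exons, seqlengths = seqlens)
  S4Vectors::mcols(ex)$type <- "exon"
  rtracklayer::export(ex, paths[["genes"]], format = "gtf")
  tg <- .gr0(annotation$te, seqlengths = seqlens)
  S4Vectors::mcols(tg)$type <- "exon"
  S4Vectors::mcols(tg)$gene_id <- annotation$te$locus_id
  rtracklayer::export(tg, paths[["te_gtf"]], format = "gtf")
  bed <- annotation$te[, c("chrom", "start", "end", "locus_id")]
  bed$score <- 0L
  bed$strand <- annotation$te$strand
  write.table(bed, paths[["te_bed"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(annotation$te, paths[["te_tsv"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
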