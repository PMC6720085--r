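#' Run the end-to-end pipeline on simulated data
#'
#' Orchestrates simulate -> annotate -> quantify (EM) -> correct ->
#' normalize -> log2 -> cluster on a [sim_config()], writing stage TSVs and
#' a manifest. Reruns with an identical config produce identical outputs.
#'
#' @param config a [sim_config()] object.
#' @param out_dir output directory.
#' @param stages named logical toggles; defaults run everything. Disabling a
#'   stage whose downstream stage is enabled is an error.
#' @return List of stage artifacts (invisibly also written under `out_dir`):
#'   `annotation`, `truth`, `alignments`, `quant`, `corrected`,
#'   `size_factors`, `log2` (genes and TE), `clustering`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c(simulate = TRUE, quantify = TRUE,
                                    correct = TRUE, normalize = TRUE,
                                    cluster = TRUE)) {
  need <- c("simulate", "quantify", "correct", "normalize", "cluster")
  stages <- stages[need]
  stages[is.na(stages)] <- FALSE
  for (i in seq_along(need)[-1]) {
    if (stages[need[i]] && !stages[need[i - 1L]])
      stop("stage '", need[i], "' requires upstream stage '", need[i - 1L], "'")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, params, outputs) {
    manifest[[stage]] <<- data.frame(
      stage = stage, param_hash = .param_hash(params),
      outputs = paste(outputs, collapse = ","), stringsAsFactors = FALSE)
  }
  out <- list()
  if (!stages[["simulate"]]) return(out)

  ann <- simulate_annotation(config)
  truth <- simulate_expression(config, ann)
  aln <- simulate_alignments(truth, ann, config,
                             out_dir = file.path(out_dir, "sam"))
  paths <- write_annotation(ann, file.path(out_dir, "annotation"))
  note("simulate", config, c(paths, aln$sam_paths))
  out$annotation <- ann; out$truth <- truth; out$alignments <- aln

  if (!stages[["quantify"]]) { out$manifest <- manifest; return(out) }
  te_ctx <- classify_te_context(ann$te, ann$genes)
  quant <- quantify_te(aln$alignments, te_ctx, ann$genes, mode = "em")
  p_counts <- file.path(out_dir, "locus_counts_em.tsv")
  write.table(quant$counts, p_counts, sep = "\t", quote = FALSE)
  note("quantify", list(mode = "em"), p_counts)
  out$te_context <- te_ctx; out$quant <- quant

  if (!stages[["correct"]]) { out$manifest <- manifest; return(out) }
  corr <- apply_counting_policy(quant$counts, te_ctx, aln$alignments,
                                read_len = config$read_len)
  p_corr <- file.path(out_dir, "locus_counts_corrected.tsv")
  write.table(corr$counts, p_corr, sep = "\t", quote = FALSE)
  p_rep <- file.path(out_dir, "correction_report.tsv")
  write.table(corr$report, p_rep, sep = "\t", quote = FALSE, row.names = FALSE)
  note("correct", list(read_len = config$read_len), c(p_corr, p_rep))
  out$corrected <- corr

  if (!stages[["normalize"]]) { out$manifest <- manifest; return(out) }
  gene_counts <- aln$counts$gene_counts
  sf <- deges_size_factors(gene_counts, truth$samples$tissue)
  te_norm <- normalize_counts(corr$counts, sf)
  gene_norm <- normalize_counts(gene_counts, sf)
  lg_te <- log_transform(te_norm); lg_gene <- log_transform(gene_norm)
  p_sf <- file.path(out_dir, "size_factors.tsv")
  write.table(data.frame(sample_id = names(sf$size_factors),
                         size_factor = sf$size_factors),
              p_sf, sep = "\t", quote = FALSE, row.names = FALSE)
  note("normalize", list(drop_fraction = 0.3), p_sf)
  out$size_factors <- sf
  out$log2 <- list(te = lg_te, genes = lg_gene)

  if (!stages[["cluster"]]) { out$manifest <- manifest; return(out) }
  truth_lab <- setNames(truth$samples$tissue, truth$samples$sample_id)
  n_feat <- min(150L, nrow(lg_te))
  cl <- evaluate_clustering(lg_te, truth_lab, n = n_feat,
                            raw_counts = corr$counts)
  p_cl <- file.path(out_dir, "clusters.tsv")
  write.table(data.frame(sample_id = names(cl$clusters),
                         cluster = cl$clusters,
                         tissue = truth_lab[names(cl$clusters)]),
              p_cl, sep = "\t", quote = FALSE, row.names = FALSE)
  note("cluster", list(n = n_feat), p_cl)
  out$clustering <- cl
  out$manifest <- do.call(rbind, manifest)
  out
}

#' Validate pipeline input files
#'
#' Checks alignment/annotation chromosome-namespace consistency, coordinate
#' sanity, and metadata completeness. Returns a report of failures rather
#' than erroring.
#'
#' @param paths named list with any of `sam` (SAM file), `te` (GTF/BED),
#'   `genes` (GTF), `meta` (TSV with `sample_id` and `tissue` columns).
#' @return Data frame with columns `check` and `message`; zero rows when all
#'   checks pass.
#' @export
validate_inputs <- function(paths) {
  report <- list()
  fail <- function(check, msg)
    report[[length(report) + 1L]] <<- data.frame(check = check, message = msg,
                                                 stringsAsFactors = FALSE)
  sam_chroms <- NULL
  if (!is.null(paths$sam)) {
    if (!file.exists(paths$sam)) fail("sam", "file missing")
    else {
      hdr <- grep("^@SQ", readLines(paths$sam, warn = FALSE), value = TRUE)
      sam_chroms <- sub(".*SN:([^\t]+).*", "\\1", hdr)
      if (!length(sam_chroms)) fail("sam", "no @SQ header lines")
    }
  }
  for (nm in c("te", "genes")) {
    if (is.null(paths[[nm]])) next
    if (!file.exists(paths[[nm]])) { fail(nm, "file missing"); next }
    df <- tryCatch(
      if (nm == "te") read_te_loci(paths[[nm]])
      else read_gene_models(paths[[nm]])$exons,
      error = function(e) NULL)
    if (is.null(df) || !nrow(df)) { fail(nm, "empty or unparseable"); next }
    if (any(df$end <= df$start)) fail(nm, "intervals with end <= start")
    if (!is.null(sam_chroms) && !any(df$chrom %in% sam_chroms))
      fail(nm, "chromosome names do not match the SAM header")
  }
  if (!is.null(paths$meta)) {
    if (!file.exists(paths$meta)) fail("meta", "file missing")
    else {
      md <- utils::read.delim(paths$meta, stringsAsFactors = FALSE)
      miss <- setdiff(c("sample_id", "tissue"), names(md))
      if (length(miss)) fail("meta", paste("missing columns:",
                                           paste(miss, collapse = ", ")))
      else if (anyNA(md$tissue)) fail("meta", "missing tissue labels")
    }
  }
  if (!length(report))
    return(data.frame(check = character(0), message = character(0)))
  do.call(rbind, report)
}
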