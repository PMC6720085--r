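test_that("read depth is count per effective base", {
  expect_equal(read_depth(90, 1048, 48), 0.09)
  expect_equal(read_depth(0, 1048, 48), 0)
  expect_equal(read_depth(100, 148, 48), 1)
  expect_error(read_depth(10, 48, 48), "undefined")
  expect_error(read_depth(-1, 148, 48))
})

test_that("the flanking-depth discount hits its three regimes exactly", {
  expect_equal(correct_te_count(100, 0.1, 0, 0), 100)       # no intron signal
  expect_equal(correct_te_count(100, 0.1, 0.05, 0.05), 50)  # half discount
  expect_equal(correct_te_count(100, 0.1, 0.15, 0.15), 0)   # zeroed out
})

test_that("corrected counts stay within [0, raw] on random inputs", {
  set.seed(81)
  n <- 10000
  cte <- runif(n, 0, 1000)
  rte <- runif(n, 1e-6, 2)
  ril <- runif(n, 0, 3)
  rir <- runif(n, 0, 3)
  out <- correct_te_count(cte, rte, ril, rir)
  expect_true(all(out >= 0))
  expect_true(all(out <= cte + 1e-12))
})

test_that("flank counts exclude TE-only fragments and use any-overlap", {
  te <- data.frame(locus_id = "T_dup1", chrom = "chr1", start = 400L,
                   end = 700L, strand = "+", family = "T",
                   context = "intronic",
                   left_intron_start = 0L, left_intron_end = 400L,
                   right_intron_start = 700L, right_intron_end = 1048L,
                   stringsAsFactors = FALSE)
  pos <- c(100L, 380L, 420L, 660L, 690L, 800L)  # 48-base reads
  aln <- data.table::data.table(
    fragment_id = sprintf("f%d", seq_along(pos)), chrom = "chr1",
    pos0 = pos, width = 48L, strand = "+", nh = 1L, sample_id = "s1")
  ic <- intron_counts(aln, te)
  # left flank [0,400): f1 and f2 (380+48 crosses 400); f3 is TE-only
  # right flank [700,1048): f4 (660+48), f5 (690+48) and f6
  expect_equal(ic$count_il, 2)
  expect_equal(ic$count_ir, 3)

  frags <- data.frame(chrom = "chr1", start = pos, end = pos + 48L)
  expect_equal(ic$count_il, sum(overlap_oracle(
    frags, data.frame(chrom = "chr1", start = 0L, end = 400L))))
  expect_equal(ic$count_ir, sum(overlap_oracle(
    frags, data.frame(chrom = "chr1", start = 700L, end = 1048L))))
})

test_that("uniform read-through is tallied like the brute-force overlap scan", {
  cfg <- sim_config(seed = 82, n_genes = 1, exons_per_gene = 2,
                    intron_length = 1048, n_te_families = 1,
                    loci_per_family = 1, te_length = 300,
                    te_context_fractions = c(intronic = 1, exonic = 0,
                                             intergenic = 0),
                    retention_fraction = 1, n_tissues = 1,
                    n_samples_per_tissue = 1, frag_reads_per_sample = 1500,
                    nb_dispersion = 1e6)
  ann <- simulate_annotation(cfg)
  truth <- simulate_expression(cfg, ann)
  al <- simulate_alignments(truth, ann, cfg)
  ctx <- classify_te_context(ann$te, ann$genes)
  ic <- intron_counts(al$alignments, ctx)
  ret <- unique(al$alignments[, .(fragment_id, pos0)])
  left <- data.frame(chrom = "chr1", start = ret$pos0, end = ret$pos0 + 48L)
  lo <- sum(overlap_oracle(left, data.frame(
    chrom = "chr1", start = ctx$left_intron_start, end = ctx$left_intron_end)))
  ro <- sum(overlap_oracle(left, data.frame(
    chrom = "chr1", start = ctx$right_intron_start, end = ctx$right_intron_end)))
  expect_equal(ic$count_il, lo)
  expect_equal(ic$count_ir, ro)
})

test_that("the counting policy zeroes exonic loci and spares intergenic ones", {
  te <- data.frame(
    locus_id = c("A_dup1", "B_dup1", "C_dup1"),
    chrom = "chr1", start = c(100L, 1000L, 5000L),
    end = c(400L, 1300L, 5300L), strand = "+",
    family = c("A", "B", "C"),
    context = c("exonic", "intergenic", "proximal"),
    left_intron_start = NA_integer_, left_intron_end = NA_integer_,
    right_intron_start = NA_integer_, right_intron_end = NA_integer_,
    stringsAsFactors = FALSE)
  counts <- matrix(c(18863, 42, 7), 3, 1,
                   dimnames = list(te$locus_id, "s1"))
  aln <- data.table::data.table(fragment_id = character(0),
                                chrom = character(0), pos0 = integer(0),
                                width = integer(0), strand = character(0),
                                nh = integer(0), sample_id = character(0))
  res <- apply_counting_policy(counts, te, aln)
  expect_equal(unname(res$counts[, "s1"]), c(0, 42, 7))
  te2 <- te; te2$context[1] <- NA
  expect_error(apply_counting_policy(counts, te2, aln), "context")
})

test_that("without read-through the correction leaves intronic counts alone", {
  cfg <- sim_config(seed = 83, n_genes = 2, exons_per_gene = 2,
                    intron_length = 2000, n_te_families = 1,
                    loci_per_family = 2, te_length = 300,
                    te_context_fractions = c(intronic = 1, exonic = 0,
                                             intergenic = 0),
                    retention_fraction = 0, n_tissues = 1,
                    n_samples_per_tissue = 2, frag_reads_per_sample = 3000)
  ann <- simulate_annotation(cfg)
  truth <- simulate_expression(cfg, ann)
  al <- simulate_alignments(truth, ann, cfg)
  ctx <- classify_te_context(ann$te, ann$genes)
  q <- quantify_te(al$alignments, ctx, ann$genes, mode = "em")
  res <- apply_counting_policy(q$counts, ctx, al$alignments,
                               read_len = cfg$read_len)
  # gene reads live in exons; the only flank signal is the read_len - 1
  # overhang of autonomous TE reads past the locus end, bounded by
  # ~read_len/len_te of the TE count, so the discount stays small
  expect_true(all(res$counts >= 0.90 * q$counts - 1))
  expect_true(all(res$counts <= q$counts + 1e-9))
})

test_that("correction never increases counts and reductions add up", {
  cfg <- sim_config(seed = 84, n_genes = 2, exons_per_gene = 3,
                    intron_length = 1500, n_te_families = 2,
                    loci_per_family = 2, te_length = 300,
                    te_context_fractions = c(intronic = 0.5, exonic = 0,
                                             intergenic = 0.5),
                    retention_fraction = 0.5, n_tissues = 1,
                    n_samples_per_tissue = 2, frag_reads_per_sample = 4000)
  ann <- simulate_annotation(cfg)
  truth <- simulate_expression(cfg, ann)
  al <- simulate_alignments(truth, ann, cfg)
  ctx <- classify_te_context(ann$te, ann$genes)
  q <- quantify_te(al$alignments, ctx, ann$genes, mode = "em")
  res <- apply_counting_policy(q$counts, ctx, al$alignments,
                               read_len = cfg$read_len)
  expect_true(all(res$counts <= q$counts + 1e-9))
  discount <- sum(q$counts) - sum(res$counts)
  per_locus <- sum(q$counts - res$counts)
  expect_equal(discount, per_locus, tolerance = 1e-9)
  expect_true(all(res$report$max_correction >= 0))
})
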