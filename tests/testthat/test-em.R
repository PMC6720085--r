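test_that("EM splits shared mass by symmetry and respects unique evidence", {
  # 5 unique to A, 5 unique to B, 10 shared: symmetric fixed point (10, 10)
  pairs <- classes_to_pairs(list("A", "B", c("A", "B")), c(5, 5, 10))
  fit <- em_assign(pairs)
  expect_equal(unname(fit$counts), c(10, 10), tolerance = 1e-6)

  # 10 unique to A, none to B: all shared mass flows to A at the fixed point
  pairs <- classes_to_pairs(list("A", c("A", "B")), c(10, 10))
  fit <- em_assign(pairs, tol = 1e-8, max_iter = 5000)
  oracle <- ml_oracle(list("A", c("A", "B")), c(10, 10))
  expect_equal(unname(fit$counts), unname(oracle$counts), tolerance = 1e-3)
  expect_equal(unname(fit$counts), c(20, 0), tolerance = 1e-3)

  # all unique: EM equals the raw tallies immediately
  pairs <- classes_to_pairs(list("A", "B", "C"), c(3, 7, 2))
  fit <- em_assign(pairs)
  expect_equal(fit$counts, c(A = 3, B = 7, C = 2), tolerance = 1e-9)
})

test_that("EM conserves mass and has non-decreasing log-likelihood", {
  set.seed(71)
  loci <- c("A", "B", "C")
  for (rep in 1:20) {
    sets <- unique(lapply(1:6, function(i)
      sort(sample(loci, sample(1:3, 1)))))
    n <- sample(1:8, length(sets), replace = TRUE)
    fit <- em_assign(classes_to_pairs(sets, n))
    expect_equal(sum(fit$counts), sum(n), tolerance = 1e-6)
    expect_true(all(diff(fit$loglik) > -1e-9))
  }
})

test_that("EM matches grid-search/optim maximum likelihood on small problems", {
  # all 2-locus configurations up to 12 fragments, plus sampled 3-locus ones;
  # configurations whose ML counts are not unique (flat ridges) are compared
  # on likelihood only
  check_config <- function(sets, n) {
    keep <- n > 0
    sets <- sets[keep]; n <- n[keep]
    if (!length(sets)) return(invisible(NULL))
    loci <- sort(unique(unlist(sets)))
    fit <- em_assign(classes_to_pairs(sets, n), loci = loci,
                     tol = 1e-9, max_iter = 20000)
    oracle <- ml_oracle(sets, n, loci)
    ll_em <- sum(n * log(vapply(sets, function(s)
      sum(fit$pi[match(s, loci)]), 0)))
    expect_gte(ll_em, oracle$loglik - 1e-5)
    # uniqueness probe: re-optimize from other corners; if near-optimal
    # solutions with different expected counts exist, the ML counts are not
    # unique and only the likelihood is compared
    alt <- lapply(seq_along(loci), function(k) {
      p0 <- rep(0.05 / max(length(loci) - 1, 1), length(loci)); p0[k] <- 0.95
      ml_oracle(sets, n, loci, start_pi = p0)$counts
    })
    spread <- max(vapply(alt, function(x) max(abs(x - oracle$counts)), 0))
    if (spread < 1e-4)
      expect_equal(unname(fit$counts), unname(oracle$counts),
                   tolerance = 1e-3)
  }
  for (na in c(0, 2, 6)) for (nb in c(0, 3)) for (nab in c(0, 1, 7))
    check_config(list("A", "B", c("A", "B")), c(na, nb, nab))
  set.seed(72)
  types <- list("A", "B", "C", c("A", "B"), c("A", "C"), c("B", "C"),
                c("A", "B", "C"))
  for (i in 1:10) {
    n <- as.vector(rmultinom(1, sample(5:20, 1), rep(1 / 7, 7)))
    check_config(types, n)
  }
})

test_that("unique-only counting implements single-best-alignment semantics", {
  aln <- data.table::data.table(
    fragment_id = c("f1", "f2", "f2", "f3"),
    chrom = "chr1", pos0 = c(100L, 100L, 500L, 520L), width = 48L,
    strand = "+", nh = c(1L, 2L, 2L, 1L), sample_id = "s1")
  te <- data.frame(locus_id = c("A_dup1", "B_dup1"), chrom = "chr1",
                   start = c(90L, 490L), end = c(200L, 600L), strand = "+",
                   family = c("A", "B"), stringsAsFactors = FALSE)
  as_ <- ingest_alignments(aln, te)
  u <- unique_only_counts(as_)
  expect_equal(u, c(A_dup1 = 1, B_dup1 = 1))
  em <- em_assign(as_)
  expect_true(all(u <= em$counts + 1e-9))
})

test_that("exon-overlapping alignments do not create candidates", {
  te <- data.frame(locus_id = "A_dup1", chrom = "chr1", start = 100L,
                   end = 400L, strand = "+", family = "A",
                   stringsAsFactors = FALSE)
  genes <- gene_models(data.frame(gene_id = "g1", chrom = "chr1",
                                  start = c(1000L, 3000L),
                                  end = c(1500L, 3500L), strand = "+"))
  aln <- data.table::data.table(
    fragment_id = c("f1", "f1", "f2"),
    chrom = "chr1", pos0 = c(150L, 1100L, 1200L), width = 48L,
    strand = "+", nh = c(2L, 2L, 1L), sample_id = "s1")
  as_ <- ingest_alignments(aln, te, genes)
  expect_identical(sort(unique(as_$pairs$locus_id)), "A_dup1")
  expect_identical(as_$stats$n_ingested, 1L)
  expect_identical(as_$stats$n_exonic_only, 1L)
})

test_that("ingestion recovers the simulator's TE-overlapping fragments", {
  cfg <- sim_config(seed = 73, n_genes = 2, n_te_families = 2,
                    loci_per_family = 3, exon_length = 400,
                    te_context_fractions = c(intronic = 1/3, exonic = 1/3,
                                             intergenic = 1/3),
                    n_tissues = 1, n_samples_per_tissue = 1,
                    frag_reads_per_sample = 4000)
  ann <- simulate_annotation(cfg)
  truth <- simulate_expression(cfg, ann)
  al <- simulate_alignments(truth, ann, cfg)
  a <- al$alignments
  as_ <- ingest_alignments(a, ann$te, ann$genes)

  te_gr <- GenomicRanges::GRanges(ann$te$chrom,
                                  IRanges::IRanges(ann$te$start + 1L,
                                                   ann$te$end))
  a_gr <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$pos0 + 1L,
                                                           a$pos0 + a$width))
  truth_frags <- unique(a$fragment_id[IRanges::overlapsAny(a_gr, te_gr)])
  expect_identical(as_$stats$n_ingested, length(truth_frags))
})

test_that("family aggregation sums non-exonic loci only", {
  te <- data.frame(locus_id = c("F_dup1", "F_dup2", "F_dup3"),
                   family = "F", context = c("intronic", "exonic",
                                             "intergenic"),
                   stringsAsFactors = FALSE)
  counts <- matrix(c(5, 3, 2), 3, 1,
                   dimnames = list(te$locus_id, "s1"))
  fam <- aggregate_family(counts, te)
  expect_equal(unname(fam["F", "s1"]), 7)
  # conservation over non-exonic loci
  expect_equal(sum(fam), sum(counts[te$context != "exonic", ]))
  expect_error(aggregate_family(
    matrix(1, 1, 1, dimnames = list("X_dup1", "s1")), te), "family")
})

test_that("L1HS 5' counting matches a direct weight sum", {
  te <- data.frame(locus_id = c("L1_dup1", "L1_dup2"), chrom = "chr1",
                   start = c(1000L, 5000L), end = c(1600L, 5600L),
                   strand = "+", family = "L1", stringsAsFactors = FALSE)
  regions <- data.frame(locus_id = c("L1_dup1", "L1_dup2"),
                        start = 0L, end = 300L, consensus_offset = 0L)
  aln <- data.table::data.table(
    fragment_id = c("f1", "f2", "f2", "f3"),
    chrom = "chr1",
    pos0 = c(1100L, 1100L, 5100L, 1500L),  # f3 outside both 5' windows
    width = 48L, strand = "+", nh = c(1L, 2L, 2L, 1L), sample_id = "s1")
  as_ <- ingest_alignments(aln, te)
  em <- em_assign(as_, loci = te$locus_id)
  got <- count_l1hs_5prime(as_, em, regions, te, aln)
  # f1 contributes weight 1; f2 splits its weight across both loci but both
  # alignments fall in 5' windows, so it contributes 1; f3 contributes 0
  expect_equal(got, 2, tolerance = 1e-6)
  # all-3'-end fragments count zero
  aln3 <- data.table::copy(aln)[, pos0 := pos0 + 400L]
  as3 <- ingest_alignments(aln3, te)
  em3 <- em_assign(as3, loci = te$locus_id)
  expect_equal(count_l1hs_5prime(as3, em3, regions, te, aln3), 0)
  expect_warning(z <- count_l1hs_5prime(as_, em, regions[0, ], te, aln),
                 "empty")
  expect_identical(z, 0)
})

test_that("mappability bias test flags proportional counts and degenerate input", {
  set.seed(74)
  ml <- setNames(seq(10, 300, length.out = 40) + rnorm(40, 0, 5),
                 sprintf("L_dup%d", 1:40))
  counts <- setNames(2^(ml / 60) - 1 + runif(40, 0, 0.2), names(ml))
  res <- mappability_bias_test(counts, ml)
  expect_gt(res$cor, 0.9)
  expect_lt(res$p_value, 1e-4)
  const <- setNames(rep(7, 40), names(ml))
  expect_true(mappability_bias_test(const, ml)$degenerate)
  expect_error(mappability_bias_test(counts[1:5], ml[1:5]), "at least")
})
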