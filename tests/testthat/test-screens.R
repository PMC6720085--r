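make_screen_data <- function(n_kzfp = 20, n_fam = 20, n_samples = 50,
                             n_tissues = 2, planted = NULL, r = 0.8,
                             seed = 121) {
  set.seed(seed)
  n <- n_samples * n_tissues
  kz <- matrix(rnorm(n_kzfp * n), n_kzfp, n,
               dimnames = list(sprintf("ZNF%03d", seq_len(n_kzfp)),
                               sprintf("s%03d", seq_len(n))))
  te <- matrix(rnorm(n_fam * n), n_fam, n,
               dimnames = list(sprintf("FAM%03d", seq_len(n_fam)),
                               sprintf("s%03d", seq_len(n))))
  if (!is.null(planted)) {
    for (p in planted) {
      te[p[2], ] <- r * scale(kz[p[1], ])[, 1] +
        sqrt(1 - r^2) * rnorm(n)
    }
  }
  list(kz = kz, te = te,
       tissue = rep(sprintf("t%d", seq_len(n_tissues)), each = n_samples))
}

test_that("family screen finds exact copies and planted pairs, not noise", {
  d <- make_screen_data(planted = list(c(1, 1)), r = 0.9)
  d$te[2, ] <- d$kz[2, ]  # exact copy: r = 1
  scr <- pairwise_family_screen(d$kz, d$te, d$tissue)
  res <- scr$result
  copy <- res[predictor == "ZNF002" & response == "FAM002"]
  expect_true(all(abs(copy$r - 1) < 1e-12))
  expect_true(all(copy$q < 1e-10))
  planted <- scr$replication[predictor == "ZNF001" & response == "FAM001"]
  expect_identical(planted$n_tissues_significant, 2L)
  expect_true(planted$sign_consistent)
  null_sig <- res[!(predictor %in% c("ZNF001", "ZNF002")) & significant == TRUE]
  expect_lt(nrow(null_sig), 20)
  expect_error(pairwise_family_screen(d$kz[, 1:5], d$te[, 1:5], rep("t", 5)),
               "fewer than")
})

test_that("BH q-values are monotone in p within each tissue batch", {
  d <- make_screen_data(seed = 122)
  res <- pairwise_family_screen(d$kz, d$te, d$tissue)$result
  for (t_ in unique(res$tissue)) {
    sub <- res[tissue == t_][order(p)]
    expect_true(all(diff(sub$q) > -1e-12))
    expect_true(all(sub$q >= sub$p - 1e-12))
    expect_true(all(sub$q >= 0 & sub$q <= 1))
  }
})

test_that("locus follow-up pinpoints the driving locus", {
  set.seed(123)
  n <- 100
  kz <- matrix(rnorm(n), 1, n,
               dimnames = list("ZNF001", sprintf("s%03d", 1:n)))
  tissue <- rep(c("t1", "t2"), each = 50)
  fam <- matrix(0.9 * kz[1, ] + sqrt(1 - 0.81) * rnorm(n), 1, n,
                dimnames = list("FAMX", colnames(kz)))
  loci <- matrix(rnorm(10 * n), 10, n,
                 dimnames = list(sprintf("FAMX_dup%d", 1:10), colnames(kz)))
  loci[4, ] <- fam[1, ]  # the driving locus
  scr <- pairwise_family_screen(kz, fam, tissue)
  fu <- locus_followup(scr, kz, loci,
                       setNames(rep("FAMX", 10), rownames(loci)), tissue)
  sig <- unique(fu[significant == TRUE, locus_id])
  expect_identical(sig, "FAMX_dup4")
  # flat loci produce no tests at all
  flat <- matrix(1, 2, n, dimnames = list(c("FAMX_dup11", "FAMX_dup12"),
                                          colnames(kz)))
  fu2 <- locus_followup(scr, kz, flat,
                        setNames(rep("FAMX", 2), rownames(flat)), tissue)
  expect_identical(nrow(fu2), 0L)
})

test_that("binding overlap builds the full pair universe and matches Fisher", {
  d <- make_screen_data(n_kzfp = 8, n_fam = 10, seed = 124,
                        planted = list(c(1, 1), c(2, 2)), r = 0.9)
  scr <- pairwise_family_screen(d$kz, d$te, d$tissue)
  enr <- expand.grid(kzfp = rownames(d$kz), family = rownames(d$te),
                     stringsAsFactors = FALSE)
  set.seed(125)
  enr$score <- runif(nrow(enr), 0, 2)
  ov <- binding_overlap_family(scr, enr, min_tissues = 2)
  expect_identical(ov$universe_size, 80L)
  expect_identical(ov$n_kzfp, 8L)
  # Fisher result equals the hypergeometric computation on the same table
  tab <- ov$table
  p_hyper <- fisher.test(tab)$p.value
  expect_equal(ov$p_value, p_hyper, tolerance = 1e-12)

  # perfect nesting: all co-expressed pairs bound
  enr2 <- enr
  enr2$score <- ifelse(paste(enr2$kzfp, enr2$family) %in%
                         c("ZNF001 FAM001", "ZNF002 FAM002"), 2, 0)
  ov2 <- binding_overlap_family(scr, enr2, min_tissues = 2)
  expect_true(is.infinite(ov2$odds_ratio))
  expect_lt(ov2$p_value, 0.01)
})

test_that("peak overlap respects the 250-base buffer exactly", {
  te <- data.frame(locus_id = "T_dup1", chrom = "chr1",
                   start = 1000L, end = 1300L, strand = "+", family = "T",
                   stringsAsFactors = FALSE)
  at_edge <- data.frame(chrom = "chr1", start = 500L, end = 750L)
  expect_identical(peak_te_overlap(at_edge, te, buffer = 250), "T_dup1")
  too_far <- data.frame(chrom = "chr1", start = 500L, end = 749L)
  expect_identical(peak_te_overlap(too_far, te, buffer = 250), character(0))

  set.seed(126)
  peaks <- data.frame(chrom = "chr1",
                      start = sample.int(10000, 60))
  peaks$end <- peaks$start + sample.int(300, 60)
  te2 <- data.frame(locus_id = sprintf("T_dup%d", 1:40), chrom = "chr1",
                    start = sample.int(10000, 40), stringsAsFactors = FALSE)
  te2$end <- te2$start + 300L
  got <- peak_te_overlap(peaks, te2, buffer = 250)
  # quadratic oracle: bound iff the gap between peak and locus is <= 250
  buf <- data.frame(chrom = peaks$chrom, start = pmax(peaks$start - 250L, 0L),
                    end = peaks$end + 251L)  # +1: a gap of exactly 250 binds
  want <- te2$locus_id[overlap_oracle(te2[, c("chrom", "start", "end")], buf)]
  expect_setequal(got, want)
})

test_that("expressed-locus rule is strictly greater-than", {
  m <- matrix(c(6, 0, 5, 5, 0, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  # a: max 6 -> expressed; c: max 5 -> not (strictly greater than 5)
  expect_identical(expressed_loci(m), "a")
  expect_identical(expressed_loci(matrix(0, 2, 2,
                                         dimnames = list(c("x", "y"), NULL))),
                   character(0))
})

test_that("category proportions hit 1 with blanket marks and recover planted bias", {
  te <- data.frame(locus_id = sprintf("T_dup%d", 1:40), chrom = "chr1",
                   start = seq(0L, 39000L, by = 1000L), stringsAsFactors = FALSE)
  te$end <- te$start + 300L
  te$context <- rep(c("intergenic", "intronic"), 20)
  expressed <- te$locus_id[1:20]
  bound <- te$locus_id[seq(1, 40, 2)]
  blanket <- list(everywhere = data.frame(chrom = "chr1", start = 0L,
                                          end = 50000L))
  res <- category_mark_overlap(te, expressed, bound, blanket)
  expect_true(all(res$proportion == 1))
  none <- category_mark_overlap(te, expressed, bound,
                                list(nothing = data.frame(chrom = "chr2",
                                                          start = 0L,
                                                          end = 10L)))
  expect_true(all(none$proportion == 0))

  # marks planted preferentially on expressed loci
  marked <- te[te$locus_id %in% expressed, ][1:15, ]
  res2 <- category_mark_overlap(
    te, expressed, bound,
    list(biased = marked[, c("chrom", "start", "end")]))
  p_expr <- res2$proportion[grepl("^expressed", res2$category)]
  p_sil <- res2$proportion[grepl("^silent", res2$category)]
  expect_gt(min(p_expr), max(p_sil))
})

test_that("gene filters enforce detection, RPM and positional exclusions", {
  m <- matrix(10, 4, 10,
              dimnames = list(c("g1", "g2", "g3", "g4"),
                              sprintf("s%02d", 1:10)))
  m["g2", 1:4] <- 0           # detected in only 6 samples
  m["g3", ] <- 1              # low RPM
  lib <- rep(1e6, 10)
  keep <- filter_screen_genes(m, lib, min_patients = 8, min_rpm = 2,
                              rpm_fraction = 0.75, exclude = "g4")
  expect_identical(keep, "g1")
})

test_that("the L1HS model recovers a planted coefficient and prunes covariates", {
  set.seed(127)
  n <- 60
  tissue <- rep(c("t1", "t2"), each = 30)
  gene <- rnorm(n)
  lib <- rnorm(n)
  covs <- data.frame(lib = lib, batch = rnorm(n), rad = rnorm(n),
                     n1 = rnorm(n))
  y <- 0.8 * gene + 0.5 * lib + rnorm(n, 0, 0.4)
  gm <- matrix(gene, 1, n, dimnames = list("GENE1", sprintf("s%03d", 1:n)))
  scr <- l1hs_gene_screen(gm, setNames(y, colnames(gm)), covs, tissue,
                          q_threshold = 0.01, min_tissues = 2)
  res <- scr$result
  expect_identical(nrow(res), 2L)
  expect_true(all(abs(res$coefficient - 0.8) < 0.2))
  expect_true(all(grepl("lib", res$covariates)))
  expect_identical(scr$replicated, "GENE1")
  expect_true(all(res$partial_eta_sq > 0 & res$partial_eta_sq <= 1))
})

test_that("models with too few residual degrees of freedom are excluded", {
  # n = 6 with 4 covariates: the full model has n - k - 1 <= 0 and must not
  # be selected even though it fits perfectly
  set.seed(128)
  n <- 6
  gene <- rnorm(n)
  covs <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  y <- gene + rnorm(n, 0, 0.1)
  gm <- matrix(gene, 1, n, dimnames = list("G", sprintf("s%d", 1:n)))
  scr <- l1hs_gene_screen(gm, setNames(y, colnames(gm)), covs,
                          rep("t1", n), q_threshold = 0.5, min_tissues = 1)
  expect_lt(nchar(scr$result$covariates), 7)  # never all four covariates
})
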