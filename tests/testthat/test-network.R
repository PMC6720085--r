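# planted two-block expression: features 1..n1 load factor 1, rest factor 2,
# within-block correlation set by the loading/noise ratio
two_block_matrix <- function(n1 = 30, n2 = 30, n_samples = 40, load = 2,
                             noise = 1, seed = 1) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  m <- rbind(
    t(sapply(seq_len(n1), function(i) load * f1 + rnorm(n_samples, 0, noise))),
    t(sapply(seq_len(n2), function(i) load * f2 + rnorm(n_samples, 0, noise)))
  )
  rownames(m) <- c(sprintf("blk1_%03d", seq_len(n1)),
                   sprintf("blk2_%03d", seq_len(n2)))
  colnames(m) <- sprintf("s%03d", seq_len(n_samples))
  list(m = m, f1 = f1, f2 = f2)
}

test_that("signed adjacency maps correlations to [0, 1] as specified", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  colnames(m) <- sprintf("s%d", 1:4)
  a <- signed_adjacency(m, beta = 14)
  expect_equal(a["a", "b"], 1)          # cor +1
  expect_equal(a["a", "c"], 0)          # cor -1
  expect_true(all(a >= 0 & a <= 1))
  expect_true(isSymmetric(unclass(a)))
  m0 <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  colnames(m0) <- sprintf("s%d", 1:4)
  expect_error(signed_adjacency(m0), "zero-variance")

  # cor 0 -> 0.5^14, via constructed orthogonal profiles
  m2 <- rbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  colnames(m2) <- sprintf("s%d", 1:4)
  a2 <- signed_adjacency(m2, beta = 14)
  expect_equal(a2["a", "b"], 0.5^14)
})

test_that("TOM has the closed-form 2-node value and correct limits", {
  a <- matrix(c(1, 0.6, 0.6, 1), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(tom(a)["x", "y"], 0.6)   # x/(min(k)+1-x) = x for 2 nodes

  n <- 6
  eye <- diag(n); dimnames(eye) <- list(letters[1:n], letters[1:n])
  expect_true(all(tom(eye)[upper.tri(eye)] == 0))
  ones <- matrix(1, n, n, dimnames = dimnames(eye))
  expect_true(all(tom(ones) == 1))

  set.seed(111)
  r <- matrix(runif(n * n, 0, 0.9), n, n); r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- dimnames(eye)
  tt <- tom(r)
  expect_true(all(tt >= 0 & tt <= 1))
  expect_true(isSymmetric(tt))
  # permutation equivariance
  p <- sample(n)
  expect_equal(tom(r[p, p]), tt[p, p], tolerance = 1e-12)
})

test_that("consensus TOM is the element-wise minimum", {
  t1 <- matrix(c(1, 0.8, 0.8, 1), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- matrix(c(1, 0.1, 0.1, 1), 2, 2, dimnames = dimnames(t1))
  expect_equal(consensus_tom(list(a = t1)), t1)
  cons <- consensus_tom(list(a = t1, b = t2))
  expect_equal(cons["x", "y"], 0.1)
  expect_true(all(cons <= t1) && all(cons <= t2))
  t3 <- t2; dimnames(t3) <- list(c("x", "z"), c("x", "z"))
  expect_error(consensus_tom(list(t1, t3)), "mismatched")
})

test_that("planted blocks are recovered with faithful eigengenes", {
  blocks <- lapply(c(112, 113), function(s)
    two_block_matrix(n1 = 40, n2 = 40, n_samples = 40, seed = s))
  mats <- lapply(blocks, `[[`, "m")
  names(mats) <- c("t1", "t2")
  net <- consensus_network(mats, beta = 14, min_module_size = 30)
  truth <- rep(1:2, each = 40)
  names(truth) <- rownames(mats$t1)

  # Rand index against the planted split
  rand_index <- function(a, b) {
    pairs <- combn(length(a), 2)
    same_a <- a[pairs[1, ]] == a[pairs[2, ]]
    same_b <- b[pairs[1, ]] == b[pairs[2, ]]
    mean(same_a == same_b)
  }
  expect_gte(rand_index(net$modules[names(truth)], truth), 0.9)

  # eigengene of the factor-1 block tracks the planted factor
  mod_of_blk1 <- as.integer(names(which.max(
    table(net$modules[sprintf("blk1_%03d", 1:40)]))))
  eg <- eigengene(mats$t1, names(net$modules)[net$modules == mod_of_blk1])
  expect_gte(abs(cor(eg, blocks[[1]]$f1)), 0.95)
})

test_that("pure noise leaves most features unassigned", {
  set.seed(114)
  m <- matrix(rnorm(200 * 30), 200, 30,
              dimnames = list(sprintf("f%03d", 1:200),
                              sprintf("s%02d", 1:30)))
  mods <- detect_modules(tom(signed_adjacency(m)), min_module_size = 30)
  expect_gt(mean(mods == 0), 0.8)
  expect_true(all(detect_modules(tom(signed_adjacency(m)),
                                 min_module_size = 300) == 0))
})

test_that("eigengenes are unit-norm, oriented, and exact on rank-1 input", {
  set.seed(115)
  f <- rnorm(20)
  m <- outer(c(2, 3, 4), f)  # rank-1, no noise
  rownames(m) <- c("a", "b", "c"); colnames(m) <- sprintf("s%02d", 1:20)
  e <- eigengene(m, c("a", "b", "c"))
  expect_equal(sum(e^2), 1, tolerance = 1e-12)
  expect_equal(abs(cor(e, f)), 1, tolerance = 1e-10)
  expect_gt(cor(e, m["a", ]), 0)
  # flipping every member still yields a profile positively tracking members
  e2 <- eigengene(-m, c("a", "b", "c"))
  expect_gt(cor(e2, -m["a", ]), 0)
  expect_error(eigengene(m, "a"), "at least 2")
})

test_that("module screens apply kME and anti-correlation rules across tissues", {
  set.seed(116)
  n <- 40
  f <- rnorm(n)
  mk <- function(noise_sd) {
    m <- rbind(
      t(sapply(1:35, function(i) 2 * f + rnorm(n, 0, noise_sd))),
      t(sapply(1:35, function(i) -2 * f + rnorm(n, 0, noise_sd)))
    )
    rownames(m) <- c(sprintf("TEfam_%02d", 1:35), sprintf("gene_%02d", 1:35))
    colnames(m) <- sprintf("s%02d", 1:n)
    m
  }
  mats <- list(t1 = mk(0.8), t2 = mk(0.8))
  modules <- setNames(rep(1:2, each = 35), rownames(mats$t1))
  scr <- module_screens(modules, mats, te_features = sprintf("TEfam_%02d", 1:35))
  expect_gt(length(scr$strict_members), 40)
  expect_identical(scr$te_modules, 1L)
  expect_identical(scr$core_te_modules, 1L)
  expect_equal(nrow(scr$anticorrelated_pairs), 1L)
  expect_identical(scr$anticorrelated_pairs$module_a, 1L)
})

test_that("soft-power selection falls back on uncorrelated data", {
  set.seed(117)
  m <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(sprintf("f%02d", 1:50), sprintf("s%02d", 1:10)))
  expect_identical(unname(c(soft_power_selection(m, candidate_powers = 14))),
                   14)
  expect_error(soft_power_selection(m, candidate_powers = numeric(0)))
})
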