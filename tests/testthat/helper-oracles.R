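# Independent oracles used to freeze expected values. These deliberately use
# brute force / direct optimization, never the package's own code paths.

# Maximum-likelihood abundances of the multinomial mixture by coarse grid
# search plus direct likelihood optimization (softmax parametrization),
# followed by one E-step to get expected counts. `classes` is a list of
# character candidate sets, `n` the fragment count per class.
ml_oracle <- function(classes, n, loci = sort(unique(unlist(classes))),
                      start_pi = NULL) {
  k <- length(loci)
  memb <- lapply(classes, function(s) match(s, loci))
  ll <- function(pi) sum(n * log(vapply(memb, function(m) sum(pi[m]), 0)))
  # coarse simplex grid
  best_pi <- rep(1 / k, k); best_ll <- ll(best_pi)
  step <- 0.05
  if (k == 1) {
    best_pi <- 1
  } else if (k == 2) {
    for (a in seq(step, 1 - step, by = step)) {
      p <- c(a, 1 - a); v <- ll(p)
      if (v > best_ll) { best_ll <- v; best_pi <- p }
    }
  } else {
    for (a in seq(step, 1 - 2 * step + 1e-9, by = step))
      for (b in seq(step, max(1 - a - step, step) + 1e-9, by = step)) {
        p <- c(a, b, 1 - a - b); v <- ll(p)
        if (v > best_ll) { best_ll <- v; best_pi <- p }
      }
  }
  # polish with unconstrained softmax optimization (optionally from a
  # caller-supplied start, used by the multi-start uniqueness probe)
  if (k > 1) {
    obj <- function(theta) {
      pi <- exp(c(theta, 0)); pi <- pi / sum(pi)
      -ll(pi)
    }
    start <- if (is.null(start_pi)) best_pi else start_pi
    par0 <- log(pmax(start[-k], 1e-8) / max(start[k], 1e-8))
    opt <- if (length(par0) == 1L)
      optim(par0, obj, method = "BFGS",
            control = list(maxit = 5000, reltol = 1e-14))
    else
      optim(par0, obj, method = "Nelder-Mead",
            control = list(maxit = 5000, reltol = 1e-14))
    pi <- exp(c(opt$par, 0)); pi <- pi / sum(pi)
    if (ll(pi) > best_ll || !is.null(start_pi)) {
      if (ll(pi) >= best_ll - 1e-9) { best_pi <- pi; best_ll <- ll(pi) }
    }
  }
  counts <- setNames(numeric(k), loci)
  for (i in seq_along(memb)) {
    denom <- sum(best_pi[memb[[i]]])
    counts[memb[[i]]] <- counts[memb[[i]]] +
      n[i] * best_pi[memb[[i]]] / denom
  }
  list(pi = best_pi, loglik = best_ll, counts = counts)
}

# expand a class specification into a fragment/locus pair table
classes_to_pairs <- function(classes, n) {
  frag <- 0L
  rows <- list()
  for (i in seq_along(classes)) {
    for (j in seq_len(n[i])) {
      frag <- frag + 1L
      rows[[frag]] <- data.frame(fragment_id = sprintf("f%04d", frag),
                                 locus_id = classes[[i]],
                                 stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Smith-Waterman local alignment with linear gap cost (match +1, mismatch -1,
# gap -2); returns the best-scoring local span on each sequence.
sw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (a[i] == b[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] + gap, H[i + 1, j] + gap)
    if (H[i + 1, j + 1] > best) { best <- H[i + 1, j + 1]; bi <- i; bj <- j }
  }
  # traceback for the start of the span
  i <- bi; j <- bj
  while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
    s <- if (a[i] == b[j]) match else mismatch
    if (H[i + 1, j + 1] == H[i, j] + s) { i <- i - 1; j <- j - 1 }
    else if (H[i + 1, j + 1] == H[i, j + 1] + gap) i <- i - 1
    else j <- j - 1
  }
  list(score = best, a_start0 = i, a_end = bi, b_start0 = j, b_end = bj)
}

# brute-force quadratic interval overlap (0-based half-open)
overlap_oracle <- function(q, s) {
  hits <- logical(nrow(q))
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(s))) {
      if (q$chrom[i] == s$chrom[j] &&
          q$start[i] < s$end[j] && s$start[j] < q$end[i]) {
        hits[i] <- TRUE; break
      }
    }
  }
  hits
}

# brute-force 48-mer mappability: count of positions inside [start, end)
# whose k-mer (canonical across strands) occurs exactly once genome-wide
mappability_oracle <- function(genome_chr, te, k = 48) {
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  all_kmers <- character(0)
  for (s in genome_chr) {
    n <- nchar(s) - k + 1
    km <- substring(s, 1:n, 1:n + k - 1)
    all_kmers <- c(all_kmers, pmin(km, vapply(km, rc, "")))
  }
  cnt <- table(all_kmers)
  out <- integer(nrow(te))
  for (i in seq_len(nrow(te))) {
    s <- genome_chr[[te$chrom[i]]]
    tot <- 0
    for (p in te$start[i]:(te$end[i] - 1)) {
      if (p + k > nchar(s)) next
      km <- substr(s, p + 1, p + k)
      if (cnt[[min(km, rc(km))]] == 1) tot <- tot + 1
    }
    out[i] <- tot
  }
  setNames(out, te$locus_id)
}

# small synthetic count matrix with planted per-sample depths
depth_matrix <- function(n_genes, depths, base_mean = 100, seed = 1) {
  set.seed(seed)
  mu <- rexp(n_genes, 1 / base_mean)
  m <- sapply(depths, function(d) rpois(n_genes, mu * d))
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_along(depths))
  m
}
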