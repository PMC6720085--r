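# fast Pearson correlation screen: all predictor x response pairs in one
# tissue, p-values from the t distribution, BH within the batch
.cor_screen <- function(pred_mat, resp_mat) {
  n <- ncol(pred_mat)
  ok_p <- apply(pred_mat, 1, sd) > 0
  ok_r <- apply(resp_mat, 1, sd) > 0
  r <- cor(t(pred_mat[ok_p, , drop = FALSE]),
           t(resp_mat[ok_r, , drop = FALSE]))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  dt <- data.table::data.table(
    predictor = rep(rownames(r), ncol(r)),
    response = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), p = as.vector(p), n_samples = n
  )
  dt$q <- p.adjust(dt$p, method = "BH")
  list(result = dt, n_skipped = sum(!ok_p) * nrow(resp_mat) +
         sum(ok_p) * sum(!ok_r))
}

#' Pairwise KZFP x TE family co-expression screen
#'
#' Pearson correlation between every KZFP gene and every TE family within
#' each tissue, two-sided t-test p-values, Benjamini-Hochberg q-values within
#' tissue. A pair is co-expressed in a tissue when `q < q_threshold`; the
#' replication count is the number of tissues where this holds (and
#' `replication_consistent` additionally requires one sign across those
#' tissues). Constant profiles are skipped and tallied.
#'
#' @param kzfp_log2,te_family_log2 features x samples log2 matrices over the
#'   same samples.
#' @param tissue tissue label per sample (screen runs per tissue).
#' @param q_threshold significance cutoff (default 0.05).
#' @param min_samples minimum samples per tissue (default 8).
#' @return List of class `"tecoex_screen"`: `result` (per pair per tissue:
#'   `r`, `p`, `q`, `significant`), `replication` (per pair: tissues
#'   significant, sign consistency), `n_skipped`.
#' @export
pairwise_family_screen <- function(kzfp_log2, te_family_log2, tissue,
                                   q_threshold = 0.05, min_samples = 8L) {
  kz <- as.matrix(kzfp_log2); te <- as.matrix(te_family_log2)
  stopifnot(ncol(kz) == ncol(te), length(tissue) == ncol(kz))
  out <- list(); skipped <- 0L
  for (t_ in unique(tissue)) {
    cols <- which(tissue == t_)
    if (length(cols) < min_samples)
      stop("tissue ", t_, " has fewer than ", min_samples, " samples")
    sc <- .cor_screen(kz[, cols, drop = FALSE], te[, cols, drop = FALSE])
    sc$result$tissue <- t_
    skipped <- skipped + sc$n_skipped
    out[[t_]] <- sc$result
  }
  res <- data.table::rbindlist(out)
  res[, significant := q < q_threshold]
  repl <- res[, .(
    n_tissues_significant = sum(significant),
    sign_consistent = {
      s <- sign(r[significant])
      length(s) == 0L || all(s == s[1])
    }
  ), by = .(predictor, response)]
  structure(list(result = res, replication = repl, n_skipped = skipped,
                 q_threshold = q_threshold), class = "tecoex_screen")
}

#' Locus-level follow-up of significant family pairs
#'
#' For each significant (KZFP, family, tissue) hit, correlates the KZFP with
#' each individual locus of the family in that tissue; BH adjustment within
#' the whole follow-up batch.
#'
#' @param screen a `tecoex_screen` from [pairwise_family_screen()].
#' @param kzfp_log2 KZFP log2 matrix.
#' @param te_locus_log2 locus-level log2 matrix.
#' @param locus_family named family per locus (or TE table with `locus_id`
#'   and `family`).
#' @param tissue tissue label per sample.
#' @param q_threshold follow-up significance cutoff (default 0.05).
#' @return `data.table` of locus-level tests with `q` and `significant`.
#' @export
locus_followup <- function(screen, kzfp_log2, te_locus_log2, locus_family,
                           tissue, q_threshold = 0.05) {
  if (is.data.frame(locus_family))
    locus_family <- setNames(locus_family$family, locus_family$locus_id)
  hits <- screen$result[significant == TRUE]
  if (!nrow(hits))
    return(data.table::data.table(predictor = character(0),
                                  locus_id = character(0), tissue = character(0),
                                  r = numeric(0), p = numeric(0), q = numeric(0),
                                  significant = logical(0)))
  kz <- as.matrix(kzfp_log2); lo <- as.matrix(te_locus_log2)
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    fam_loci <- names(locus_family)[locus_family == hits$response[i]]
    fam_loci <- intersect(fam_loci, rownames(lo))
    cols <- which(tissue == hits$tissue[i])
    x <- kz[hits$predictor[i], cols]
    for (l in fam_loci) {
      y <- lo[l, cols]
      if (sd(y) == 0 || sd(x) == 0) next
      ct <- cor.test(x, y)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        predictor = hits$predictor[i], locus_id = l,
        tissue = hits$tissue[i], r = unname(ct$estimate), p = ct$p.value)
    }
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out)) {
    out[, q := p.adjust(p, method = "BH")]
    out[, significant := q < q_threshold]
  }
  out
}

#' Association between co-expression and binding enrichment
#'
#' Builds the 2x2 table (co-expressed? x binding-enriched?) over the shared
#' universe of (KZFP, TE family) pairs -- KZFPs present in the binding assay
#' crossed with families present in both datasets -- and tests association
#' with Fisher's exact test.
#'
#' @param screen a `tecoex_screen` from [pairwise_family_screen()].
#' @param enrichment data frame with columns `kzfp`, `family`, `score` (one
#'   row per assayed pair with a reported enrichment).
#' @param score_threshold binding call: `score > score_threshold` (default 1).
#' @param min_tissues co-expression call: significant in at least this many
#'   tissues (1 or 2; default 1).
#' @return List of class `"tecoex_overlap"`: `table` (2x2), `p_value`,
#'   `odds_ratio`, `universe_size`, `n_kzfp`, `n_family`.
#' @export
binding_overlap_family <- function(screen, enrichment, score_threshold = 1,
                                   min_tissues = 1L) {
  repl <- screen$replication
  kz <- intersect(unique(repl$predictor), unique(enrichment$kzfp))
  fam <- intersect(unique(repl$response), unique(enrichment$family))
  if (!length(kz) || !length(fam)) stop("empty co-expression/binding universe")
  uni <- data.table::CJ(predictor = kz, response = fam)
  uni <- merge(uni, repl, by = c("predictor", "response"), all.x = TRUE)
  uni[is.na(n_tissues_significant), n_tissues_significant := 0L]
  enr <- data.table::as.data.table(enrichment)
  bound_pairs <- enr[score > score_threshold, paste(kzfp, family)]
  uni[, coexpressed := n_tissues_significant >= min_tissues]
  uni[, bound := paste(predictor, response) %in% bound_pairs]
  tab <- table(factor(uni$coexpressed, c(TRUE, FALSE)),
               factor(uni$bound, c(TRUE, FALSE)),
               dnn = c("coexpressed", "bound"))
  ft <- fisher.test(tab)
  structure(list(table = tab, p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate),
                 universe_size = nrow(uni), n_kzfp = length(kz),
                 n_family = length(fam)),
            class = "tecoex_overlap")
}

#' TE loci bound by peaks (with buffer)
#'
#' A locus is bound when any peak, extended by `buffer` bases on each side,
#' reaches it: a peak whose boundary lies exactly `buffer` bases from the
#' locus counts as bound, one base further does not. Coordinates are never
#' extended below 0.
#'
#' @param peaks data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param te TE locus table.
#' @param buffer extension in bases (default 250).
#' @return Character vector of bound `locus_id`s.
#' @export
peak_te_overlap <- function(peaks, te, buffer = 250L) {
  if (!nrow(peaks)) return(character(0))
  pk_gr <- .gr0(peaks[, c("chrom", "start", "end")])
  te_gr <- .gr0(te[, c("chrom", "start", "end")])
  bound <- IRanges::overlapsAny(te_gr, pk_gr, maxgap = buffer,
                                ignore.strand = TRUE)
  te$locus_id[bound]
}

#' Expressed TE loci
#'
#' A locus is expressed when some sample has strictly more than `threshold`
#' reads mapped to it.
#'
#' @param raw_counts loci x samples raw (or corrected) count matrix.
#' @param threshold read-count cutoff (default 5; `> 5`, strictly).
#' @return Character vector of expressed `locus_id`s.
#' @export
expressed_loci <- function(raw_counts, threshold = 5) {
  m <- as.matrix(raw_counts)
  if (!nrow(m)) return(character(0))
  rownames(m)[apply(m, 1, max) > threshold]
}

#' Regulatory-mark overlap by expression/binding category
#'
#' Splits loci into the four expressed x bound categories and reports, for
#' each named mark interval set, the proportion of loci in each category
#' overlapped by at least one mark (optionally split by gene-region vs
#' intergenic context).
#'
#' @param te contexted TE table.
#' @param expressed character vector of expressed locus ids.
#' @param bound character vector of bound locus ids.
#' @param marks named list of mark interval data frames (`chrom`, `start`,
#'   `end`).
#' @param split_context also split by genic (exonic/intronic/proximal) vs
#'   intergenic context.
#' @return Data frame: `mark`, `category`, (`region`,) `n_loci`,
#'   `proportion`.
#' @export
category_mark_overlap <- function(te, expressed, bound, marks,
                                  split_context = FALSE) {
  te_gr <- .gr0(te[, c("chrom", "start", "end")])
  cat_ <- paste0(ifelse(te$locus_id %in% expressed, "expressed", "silent"),
                 "_",
                 ifelse(te$locus_id %in% bound, "bound", "unbound"))
  region <- if (split_context && "context" %in% names(te))
    ifelse(te$context == "intergenic", "intergenic", "genic")
  else rep("all", nrow(te))
  rows <- list()
  for (mk in names(marks)) {
    mgr <- .gr0(marks[[mk]][, c("chrom", "start", "end")])
    # marks confined to other chromosomes are a legitimate all-miss case
    hit <- suppressWarnings(
      IRanges::overlapsAny(te_gr, mgr, ignore.strand = TRUE))
    agg <- stats::aggregate(hit, by = list(category = cat_, region = region),
                            FUN = function(x) c(n = length(x), p = mean(x)))
    rows[[mk]] <- data.frame(mark = mk, category = agg$category,
                             region = agg$region,
                             n_loci = agg$x[, "n"], proportion = agg$x[, "p"],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# second-order Akaike information criterion
.aicc <- function(fit) {
  k <- attr(logLik(fit), "df")
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) return(NA_real_)
  AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Gene filters for the L1HS screen
#'
#' Keeps genes detected (count > 0) in at least `min_patients` samples and
#' with reads-per-million at or above `min_rpm` in at least `rpm_fraction`
#' of samples; genes in `exclude` (e.g. genes positionally overlapping
#' counted L1HS loci) are removed.
#'
#' @param raw_counts genes x samples raw count matrix.
#' @param lib_sizes per-sample library sizes for the RPM computation
#'   (default: column sums).
#' @param min_patients detection threshold (default 8).
#' @param min_rpm,rpm_fraction RPM threshold (default 2 in 75% of samples).
#' @param exclude gene ids to drop.
#' @return Character vector of passing gene ids.
#' @export
filter_screen_genes <- function(raw_counts, lib_sizes = NULL,
                                min_patients = 8L, min_rpm = 2,
                                rpm_fraction = 0.75, exclude = character(0)) {
  m <- as.matrix(raw_counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  rpm <- sweep(m, 2, lib_sizes / 1e6, `/`)
  ok <- rowSums(m > 0) >= min_patients &
    rowMeans(rpm >= min_rpm) >= rpm_fraction
  setdiff(rownames(m)[ok], exclude)
}

#' L1HS 5' x gene linear-model screen with all-subsets AICc selection
#'
#' Within each tissue, models `log2 L1HS ~ log2 gene (+ covariates)`, fitting
#' every subset of the optional covariates (the gene term is always
#' included) and selecting the model with the smallest AICc
#' (`AIC + 2k(k+1)/(n-k-1)`; models with `n - k - 1 <= 0` are excluded).
#' Reports the gene coefficient, its p-value and partial eta-squared from
#' the selected model, BH q-values within tissue, and calls a gene
#' replicated when `q < q_threshold` with a consistent coefficient sign in
#' at least `min_tissues` tissues.
#'
#' @param gene_log2 genes x samples log2 matrix (already filtered, e.g. via
#'   [filter_screen_genes()]).
#' @param l1hs_log2 named per-sample log2 L1HS 5' signal.
#' @param covariates data frame of optional covariates per sample (e.g.
#'   log2 effective library size, batch, radiation, intronic-TE module
#'   eigengene); may be `NULL`.
#' @param tissue tissue label per sample.
#' @param q_threshold replication q cutoff (default 1e-4).
#' @param min_tissues tissues required for replication (default 2).
#' @return List of class `"tecoex_l1hs_screen"`: `result` (per gene per
#'   tissue: coefficient, p, q, partial eta-squared, selected covariates),
#'   `replicated` (gene ids).
#' @export
l1hs_gene_screen <- function(gene_log2, l1hs_log2, covariates = NULL,
                             tissue, q_threshold = 1e-4, min_tissues = 2L) {
  g <- as.matrix(gene_log2)
  stopifnot(length(l1hs_log2) == ncol(g))
  cov_names <- if (is.null(covariates)) character(0) else colnames(covariates)
  subsets <- if (length(cov_names))
    lapply(seq_len(2^length(cov_names)) - 1L, function(b)
      cov_names[bitwAnd(b, 2^(seq_along(cov_names) - 1L)) > 0])
  else list(character(0))

  rows <- list()
  for (t_ in unique(tissue)) {
    cols <- which(tissue == t_)
    y <- l1hs_log2[cols]
    cv <- if (is.null(covariates)) NULL else covariates[cols, , drop = FALSE]
    for (gene in rownames(g)) {
      x <- g[gene, cols]
      if (sd(x) == 0) next
      best <- NULL; best_aicc <- Inf; best_cov <- character(0)
      for (ss in subsets) {
        dat <- data.frame(y = y, gene = x)
        if (length(ss)) dat <- cbind(dat, cv[, ss, drop = FALSE])
        fit <- lm(y ~ ., data = dat)
        a <- .aicc(fit)
        if (!is.na(a) && a < best_aicc) {
          best <- fit; best_aicc <- a; best_cov <- ss
        }
      }
      if (is.null(best)) next
      sm <- summary(best)$coefficients
      if (!"gene" %in% rownames(sm)) next
      tval <- sm["gene", "t value"]
      dfres <- best$df.residual
      rows[[length(rows) + 1L]] <- data.table::data.table(
        response = "L1HS_5p", predictor = gene, tissue = t_,
        coefficient = sm["gene", "Estimate"], p = sm["gene", "Pr(>|t|)"],
        partial_eta_sq = tval^2 / (tval^2 + dfres),
        n_samples = length(cols), aicc = best_aicc,
        covariates = paste(best_cov, collapse = "+"))
    }
  }
  res <- data.table::rbindlist(rows)
  if (nrow(res)) res[, q := p.adjust(p, method = "BH"), by = tissue]
  repl <- res[, .(
    n_sig = sum(q < q_threshold),
    consistent = {
      s <- sign(coefficient[q < q_threshold])
      length(s) > 0L && all(s == s[1])
    }), by = predictor]
  structure(list(result = res,
                 replicated = repl[n_sig >= min_tissues & consistent == TRUE,
                                   predictor]),
            class = "tecoex_l1hs_screen")
}
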