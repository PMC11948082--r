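# Transcriptomic / immune association stage: TPM normalization, moderated
# differential expression, preranked and single-sample gene-set enrichment,
# marker-based immune indices, feature-immune correlation, Ro/e, and group
# comparison.

#' TPM normalization
#'
#' `TPM_g = 1e6 * (c_g / L_g) / sum_j (c_j / L_j)` per sample; every column
#' sums to one million.
#'
#' @param counts Genes x samples non-negative count matrix.
#' @param gene_lengths_kb Per-gene lengths in kilobases (named or aligned).
#' @return TPM matrix of the same shape.
#' @export
tpm_normalize <- function(counts, gene_lengths_kb) {
  counts <- as.matrix(counts)
  L <- as.numeric(gene_lengths_kb)
  if (length(L) != nrow(counts)) stop("one length per gene required", call. = FALSE)
  if (any(L <= 0)) stop("gene lengths must be positive", call. = FALSE)
  rate <- counts / L
  lib <- colSums(rate)
  if (any(lib == 0)) stop("zero library after length correction", call. = FALSE)
  sweep(rate, 2, lib, "/") * 1e6
}

#' Moderated two-group differential expression
#'
#' Per-gene two-sample comparison on `log2(TPM + 1)` with empirical-Bayes
#' variance moderation: the residual variances are shrunk toward a pooled
#' prior whose scale and degrees of freedom are fitted by moment matching of
#' the log residual variances, and the moderated t statistic is referred to
#' a t distribution with augmented degrees of freedom. Benjamini-Hochberg
#' adjusted p-values are reported alongside the raw ones.
#'
#' @param expr Genes x samples matrix of `log2(TPM + 1)` values.
#' @param groups Per-sample labels with exactly two levels (`low`/`high` or
#'   any two values; the second sorted level is the "high" group).
#' @param alpha Significance threshold recorded in the report.
#' @return Tibble: gene, log_fc (high minus low), t, p_value, p_adjusted,
#'   significant.
#' @export
differential_expression <- function(expr, groups, alpha = 0.05) {
  expr <- as.matrix(expr)
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  g1 <- if ("high" %in% lv) groups == "high" else groups == lv[2]
  n1 <- sum(g1)
  n0 <- sum(!g1)
  if (min(n1, n0) < 3) stop("each group needs at least 3 samples", call. = FALSE)
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m0 <- rowMeans(expr[, !g1, drop = FALSE])
  v1 <- apply(expr[, g1, drop = FALSE], 1, stats::var)
  v0 <- apply(expr[, !g1, drop = FALSE], 1, stats::var)
  df <- n1 + n0 - 2
  s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / df
  # moment matching of log s2 to a scaled inverse-chi-square prior:
  # var(log s2) = trigamma(df/2) + trigamma(d0/2)
  pos <- s2 > 0
  zg <- log(s2[pos])
  excess <- stats::var(zg) - trigamma(df / 2)
  d0 <- if (is.finite(excess) && excess > 1e-8) {
    # invert trigamma by bisection
    f <- function(d) trigamma(d / 2) - excess
    lo <- 0.1; hi <- 1e7
    if (f(hi) > 0) Inf else stats::uniroot(f, c(lo, hi))$root
  } else {
    Inf
  }
  s0_2 <- if (is.finite(d0)) {
    exp(mean(zg) - digamma(df / 2) + digamma(d0 / 2) + log(df / d0))
  } else {
    exp(mean(zg) - digamma(df / 2) + log(df / 2))
  }
  s2_post <- if (is.finite(d0)) (d0 * s0_2 + df * s2) / (d0 + df) else rep(s0_2, length(s2))
  s2_post[!pos & s2_post <= 0] <- s0_2
  df_post <- if (is.finite(d0)) d0 + df else 1e6
  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  lfc <- m1 - m0
  tstat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = df_post)
  zero_var <- v1 == 0 & v0 == 0 & lfc == 0
  p[zero_var] <- 1
  tibble::tibble(
    gene = rownames(expr) %||% as.character(seq_len(nrow(expr))),
    log_fc = unname(lfc), t = unname(tstat), p_value = unname(p),
    p_adjusted = stats::p.adjust(p, "BH"),
    significant = p < alpha
  )
}

#' Preranked gene-set enrichment (weighted Kolmogorov-Smirnov)
#'
#' Walks the ranked gene list accumulating the weighted running-sum
#' difference between in-set and out-of-set ECDFs (weight = |score|^p). The
#' enrichment score is the extreme deviation; NES divides by the mean |ES|
#' of same-sign scores over gene-label permutations, with a two-sided
#' permutation p-value.
#'
#' @param scores Named numeric ranking statistic (e.g. DE t statistics).
#' @param gene_set Character vector of gene names.
#' @param n_permutations Gene-label permutations for the null.
#' @param weight Rank-weight exponent (1 = classic weighted GSEA).
#' @param seed Integer seed.
#' @return List: es, nes, p_value, n_overlap.
#' @export
gsea_preranked <- function(scores, gene_set, n_permutations = 1000, weight = 1,
                           seed = NULL) {
  if (is.null(names(scores))) stop("scores must be named by gene", call. = FALSE)
  if (anyDuplicated(names(scores))) stop("gene names must be unique", call. = FALSE)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  in_set <- names(scores) %in% gene_set
  m <- sum(in_set)
  if (m < 2) stop("gene set overlaps the universe in fewer than 2 genes", call. = FALSE)
  es_of <- function(in_set_perm) {
    ord <- order(scores, decreasing = TRUE)
    s <- abs(scores[ord])^weight
    hit <- in_set_perm[ord]
    p_hit <- cumsum(ifelse(hit, s, 0)) / sum(s[hit])
    p_miss <- cumsum(!hit) / sum(!hit)
    dev <- p_hit - p_miss
    dev[which.max(abs(dev))]
  }
  es <- es_of(in_set)
  with_local_seed(seed, {
    perm <- vapply(seq_len(n_permutations), function(i) {
      es_of(sample(in_set))
    }, numeric(1))
    same <- perm[sign(perm) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(perm) >= abs(es))) / (1 + n_permutations)
    list(es = es, nes = nes, p_value = p, n_overlap = m)
  })
}

#' Marker-based immune abundance indices
#'
#' MCPcounter-style score per cell population: the arithmetic mean of
#' `log2(TPM + 1)` over the population's marker genes, per sample.
#'
#' @param tpm Genes x samples TPM matrix.
#' @param marker_sets Named list of marker genes (see
#'   [default_marker_sets()]).
#' @return Cell-type x sample matrix; rows with no markers present are
#'   `NA` and flagged via the `missing_sets` attribute.
#' @export
marker_index <- function(tpm, marker_sets = default_marker_sets()) {
  logx <- log2(as.matrix(tpm) + 1)
  out <- matrix(NA_real_, length(marker_sets), ncol(logx),
    dimnames = list(names(marker_sets), colnames(logx))
  )
  missing_sets <- character(0)
  for (s in names(marker_sets)) {
    genes <- intersect(marker_sets[[s]], rownames(logx))
    if (!length(genes)) {
      missing_sets <- c(missing_sets, s)
      next
    }
    out[s, ] <- colMeans(logx[genes, , drop = FALSE])
  }
  attr(out, "missing_sets") <- missing_sets
  out
}

#' Spearman correlation between radiomics features and immune indices
#'
#' Pairwise Spearman rank correlation (average ranks for ties) between each
#' immune index and each selected radiomics feature over shared patients.
#'
#' @param radiomics Patients x features tibble/matrix (with `patient_id`
#'   column or rownames).
#' @param indices Cell-type x patient matrix from [marker_index()].
#' @return Tibble of class `hab_immune_cor`: cell_type, feature, rho; the
#'   wide matrix is available via attribute `matrix`. Constant vectors give
#'   `NA` with a flag.
#' @export
correlate_features_immune <- function(radiomics, indices) {
  if (is.data.frame(radiomics)) {
    ids <- radiomics$patient_id %||% rownames(radiomics)
    x <- as.matrix(dplyr::select(radiomics, -dplyr::any_of("patient_id")))
    rownames(x) <- ids
  } else {
    x <- as.matrix(radiomics)
  }
  shared <- intersect(rownames(x), colnames(indices))
  if (length(shared) < 10) stop("need at least 10 shared patients", call. = FALSE)
  x <- x[shared, , drop = FALSE]
  idx <- indices[, shared, drop = FALSE]
  rho <- matrix(NA_real_, nrow(idx), ncol(x),
    dimnames = list(rownames(idx), colnames(x))
  )
  for (ct in rownames(idx)) {
    for (f in colnames(x)) {
      a <- idx[ct, ]
      b <- x[, f]
      if (stats::sd(a) == 0 || stats::sd(b) == 0 || anyNA(a)) next
      rho[ct, f] <- stats::cor(rank(a), rank(b))
    }
  }
  long <- tibble::as_tibble(as.data.frame.table(rho, stringsAsFactors = FALSE)) |>
    stats::setNames(c("cell_type", "feature", "rho"))
  structure(long, matrix = rho, class = c("hab_immune_cor", class(long)))
}

#' Single-sample GSEA scores
#'
#' Per sample: genes are ranked by expression and the score is the sum of
#' the running difference between the rank-weighted in-set ECDF (weight =
#' rank^exponent) and the unweighted out-of-set ECDF. Scores are min-max
#' normalized across the cohort.
#'
#' @param expr Genes x samples expression matrix (TPM or log-TPM).
#' @param gene_set Character vector of genes (at least 2 in the universe).
#' @param exponent Rank weight exponent (ssGSEA default 0.25).
#' @param normalize Min-max normalize across samples.
#' @return Named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(expr, gene_set, exponent = 0.25, normalize = TRUE) {
  expr <- as.matrix(expr)
  in_set <- rownames(expr) %in% gene_set
  if (sum(in_set) < 2) {
    stop("gene set overlaps the universe in fewer than 2 genes", call. = FALSE)
  }
  n <- nrow(expr)
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    hit <- in_set[ord]
    w <- (n - seq_len(n) + 1)^exponent # descending rank weight
    p_hit <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
    p_miss <- cumsum(!hit) / sum(!hit)
    sum(p_hit - p_miss)
  }, numeric(1))
  names(scores) <- colnames(expr)
  if (normalize && diff(range(scores)) > 0) {
    scores <- (scores - min(scores)) / diff(range(scores))
  }
  scores
}

#' Ratio of observed to expected cell counts (Ro/e)
#'
#' For a cell-type x group contingency table, `Ro/e(c, g) =
#' observed(c, g) / expected(c, g)` with the chi-square independence
#' expectation `row_total * col_total / grand_total`. Values above 1
#' indicate enrichment of the cell type in that group.
#'
#' @param counts Cell-type x patient (or x group) count matrix.
#' @param group Optional per-column group labels; columns are summed per
#'   group when given.
#' @return Tibble of class `hab_roe`: cell_type, group, observed, expected,
#'   roe; matrix via attribute `matrix`.
#' @export
roe <- function(counts, group = NULL) {
  m <- as.matrix(counts)
  if (!is.null(group)) {
    group <- as.character(group)
    stopifnot(length(group) == ncol(m))
    m <- t(rowsum(t(m), group))
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("zero margin; Ro/e undefined for those entries", call. = FALSE)
  }
  exp_m <- outer(rowSums(m), colSums(m)) / sum(m)
  r <- ifelse(exp_m > 0, m / exp_m, NA_real_)
  long <- tibble::as_tibble(as.data.frame.table(r, stringsAsFactors = FALSE)) |>
    stats::setNames(c("cell_type", "group", "roe"))
  long$observed <- as.numeric(m)[match(
    paste(long$cell_type, long$group),
    paste(rownames(m)[row(m)], colnames(m)[col(m)])
  )]
  long$expected <- as.numeric(exp_m)[match(
    paste(long$cell_type, long$group),
    paste(rownames(m)[row(m)], colnames(m)[col(m)])
  )]
  structure(long[, c("cell_type", "group", "observed", "expected", "roe")],
    matrix = r, class = c("hab_roe", class(long))
  )
}

#' Two-group Wilcoxon rank-sum comparison of per-sample scores
#'
#' Exact test for small untied samples, normal approximation with tie
#' correction otherwise; reports the effect direction as the difference of
#' group medians (high minus low).
#'
#' @param scores Numeric per-sample values.
#' @param groups Two-level labels (the `"high"` level, or the second sorted
#'   level, is the reference for direction).
#' @return Tibble: p_value, direction, median_high, median_low.
#' @export
compare_groups <- function(scores, groups) {
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  hi <- if ("high" %in% lv) "high" else lv[2]
  lo <- setdiff(lv, hi)
  a <- scores[groups == hi]
  b <- scores[groups == lo]
  if (length(a) < 3 || length(b) < 3) stop("each group needs at least 3 samples", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
  tibble::tibble(
    p_value = wt$p.value,
    direction = sign(stats::median(a) - stats::median(b)),
    median_high = stats::median(a),
    median_low = stats::median(b)
  )
}
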