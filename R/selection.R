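# Staged feature-selection cascade: ICC reliability, variance/Spearman
# redundancy, Mann-Whitney association, LASSO sparsity. Every stage returns
# a tidy report recording each feature's statistic and fate.

feature_cols <- function(table) {
  setdiff(names(table), "patient_id")
}

as_feature_matrix <- function(table) {
  as.matrix(dplyr::select(table, -dplyr::any_of("patient_id")))
}

#' Two-way random-effects single-measurement ICC with absolute agreement
#'
#' The ICC(2,1) variance-components form
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, where MSR, MSC and
#' MSE are the rows (targets), columns (raters) and error mean squares of
#' the two-way layout.
#'
#' @param m Numeric matrix, targets (patients) x raters (measurements).
#' @return ICC value; 0 for zero-variance input by convention.
#' @export
icc21 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (stats::sd(m) == 0) return(0)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  gm <- mean(m)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + gm)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (!is.finite(den) || den <= 0) return(0)
  (msr - mse) / den
}

#' Reliability (ICC) filter over repeated delineations
#'
#' Given feature tables extracted from repeated mask delineations (the first
#' table is the reference reader; `intra` tables are re-reads of the same
#' reader, `inter` tables other readers), retains the features whose
#' single-measurement absolute-agreement ICC exceeds `threshold` for both
#' the intra- and inter-reader comparison.
#'
#' @param tables List of feature tibbles with identical `patient_id` and
#'   feature columns. Order: reference, intra re-read(s), inter reader(s).
#' @param n_intra How many tables after the first are intra-reader re-reads
#'   (the rest are inter-reader).
#' @param threshold Retention threshold (default 0.8).
#' @return A `hab_selection_report` tibble: feature, icc_intra, icc_inter,
#'   retained.
#' @export
icc_filter <- function(tables, n_intra = 1, threshold = 0.8) {
  stopifnot(length(tables) >= 2)
  cols <- feature_cols(tables[[1]])
  for (t in tables[-1]) {
    if (!identical(feature_cols(t), cols) || nrow(t) != nrow(tables[[1]])) {
      stop("all measurement tables must share features and patients", call. = FALSE)
    }
  }
  if (nrow(tables[[1]]) < 5) stop("ICC needs at least 5 patients", call. = FALSE)
  ref <- as_feature_matrix(tables[[1]])
  intra_idx <- seq_len(n_intra) + 1
  inter_idx <- setdiff(seq_along(tables)[-1], intra_idx)
  if (!length(inter_idx)) inter_idx <- intra_idx
  icc_of <- function(other_tables) {
    ms <- lapply(other_tables, as_feature_matrix)
    vapply(seq_along(cols), function(j) {
      icc21(cbind(ref[, j], sapply(ms, function(m) m[, j])))
    }, numeric(1))
  }
  icc_intra <- icc_of(tables[intra_idx])
  icc_inter <- icc_of(tables[inter_idx])
  rep <- tibble::tibble(
    feature = cols,
    icc_intra = icc_intra,
    icc_inter = icc_inter,
    retained = icc_intra > threshold & icc_inter > threshold,
    reason = dplyr::if_else(icc_intra > threshold & icc_inter > threshold,
      NA_character_, "icc_below_threshold"
    )
  )
  new_selection_report(rep, stage = "icc", threshold = threshold)
}

#' Variance and Spearman-redundancy filter
#'
#' Drops features with variance at or below `variance_floor` (on the given
#' scale), then greedily prunes correlated pairs: feature pairs with
#' absolute Spearman correlation above `rho_threshold` are visited in
#' deterministic (name) order and the member with the weaker univariate
#' ranking (smaller centred Mann-Whitney statistic `|U - n1 n2 / 2|`) is
#' dropped, until all surviving pairwise correlations are at or below the
#' threshold.
#'
#' @param table Feature tibble (`patient_id` + features).
#' @param labels Binary outcome factor/vector used by the ranker.
#' @param variance_floor Minimum variance retained.
#' @param rho_threshold Spearman threshold (default 0.9).
#' @return A `hab_selection_report` tibble.
#' @export
redundancy_filter <- function(table, labels, variance_floor = 1e-8,
                              rho_threshold = 0.9) {
  cols <- feature_cols(table)
  x <- as_feature_matrix(table)
  labels <- as_binary_labels(labels)
  v <- apply(x, 2, stats::var)
  alive <- v > variance_floor
  ustat <- vapply(seq_along(cols), function(j) {
    if (!alive[j]) return(0)
    centred_u(x[, j], labels)
  }, numeric(1))
  reason <- ifelse(alive, NA_character_, "low_variance")
  keep_idx <- which(alive)
  if (length(keep_idx) > 1) {
    ord <- keep_idx[order(cols[keep_idx])]
    rho <- suppressWarnings(stats::cor(x[, ord, drop = FALSE], method = "spearman"))
    rho[!is.finite(rho)] <- 0
    alive2 <- rep(TRUE, length(ord))
    for (a in seq_along(ord)) {
      if (!alive2[a]) next
      for (b in seq_along(ord)) {
        if (b == a || !alive2[b]) next
        if (abs(rho[a, b]) > rho_threshold) {
          drop <- if (ustat[ord[a]] >= ustat[ord[b]]) b else a
          alive2[drop] <- FALSE
          reason[ord[drop]] <- "correlated"
          if (drop == a) break
        }
      }
    }
    alive[ord[!alive2]] <- FALSE
  }
  rep <- tibble::tibble(
    feature = cols, variance = unname(v), rank_stat = unname(ustat),
    retained = unname(alive), reason = unname(reason)
  )
  new_selection_report(rep, stage = "redundancy", threshold = rho_threshold)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.character(labels)) labels <- as.integer(factor(labels)) - 1L
  u <- sort(unique(labels))
  if (length(u) != 2) stop("labels must contain exactly two classes", call. = FALSE)
  as.integer(labels == u[2])
}

# |U - n1 n2 / 2|, the centred Mann-Whitney statistic used as ranker
centred_u <- function(x, y01) {
  n1 <- sum(y01 == 1)
  n0 <- sum(y01 == 0)
  r <- rank(x)
  u <- sum(r[y01 == 1]) - n1 * (n1 + 1) / 2
  abs(u - n1 * n0 / 2)
}

#' Univariate Mann-Whitney association filter
#'
#' Two-sided Mann-Whitney U test of each feature against the binary outcome
#' (exact for small untied samples, normal approximation with tie correction
#' otherwise, as in [stats::wilcox.test()]); features with `p < alpha` are
#' retained. No multiplicity correction is applied at this stage.
#'
#' @inheritParams redundancy_filter
#' @param alpha Retention level (default 0.05).
#' @return A `hab_selection_report` tibble with the per-feature p-values.
#' @export
univariate_filter <- function(table, labels, alpha = 0.05) {
  cols <- feature_cols(table)
  x <- as_feature_matrix(table)
  y <- as_binary_labels(labels)
  if (min(table(y)) < 3) stop("each outcome class needs at least 3 patients", call. = FALSE)
  p <- vapply(seq_along(cols), function(j) {
    xi <- x[, j]
    if (stats::sd(xi) == 0) return(1)
    suppressWarnings(
      stats::wilcox.test(xi[y == 1], xi[y == 0], exact = NULL)$p.value
    )
  }, numeric(1))
  rep <- tibble::tibble(
    feature = cols, p_value = p, retained = p < alpha,
    reason = dplyr::if_else(p < alpha, NA_character_, "not_significant")
  )
  new_selection_report(rep, stage = "univariate", threshold = alpha)
}

#' LASSO sparse selection
#'
#' L1-penalized logistic regression on standardized features, with the
#' penalty chosen by stratified k-fold cross-validated deviance; selected
#' features are those with nonzero coefficients at the chosen penalty.
#'
#' @inheritParams redundancy_filter
#' @param n_folds Cross-validation folds (default 10).
#' @param lambda_rule `"min"` (minimum CV deviance, default) or `"1se"`.
#' @param seed Integer seed controlling fold assignment.
#' @return A `hab_selection_report` tibble with standardized coefficients.
#' @export
lasso_select <- function(table, labels, n_folds = 10, lambda_rule = c("min", "1se"),
                         seed = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  cols <- feature_cols(table)
  x <- as_feature_matrix(table)
  y <- as_binary_labels(labels)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- scale(x, center = mu, scale = sdv)
  with_local_seed(seed, {
    foldid <- stratified_folds(y, n_folds)
    fit <- glmnet::cv.glmnet(xs, y,
      family = "binomial", foldid = foldid,
      type.measure = "deviance", standardize = FALSE
    )
    lam <- if (lambda_rule == "min") fit$lambda.min else fit$lambda.1se
    beta <- as.numeric(stats::coef(fit, s = lam))[-1]
    rep <- tibble::tibble(
      feature = cols, coefficient = beta, retained = beta != 0,
      reason = dplyr::if_else(beta != 0, NA_character_, "shrunk_to_zero")
    )
    out <- new_selection_report(rep, stage = "lasso", threshold = lam)
    attr(out, "standardization") <- list(mean = mu, sd = sdv)
    out
  })
}

stratified_folds <- function(y, n_folds) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

new_selection_report <- function(tbl, stage, threshold) {
  structure(tbl,
    stage = stage, threshold = threshold,
    class = c("hab_selection_report", class(tbl))
  )
}

#' @export
print.hab_selection_report <- function(x, ...) {
  cat(sprintf(
    "Selection stage '%s': %d of %d features retained\n",
    attr(x, "stage"), sum(x$retained), nrow(x)
  ))
  NextMethod()
}

#' Run the full selection cascade on one feature set
#'
#' Applies, in order: ICC reliability (when measurement replicates are
#' given), variance/Spearman redundancy, univariate Mann-Whitney, and LASSO.
#' Feature counts are non-increasing across stages and every dropped
#' feature's stage and statistic are kept in the stage reports.
#'
#' @param table Feature tibble for one (timepoint, TR/SHR) set.
#' @param labels Binary outcome.
#' @param replicate_tables Optional list of re-measured tables for the ICC
#'   stage (reference first); skipped when `NULL`.
#' @param icc_threshold,variance_floor,rho_threshold,alpha,n_folds,seed
#'   Stage parameters.
#' @return A list of class `hab_selection_cascade`: `selected` (character),
#'   `stages` (list of stage reports), `counts` (tibble).
#' @export
select_cascade <- function(table, labels, replicate_tables = NULL,
                           icc_threshold = 0.8, variance_floor = 1e-8,
                           rho_threshold = 0.9, alpha = 0.05,
                           n_folds = 10, seed = NULL) {
  stages <- list()
  current <- table
  if (!is.null(replicate_tables)) {
    icc_rep <- icc_filter(c(list(current), replicate_tables), threshold = icc_threshold)
    stages$icc <- icc_rep
    current <- dplyr::select(
      current,
      dplyr::any_of(c("patient_id", icc_rep$feature[icc_rep$retained]))
    )
  }
  red <- redundancy_filter(current, labels,
    variance_floor = variance_floor,
    rho_threshold = rho_threshold
  )
  stages$redundancy <- red
  current <- dplyr::select(
    current,
    dplyr::any_of(c("patient_id", red$feature[red$retained]))
  )
  uni <- univariate_filter(current, labels, alpha = alpha)
  stages$univariate <- uni
  current <- dplyr::select(
    current,
    dplyr::any_of(c("patient_id", uni$feature[uni$retained]))
  )
  if (length(feature_cols(current)) >= 2) {
    las <- lasso_select(current, labels, n_folds = n_folds, seed = seed)
    stages$lasso <- las
    selected <- las$feature[las$retained]
  } else {
    selected <- feature_cols(current)
  }
  counts <- tibble::tibble(
    stage = names(stages),
    features_in = vapply(stages, nrow, integer(1)),
    features_out = vapply(stages, function(s) sum(s$retained), integer(1))
  )
  structure(
    list(selected = selected, stages = stages, counts = counts),
    class = "hab_selection_cascade"
  )
}

#' @export
print.hab_selection_cascade <- function(x, ...) {
  cat("Feature-selection cascade\n")
  print(x$counts)
  cat("selected:", length(x$selected), "feature(s)\n")
  invisible(x)
}

#' @rdname select_cascade
#' @param x A `hab_selection_cascade`.
#' @param ... Unused.
#' @export
tidy.hab_selection_cascade <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$stages), function(st) {
    s <- x$stages[[st]]
    tibble::tibble(
      stage = st, feature = s$feature, retained = s$retained,
      reason = s$reason
    )
  }))
}
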