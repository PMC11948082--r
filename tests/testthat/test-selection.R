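make_table <- function(x) {
  colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  tibble::as_tibble(as.data.frame(x))
}

test_that("ICC equals the ANOVA mean-squares oracle and handles edge cases", {
  set.seed(1)
  m <- matrix(rnorm(12, 10), 6, 2)
  expect_equal(icc21(m), icc_aov_oracle(m), tolerance = 1e-9)
  for (rep in 1:5) {
    mm <- matrix(rnorm(8 * 3, 5, 2), 8, 3)
    expect_equal(icc21(mm), icc_aov_oracle(mm), tolerance = 1e-9)
  }
  expect_identical(icc21(matrix(3, 6, 2)), 0)
})

test_that("identical tables give ICC 1 and full retention", {
  set.seed(2)
  t1 <- make_table(matrix(rnorm(60), 10, 6))
  rep <- icc_filter(list(t1, t1, t1))
  expect_true(all(rep$icc_intra == 1))
  expect_true(all(rep$retained))
})

test_that("equal-variance independent noise drives ICC toward one half", {
  set.seed(3)
  n <- 400
  signal <- matrix(rnorm(n * 4, 0, 1), n, 4)
  t1 <- make_table(signal + matrix(rnorm(n * 4), n, 4))
  t2 <- make_table(signal + matrix(rnorm(n * 4), n, 4))
  rep <- icc_filter(list(t1, t2), n_intra = 1)
  expect_true(all(abs(rep$icc_intra - 0.5) < 0.12))
  expect_false(any(rep$retained))
  expect_error(icc_filter(list(t1[1:4, ], t2[1:4, ])), "at least 5")
})

test_that("redundancy filter keeps one copy of duplicates and respects ranking", {
  set.seed(4)
  y <- rep(0:1, each = 15)
  base <- rnorm(30)
  x <- cbind(
    f_dup_a = base, f_dup_b = base,
    f_solo = rnorm(30)
  )
  tab <- tibble::as_tibble(as.data.frame(x))
  rep <- redundancy_filter(tab, y)
  expect_identical(sum(rep$retained[1:2]), 1L)
  expect_true(rep$retained[rep$feature == "f_solo"])
  # orthogonal features: nothing dropped
  x2 <- make_table(matrix(rnorm(300), 30, 10))
  rep2 <- redundancy_filter(x2, y)
  expect_true(all(rep2$retained))
  # three mutually correlated features: only the best-ranked survives
  s <- rnorm(200)
  y3 <- as.integer(s + rnorm(200, 0, 0.5) > 0)
  x3 <- tibble::tibble(
    a_strong = s + rnorm(200, 0, 0.05),
    b_weaker = s + rnorm(200, 0, 0.20),
    c_weakest = s + rnorm(200, 0, 0.25)
  )
  rho <- cor(as.matrix(x3), method = "spearman")
  expect_true(all(rho[upper.tri(rho)] > 0.9))
  rep3 <- redundancy_filter(x3, y3)
  expect_identical(rep3$feature[rep3$retained], "a_strong")
  # zero-variance features are dropped with a reason
  x4 <- tibble::tibble(flat = rep(1, 30), ok = rnorm(30))
  rep4 <- redundancy_filter(x4, y)
  expect_identical(rep4$reason[rep4$feature == "flat"], "low_variance")
  expect_true(rep4$retained[rep4$feature == "ok"])
})

test_that("univariate filter is calibrated under the null", {
  set.seed(5)
  n <- 60
  y <- rep(0:1, each = n / 2)
  p_feats <- 2000
  x <- make_table(matrix(rnorm(n * p_feats), n, p_feats))
  rep <- univariate_filter(x, y, alpha = 0.05)
  kept <- mean(rep$retained)
  # binomial 99% band around 0.05 with 2000 features
  expect_lt(abs(kept - 0.05), 3 * sqrt(0.05 * 0.95 / p_feats))
})

test_that("univariate filter flags perfect separation and exact small samples", {
  y <- rep(0:1, each = 15)
  x <- tibble::tibble(sep = y + rnorm(30, 0, 1e-4))
  rep <- univariate_filter(x, y)
  expect_lt(rep$p_value[1], 1e-6)
  expect_true(rep$retained[1])
  # {1,2,3} vs {4,5,6}: exact two-sided p = 0.1 (2/20 orderings as extreme)
  y6 <- c(0, 0, 0, 1, 1, 1)
  x6 <- tibble::tibble(f = c(1, 2, 3, 4, 5, 6))
  rep6 <- univariate_filter(x6, y6)
  expect_equal(rep6$p_value[1], 0.1, tolerance = 1e-12)
  # constant feature: p = 1 by convention
  repc <- univariate_filter(tibble::tibble(flat = rep(2, 30)), y)
  expect_identical(repc$p_value[1], 1)
})

test_that("LASSO selection recovers planted informative features", {
  set.seed(6)
  n <- 400
  p_inf <- 5
  p_null <- 195
  hits <- replicate(10, {
    x <- matrix(rnorm(n * (p_inf + p_null)), n)
    colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
    lp <- x[, 1:p_inf] %*% rep(0.8, p_inf)
    y <- rbinom(n, 1, plogis(lp))
    rep <- lasso_select(make_table(x), y, seed = sample.int(1e6, 1))
    sum(rep$retained[1:p_inf])
  })
  expect_gte(median(hits), 4)
})

test_that("the cascade is monotone with containment and an audit trail", {
  set.seed(7)
  n <- 150
  x <- matrix(rnorm(n * 40), n, 40)
  x[, 2] <- x[, 1] + rnorm(n, 0, 0.05) # redundant pair
  colnames(x) <- sprintf("f%03d", 1:40)
  y <- rbinom(n, 1, plogis(1.5 * x[, 1] - x[, 3]))
  casc <- select_cascade(make_table(x), y, seed = 8)
  expect_true(all(casc$counts$features_out <= casc$counts$features_in))
  # pipeline containment: lasso picks only univariate survivors
  uni_kept <- casc$stages$univariate$feature[casc$stages$univariate$retained]
  expect_true(all(casc$selected %in% uni_kept))
  # audit: every dropped feature has a recorded reason
  audit <- tidy(casc)
  expect_true(all(!is.na(audit$reason[!audit$retained])))
})

test_that("simulated re-delineations feed the reliability filter sensibly", {
  cfg <- feature_panel(families = "firstorder", transforms = "original")
  extract_under <- function(ph, mask) {
    ch <- apply_transforms(ph$pre$volume, cfg)
    as.list(extract_region_features(ch, mask$voxels > 0, config = cfg))
  }
  rows_ref <- list()
  rows_small <- list()
  rows_large <- list()
  for (i in 1:8) {
    ph <- generate_phantom_pair(seed = 200 + i)
    rows_ref[[i]] <- extract_under(ph, ph$pre$mask)
    rows_small[[i]] <- extract_under(ph, perturb_mask(ph$pre$mask, 0.5, seed = i))
    rows_large[[i]] <- extract_under(ph, perturb_mask(ph$pre$mask, 3, seed = i))
  }
  as_tab <- function(rows) dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  rep_small <- icc_filter(list(as_tab(rows_ref), as_tab(rows_small)))
  rep_large <- icc_filter(list(as_tab(rows_ref), as_tab(rows_large)))
  # gentler re-delineations give systematically higher reliability
  expect_gt(
    median(rep_small$icc_intra, na.rm = TRUE),
    median(rep_large$icc_intra, na.rm = TRUE)
  )
})
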