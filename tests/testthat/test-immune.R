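test_that("TPM normalization matches hand arithmetic and its invariants", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm <- tpm_normalize(counts, c(1, 2))
  expect_equal(as.numeric(tpm), c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-9)
  # equal counts and lengths: 1e6 / G each
  cts <- matrix(5, 8, 3, dimnames = list(paste0("g", 1:8), paste0("s", 1:3)))
  expect_true(all(abs(tpm_normalize(cts, rep(2, 8)) - 1e6 / 8) < 1e-9))
  expect_error(tpm_normalize(cts, rep(0, 8)), "positive")
  set.seed(1)
  cmat <- matrix(rpois(200, 20), 20, 10)
  expect_true(all(abs(colSums(tpm_normalize(cmat, runif(20, 0.5, 3))) - 1e6) < 1e-3))
})

test_that("moderated differential expression is null-calibrated", {
  ex <- generate_expression(n_genes = 5000, n_samples = 40, shift = 0, seed = 11)
  tpm <- tpm_normalize(ex$counts, ex$gene_lengths_kb)
  de <- differential_expression(log2(tpm + 1), ex$group)
  ks <- suppressWarnings(stats::ks.test(de$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("moderated differential expression recovers planted marker shifts", {
  ex <- generate_expression(
    n_genes = 2000, n_samples = 40, shift = 1,
    marker_sets = list(B_cells = sprintf("gene%04d", 1000:1049)),
    shifted_sets = "B_cells", seed = 12
  )
  tpm <- tpm_normalize(ex$counts, ex$gene_lengths_kb)
  de <- differential_expression(log2(tpm + 1), ex$group)
  mk <- de$gene %in% sprintf("gene%04d", 1000:1049)
  expect_lt(median(rank(de$p_value)[mk]) / nrow(de), 0.05)
  expect_gt(median(de$log_fc[mk]), 0.5)
  # constant gene: p = 1
  expr <- log2(tpm + 1)
  expr[1, ] <- 3
  de2 <- differential_expression(expr, ex$group)
  expect_equal(de2$p_value[1], 1)
})

test_that("moderated t agrees with the limma oracle on a small matrix", {
  skip_if_not_installed("limma")
  set.seed(13)
  expr <- matrix(rnorm(200 * 12, 6, 1), 200, 12,
    dimnames = list(paste0("g", 1:200), paste0("s", 1:12))
  )
  grp <- rep(c("low", "high"), each = 6)
  ours <- differential_expression(expr, grp)
  design <- stats::model.matrix(~ factor(grp, levels = c("low", "high")))
  fit <- limma::eBayes(limma::lmFit(expr, design))
  lim_p <- fit$p.value[, 2]
  lim_lfc <- fit$coefficients[, 2]
  expect_equal(ours$log_fc, unname(lim_lfc), tolerance = 1e-9)
  expect_gt(cor(-log10(ours$p_value), -log10(lim_p)), 0.999)
  expect_lt(median(abs(ours$p_value - lim_p)), 0.005)
})

test_that("preranked GSEA behaves at its limits and matches the fgsea oracle", {
  set.seed(14)
  scores <- sort(rnorm(1000), decreasing = TRUE)
  names(scores) <- paste0("g", 1:1000)
  top <- names(scores)[1:20]
  gs <- gsea_preranked(scores, top, n_permutations = 100, seed = 1)
  expect_gte(gs$es, 0.95)
  # antisymmetry under ranking reversal
  gs_rev <- gsea_preranked(-scores, top, n_permutations = 100, seed = 1)
  expect_equal(gs_rev$es, -gs$es, tolerance = 1e-9)
  expect_error(gsea_preranked(scores, "absent_gene"), "fewer than 2")
  skip_if_not_installed("fgsea")
  for (rep in 1:5) {
    set_genes <- sample(names(scores), 30)
    ours <- gsea_preranked(scores, set_genes, n_permutations = 10, seed = 1)$es
    oracle <- fgsea::calcGseaStat(scores, which(names(scores) %in% set_genes),
      gseaParam = 1
    )
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("random gene sets give uniform GSEA permutation p-values", {
  set.seed(15)
  scores <- rnorm(300)
  names(scores) <- paste0("g", 1:300)
  ps <- vapply(1:200, function(i) {
    gsea_preranked(scores, sample(names(scores), 15),
      n_permutations = 99, seed = i
    )$p_value
  }, numeric(1))
  # permutation p-values are discrete; check rejection-rate calibration
  for (a in c(0.1, 0.25, 0.5)) {
    expect_lt(abs(mean(ps <= a) - a), 3 * sqrt(a * (1 - a) / 200) + 1 / 99)
  }
})

test_that("marker indices obey their algebraic identities", {
  tpm <- matrix(2^6 - 1, 4, 3, dimnames = list(c("CD19", "MS4A1", "x1", "x2"), paste0("s", 1:3)))
  idx <- marker_index(tpm, list(B = c("CD19", "MS4A1")))
  expect_true(all(abs(idx["B", ] - 6) < 1e-12))
  # doubling marker TPM adds ~1 in log2 space at high expression
  tpm2 <- tpm
  tpm2[c("CD19", "MS4A1"), ] <- 2 * tpm2[c("CD19", "MS4A1"), ]
  idx2 <- marker_index(tpm2, list(B = c("CD19", "MS4A1")))
  expect_lt(max(abs(idx2["B", ] - idx["B", ] - 1)), 0.05)
  idx3 <- marker_index(tpm, list(B = "CD19", missing = "NOPE"))
  expect_true(all(is.na(idx3["missing", ])))
  expect_identical(attr(idx3, "missing_sets"), "missing")
})

test_that("planted B-cell shifts propagate to index, ssGSEA and group test", {
  ex <- generate_expression(n_genes = 1500, n_samples = 60, shift = 2, seed = 16)
  tpm <- tpm_normalize(ex$counts, ex$gene_lengths_kb)
  idx <- marker_index(tpm, ex$marker_sets)
  hi <- ex$group == "high"
  wt <- stats::wilcox.test(idx["B_cells", hi], idx["B_cells", !hi], alternative = "greater")
  expect_lt(wt$p.value, 0.05)
  ss <- ssgsea_score(tpm, ex$marker_sets$B_cells)
  cg <- compare_groups(ss, ex$group)
  expect_lt(cg$p_value, 0.01)
  expect_identical(cg$direction, 1)
})

test_that("Spearman correlation equals the rank-then-Pearson oracle", {
  set.seed(17)
  n <- 30
  rad <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:n),
    f1 = rnorm(n), f2 = rnorm(n)
  )
  idx <- matrix(rnorm(2 * n), 2, n,
    dimnames = list(c("B", "T"), sprintf("P%02d", 1:n))
  )
  res <- correlate_features_immune(rad, idx)
  m <- attr(res, "matrix")
  for (ct in rownames(m)) {
    for (f in colnames(m)) {
      oracle <- cor(rank(idx[ct, ]), rank(rad[[f]]))
      expect_equal(m[ct, f], oracle, tolerance = 1e-12)
    }
  }
  # monotone transform: rho = 1
  rad2 <- tibble::tibble(patient_id = rad$patient_id, f = exp(idx["B", ]))
  res2 <- correlate_features_immune(rad2, idx)
  expect_equal(attr(res2, "matrix")["B", "f"], 1, tolerance = 1e-12)
  # independent pairs rarely exceed |rho| 0.5 at n = 30
  set.seed(18)
  hits <- replicate(100, {
    abs(cor(rank(rnorm(n)), rank(rnorm(n))))
  })
  expect_gt(mean(hits < 0.5), 0.95)
})

test_that("ssGSEA extremes and ties behave canonically", {
  set.seed(19)
  expr <- matrix(rnorm(100 * 5, 5), 100, 5,
    dimnames = list(paste0("g", 1:100), paste0("s", 1:5))
  )
  gs <- paste0("g", 1:10)
  expr[gs, 3] <- 50 # set genes top-ranked in sample 3
  sc <- ssgsea_score(expr, gs)
  expect_identical(names(which.max(sc)), "s3")
  expr[, 2] <- expr[, 1]
  sc2 <- ssgsea_score(expr, gs, normalize = FALSE)
  expect_equal(sc2["s1"], sc2["s2"], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Ro/e reproduces hand arithmetic and conserves margins", {
  m <- matrix(c(30, 10, 10, 30), 2, 2,
    dimnames = list(c("B", "T"), c("high", "low"))
  )
  r <- attr(roe(m), "matrix")
  expect_equal(as.numeric(r), c(1.5, 0.5, 0.5, 1.5), tolerance = 1e-12)
  # group-independent composition: all entries 1
  ind <- outer(c(10, 20, 30), c(2, 3))
  dimnames(ind) <- list(c("a", "b", "c"), c("g1", "g2"))
  expect_true(all(abs(attr(roe(ind), "matrix") - 1) < 1e-12))
  # margin conservation: column-total-weighted average of Ro/e rows is 1
  set.seed(20)
  mm <- matrix(rpois(12, 50) + 1, 3, 4,
    dimnames = list(c("B", "T", "M"), paste0("g", 1:4))
  )
  rr <- attr(roe(mm), "matrix")
  w <- colSums(mm) / sum(mm)
  expect_true(all(abs(rr %*% w - 1) < 1e-12))
})

test_that("group comparison matches exact enumeration and is symmetric", {
  s <- c(1, 2, 3, 4, 5, 6)
  g <- c("low", "low", "low", "high", "high", "high")
  res <- compare_groups(s, g)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_identical(res$direction, 1)
  res_sw <- compare_groups(s, rev(g))
  expect_equal(res_sw$p_value, res$p_value, tolerance = 1e-12)
  expect_identical(res_sw$direction, -1)
  expect_error(compare_groups(s, rep("high", 6)), "two groups")
})
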