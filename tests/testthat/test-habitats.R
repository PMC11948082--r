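test_that("supervoxels on a homogeneous sphere have near-global means", {
  dims <- c(24, 24, 24)
  set.seed(4)
  noise_sd <- 3
  v <- hab_volume(array(rnorm(prod(dims), 100, noise_sd), dims))
  m <- hab_mask(sphere_mask_array(dims, 8))
  sv <- supervoxel_segment(v, m, n_supervoxels = 50, seed = 1)
  big <- sv$features$n_voxels >= 8
  expect_true(all(abs(sv$features$raw_mean[big] - mean(v$voxels[m$voxels > 0])) <= 2 * noise_sd))
  # achieved count within a factor two of the target
  expect_gte(nrow(sv$features), 25)
  expect_lte(nrow(sv$features), 100)
})

test_that("supervoxel map partitions the mask into connected pieces", {
  ph <- std_phantom()
  sv <- supervoxel_segment(ph$pre$volume, ph$pre$mask, n_supervoxels = 60, seed = 2)
  fg <- ph$pre$mask$voxels > 0
  expect_true(all(sv$labels[fg] > 0))
  expect_true(all(sv$labels[!fg] == 0))
  for (lab in sample(unique(sv$labels[fg]), 10)) {
    expect_true(habitatr:::is_single_component(sv$labels == lab))
  }
})

test_that("two-compartment phantoms give a bimodal supervoxel mean distribution", {
  ph <- generate_phantom_pair(
    fractions_pre = c(0.5, 0, 0.5),
    class_means = c(300, 200, 100), class_sds = c(10, 10, 10), seed = 6
  )
  sv <- supervoxel_segment(ph$pre$volume, ph$pre$mask, seed = 1)
  mid <- (300 + 100) / 2
  # a clear valley: almost no supervoxel means near the midpoint
  near_mid <- mean(abs(sv$features$raw_mean - mid) < 40)
  expect_lt(near_mid, 0.05)
  expect_gt(mean(sv$features$raw_mean > mid), 0.3)
  expect_gt(mean(sv$features$raw_mean < mid), 0.3)
})

test_that("too many supervoxels for a small mask errors", {
  ph <- std_phantom()
  expect_error(
    supervoxel_segment(ph$pre$volume, ph$pre$mask, n_supervoxels = 1e5),
    "too small"
  )
})

test_that("Calinski-Harabasz selection recovers planted cluster counts", {
  # constructed supervoxel-like feature matrices with g tight clusters
  make_feats <- function(g, n = 120, sep = 10) {
    centers <- seq(0, sep * (g - 1), by = sep)
    x <- cbind(
      rnorm(n, centers[1 + (seq_len(n) %% g)], 1),
      rnorm(n, 0, 1), rnorm(n, 0, 1)
    )
    x
  }
  set.seed(9)
  for (g in 2:4) {
    sel <- select_k(make_feats(g), candidate_ks = 2:6, seed = g)
    expect_identical(attr(sel, "chosen_k"), as.integer(g))
  }
  expect_error(select_k(matrix(rnorm(30), 10, 3), candidate_ks = 1:3), "at least 2")
})

test_that("habitat maps recover the planted classes and their ordering", {
  skip_if_not_installed("mclust")
  ph <- std_phantom()
  sv <- supervoxel_segment(ph$pre$volume, ph$pre$mask, seed = 3)
  map <- cluster_habitats(sv, k = 3, seed = 3)
  fg <- ph$truth$latent_class_map > 0
  ari <- mclust::adjustedRandIndex(map$labels[fg], ph$truth$latent_class_map[fg])
  expect_gte(ari, 0.8)
  # canonical ordering: label 1 has the highest mean enhancement
  expect_true(all(diff(map$habitat_means) <= 0))
  means_by_label <- sapply(1:3, function(h) mean(ph$pre$volume$voxels[map$labels == h]))
  expect_true(all(diff(means_by_label) <= 0))
})

test_that("habitat maps partition the tumor mask exactly", {
  ph <- std_phantom()
  map <- delineate_habitats(ph$pre$volume, ph$pre$mask, seed = 5)
  fg <- ph$pre$mask$voxels > 0
  expect_true(all(map$labels[fg] %in% 1:3))
  expect_true(all(map$labels[!fg] == 0))
  comp <- habitat_composition(map)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-9)
})

test_that("habitat composition recovers planted fractions", {
  ph <- generate_phantom_pair(
    fractions_pre = c(0.5, 0.3, 0.2),
    class_sds = c(5, 5, 5), noise_sd = 2, seed = 12
  )
  map <- delineate_habitats(ph$pre$volume, ph$pre$mask, seed = 2)
  comp <- habitat_composition(map)
  expect_true(all(abs(comp$fraction - c(0.5, 0.3, 0.2)) <= 0.05))
})

test_that("clustering is deterministic and label-order canonical", {
  ph <- std_phantom()
  sv <- supervoxel_segment(ph$pre$volume, ph$pre$mask, seed = 8)
  a <- cluster_habitats(sv, k = 3, seed = 4)
  b <- cluster_habitats(sv, k = 3, seed = 4)
  expect_identical(a$labels, b$labels)
  # a different k-means seed may permute raw clusters, but the canonical
  # enhancement ordering makes the final map invariant
  c3 <- cluster_habitats(sv, k = 3, seed = 99)
  agree <- mean(a$labels[a$labels > 0] == c3$labels[c3$labels > 0])
  expect_gt(agree, 0.98)
})

test_that("voxel-level fallback serves masks too small to over-segment", {
  dims <- c(12, 12, 12)
  set.seed(2)
  arr <- array(rnorm(prod(dims), 100, 5), dims)
  fg <- sphere_mask_array(dims, 3.3)
  arr[fg][seq_len(sum(fg) / 2)] <- rnorm(sum(fg) / 2, 300, 5)
  v <- hab_volume(arr)
  m <- hab_mask(fg)
  map <- delineate_habitats(v, m, k = 2, seed = 1)
  expect_identical(sort(unique(map$labels[fg])), c(1L, 2L))
  expect_true(all(diff(map$habitat_means) <= 0))
})

test_that("pre and mid maps of one patient share the fixed K", {
  ph <- std_phantom()
  pre_map <- delineate_habitats(ph$pre$volume, ph$pre$mask, k = 3, seed = 1)
  mid_map <- delineate_habitats(ph$mid$volume, ph$mid$mask, k = 3, seed = 1)
  expect_identical(pre_map$k, mid_map$k)
})

test_that("automatic per-tumor K selection is available behind a flag", {
  ph <- std_phantom()
  map <- delineate_habitats(ph$pre$volume, ph$pre$mask, k = "auto", seed = 3)
  expect_identical(map$k, 3L)
})
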