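test_that("transform channels: count, flat-signal algebra, LoG scale selection", {
  cfg <- feature_panel()
  v_const <- hab_volume(array(7, c(12, 12, 12)))
  ch <- apply_transforms(v_const, cfg)
  expect_length(ch, 13)
  # flat signal: all detail sub-bands vanish, LLL is a scaled constant
  for (nm in names(ch)) {
    if (grepl("^wavelet_", nm) && nm != "wavelet_LLL") {
      expect_lt(max(abs(ch[[nm]])), 1e-10)
    }
  }
  expect_equal(unique(round(as.vector(ch$wavelet_LLL), 8)), round(7 * 2^1.5, 8))

  # scale selection: the normalized centre response of a Gaussian blob of
  # scale b peaks analytically at sigma = b / sqrt(1.5); check the grid
  # argmax lands there and shifts up with the blob scale
  blob_resp <- function(blob_sigma) {
    dims <- c(25, 25, 25)
    g <- expand.grid(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    r2 <- (g[, 1] - 13)^2 + (g[, 2] - 13)^2 + (g[, 3] - 13)^2
    v_blob <- hab_volume(array(100 * exp(-r2 / (2 * blob_sigma^2)), dims))
    chb <- apply_transforms(v_blob, cfg)
    sapply(cfg$log_sigmas_mm, function(s) {
      abs(chb[[sprintf("log_sigma_%g_mm", s)]][13, 13, 13])
    })
  }
  pick <- function(b) cfg$log_sigmas_mm[which.max(blob_resp(b))]
  expect_identical(pick(2.5), 2) # analytic argmax 2.5/sqrt(1.5) = 2.04
  expect_identical(pick(5.0), 4) # analytic argmax 4.08
  expect_lt(pick(2.5), pick(5.0))
})

test_that("panel accounting reproduces the printed feature arithmetic", {
  expect_identical(n_features_per_region(feature_panel()), 14L + 93L * 13L)
  expect_identical(n_features_per_region(feature_panel()), 1223L)
  expect_identical(3L * n_features_per_region(feature_panel()), 3669L)
  expect_identical(2L * (1223L + 3669L), 9784L)
  expect_length(region_feature_names(feature_panel()), 1223)
  expect_false(anyDuplicated(region_feature_names(feature_panel())) > 0)
})

test_that("a reduced-panel patient row concatenates all regions and timepoints", {
  cfg <- feature_panel(families = "firstorder", transforms = "original")
  ph <- std_phantom()
  hpre <- delineate_habitats(ph$pre$volume, ph$pre$mask, seed = 1)
  hmid <- delineate_habitats(ph$mid$volume, ph$mid$mask, seed = 1)
  row <- extract_patient_features(
    pre = list(volume = ph$pre$volume, mask = ph$pre$mask, habitats = hpre),
    mid = list(volume = ph$mid$volume, mask = ph$mid$mask, habitats = hmid),
    config = cfg
  )
  expect_length(row, 2 * 4 * 18)
  mf <- feature_manifest(names(row))
  expect_identical(sort(unique(mf$region)), c("H1", "H2", "H3", "TR"))
  # SHR/TR ratio of 3 per timepoint
  expect_identical(
    sum(mf$region != "TR" & mf$timepoint == "pre"),
    3L * sum(mf$region == "TR" & mf$timepoint == "pre")
  )
})

test_that("sphere shape features approach their analytic limits", {
  dims <- c(26, 26, 26)
  ch <- list(original = array(1, dims))
  mask <- sphere_mask_array(dims, 10)
  f <- extract_region_features(ch, mask,
    config = feature_panel(families = "shape", transforms = "original")
  )
  expect_lt(abs(f["shape_sphericity"] - 1), 0.05)
  expect_lt(abs(f["shape_mesh_volume"] - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
  expect_lt(abs(f["shape_max_3d_diameter"] - 20) / 20, 0.1)
  expect_lt(abs(f["shape_elongation"] - 1), 0.05)
})

test_that("first-order features equal brute-force recomputation", {
  set.seed(3)
  dims <- c(6, 6, 6)
  vals <- array(runif(prod(dims), 0, 200), dims)
  mask <- array(runif(prod(dims)) < 0.7, dims)
  mask[1:2, 1, 1] <- TRUE # ensure >= 8
  ch <- list(original = vals)
  f <- extract_region_features(ch, mask,
    config = feature_panel(families = "firstorder", transforms = "original")
  )
  x <- vals[mask]
  expect_equal(unname(f["original_firstorder_mean"]), mean(x), tolerance = 1e-9)
  expect_equal(unname(f["original_firstorder_variance"]),
    mean((x - mean(x))^2),
    tolerance = 1e-9
  )
  expect_equal(unname(f["original_firstorder_energy"]), sum(x^2), tolerance = 1e-9)
  expect_equal(unname(f["original_firstorder_rms"]), sqrt(mean(x^2)), tolerance = 1e-9)
  expect_equal(
    unname(f["original_firstorder_skewness"]),
    mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5,
    tolerance = 1e-9
  )
})

test_that("GLCM matches a brute-force co-occurrence oracle on a toy grid", {
  # 4x4 two-level checkerboard, printed:
  #   1 2 1 2
  #   2 1 2 1
  #   1 2 1 2
  #   2 1 2 1
  grid <- outer(1:4, 1:4, function(i, j) 1 + (i + j) %% 2)
  gbox <- array(NA_real_, c(4, 4, 1))
  gbox[, , 1] <- grid
  brute_glcm <- function(gbox, ng, off) {
    d <- dim(gbox)
    P <- matrix(0, ng, ng)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      xx <- x + off[1]; yy <- y + off[2]; zz <- z + off[3]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) next
      a <- gbox[x, y, z]; b <- gbox[xx, yy, zz]
      if (is.na(a) || is.na(b)) next
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
    P / sum(P)
  }
  contrast_of <- function(P) sum((row(P) - col(P))^2 * P)
  # horizontal neighbours always differ by one level: contrast 1
  P_h <- habitatr:::glcm_matrix_dir(gbox, 2, c(1, 0, 0))
  expect_equal(P_h, brute_glcm(gbox, 2, c(1, 0, 0)), tolerance = 1e-12)
  expect_equal(contrast_of(P_h), 1, tolerance = 1e-12)
  # diagonal neighbours are always equal: contrast 0
  P_d <- habitatr:::glcm_matrix_dir(gbox, 2, c(1, 1, 0))
  expect_equal(contrast_of(P_d), 0, tolerance = 1e-12)
  # random small 3D grids against the oracle for every direction
  set.seed(8)
  for (rep in 1:3) {
    gb <- array(sample(1:4, 5^3, TRUE), c(5, 5, 5))
    gb[sample(125, 20)] <- NA
    offs <- habitatr:::offset_table_13()
    for (o in seq_len(nrow(offs))) {
      expect_equal(
        habitatr:::glcm_matrix_dir(gb, 4, offs[o, ]),
        brute_glcm(gb, 4, offs[o, ]),
        tolerance = 1e-12
      )
    }
  }
})

test_that("GLRLM run counts equal a brute-force run enumeration", {
  brute_glrlm <- function(gbox, ng, off) {
    d <- dim(gbox)
    runs <- list()
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if (is.na(gbox[x, y, z])) next
      # start of a run: predecessor missing or different
      px <- x - off[1]; py <- y - off[2]; pz <- z - off[3]
      pred <- if (px >= 1 && px <= d[1] && py >= 1 && py <= d[2] &&
        pz >= 1 && pz <= d[3]) {
        gbox[px, py, pz]
      } else {
        NA
      }
      if (!is.na(pred) && pred == gbox[x, y, z]) next
      len <- 1
      cx <- x + off[1]; cy <- y + off[2]; cz <- z + off[3]
      while (cx >= 1 && cx <= d[1] && cy >= 1 && cy <= d[2] &&
        cz >= 1 && cz <= d[3] && !is.na(gbox[cx, cy, cz]) &&
        gbox[cx, cy, cz] == gbox[x, y, z]) {
        len <- len + 1
        cx <- cx + off[1]; cy <- cy + off[2]; cz <- cz + off[3]
      }
      runs[[length(runs) + 1]] <- c(gbox[x, y, z], len)
    }
    m <- do.call(rbind, runs)
    R <- matrix(0, ng, max(m[, 2]))
    for (i in seq_len(nrow(m))) R[m[i, 1], m[i, 2]] <- R[m[i, 1], m[i, 2]] + 1
    R
  }
  set.seed(5)
  offs <- habitatr:::offset_table_13()
  for (rep in 1:3) {
    gb <- array(sample(1:3, 6^3, TRUE), c(6, 6, 6))
    gb[sample(216, 40)] <- NA
    for (o in sample(nrow(offs), 5)) {
      ours <- habitatr:::glrlm_matrix_dir(gb, 3, offs[o, ])
      oracle <- brute_glrlm(gb, 3, offs[o, ])
      # pad to common width
      w <- max(ncol(ours), ncol(oracle))
      pad <- function(m) cbind(m, matrix(0, nrow(m), w - ncol(m)))
      expect_equal(pad(ours), pad(oracle), tolerance = 1e-12)
    }
  }
})

test_that("intensity and texture features are translation invariant", {
  set.seed(6)
  patt <- array(sample(1:50, 4^3, TRUE) * 5, c(4, 4, 4))
  place <- function(at) {
    arr <- array(0, c(14, 14, 14))
    msk <- array(FALSE, c(14, 14, 14))
    arr[at[1]:(at[1] + 3), at[2]:(at[2] + 3), at[3]:(at[3] + 3)] <- patt
    msk[at[1]:(at[1] + 3), at[2]:(at[2] + 3), at[3]:(at[3] + 3)] <- TRUE
    cfg <- feature_panel(
      families = c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm"),
      transforms = "original"
    )
    extract_region_features(list(original = arr), msk, config = cfg)
  }
  expect_equal(place(c(2, 2, 2)), place(c(7, 9, 5)), tolerance = 1e-12)
})

test_that("direction-averaged GLCM features are exact under 90-degree rotation", {
  set.seed(7)
  n <- 6
  arr <- array(sample(1:40, n^3, TRUE) * 6, c(n, n, n))
  rot <- aperm(arr, c(2, 1, 3))[n:1, , ] # 90 degrees about z
  cfg <- feature_panel(families = "glcm", transforms = "original")
  msk <- array(TRUE, c(n, n, n))
  f1 <- extract_region_features(list(original = arr), msk, config = cfg)
  f2 <- extract_region_features(list(original = rot), msk, config = cfg)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("tiny regions are flagged, not silently dropped", {
  ch <- list(original = array(1, c(8, 8, 8)))
  msk <- array(FALSE, c(8, 8, 8))
  msk[1:7] <- TRUE
  f <- extract_region_features(ch, msk,
    config = feature_panel(families = "firstorder", transforms = "original")
  )
  expect_true(all(is.na(f)))
  expect_true(attr(f, "degenerate"))
})
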