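# Morphological (shape) features of a region mask: 14 descriptors computed
# from the voxel geometry. Surface area uses a smoothed-gradient surface
# estimator (integral of |grad| of the Gaussian-smoothed indicator), which
# tracks the true surface much more closely than voxel-face counting on
# curved objects.

shape_surface_area <- function(region_mask, spacing, sigma_mm = 0.8) {
  ind <- array(as.numeric(region_mask), dim(region_mask))
  s <- gaussian_smooth(ind, sigma_mm = sigma_mm, spacing = spacing)
  d <- dim(s)
  grad2 <- array(0, d)
  for (ax in 1:3) {
    kp <- ks <- lapply(d, seq_len)
    # central differences, replicate edges
    up <- pmin(seq_len(d[ax]) + 1L, d[ax])
    dn <- pmax(seq_len(d[ax]) - 1L, 1L)
    kp[[ax]] <- up
    ks[[ax]] <- dn
    g <- (do.call(`[`, c(list(s), kp)) - do.call(`[`, c(list(s), ks))) /
      (2 * spacing[ax])
    # edge voxels used a one-sided step
    edge <- seq_len(d[ax]) %in% c(1L, d[ax])
    if (any(edge)) {
      sel <- lapply(d, seq_len)
      sel[[ax]] <- which(edge)
      ge <- do.call(`[`, c(list(array(g, d)), sel, list(drop = FALSE))) * 2
      g <- array(g, d)
      g <- do.call(`[<-`, c(list(g), sel, list(ge)))
    }
    grad2 <- grad2 + array(g, d)^2
  }
  sum(sqrt(grad2)) * prod(spacing)
}

max_pairwise_distance <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(0)
  if (n > 1200) {
    # restrict to extreme points along a fixed fan of projections
    # (deterministic, slight underestimate possible on huge regions)
    dirs <- rbind(diag(3), offset_table_13())
    set <- unique(unlist(lapply(seq_len(nrow(dirs)), function(i) {
      p <- coords %*% dirs[i, ]
      c(which.min(p), which.max(p))
    })))
    coords <- coords[set, , drop = FALSE]
    n <- nrow(coords)
  }
  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") - 2 * coords %*% t(coords)
  sqrt(max(d2, 0))
}

shape_features <- function(region_mask, spacing) {
  idx <- which(region_mask)
  n <- length(idx)
  pos <- arrayInd(idx, dim(region_mask))
  coords <- sweep(pos, 2, spacing, "*")
  voxvol <- prod(spacing)
  volume <- n * voxvol
  area <- shape_surface_area(region_mask, spacing)
  # principal axes from the physical-coordinate covariance
  ev <- if (n > 3) {
    sort(pmax(eigen(stats::cov(coords), only.values = TRUE)$values, 0), decreasing = TRUE)
  } else {
    c(0, 0, 0)
  }
  axes <- 4 * sqrt(ev)
  # boundary voxels only, for diameters
  er <- erode6(region_mask)
  bidx <- which(region_mask & !er)
  if (!length(bidx)) bidx <- idx
  bpos <- arrayInd(bidx, dim(region_mask))
  bco <- sweep(bpos, 2, spacing, "*")
  max3d <- max_pairwise_distance(bco)
  diam2d <- function(drop_ax) {
    planes <- split.data.frame(bco[, -drop_ax, drop = FALSE], bpos[, drop_ax])
    max(vapply(planes, function(m) max_pairwise_distance(as.matrix(m)), numeric(1)))
  }
  sph <- guard_div((36 * pi * volume^2)^(1 / 3), area)
  c(
    shape_mesh_volume = volume,
    shape_voxel_volume = volume,
    shape_surface_area = area,
    shape_surface_volume_ratio = guard_div(area, volume),
    shape_sphericity = sph,
    shape_max_3d_diameter = max3d,
    shape_max_2d_diameter_slice = diam2d(3),
    shape_max_2d_diameter_column = diam2d(1),
    shape_max_2d_diameter_row = diam2d(2),
    shape_major_axis_length = axes[1],
    shape_minor_axis_length = axes[2],
    shape_least_axis_length = axes[3],
    shape_elongation = guard_div(sqrt(ev[2]), sqrt(ev[1])),
    shape_flatness = guard_div(sqrt(ev[3]), sqrt(ev[1]))
  )
}
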