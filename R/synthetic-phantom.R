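# Synthetic phantoms: ellipsoidal tumors partitioned into three spatially
# coherent perfusion classes, used as ground truth for habitat recovery.

with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# smoothly perturbed ellipsoid indicator on a voxel grid
ellipsoid_mask_array <- function(dims, center, radii, boundary_jitter = 0.06) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3]))
  u <- cbind(
    (g$x - center[1]) / radii[1],
    (g$y - center[2]) / radii[2],
    (g$z - center[3]) / radii[3]
  )
  r2 <- rowSums(u^2)
  theta <- atan2(u[, 2], u[, 1])
  phi <- atan2(sqrt(u[, 1]^2 + u[, 2]^2), u[, 3])
  a <- stats::rnorm(4, 0, boundary_jitter)
  p <- 1 + a[1] * sin(2 * theta) + a[2] * cos(theta + phi) +
    a[3] * sin(2 * phi) + a[4] * cos(2 * theta - phi)
  inside <- r2 <= p^2
  array(inside, dim = dims)
}

# farthest-point seed selection among foreground coordinates
pick_region_seeds <- function(coords, k) {
  n <- nrow(coords)
  seeds <- sample.int(n, 1)
  while (length(seeds) < k) {
    d2 <- matrix(Inf, n, length(seeds))
    for (j in seq_along(seeds)) {
      d2[, j] <- rowSums(sweep(coords, 2, coords[seeds[j], ], "-")^2)
    }
    seeds <- c(seeds, which.max(apply(d2, 1, min)))
  }
  seeds
}

# capacity-balanced competitive growth: assign each foreground voxel to the
# seed with smallest biased squared distance, iterating additive biases until
# realized volume fractions approach the targets (a discrete power diagram)
grow_regions <- function(coords, fractions, n_iter = 60) {
  k <- length(fractions)
  active <- which(fractions > 0)
  if (length(active) == 1L) return(rep(active, nrow(coords)))
  seeds <- pick_region_seeds(coords, length(active))
  d2 <- sapply(seq_along(active), function(j) {
    rowSums(sweep(coords, 2, coords[seeds[j], ], "-")^2)
  })
  scale2 <- mean(apply(d2, 1, min)) + mean(d2)
  bias <- rep(0, length(active))
  tgt <- fractions[active] / sum(fractions[active])
  assign <- max.col(-(d2), ties.method = "first")
  for (it in seq_len(n_iter)) {
    biased <- sweep(d2, 2, bias, "+")
    assign <- max.col(-biased, ties.method = "first")
    got <- tabulate(assign, nbins = length(active)) / nrow(coords)
    err <- got - tgt
    if (max(abs(err)) < 0.005) break
    bias <- bias + 0.35 * scale2 * err
  }
  active[assign]
}

#' Generate a paired pre/mid-treatment tumor phantom
#'
#' Builds an ellipsoidal tumor (smoothly perturbed boundary) whose voxels are
#' partitioned into up to three spatially coherent perfusion classes grown
#' from well-separated seeds, with per-class Gaussian intensities on a noisy
#' background. The mid-treatment image is a shrunken tumor recomposed to the
#' mid-timepoint volume fractions. The planted class map is returned as
#' ground truth for habitat-recovery experiments.
#'
#' Class semantics follow the enhancement ordering used for habitat maps:
#' class 1 has the highest mean signal (highly perfused, metabolically
#' active core), class 3 the lowest (marginal / hypoxic tissue), so
#' `class_means` must be strictly decreasing.
#'
#' @param size Integer length-3 grid size in voxels (spacing fixed at 1 mm).
#' @param fractions_pre,fractions_mid Length-3 class volume fractions at each
#'   timepoint; each must sum to 1.
#' @param class_means,class_sds Length-3 per-class intensity means (strictly
#'   decreasing) and SDs.
#' @param noise_sd Additive acquisition noise SD, also used for background.
#' @param shrink Mid-treatment linear shrink factor of the tumor radii.
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @return A list with `pre` and `mid` (each `volume`, `mask`) and `truth`
#'   (planted class maps, per-timepoint planted and realized fractions,
#'   class means/SDs).
#' @examples
#' ph <- generate_phantom_pair(seed = 1)
#' table(ph$truth$latent_class_map[ph$truth$latent_class_map > 0])
#' @export
generate_phantom_pair <- function(size = c(32, 32, 32),
                                  fractions_pre = c(0.40, 0.35, 0.25),
                                  fractions_mid = c(0.25, 0.35, 0.40),
                                  class_means = c(300, 200, 100),
                                  class_sds = c(15, 15, 15),
                                  noise_sd = 5,
                                  shrink = 0.7,
                                  seed = NULL) {
  stopifnot(length(fractions_pre) == 3, length(fractions_mid) == 3)
  if (abs(sum(fractions_pre) - 1) > 1e-9 || abs(sum(fractions_mid) - 1) > 1e-9) {
    stop("class fractions must each sum to 1", call. = FALSE)
  }
  if (any(fractions_pre < 0) || any(fractions_mid < 0)) {
    stop("class fractions must be non-negative", call. = FALSE)
  }
  if (any(diff(class_means) >= 0)) {
    stop("class_means must be strictly decreasing (class 1 = highest enhancement)",
      call. = FALSE
    )
  }
  if (any(class_sds < 0) || noise_sd < 0) {
    stop("class_sds and noise_sd must be non-negative", call. = FALSE)
  }
  with_local_seed(seed, {
    dims <- as.integer(size)
    center <- (dims + 1) / 2
    radii_pre <- pmax(3.5, dims * 0.31 * stats::runif(3, 0.9, 1.1))
    tumors <- list(
      pre = ellipsoid_mask_array(dims, center, radii_pre),
      mid = ellipsoid_mask_array(dims, center, radii_pre * shrink)
    )
    fracs <- list(pre = fractions_pre, mid = fractions_mid)
    out <- list()
    truth_maps <- list()
    realized <- list()
    bg_level <- 40
    for (tp in c("pre", "mid")) {
      fg <- largest_component(tumors[[tp]])
      if (sum(fg) < 64) stop("phantom tumor smaller than 64 voxels", call. = FALSE)
      coords <- arrayInd(which(fg), dims)
      cls <- grow_regions(coords, fracs[[tp]])
      cmap <- array(0L, dims)
      cmap[which(fg)] <- cls
      vox <- array(stats::rnorm(prod(dims), bg_level, max(noise_sd, 1e-8)), dims)
      for (c in 1:3) {
        sel <- which(cmap == c)
        if (length(sel)) {
          vox[sel] <- stats::rnorm(length(sel), class_means[c], class_sds[c]) +
            stats::rnorm(length(sel), 0, noise_sd)
        }
      }
      out[[tp]] <- list(
        volume = hab_volume(vox, spacing = c(1, 1, 1)),
        mask = hab_mask(cmap > 0, spacing = c(1, 1, 1))
      )
      truth_maps[[tp]] <- cmap
      realized[[tp]] <- tabulate(cls, nbins = 3) / length(cls)
    }
    list(
      pre = out$pre,
      mid = out$mid,
      truth = list(
        latent_class_map = truth_maps$pre,
        latent_class_map_mid = truth_maps$mid,
        class_means = class_means,
        class_sds = class_sds,
        volume_fractions_pre = fractions_pre,
        volume_fractions_mid = fractions_mid,
        realized_fractions_pre = realized$pre,
        realized_fractions_mid = realized$mid
      )
    )
  })
}

#' Simulate a re-delineation of a tumor mask
#'
#' Perturbs the mask boundary by a smooth random level-set displacement of
#' scale `magnitude` (mm) plus a random global dilate/erode offset, emulating
#' a second reader's delineation for reliability (ICC) analysis. The result
#' is kept a single 26-connected component with at least 64 voxels.
#'
#' @param mask A `hab_mask`.
#' @param magnitude Displacement scale in mm; 0 returns the mask unchanged.
#' @param seed Integer seed.
#' @return A perturbed `hab_mask`.
#' @export
perturb_mask <- function(mask, magnitude, seed = NULL) {
  stopifnot(inherits(mask, "hab_mask"))
  if (magnitude < 0) stop("magnitude must be >= 0", call. = FALSE)
  if (magnitude == 0) return(mask)
  with_local_seed(seed, {
    dims <- dim(mask$voxels)
    fg <- mask$voxels > 0
    for (attempt in 1:10) {
      sdist <- signed_boundary_distance(fg, mask$spacing)
      field <- array(stats::rnorm(prod(dims)), dims)
      field <- gaussian_smooth(field, sigma_mm = 3, spacing = mask$spacing)
      field <- field / stats::sd(field)
      offset <- stats::rnorm(1, 0, magnitude / 2)
      new_fg <- (sdist + magnitude * field + offset) > 0
      new_fg <- largest_component(new_fg)
      if (sum(new_fg) >= 64) {
        return(hab_mask(new_fg, spacing = mask$spacing, origin = mask$origin))
      }
    }
    stop("mask perturbation emptied the mask after 10 attempts", call. = FALSE)
  })
}

# signed distance (mm) to the mask surface: positive inside, negative outside.
# Exact only near the boundary (far voxels get a saturated value), which is
# all the level-set perturbation needs.
signed_boundary_distance <- function(fg, spacing, band_mm = 6) {
  dims <- dim(fg)
  s <- gaussian_smooth(array(as.numeric(fg), dims), sigma_mm = 1.2, spacing = spacing)
  near <- which(s > 0.02 & s < 0.98)
  sdist <- array(ifelse(fg, band_mm, -band_mm), dims)
  if (!length(near)) return(sdist)
  # boundary voxels: foreground with a 6-neighbour background
  bnd <- fg & !erode6(fg)
  bcoords <- sweep(arrayInd(which(bnd), dims), 2, spacing, "*")
  ncoords <- sweep(arrayInd(near, dims), 2, spacing, "*")
  if (nrow(bcoords) == 0) return(sdist)
  # chunked nearest-boundary distance
  chunk <- 4000L
  dmin <- numeric(nrow(ncoords))
  for (i in seq(1, nrow(ncoords), by = chunk)) {
    j <- seq(i, min(i + chunk - 1L, nrow(ncoords)))
    d2 <- outer(rowSums(ncoords[j, , drop = FALSE]^2), rowSums(bcoords^2), "+") -
      2 * ncoords[j, , drop = FALSE] %*% t(bcoords)
    dmin[j] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  sdist[near] <- ifelse(fg[near], dmin, -dmin)
  sdist
}

erode6 <- function(fg) {
  dims <- dim(fg)
  out <- fg
  shift_and <- function(a, ax, by) {
    b <- array(FALSE, dims)
    idx_src <- lapply(dims, seq_len)
    idx_dst <- idx_src
    n <- dims[ax]
    if (by == 1) {
      idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n
    } else {
      idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1)
    }
    b <- do.call(`[<-`, c(list(b), idx_dst, list(do.call(`[`, c(list(a), idx_src)))))
    b
  }
  for (ax in 1:3) {
    out <- out & shift_and(fg, ax, 1) & shift_and(fg, ax, -1)
  }
  out
}

#' Dice similarity of two masks
#'
#' @param a,b `hab_mask` objects on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a$voxels), dim(b$voxels)))
  2 * sum(a$voxels & b$voxels) / (sum(a$voxels) + sum(b$voxels))
}
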