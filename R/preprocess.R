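# Volume preprocessing: multiplicative bias-field correction, isotropic
# resampling, and piecewise-linear histogram landmark standardization.
# Order contract: bias correction -> resampling -> standardization.

#' Preprocessing configuration
#'
#' @param target_spacing Isotropic output spacing in mm (default 1).
#' @param landmark_percentiles Strictly increasing percentiles in (0, 100)
#'   used as histogram landmarks (deciles plus the 1st/99th by default),
#'   computed inside the tumor mask.
#' @param bias_sigma_mm Smoothing scale (mm) of the bias-field estimator.
#' @param bias_correction Logical switch.
#' @return A list of class `hab_preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = 1,
                              landmark_percentiles = c(1, seq(10, 90, 10), 99),
                              bias_sigma_mm = 8,
                              bias_correction = TRUE) {
  stopifnot(target_spacing > 0)
  p <- landmark_percentiles
  if (any(diff(p) <= 0) || any(p <= 0) || any(p >= 100)) {
    stop("landmark percentiles must be strictly increasing within (0, 100)", call. = FALSE)
  }
  structure(
    list(
      target_spacing = target_spacing,
      landmark_percentiles = p,
      bias_sigma_mm = bias_sigma_mm,
      bias_correction = bias_correction
    ),
    class = "hab_preprocess_config"
  )
}

#' Multiplicative bias-field correction
#'
#' Estimates a smooth, strictly positive multiplicative gain field as the
#' exponential of a coarse-scale Gaussian low-pass of the log intensities
#' over a dilated tumor region, normalizes it to unit mean inside the mask,
#' and divides it out of the whole volume. Removes slowly varying coil/field
#' inhomogeneity while leaving tissue-scale contrast intact.
#'
#' @param volume A `hab_volume`.
#' @param mask An aligned `hab_mask` (the estimation region).
#' @param sigma_mm Smoothing scale of the field estimate, in mm.
#' @return Bias-corrected `hab_volume`.
#' @export
bias_field_correct <- function(volume, mask, sigma_mm = 8) {
  check_aligned(volume, mask)
  arr <- volume$voxels
  if (!all(is.finite(arr))) stop("non-finite voxels in input volume", call. = FALSE)
  eps <- max(1e-6, 1e-6 * max(abs(arr)))
  shift <- max(0, -min(arr)) + eps
  logv <- log(arr + shift)
  smooth_log <- gaussian_smooth(logv, sigma_mm = sigma_mm, spacing = volume$spacing)
  field <- exp(smooth_log - mean(smooth_log[mask$voxels > 0]))
  out <- (arr + shift) / field - shift
  hab_volume(out, spacing = volume$spacing, origin = volume$origin)
}

# cubic convolution (Keys a = -0.5) interpolation weights
cubic_kernel <- function(t) {
  a <- -0.5
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  i2 <- at > 1 & at < 2
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# (n_new x n_old) interpolation matrix along one axis, voxel-centre aligned
axis_weights <- function(n_old, sp_old, n_new, sp_new, method = c("cubic", "nearest")) {
  method <- match.arg(method)
  # voxel-centre world coordinates with a shared half-voxel origin so the
  # physical extent is preserved
  x_new <- (seq_len(n_new) - 0.5) * sp_new
  src <- x_new / sp_old + 0.5 # fractional index in old grid
  W <- matrix(0, n_new, n_old)
  if (method == "nearest") {
    j <- pmin(pmax(round(src), 1), n_old)
    W[cbind(seq_len(n_new), j)] <- 1
  } else {
    for (k in -1:2) {
      j <- floor(src) + k
      w <- cubic_kernel(src - j)
      j <- pmin(pmax(j, 1), n_old) # replicate edges
      for (i in seq_len(n_new)) W[i, j[i]] <- W[i, j[i]] + w[i]
    }
    W <- W / rowSums(W)
  }
  W
}

resample_array <- function(arr, spacing, target, method) {
  d <- dim(arr)
  n_new <- pmax(4L, as.integer(round(d * spacing / target)))
  for (ax in 1:3) {
    W <- axis_weights(dim(arr)[ax], spacing[ax], n_new[ax], target, method)
    perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    a <- aperm(arr, perm)
    dp <- dim(a)
    m <- W %*% matrix(a, nrow = dp[1])
    out <- array(m, dim = c(n_new[ax], dp[2], dp[3]))
    arr <- aperm(out, order(perm))
  }
  arr
}

#' Resample a volume and mask to isotropic spacing
#'
#' Intensities are interpolated with a separable cubic (spline) kernel, the
#' mask with nearest neighbour and re-binarized; the physical extent is
#' preserved within one voxel. Volumes already at the target spacing are
#' returned unchanged.
#'
#' @param volume A `hab_volume`.
#' @param mask An aligned `hab_mask` (optional).
#' @param config A [preprocess_config()].
#' @return List with resampled `volume` and `mask`.
#' @export
resample_isotropic <- function(volume, mask = NULL, config = preprocess_config()) {
  spacing <- volume$spacing
  if (any(spacing <= 0)) stop("voxel spacing must be positive", call. = FALSE)
  if (max(spacing) / min(spacing) > 20) {
    warning("anisotropy ratio exceeds 20; proceeding", call. = FALSE)
  }
  target <- config$target_spacing
  if (!is.null(mask)) check_aligned(volume, mask)
  if (max(abs(spacing - target)) < 1e-9) {
    return(list(volume = volume, mask = mask))
  }
  vox <- resample_array(volume$voxels, spacing, target, "cubic")
  new_vol <- hab_volume(vox, spacing = rep(target, 3), origin = volume$origin)
  new_mask <- NULL
  if (!is.null(mask)) {
    mvox <- resample_array(mask$voxels + 0, spacing, target, "nearest")
    mvox <- largest_component(mvox > 0.5)
    new_mask <- hab_mask(mvox, spacing = rep(target, 3), origin = mask$origin)
  }
  list(volume = new_vol, mask = new_mask)
}

#' Compute histogram landmarks inside a mask
#'
#' @param volume A `hab_volume`.
#' @param mask An aligned `hab_mask`.
#' @param config A [preprocess_config()] supplying the percentiles.
#' @return Named numeric vector of landmark intensities.
#' @export
histogram_landmarks <- function(volume, mask, config = preprocess_config()) {
  check_aligned(volume, mask)
  vals <- volume$voxels[mask$voxels > 0]
  stats::quantile(vals, probs = config$landmark_percentiles / 100, names = TRUE, type = 7)
}

#' Piecewise-linear histogram standardization
#'
#' Maps the volume's landmark intensities (percentiles computed inside the
#' mask) onto a set of reference landmark intensities with a monotone
#' piecewise-linear transform (Nyul-style landmark matching); the end
#' segments are extrapolated linearly.
#'
#' @param volume A `hab_volume`.
#' @param mask An aligned `hab_mask`.
#' @param reference_landmarks Strictly increasing reference intensities, one
#'   per configured percentile.
#' @param config A [preprocess_config()].
#' @return Standardized `hab_volume`.
#' @export
standardize_histogram <- function(volume, mask, reference_landmarks,
                                  config = preprocess_config()) {
  check_aligned(volume, mask)
  ref <- as.numeric(reference_landmarks)
  if (any(diff(ref) <= 0)) {
    stop("reference landmarks must be strictly increasing", call. = FALSE)
  }
  if (length(ref) != length(config$landmark_percentiles)) {
    stop("reference landmarks must match the configured percentiles", call. = FALSE)
  }
  own <- as.numeric(histogram_landmarks(volume, mask, config))
  if (length(unique(own)) < 2 || any(diff(own) < 0) || max(own) - min(own) <= 0) {
    stop("fewer than 2 distinct intensities inside mask", call. = FALSE)
  }
  # collapse ties in source landmarks to keep the map a function
  keep <- c(TRUE, diff(own) > 0)
  own_u <- own[keep]
  ref_u <- ref[keep]
  x <- as.numeric(volume$voxels)
  inner <- stats::approx(own_u, ref_u, xout = x, rule = 2)$y
  # linear extrapolation beyond the outer landmarks
  lo_slope <- (ref_u[2] - ref_u[1]) / (own_u[2] - own_u[1])
  m <- length(own_u)
  hi_slope <- (ref_u[m] - ref_u[m - 1]) / (own_u[m] - own_u[m - 1])
  below <- x < own_u[1]
  above <- x > own_u[m]
  inner[below] <- ref_u[1] + (x[below] - own_u[1]) * lo_slope
  inner[above] <- ref_u[m] + (x[above] - own_u[m]) * hi_slope
  hab_volume(array(inner, dim = dim(volume$voxels)),
    spacing = volume$spacing, origin = volume$origin
  )
}

#' Full preprocessing pipeline for one volume/mask pair
#'
#' Applies bias-field correction, isotropic resampling and (when reference
#' landmarks are supplied) histogram standardization, in that order.
#'
#' @inheritParams resample_isotropic
#' @param reference_landmarks Optional reference landmark intensities.
#' @return List with preprocessed `volume` and `mask`.
#' @export
preprocess_pair <- function(volume, mask, reference_landmarks = NULL,
                            config = preprocess_config()) {
  if (config$bias_correction) {
    volume <- bias_field_correct(volume, mask, sigma_mm = config$bias_sigma_mm)
  }
  rs <- resample_isotropic(volume, mask, config)
  volume <- rs$volume
  mask <- rs$mask
  if (!is.null(reference_landmarks)) {
    volume <- standardize_histogram(volume, mask, reference_landmarks, config)
  }
  list(volume = volume, mask = mask)
}
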