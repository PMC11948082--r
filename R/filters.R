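# Separable 3D filtering primitives shared by preprocessing (bias-field
# smoothing) and the feature-panel image transforms (wavelet, LoG).

# 1D convolution of a 3D array along one axis with replicate ("nearest")
# edge padding. Kernel length must be odd; its centre aligns with the voxel.
convolve_axis <- function(arr, kernel, axis) {
  stopifnot(length(kernel) %% 2 == 1)
  h <- (length(kernel) - 1L) / 2L
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  dp <- dim(a)
  n <- dp[1]
  pad_top <- a[rep(1L, h), , , drop = FALSE]
  pad_bot <- a[rep(n, h), , , drop = FALSE]
  ap <- array(0, dim = c(n + 2L * h, dp[2], dp[3]))
  ap[seq_len(h), , ] <- pad_top
  ap[h + seq_len(n), , ] <- a
  ap[h + n + seq_len(h), , ] <- pad_bot
  m <- matrix(ap, nrow = n + 2L * h)
  # stats::filter convolves columns; reverse kernel for true convolution
  fm <- stats::filter(m, rev(kernel), method = "convolution", sides = 2)
  fm <- matrix(fm, nrow = n + 2L * h)[h + seq_len(n), , drop = FALSE]
  out <- array(fm, dim = dp)
  aperm(out, order(perm))
}

separable_filter <- function(arr, kernels) {
  for (ax in 1:3) arr <- convolve_axis(arr, kernels[[ax]], ax)
  arr
}

gaussian_kernel_1d <- function(sigma_vox, radius = NULL) {
  if (sigma_vox <= 0) return(1)
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma_vox))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# second derivative of a Gaussian, discretised; normalised so that the
# positive Gaussian factor integrates to 1 in the other axes
gaussian_d2_kernel_1d <- function(sigma_vox, radius = NULL) {
  if (is.null(radius)) radius <- max(2L, ceiling(3 * sigma_vox))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  ((x^2 - sigma_vox^2) / sigma_vox^4) * g
}

# Gaussian smoothing with per-axis sigma given in mm
gaussian_smooth <- function(arr, sigma_mm, spacing) {
  sig_vox <- sigma_mm / spacing
  kernels <- lapply(1:3, function(ax) gaussian_kernel_1d(sig_vox[ax]))
  separable_filter(arr, kernels)
}

# Laplacian of Gaussian, sigma in mm: sum over axes of (G'' along that axis
# times G along the others). Scale-normalised by sigma^2 as is conventional
# for multi-scale blob response.
log_filter <- function(arr, sigma_mm, spacing) {
  sig_vox <- sigma_mm / spacing
  out <- 0
  for (ax in 1:3) {
    kernels <- lapply(1:3, function(a) {
      if (a == ax) gaussian_d2_kernel_1d(sig_vox[a]) else gaussian_kernel_1d(sig_vox[a])
    })
    out <- out + separable_filter(arr, kernels)
  }
  sigma_mm^2 * out
}

# Single-level stationary (undecimated) 3D Haar wavelet transform: eight
# sub-bands LLL..HHH, each aligned voxel-wise with the input.
wavelet_subbands <- function(arr) {
  lo <- c(1, 1) / sqrt(2)
  hi <- c(-1, 1) / sqrt(2)
  # pad to odd length kernels centred between the two taps: use length-3
  # kernels with a zero so convolve_axis centring applies
  lo3 <- c(lo, 0)
  hi3 <- c(hi, 0)
  bands <- list()
  for (f1 in c("L", "H")) {
    a1 <- convolve_axis(arr, if (f1 == "L") lo3 else hi3, 1)
    for (f2 in c("L", "H")) {
      a2 <- convolve_axis(a1, if (f2 == "L") lo3 else hi3, 2)
      for (f3 in c("L", "H")) {
        a3 <- convolve_axis(a2, if (f3 == "L") lo3 else hi3, 3)
        bands[[paste0(f1, f2, f3)]] <- a3
      }
    }
  }
  bands
}

#' Image transform channels for feature extraction
#'
#' Computes the 13 aligned channels the feature panel is extracted from: the
#' original volume, the eight sub-bands of a single-level stationary 3D Haar
#' wavelet transform (LLL...HHH), and Laplacian-of-Gaussian responses at the
#' configured sigmas (mm). All channels are voxel-aligned with the input.
#'
#' @param volume A `hab_volume` (preprocessed).
#' @param config A [feature_panel()] configuration (supplies the LoG sigmas
#'   and which transform groups are enabled).
#' @return Named list of 3D arrays, one per channel.
#' @export
apply_transforms <- function(volume, config = feature_panel()) {
  arr <- volume$voxels
  if (any(dim(arr) < 4)) stop("volume smaller than filter support", call. = FALSE)
  channels <- list(original = arr)
  if ("wavelet" %in% config$transforms) {
    wb <- wavelet_subbands(arr)
    names(wb) <- paste0("wavelet_", names(wb))
    channels <- c(channels, wb)
  }
  if ("log" %in% config$transforms) {
    for (s in config$log_sigmas_mm) {
      channels[[sprintf("log_sigma_%g_mm", s)]] <-
        log_filter(arr, s, volume$spacing)
    }
  }
  channels
}
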