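# Feature panel configuration and accounting. The per-region panel is
# 14 shape features plus 93 intensity/texture features on each of the 13
# image channels (original + 8 wavelet sub-bands + 4 LoG sigmas):
# 14 + 93 * 13 = 1223.

panel_family_sizes <- c(
  shape = 14L, firstorder = 18L, glcm = 24L, glrlm = 16L,
  glszm = 16L, gldm = 14L, ngtdm = 5L
)

#' Feature panel configuration
#'
#' Defines which feature families and image transforms are extracted, the
#' fixed bin width used to discretize intensities for the grey-level
#' matrices, and the LoG scales. The default configuration reproduces the
#' 1223-features-per-region accounting: 14 shape + 93 texture/intensity
#' features on 13 channels (original, 8 stationary-wavelet sub-bands, 4
#' Laplacian-of-Gaussian scales).
#'
#' @param families Character subset of
#'   `c("shape","firstorder","glcm","glrlm","glszm","gldm","ngtdm")`.
#' @param transforms Character subset of `c("original","wavelet","log")`
#'   (the original channel is always included).
#' @param log_sigmas_mm LoG scales in mm.
#' @param bin_width Fixed discretization bin width in intensity units
#'   (applied per channel, from the region minimum).
#' @param max_bins Safety cap on the number of grey levels.
#' @return A list of class `hab_feature_panel`.
#' @export
feature_panel <- function(families = names(panel_family_sizes),
                          transforms = c("original", "wavelet", "log"),
                          log_sigmas_mm = c(2, 3, 4, 5),
                          bin_width = 25,
                          max_bins = 64) {
  families <- match.arg(families, names(panel_family_sizes), several.ok = TRUE)
  transforms <- unique(c("original", match.arg(transforms,
    c("original", "wavelet", "log"),
    several.ok = TRUE
  )))
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  structure(
    list(
      families = families, transforms = transforms,
      log_sigmas_mm = log_sigmas_mm, bin_width = bin_width,
      max_bins = as.integer(max_bins)
    ),
    class = "hab_feature_panel"
  )
}

#' Feature count per region implied by a panel configuration
#'
#' @param config A [feature_panel()].
#' @return Integer feature count (1223 for the default panel).
#' @export
n_features_per_region <- function(config = feature_panel()) {
  n_channels <- 1L +
    if ("wavelet" %in% config$transforms) 8L else 0L
  n_channels <- n_channels +
    if ("log" %in% config$transforms) length(config$log_sigmas_mm) else 0L
  n_shape <- if ("shape" %in% config$families) panel_family_sizes[["shape"]] else 0L
  tex_fams <- setdiff(config$families, "shape")
  n_shape + n_channels * sum(panel_family_sizes[tex_fams])
}

# fixed-bin-width discretization from the region minimum; returns integer
# grey levels 1..ng
discretize_fbw <- function(values, bin_width, max_bins = 64L) {
  g <- floor((values - min(values)) / bin_width) + 1L
  ng <- max(g)
  if (ng > max_bins) {
    # re-bin with a wider width to respect the cap (degenerate inputs only)
    bin_width <- (max(values) - min(values)) / (max_bins - 1L)
    g <- floor((values - min(values)) / bin_width) + 1L
    ng <- max(g)
  }
  list(levels = as.integer(g), n_levels = as.integer(ng))
}

guard_div <- function(num, den) if (!is.finite(den) || den == 0) 0 else num / den

# all 26 neighbourhood offsets
offset_table_26 <- function() {
  o <- offset_table_13()
  rbind(o, -o)
}

# crop a region to its bounding box; returns the grey-level array with NA
# outside the region
region_box <- function(channel, region_mask) {
  idx <- which(region_mask)
  pos <- arrayInd(idx, dim(region_mask))
  rng <- apply(pos, 2, range)
  sub <- channel[
    rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
    drop = FALSE
  ]
  msk <- region_mask[
    rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
    drop = FALSE
  ]
  sub[!msk] <- NA
  sub
}

# pad a box array with one NA voxel on every side
pad_na <- function(box) {
  d <- dim(box)
  out <- array(NA_real_, d + 2L)
  out[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- box
  out
}

# neighbour values of every voxel for the 26 offsets: returns a matrix
# (n_voxels x 26) of grey levels, NA where the neighbour is outside
neighbour_matrix <- function(box) {
  d <- dim(box)
  p <- pad_na(box)
  idx <- which(!is.na(box))
  pos <- arrayInd(idx, d) + 1L # position in padded array
  offs <- offset_table_26()
  out <- matrix(NA_real_, length(idx), nrow(offs))
  for (o in seq_len(nrow(offs))) {
    np <- sweep(pos, 2, offs[o, ], "+")
    out[, o] <- p[np]
  }
  out
}
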