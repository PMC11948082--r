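#' Image volume and tumor mask containers
#'
#' A `hab_volume` is a 3D scalar grid (MR signal, arbitrary units) with voxel
#' spacing and world origin in millimetres. A `hab_mask` is a binary volume
#' aligned to a `hab_volume` (same shape, spacing and origin) delineating the
#' tumor. Both are thin S3 wrappers around plain arrays so they interoperate
#' with base R and with NIfTI files via \pkg{RNifti}.
#'
#' @param voxels 3D numeric array of intensities (or 0/1 for masks).
#' @param spacing Numeric length-3, voxel size in mm along each axis.
#' @param origin Numeric length-3, world coordinate of voxel (1,1,1) in mm.
#' @return An object of class `hab_volume` or `hab_mask`.
#' @examples
#' v <- hab_volume(array(rnorm(8^3), dim = c(8, 8, 8)))
#' dim(v)
#' @export
hab_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- unclass(voxels)
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  if (any(dim(voxels) < 8)) {
    stop("volume shape must be at least 8 x 8 x 8", call. = FALSE)
  }
  if (!all(is.finite(voxels))) stop("volume intensities must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive finite values (mm)", call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
    class = "hab_volume"
  )
}

#' @rdname hab_volume
#' @export
hab_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- unclass(voxels)
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  vox <- array(as.integer(voxels != 0), dim = dim(voxels))
  n_fg <- sum(vox)
  if (n_fg < 64) stop("mask must contain at least 64 foreground voxels", call. = FALSE)
  structure(
    list(voxels = vox, spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "hab_mask"
  )
}

#' @export
dim.hab_volume <- function(x) dim(x$voxels)
#' @export
dim.hab_mask <- function(x) dim(x$voxels)

#' @export
print.hab_volume <- function(x, ...) {
  cat(sprintf(
    "<hab_volume %s, spacing %s mm, range [%.3g, %.3g]>\n",
    paste(dim(x$voxels), collapse = "x"),
    paste(format(x$spacing, digits = 3), collapse = "x"),
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' @export
print.hab_mask <- function(x, ...) {
  cat(sprintf(
    "<hab_mask %s, spacing %s mm, %d foreground voxels>\n",
    paste(dim(x$voxels), collapse = "x"),
    paste(format(x$spacing, digits = 3), collapse = "x"),
    sum(x$voxels)
  ))
  invisible(x)
}

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask$voxels))) {
    stop("mask shape does not match volume shape", call. = FALSE)
  }
  if (max(abs(volume$spacing - mask$spacing)) > 1e-8) {
    stop("mask spacing does not match volume spacing", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write volumes as NIfTI
#'
#' Round-trips `hab_volume`/`hab_mask` objects through `.nii`/`.nii.gz` files
#' using \pkg{RNifti}. Spacing is stored in the NIfTI pixdim field.
#'
#' @param x A `hab_volume` or `hab_mask`.
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @export
write_volume_nifti <- function(x, path) {
  img <- RNifti::asNifti(x$voxels, pixdim = x$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param mask Logical; read as a binary `hab_mask` instead of a `hab_volume`.
#' @export
read_volume_nifti <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  spc <- RNifti::pixdim(img)[seq_len(3)]
  arr <- array(as.numeric(img), dim = dim(img)[seq_len(3)])
  if (mask) hab_mask(arr, spacing = spc) else hab_volume(arr, spacing = spc)
}

# 26-connected component labels of a logical 3D array, as an integer array
# (0 = background). Union-find over the 13 forward neighbour offsets.
connected_components_26 <- function(fg) {
  dims <- dim(fg)
  idx <- which(fg)
  if (length(idx) == 0L) return(array(0L, dims))
  pos <- arrayInd(idx, dims)
  vox_id <- array(0L, dims)
  vox_id[idx] <- seq_along(idx)
  offsets <- offset_table_13()
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in seq_len(nrow(offsets))) {
    np <- sweep(pos, 2, offsets[o, ], "+")
    ok <- np[, 1] >= 1 & np[, 1] <= dims[1] &
      np[, 2] >= 1 & np[, 2] <= dims[2] &
      np[, 3] >= 1 & np[, 3] <= dims[3]
    if (!any(ok)) next
    ni <- vox_id[np[ok, , drop = FALSE]]
    a <- which(ok)[ni > 0L]
    b <- ni[ni > 0L]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  labels <- match(roots, unique(roots))
  out <- array(0L, dims)
  out[idx] <- labels
  out
}

# the 13 forward offsets of the 26-neighbourhood (each unordered pair once)
offset_table_13 <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), ]
  keep <- off[, 3] > 0 |
    (off[, 3] == 0 & off[, 2] > 0) |
    (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
  unname(off[keep, , drop = FALSE])
}

is_single_component <- function(fg) {
  max(connected_components_26(fg)) == 1L
}

largest_component <- function(fg) {
  cc <- connected_components_26(fg)
  if (max(cc) <= 1L) return(fg)
  tab <- tabulate(cc[cc > 0L])
  cc == which.max(tab)
}
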