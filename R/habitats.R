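# Habitat delineation: SLIC-style supervoxel over-segmentation inside the
# tumor mask, k-means on supervoxel summary features with Calinski-Harabasz
# cluster-number selection (silhouette reported alongside), and canonical
# enhancement-ordered habitat labels.

# normalized Shannon entropy (0..1) of intensities over fixed-width bins
local_entropy <- function(values, n_bins = 16) {
  if (length(values) < 2 || stats::sd(values) == 0) return(0)
  h <- tabulate(cut(values, breaks = n_bins, labels = FALSE), nbins = n_bins)
  p <- h[h > 0] / sum(h)
  -sum(p * log2(p)) / log2(n_bins)
}

#' SLIC-style supervoxel over-segmentation of a tumor
#'
#' Clusters tumor voxels in joint (intensity, x, y, z) space from seeds laid
#' out on a regular grid inside the mask, iterating localized assignment and
#' centroid updates, then enforces spatial 26-connectivity by reassigning
#' stray fragments to the dominant adjacent supervoxel. Per-supervoxel
#' summary features (mean intensity, intensity SD, local entropy) are
#' attached as the clustering matrix for habitat delineation.
#'
#' @param volume A preprocessed `hab_volume`.
#' @param mask An aligned `hab_mask` (at least 64 voxels).
#' @param n_supervoxels Target supervoxel count.
#' @param compactness Relative weight of spatial vs intensity distance
#'   (larger gives more compact supervoxels).
#' @param n_iter Assignment/update iterations.
#' @param seed Integer seed (seed placement jitter).
#' @return A list of class `hab_supervoxels`: `labels` (3D integer array,
#'   0 outside mask), `features` (tibble: supervoxel, n_voxels, mean, sd,
#'   entropy), and the voxel index of each supervoxel.
#' @export
supervoxel_segment <- function(volume, mask, n_supervoxels = 150,
                               compactness = 0.05, n_iter = 8, seed = NULL) {
  check_aligned(volume, mask)
  fg_idx <- which(mask$voxels > 0)
  n_fg <- length(fg_idx)
  if (n_fg < 64) stop("mask too small for supervoxel segmentation", call. = FALSE)
  if (n_supervoxels < 2) stop("n_supervoxels must be at least 2", call. = FALSE)
  if (n_supervoxels > n_fg / 4) {
    stop("mask too small to yield the requested supervoxel count", call. = FALSE)
  }
  with_local_seed(seed, {
    dims <- dim(mask$voxels)
    coords <- arrayInd(fg_idx, dims) * rep(volume$spacing, each = n_fg)
    intens <- volume$voxels[fg_idx]
    s_int <- stats::sd(intens)
    if (s_int == 0) s_int <- 1
    zi <- (intens - mean(intens)) / s_int
    # seed step so that roughly n_supervoxels seeds fall inside the mask
    step <- (n_fg * prod(volume$spacing) / n_supervoxels)^(1 / 3)
    grid_pos <- lapply(1:3, function(ax) {
      lo <- min(coords[, ax]); hi <- max(coords[, ax])
      seq(lo + step / 2, hi, by = step)
    })
    seeds <- as.matrix(expand.grid(grid_pos[[1]], grid_pos[[2]], grid_pos[[3]]))
    # snap each grid seed to the nearest tumor voxel; drop far-away seeds
    seed_rows <- unique(vapply(seq_len(nrow(seeds)), function(i) {
      d2 <- rowSums(sweep(coords, 2, seeds[i, ], "-")^2)
      j <- which.min(d2)
      if (d2[j] > (step)^2) NA_integer_ else j
    }, integer(1)))
    seed_rows <- seed_rows[!is.na(seed_rows)]
    if (length(seed_rows) < 2) {
      seed_rows <- sample.int(n_fg, max(2, min(n_supervoxels, n_fg)))
    }
    centers_sp <- coords[seed_rows, , drop = FALSE]
    centers_in <- zi[seed_rows]
    m <- nrow(centers_sp)
    w_sp <- compactness / step^2
    assign <- rep(1L, n_fg)
    for (it in seq_len(n_iter)) {
      best <- rep(Inf, n_fg)
      for (c in seq_len(m)) {
        box <- abs(coords[, 1] - centers_sp[c, 1]) <= 2 * step &
          abs(coords[, 2] - centers_sp[c, 2]) <= 2 * step &
          abs(coords[, 3] - centers_sp[c, 3]) <= 2 * step
        if (!any(box)) next
        d <- (zi[box] - centers_in[c])^2 +
          w_sp * rowSums(sweep(coords[box, , drop = FALSE], 2, centers_sp[c, ], "-")^2)
        upd <- d < best[box]
        bi <- which(box)[upd]
        best[bi] <- d[upd]
        assign[bi] <- c
      }
      # any voxel outside all boxes: nearest centre globally
      far <- !is.finite(best)
      if (any(far)) {
        for (i in which(far)) {
          d <- (zi[i] - centers_in)^2 +
            w_sp * rowSums(sweep(centers_sp, 2, coords[i, ], "-")^2)
          assign[i] <- which.min(d)
        }
      }
      for (c in seq_len(m)) {
        sel <- assign == c
        if (any(sel)) {
          centers_sp[c, ] <- colMeans(coords[sel, , drop = FALSE])
          centers_in[c] <- mean(zi[sel])
        }
      }
    }
    labels <- array(0L, dims)
    labels[fg_idx] <- assign
    intens_full <- array(0, dims); intens_full[fg_idx] <- zi
    labels <- enforce_supervoxel_connectivity(labels, fg_idx, dims, intens_full)
    lab_fg <- labels[fg_idx]
    ids <- sort(unique(lab_fg))
    labels[fg_idx] <- match(lab_fg, ids)
    lab_fg <- labels[fg_idx]
    # summary features on mask-standardized intensity, so the clustering
    # space needs no further per-column rescaling (the class-mean axis keeps
    # its natural dominance over the dispersion axes)
    feats <- tibble::tibble(
      supervoxel = seq_along(ids),
      n_voxels = as.integer(tabulate(lab_fg)),
      mean = as.numeric(tapply(zi, lab_fg, mean)),
      sd = as.numeric(tapply(zi, lab_fg, function(v) {
        if (length(v) > 1) stats::sd(v) else 0
      })),
      entropy = as.numeric(tapply(zi, lab_fg, local_entropy)),
      raw_mean = as.numeric(tapply(intens, lab_fg, mean))
    )
    structure(
      list(labels = labels, features = feats, mask_index = fg_idx),
      class = "hab_supervoxels"
    )
  })
}

# split spatially disconnected supervoxels; merge fragments smaller than the
# largest piece into the dominant 26-adjacent neighbour label
enforce_supervoxel_connectivity <- function(labels, fg_idx, dims, intens_ref) {
  offs <- offset_table_13()
  offs <- rbind(offs, -offs)
  for (pass in 1:3) {
    changed <- FALSE
    for (lab in setdiff(unique(labels[fg_idx]), 0L)) {
      fg <- labels == lab
      cc <- connected_components_26(fg)
      ncomp <- max(cc)
      if (ncomp <= 1L) next
      main <- which.max(tabulate(cc[cc > 0L]))
      for (comp in setdiff(seq_len(ncomp), main)) {
        vidx <- which(cc == comp)
        pos <- arrayInd(vidx, dims)
        neigh <- integer(0)
        for (o in seq_len(nrow(offs))) {
          np <- sweep(pos, 2, offs[o, ], "+")
          ok <- np[, 1] >= 1 & np[, 1] <= dims[1] &
            np[, 2] >= 1 & np[, 2] <= dims[2] &
            np[, 3] >= 1 & np[, 3] <= dims[3]
          nl <- labels[np[ok, , drop = FALSE]]
          neigh <- c(neigh, nl[nl > 0L & nl != lab])
        }
        labels[vidx] <- if (length(neigh)) {
          # merge into the adjacent supervoxel with the closest mean signal,
          # so interface fragments do not contaminate a foreign class
          cand <- unique(neigh)
          frag_mean <- mean(intens_ref[vidx])
          cand_means <- vapply(cand, function(l) mean(intens_ref[which(labels == l)]), numeric(1))
          cand[which.min(abs(cand_means - frag_mean))]
        } else {
          lab
        }
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}

# Calinski-Harabasz index: [B/(K-1)] / [W/(N-K)]
calinski_harabasz <- function(x, cluster) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- length(unique(cluster))
  if (k < 2 || n <= k) return(NA_real_)
  gm <- colMeans(x)
  B <- 0
  W <- 0
  for (c in unique(cluster)) {
    xc <- x[cluster == c, , drop = FALSE]
    cm <- colMeans(xc)
    B <- B + nrow(xc) * sum((cm - gm)^2)
    W <- W + sum(sweep(xc, 2, cm, "-")^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# k-means with k-means++ initialisation and multiple restarts
kmeanspp <- function(x, k, n_start = 10, iter_max = 50, tol = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- NULL
  for (s in seq_len(n_start)) {
    centers <- matrix(0, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1), ]
    d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
    for (j in seq_len(k - 1)) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j + 1, ] <- x[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ], "-")^2))
    }
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter_max, algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss - tol) best <- fit
  }
  best
}

#' Select the habitat count by Calinski-Harabasz score
#'
#' Runs k-means (k-means++ initialisation, multiple restarts) on the
#' supervoxel feature matrix for each candidate K, recording the
#' Calinski-Harabasz index and the mean silhouette width; the chosen K
#' maximizes the Calinski-Harabasz score.
#'
#' @param features Numeric matrix or data frame of clustering features (one
#'   row per supervoxel), or a `hab_supervoxels` object.
#' @param candidate_ks Candidate cluster counts (all at least 2).
#' @param n_start k-means restarts per K.
#' @param seed Integer seed.
#' @return A tibble of class `hab_cluster_selection` with columns `k`,
#'   `ch_score`, `silhouette`, and attribute `chosen_k`.
#' @export
select_k <- function(features, candidate_ks = 2:6, n_start = 10, seed = NULL) {
  if (inherits(features, "hab_supervoxels")) {
    features <- features$features[, c("mean", "sd", "entropy")]
  }
  x <- as.matrix(features)
  if (any(candidate_ks < 2)) stop("candidate K values must be at least 2", call. = FALSE)
  n_distinct <- nrow(unique(round(x, 10)))
  if (nrow(x) < max(candidate_ks) + 1) {
    stop("need more feature rows than the largest candidate K", call. = FALSE)
  }
  with_local_seed(seed, {
    rows <- lapply(candidate_ks, function(k) {
      if (k > n_distinct) {
        warning(sprintf("K = %d exceeds distinct rows; skipped", k), call. = FALSE)
        return(tibble::tibble(k = k, ch_score = NA_real_, silhouette = NA_real_))
      }
      fit <- kmeanspp(x, k, n_start = n_start)
      ch <- calinski_harabasz(x, fit$cluster)
      sil <- mean(cluster::silhouette(fit$cluster, stats::dist(x))[, 3])
      tibble::tibble(k = k, ch_score = ch, silhouette = sil)
    })
    out <- dplyr::bind_rows(rows)
    chosen <- out$k[which.max(out$ch_score)]
    structure(out, chosen_k = chosen, class = c("hab_cluster_selection", class(out)))
  })
}

#' @export
print.hab_cluster_selection <- function(x, ...) {
  NextMethod()
  cat(sprintf("chosen K = %d (max Calinski-Harabasz)\n", attr(x, "chosen_k")))
  invisible(x)
}

#' Cluster supervoxels into an enhancement-ordered habitat map
#'
#' Applies k-means to the supervoxel feature matrix, propagates each
#' supervoxel's cluster to its voxels, and relabels clusters canonically by
#' descending mean intensity: label 1 is the most-enhancing habitat
#' (metabolically active core), label K the least (marginal/necrotic rim).
#' Ties in mean intensity are broken by larger volume first.
#'
#' @param supervoxels A `hab_supervoxels` object.
#' @param k Habitat count (at least 2).
#' @param seed Integer seed.
#' @param max_retries Re-initialisations allowed if a cluster comes back
#'   empty.
#' @return A list of class `hab_map`: `labels` (3D integer array, 0 outside
#'   tumor), `k`, and per-habitat mean intensities.
#' @export
cluster_habitats <- function(supervoxels, k = 3, seed = NULL, max_retries = 5) {
  stopifnot(inherits(supervoxels, "hab_supervoxels"))
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  x <- as.matrix(supervoxels$features[, c("mean", "sd", "entropy")])
  with_local_seed(seed, {
    fit <- NULL
    for (try in 0:max_retries) {
      cand <- kmeanspp(x, k)
      if (length(unique(cand$cluster)) == k) {
        fit <- cand
        break
      }
    }
    if (is.null(fit)) stop("k-means produced an empty cluster after retries", call. = FALSE)
    cl <- fit$cluster
    lab_fg <- cl[supervoxels$labels[supervoxels$mask_index]]
    intens_mean <- vapply(seq_len(k), function(c) {
      stats::weighted.mean(
        supervoxels$features$raw_mean[cl == c],
        supervoxels$features$n_voxels[cl == c]
      )
    }, numeric(1))
    sizes <- vapply(seq_len(k), function(c) {
      sum(supervoxels$features$n_voxels[cl == c])
    }, numeric(1))
    ord <- order(-intens_mean, -sizes)
    relab <- match(seq_len(k), ord)
    labels <- array(0L, dim(supervoxels$labels))
    labels[supervoxels$mask_index] <- relab[lab_fg]
    structure(
      list(
        labels = labels, k = k,
        habitat_means = intens_mean[ord],
        habitat_sizes = as.integer(sizes[ord])
      ),
      class = "hab_map"
    )
  })
}

#' @export
print.hab_map <- function(x, ...) {
  cat(sprintf(
    "<hab_map K = %d, habitat sizes: %s voxels>\n",
    x$k, paste(x$habitat_sizes, collapse = ", ")
  ))
  invisible(x)
}

#' Per-habitat volume fractions
#'
#' @param map A `hab_map`.
#' @return Tibble with `habitat` and `fraction` (summing to 1).
#' @export
habitat_composition <- function(map) {
  stopifnot(inherits(map, "hab_map"))
  counts <- tabulate(map$labels[map$labels > 0], nbins = map$k)
  tibble::tibble(habitat = seq_len(map$k), fraction = counts / sum(counts))
}

#' Delineate habitats for one volume/mask pair
#'
#' Convenience wrapper chaining [supervoxel_segment()] and
#' [cluster_habitats()], with a voxel-level fallback (clustering voxels
#' directly on intensity) for masks too small to over-segment. The habitat
#' count is normally held fixed cohort-wide (K = 3); `k = "auto"` instead
#' selects K per tumor by Calinski-Harabasz over `candidate_ks`, for
#' experimentation.
#'
#' @inheritParams supervoxel_segment
#' @param k Habitat count, or `"auto"`.
#' @param candidate_ks Candidate counts for `k = "auto"`.
#' @return A `hab_map`.
#' @export
delineate_habitats <- function(volume, mask, k = 3, n_supervoxels = 150,
                               compactness = 0.05, candidate_ks = 2:6,
                               seed = NULL) {
  n_fg <- sum(mask$voxels)
  if (n_fg < 200 || n_supervoxels > n_fg / 4) {
    if (identical(k, "auto")) k <- 3
    return(voxel_habitats(volume, mask, k, seed))
  }
  sv <- supervoxel_segment(volume, mask,
    n_supervoxels = n_supervoxels,
    compactness = compactness, seed = seed
  )
  if (identical(k, "auto")) {
    k <- attr(select_k(sv, candidate_ks = candidate_ks, seed = seed), "chosen_k")
  }
  cluster_habitats(sv, k = k, seed = seed)
}

# fallback for small masks: k-means on voxel intensities directly
voxel_habitats <- function(volume, mask, k, seed = NULL) {
  fg_idx <- which(mask$voxels > 0)
  x <- matrix(scale(volume$voxels[fg_idx]), ncol = 1)
  with_local_seed(seed, {
    fit <- kmeanspp(x, k)
    means <- tapply(volume$voxels[fg_idx], fit$cluster, mean)
    sizes <- tabulate(fit$cluster, nbins = k)
    ord <- order(-means, -sizes)
    relab <- match(seq_len(k), ord)
    labels <- array(0L, dim(mask$voxels))
    labels[fg_idx] <- relab[fit$cluster]
    structure(
      list(
        labels = labels, k = k,
        habitat_means = as.numeric(means[ord]),
        habitat_sizes = as.integer(sizes[ord])
      ),
      class = "hab_map"
    )
  })
}

#' Write a habitat map as an integer NIfTI labelmap
#'
#' @param map A `hab_map`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param spacing Voxel spacing of the map grid (mm).
#' @export
write_habitat_nifti <- function(map, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(map, "hab_map"))
  img <- RNifti::asNifti(map$labels + 0L, pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
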