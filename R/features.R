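# Region- and patient-level feature extraction with the published-count
# accounting: 1223 features per region (14 shape + 93 x 13 channels),
# 3669 per habitat timepoint (3 habitats), 9784 per patient
# (2 timepoints x (whole-tumor 1223 + habitats 3669)).

texture_family_fun <- list(
  glcm = function(gbox, ng) glcm_features(gbox, ng),
  glrlm = function(gbox, ng) glrlm_features(gbox, ng),
  glszm = function(gbox, ng) glszm_features(gbox, ng),
  gldm = function(gbox, ng) gldm_features(gbox, ng),
  ngtdm = function(gbox, ng) ngtdm_features(gbox, ng)
)

region_feature_names <- function(config = feature_panel()) {
  nm <- character(0)
  if ("shape" %in% config$families) {
    nm <- c(nm, names(shape_features(array(TRUE, c(4, 4, 4)), c(1, 1, 1))))
  }
  channels <- "original"
  if ("wavelet" %in% config$transforms) {
    combos <- as.vector(vapply(
      c("L", "H"),
      function(f1) vapply(c("L", "H"), function(f2) paste0(f1, f2, c("L", "H")), character(2)),
      matrix(character(1), 2, 2)
    ))
    channels <- c(channels, paste0("wavelet_", combos))
  }
  if ("log" %in% config$transforms) {
    channels <- c(channels, sprintf("log_sigma_%g_mm", config$log_sigmas_mm))
  }
  fam_names <- list(
    firstorder = paste0("firstorder_", c(
      "energy", "total_energy", "entropy", "minimum", "p10", "p90", "maximum",
      "mean", "median", "iqr", "range", "mad", "rmad", "rms", "skewness",
      "kurtosis", "variance", "uniformity"
    )),
    glcm = names(glcm_features_dir(matrix(c(0.5, 0, 0, 0.5), 2))),
    glrlm = paste0("glrlm_", glrlm_names),
    glszm = paste0("glszm_", glszm_names),
    gldm = paste0("gldm_", c(
      "sde", "lde", "gln", "dn", "dnn", "glv", "dv", "de",
      "lgle", "hgle", "sdlgle", "sdhgle", "ldlgle", "ldhgle"
    )),
    ngtdm = paste0("ngtdm_", c("coarseness", "contrast", "busyness", "complexity", "strength"))
  )
  for (ch in channels) {
    for (fam in setdiff(config$families, "shape")) {
      nm <- c(nm, paste(ch, fam_names[[fam]], sep = "_"))
    }
  }
  nm
}

#' Extract the feature panel from one region
#'
#' Computes the configured shape, first-order and texture families from a
#' region of a channel set produced by [apply_transforms()]. Texture/grey
#' level features are computed on fixed-bin-width discretized intensities in
#' the region bounding box; shape features once from the region geometry.
#' Regions below 8 voxels return an all-`NA` vector flagged via the
#' `degenerate` attribute rather than being dropped silently.
#'
#' @param channels Named list of aligned 3D channel arrays
#'   (from [apply_transforms()]).
#' @param region_mask Logical/integer 3D array delimiting the region.
#' @param spacing Voxel spacing (mm).
#' @param config A [feature_panel()].
#' @return Named numeric vector (length [n_features_per_region()]), with
#'   attribute `degenerate = TRUE` when the region was too small.
#' @export
extract_region_features <- function(channels, region_mask, spacing = c(1, 1, 1),
                                    config = feature_panel()) {
  region_mask <- region_mask > 0
  nm <- region_feature_names(config)
  if (sum(region_mask) < 8) {
    out <- stats::setNames(rep(NA_real_, length(nm)), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  vals <- numeric(0)
  if ("shape" %in% config$families) {
    vals <- c(vals, shape_features(region_mask, spacing))
  }
  voxvol <- prod(spacing)
  tex_fams <- setdiff(config$families, "shape")
  for (ch in names(channels)) {
    box <- region_box(channels[[ch]], region_mask)
    values <- box[!is.na(box)]
    if ("firstorder" %in% tex_fams) {
      v <- firstorder_features(values, voxvol, config$bin_width, config$max_bins)
      names(v) <- paste(ch, names(v), sep = "_")
      vals <- c(vals, v)
    }
    gl_fams <- setdiff(tex_fams, "firstorder")
    if (length(gl_fams)) {
      dsc <- discretize_fbw(values, config$bin_width, config$max_bins)
      gbox <- box
      gbox[!is.na(box)] <- dsc$levels
      for (fam in gl_fams) {
        v <- texture_family_fun[[fam]](gbox, dsc$n_levels)
        names(v) <- paste(ch, names(v), sep = "_")
        vals <- c(vals, v)
      }
    }
  }
  vals <- vals[nm]
  names(vals) <- nm
  attr(vals, "degenerate") <- FALSE
  vals
}

#' Extract the full longitudinal feature row for one patient
#'
#' Concatenates the whole-tumor (TR) panel and the per-habitat (SHR) panels
#' at both timepoints: `2 x (1223 + 3 x 1223) = 9784` named values under the
#' default panel. Feature names carry their provenance as
#' `{timepoint}_{region}_{channel}_{family}_{feature}` with region `TR` or
#' `H1`/`H2`/`H3` (habitats in descending enhancement order). An empty or
#' tiny habitat yields flagged `NA` features; the row is retained.
#'
#' @param pre,mid Lists with elements `volume` (`hab_volume`), `mask`
#'   (`hab_mask`) and `habitats` (`hab_map`, K = 3) for each timepoint.
#' @param config A [feature_panel()].
#' @return A named numeric vector (one [feature_table()] row).
#' @export
extract_patient_features <- function(pre, mid, config = feature_panel()) {
  out <- numeric(0)
  for (tp in c("pre", "mid")) {
    tpdata <- if (tp == "pre") pre else mid
    stopifnot(!is.null(tpdata$volume), !is.null(tpdata$mask), !is.null(tpdata$habitats))
    channels <- apply_transforms(tpdata$volume, config)
    regions <- c(
      list(TR = tpdata$mask$voxels > 0),
      stats::setNames(
        lapply(seq_len(tpdata$habitats$k), function(h) tpdata$habitats$labels == h),
        paste0("H", seq_len(tpdata$habitats$k))
      )
    )
    for (rg in names(regions)) {
      v <- extract_region_features(channels, regions[[rg]],
        spacing = tpdata$volume$spacing, config = config
      )
      names(v) <- paste(tp, rg, names(v), sep = "_")
      out <- c(out, v)
    }
  }
  out
}

#' Build a patients-by-features table for a cohort
#'
#' Runs habitat delineation and [extract_patient_features()] for every
#' patient of a synthetic cohort (or any list with the same structure) and
#' binds the rows into a tibble keyed by `patient_id`.
#'
#' Volumes are histogram-standardized before habitat delineation and
#' extraction (the preprocessing contract): landmark percentiles are
#' computed inside each tumor mask, the cohort-mean landmark vector serves
#' as the reference, and each volume is mapped onto it. Standardization can
#' be disabled, or an externally frozen reference supplied.
#'
#' @param imaging Named per-patient list with `pre` and `mid`
#'   volume/mask pairs (as returned by [generate_cohort()]).
#' @param k Habitat count (held fixed across timepoints and patients).
#' @param config A [feature_panel()].
#' @param n_supervoxels,compactness Supervoxel settings.
#' @param standardize Apply histogram landmark standardization.
#' @param reference_landmarks Optional frozen reference landmark vector; the
#'   cohort mean is used when `NULL`.
#' @param preprocess A [preprocess_config()] (landmark percentiles).
#' @param seed Integer seed for habitat delineation.
#' @return A tibble: `patient_id` plus one column per feature.
#' @export
feature_table <- function(imaging, k = 3, config = feature_panel(),
                          n_supervoxels = 150, compactness = 0.05,
                          standardize = TRUE, reference_landmarks = NULL,
                          preprocess = preprocess_config(), seed = 1) {
  if (standardize) {
    if (is.null(reference_landmarks)) {
      lms <- lapply(imaging, function(pt) {
        rbind(
          histogram_landmarks(pt$pre$volume, pt$pre$mask, preprocess),
          histogram_landmarks(pt$mid$volume, pt$mid$mask, preprocess)
        )
      })
      reference_landmarks <- colMeans(do.call(rbind, lms))
      # enforce strict monotonicity for degenerate cohorts
      reference_landmarks <- cummax(reference_landmarks +
        seq_along(reference_landmarks) * 1e-9)
    }
    imaging <- lapply(imaging, function(pt) {
      pt$pre$volume <- standardize_histogram(
        pt$pre$volume, pt$pre$mask, reference_landmarks, preprocess
      )
      pt$mid$volume <- standardize_histogram(
        pt$mid$volume, pt$mid$mask, reference_landmarks, preprocess
      )
      pt
    })
  }
  rows <- purrr::imap(imaging, function(pt, id) {
    hpre <- delineate_habitats(pt$pre$volume, pt$pre$mask,
      k = k,
      n_supervoxels = n_supervoxels, compactness = compactness, seed = seed
    )
    hmid <- delineate_habitats(pt$mid$volume, pt$mid$mask,
      k = k,
      n_supervoxels = n_supervoxels, compactness = compactness, seed = seed
    )
    v <- extract_patient_features(
      pre = list(volume = pt$pre$volume, mask = pt$pre$mask, habitats = hpre),
      mid = list(volume = pt$mid$volume, mask = pt$mid$mask, habitats = hmid),
      config = config
    )
    tibble::as_tibble_row(c(list(patient_id = id), as.list(v)))
  })
  dplyr::bind_rows(rows)
}

#' Feature-name provenance manifest
#'
#' Splits provenance-tagged feature names into timepoint, region, channel,
#' family and feature components.
#'
#' @param feature_names Character vector of names produced by
#'   [extract_patient_features()].
#' @return A tibble with one row per feature.
#' @export
feature_manifest <- function(feature_names) {
  m <- regmatches(
    feature_names,
    regexec("^(pre|mid)_(TR|H[0-9]+)_(.*)$", feature_names)
  )
  fams <- paste(names(panel_family_sizes), collapse = "|")
  tibble::tibble(
    feature = feature_names,
    timepoint = vapply(m, function(x) x[2], character(1)),
    region = vapply(m, function(x) x[3], character(1)),
    rest = vapply(m, function(x) x[4], character(1))
  ) |>
    dplyr::mutate(
      family = sub(sprintf("^.*?(%s)_.*$", fams), "\\1", .data$rest),
      channel = dplyr::if_else(
        .data$family == "shape", "none",
        sub(sprintf("^(.*?)_(%s)_.*$", fams), "\\1", .data$rest)
      ),
      name = sub(sprintf("^.*(%s)_", fams), "\\1_", .data$rest),
      rest = NULL
    )
}
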