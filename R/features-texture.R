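# Grey-level texture families: GLCM (24), GLRLM (16), GLSZM (16), GLDM (14)
# and NGTDM (5). All operate on fixed-bin-width discretized grey levels in a
# region bounding box (NA outside the region); 3D aggregation with the 13
# unique voxel directions, distance 1; GLCM/GLRLM features are averaged over
# directions, GLSZM/GLDM/NGTDM use a single 26-neighbourhood matrix.

# ---- GLCM -----------------------------------------------------------------

# symmetric normalized co-occurrence matrix for one direction
glcm_matrix_dir <- function(gbox, ng, offset) {
  d <- dim(gbox)
  src <- list(
    seq_len(d[1] - abs(offset[1])), seq_len(d[2] - abs(offset[2])),
    seq_len(d[3] - abs(offset[3]))
  )
  for (ax in 1:3) if (offset[ax] < 0) src[[ax]] <- src[[ax]] + abs(offset[ax])
  dst <- lapply(1:3, function(ax) src[[ax]] + offset[ax])
  a <- gbox[src[[1]], src[[2]], src[[3]], drop = FALSE]
  b <- gbox[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  i <- a[ok]; j <- b[ok]
  P <- matrix(tabulate((j - 1) * ng + i, nbins = ng * ng), ng, ng)
  P <- P + t(P)
  P / sum(P)
}

glcm_features_dir <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(i * P)
  sigma2 <- sum((i - mu)^2 * P)
  sigma <- sqrt(sigma2)
  k_diff <- 0:(ng - 1)
  p_dif <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  nz <- P > 0
  H <- -sum(P[nz] * log2(P[nz]))
  pxpy <- outer(px, px)
  hxy1 <- -sum(P[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  da <- sum(k_diff * p_dif)
  # maximal correlation coefficient: sqrt of second-largest eigenvalue of Q
  mcc <- tryCatch({
    if (ng < 2) 1 else {
      pxs <- ifelse(px > 0, px, 1)
      Q <- (P / pxs) %*% t(P / pxs) # Q[i,j] = sum_k p(i,k) p(j,k) / (px(i) px(k))
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, min(1, ev[2])))
    }
  }, error = function(e) NA_real_)
  c(
    glcm_autocorrelation = sum(i * j * P),
    glcm_joint_average = mu,
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * P),
    glcm_cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = guard_div(sum(i * j * P) - mu^2, sigma2),
    glcm_difference_average = da,
    glcm_difference_entropy = -sum(p_dif[p_dif > 0] * log2(p_dif[p_dif > 0])),
    glcm_difference_variance = sum((k_diff - da)^2 * p_dif),
    glcm_joint_energy = sum(P^2),
    glcm_joint_entropy = H,
    glcm_imc1 = guard_div(H - hxy1, hx), # hx == hy by symmetry
    glcm_imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - H)))),
    glcm_idm = sum(P / (1 + (i - j)^2)),
    glcm_idmn = sum(P / (1 + ((i - j) / ng)^2)),
    glcm_id = sum(P / (1 + abs(i - j))),
    glcm_idn = sum(P / (1 + abs(i - j) / ng)),
    glcm_inverse_variance = sum(P[i != j] / (i - j)[i != j]^2),
    glcm_maximum_probability = max(P),
    glcm_sum_average = sum(k_sum * p_sum),
    glcm_sum_entropy = -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0])),
    glcm_sum_squares = sigma2,
    glcm_mcc = mcc
  )
}

glcm_features <- function(gbox, ng) {
  offs <- offset_table_13()
  vals <- lapply(seq_len(nrow(offs)), function(o) {
    P <- glcm_matrix_dir(gbox, ng, offs[o, ])
    if (is.null(P)) NULL else glcm_features_dir(P)
  })
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (!length(vals)) {
    return(stats::setNames(
      rep(0, panel_family_sizes[["glcm"]]),
      names(glcm_features_dir(matrix(1)))
    ))
  }
  colMeans(do.call(rbind, vals))
}

# ---- GLRLM ----------------------------------------------------------------

# run-length matrix for one direction: rows grey level, cols run length
glrlm_matrix_dir <- function(gbox, ng, offset) {
  d <- dim(gbox)
  idx <- which(!is.na(gbox))
  if (!length(idx)) return(NULL)
  pos <- arrayInd(idx, d)
  g <- gbox[idx]
  step2 <- sum(offset^2)
  t_step <- as.integer(floor((pos %*% offset) / step2))
  anchor <- pos - t_step %*% t(offset)
  key <- anchor %*% c(1, 4096, 4096^2)
  ord <- order(key, t_step)
  key_o <- key[ord]; t_o <- t_step[ord]; g_o <- g[ord]
  n <- length(ord)
  brk <- c(TRUE, key_o[-1] != key_o[-n] | t_o[-1] != t_o[-n] + 1L | g_o[-1] != g_o[-n])
  run_id <- cumsum(brk)
  run_len <- tabulate(run_id)
  run_gl <- g_o[brk]
  max_len <- max(run_len)
  R <- matrix(0, ng, max_len)
  counts <- table(factor(run_gl, levels = seq_len(ng)), factor(run_len, levels = seq_len(max_len)))
  R[] <- as.numeric(counts)
  R
}

rlm_style_features <- function(M, n_voxels, prefix, names_map) {
  # shared feature algebra for run-length and zone-size matrices:
  # rows = grey level i, cols = size/length l
  nr <- sum(M)
  if (nr == 0) M <- matrix(1, 1, 1)
  nr <- sum(M)
  i <- row(M); l <- col(M)
  p <- M / nr
  r_i <- rowSums(M)
  r_l <- colSums(M)
  mu_i <- sum(i * p)
  mu_l <- sum(l * p)
  vals <- c(
    sum(r_l / (seq_along(r_l))^2) / nr,                 # short emphasis
    sum(r_l * (seq_along(r_l))^2) / nr,                 # long emphasis
    sum(r_i^2) / nr,                                    # grey-level non-uniformity
    sum(r_i^2) / nr^2,                                  # ... normalized
    sum(r_l^2) / nr,                                    # length non-uniformity
    sum(r_l^2) / nr^2,                                  # ... normalized
    nr / n_voxels,                                      # percentage
    sum((i - mu_i)^2 * p),                              # grey-level variance
    sum((l - mu_l)^2 * p),                              # length variance
    -sum(p[p > 0] * log2(p[p > 0])),                    # entropy
    sum(r_i / (seq_along(r_i))^2) / nr,                 # low grey-level emphasis
    sum(r_i * (seq_along(r_i))^2) / nr,                 # high grey-level emphasis
    sum(M / (i^2 * l^2)) / nr,                          # short + low
    sum(M * i^2 / l^2) / nr,                            # short + high
    sum(M * l^2 / i^2) / nr,                            # long + low
    sum(M * i^2 * l^2) / nr                             # long + high
  )
  stats::setNames(vals, paste0(prefix, names_map))
}

glrlm_names <- c(
  "sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv", "rv", "re",
  "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle"
)

glrlm_features <- function(gbox, ng) {
  n_vox <- sum(!is.na(gbox))
  offs <- offset_table_13()
  vals <- lapply(seq_len(nrow(offs)), function(o) {
    R <- glrlm_matrix_dir(gbox, ng, offs[o, ])
    if (is.null(R)) NULL else {
      rlm_style_features(R, n_vox, "glrlm_", names_map = glrlm_names)
    }
  })
  vals <- vals[!vapply(vals, is.null, logical(1))]
  colMeans(do.call(rbind, vals))
}

# ---- GLSZM ----------------------------------------------------------------

glszm_names <- c(
  "sae", "lae", "gln", "glnn", "szn", "sznn", "zp", "glv", "zv", "ze",
  "lglze", "hglze", "salgle", "sahgle", "lalgle", "lahgle"
)

# zone-size matrix: 26-connected zones of equal grey level
glszm_matrix <- function(gbox, ng) {
  d <- dim(gbox)
  idx <- which(!is.na(gbox))
  g <- gbox[idx]
  vox_id <- array(0L, d)
  vox_id[idx] <- seq_along(idx)
  pos <- arrayInd(idx, d)
  offs <- offset_table_13()
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in seq_len(nrow(offs))) {
    np <- sweep(pos, 2, offs[o, ], "+")
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] &
      np[, 2] >= 1 & np[, 2] <= d[2] &
      np[, 3] >= 1 & np[, 3] <= d[3]
    ni <- rep(0L, length(idx))
    ni[ok] <- vox_id[np[ok, , drop = FALSE]]
    same <- which(ni > 0L)
    same <- same[g[same] == g[ni[same]]]
    for (k in same) {
      ra <- find(k); rb <- find(ni[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  zone_id <- match(roots, unique(roots))
  zone_size <- tabulate(zone_id)
  zone_gl <- g[match(seq_len(max(zone_id)), zone_id)]
  S <- matrix(0, ng, max(zone_size))
  tab <- table(
    factor(zone_gl, levels = seq_len(ng)),
    factor(zone_size, levels = seq_len(max(zone_size)))
  )
  S[] <- as.numeric(tab)
  S
}

glszm_features <- function(gbox, ng) {
  n_vox <- sum(!is.na(gbox))
  S <- glszm_matrix(gbox, ng)
  rlm_style_features(S, n_vox, "glszm_", names_map = glszm_names)
}

# ---- GLDM -----------------------------------------------------------------

gldm_features <- function(gbox, ng, alpha = 0) {
  idx <- which(!is.na(gbox))
  g <- gbox[idx]
  nb <- neighbour_matrix(gbox)
  dep <- 1L + rowSums(abs(nb - g) <= alpha, na.rm = TRUE)
  nd <- max(dep)
  D <- matrix(0, ng, nd)
  tab <- table(factor(g, levels = seq_len(ng)), factor(dep, levels = seq_len(nd)))
  D[] <- as.numeric(tab)
  nz <- sum(D)
  i <- row(D); j <- col(D)
  p <- D / nz
  d_i <- rowSums(D)
  d_j <- colSums(D)
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  c(
    gldm_sde = sum(d_j / seq_along(d_j)^2) / nz,
    gldm_lde = sum(d_j * seq_along(d_j)^2) / nz,
    gldm_gln = sum(d_i^2) / nz,
    gldm_dn = sum(d_j^2) / nz,
    gldm_dnn = sum(d_j^2) / nz^2,
    gldm_glv = sum((i - mu_i)^2 * p),
    gldm_dv = sum((j - mu_j)^2 * p),
    gldm_de = -sum(p[p > 0] * log2(p[p > 0])),
    gldm_lgle = sum(d_i / seq_along(d_i)^2) / nz,
    gldm_hgle = sum(d_i * seq_along(d_i)^2) / nz,
    gldm_sdlgle = sum(D / (i^2 * j^2)) / nz,
    gldm_sdhgle = sum(D * i^2 / j^2) / nz,
    gldm_ldlgle = sum(D * j^2 / i^2) / nz,
    gldm_ldhgle = sum(D * i^2 * j^2) / nz
  )
}

# ---- NGTDM ----------------------------------------------------------------

ngtdm_features <- function(gbox, ng) {
  idx <- which(!is.na(gbox))
  g <- gbox[idx]
  nb <- neighbour_matrix(gbox)
  n_nb <- rowSums(!is.na(nb))
  a_bar <- rowMeans(nb, na.rm = TRUE)
  valid <- n_nb > 0
  n_i <- tabulate(g[valid], nbins = ng)
  s_i <- vapply(seq_len(ng), function(i) {
    sel <- valid & g == i
    if (any(sel)) sum(abs(i - a_bar[sel])) else 0
  }, numeric(1))
  nvp <- sum(n_i)
  p_i <- n_i / nvp
  present <- which(p_i > 0)
  ngp <- length(present)
  coarseness <- guard_div(1, sum(p_i * s_i))
  if (is.finite(coarseness) && sum(p_i * s_i) == 0) coarseness <- 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p_i[present], p_i[present]) *
      outer(present, present, "-")^2) / (ngp * (ngp - 1))) * (sum(s_i) / nvp)
  } else {
    0
  }
  busyness <- guard_div(
    sum(p_i * s_i),
    sum(abs(outer(present * p_i[present], present * p_i[present], "-")))
  )
  complexity <- sum(vapply(present, function(i) {
    sum(abs(i - present) * (p_i[i] * s_i[i] + p_i[present] * s_i[present]) /
      (p_i[i] + p_i[present]))
  }, numeric(1))) / nvp
  strength <- guard_div(
    sum(vapply(present, function(i) {
      sum((p_i[i] + p_i[present]) * (i - present)^2)
    }, numeric(1))),
    sum(s_i)
  )
  c(
    ngtdm_coarseness = coarseness,
    ngtdm_contrast = contrast,
    ngtdm_busyness = busyness,
    ngtdm_complexity = complexity,
    ngtdm_strength = strength
  )
}
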