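# First-order intensity statistics (18 features), IBSI-style definitions
# with population moments and histogram entropy/uniformity on the
# fixed-bin-width discretized intensities.

firstorder_features <- function(values, voxel_volume, bin_width, max_bins = 64L) {
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  d <- discretize_fbw(values, bin_width, max_bins)
  p <- tabulate(d$levels, nbins = d$n_levels) / n
  p_nz <- p[p > 0]
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  trimmed <- values[values >= q[1] & values <= q[5]]
  c(
    firstorder_energy = sum(values^2),
    firstorder_total_energy = voxel_volume * sum(values^2),
    firstorder_entropy = -sum(p_nz * log2(p_nz)),
    firstorder_minimum = min(values),
    firstorder_p10 = q[1],
    firstorder_p90 = q[5],
    firstorder_maximum = max(values),
    firstorder_mean = mu,
    firstorder_median = q[3],
    firstorder_iqr = q[4] - q[2],
    firstorder_range = max(values) - min(values),
    firstorder_mad = mean(abs(values - mu)),
    firstorder_rmad = if (length(trimmed)) mean(abs(trimmed - mean(trimmed))) else 0,
    firstorder_rms = sqrt(mean(values^2)),
    firstorder_skewness = guard_div(m3, m2^1.5),
    firstorder_kurtosis = guard_div(m4, m2^2),
    firstorder_variance = m2,
    firstorder_uniformity = sum(p_nz^2)
  )
}
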