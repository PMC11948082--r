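# shared fixtures, built once per test run

sphere_mask_array <- function(dims, radius, center = (dims + 1) / 2) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3]))
  r <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2)
  array(r <= radius, dims)
}

# cached standard phantom (several tests reuse it)
.fixtures <- new.env()
std_phantom <- function() {
  if (is.null(.fixtures$ph)) .fixtures$ph <- generate_phantom_pair(seed = 101)
  .fixtures$ph
}

# brute-force pairwise-concordance AUC oracle
auc_bruteforce <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# ANOVA mean-squares ICC(2,1) oracle via aov()
icc_aov_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  fit <- stats::aov(y ~ subject + rater, data = df)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
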