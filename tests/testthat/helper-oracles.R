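# Independent textbook-formula oracles used to cross-check the package's
# statistical wrappers. These are deliberately written from first
# principles (never by calling the code paths they verify).

oracle_one_sample_t <- function(x, mu = 0) {
  n <- length(x)
  t <- (mean(x) - mu) / (sd(x) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

oracle_paired_t <- function(x, y) oracle_one_sample_t(x - y, 0)

oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), df = nx + ny - 2))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

# Brute-force PCA: eigen-decomposition of the covariance matrix.
oracle_pca <- function(m, k = 2) {
  mc <- scale(m, center = TRUE, scale = FALSE)
  eg <- eigen(cov(mc), symmetric = TRUE)
  list(loadings = eg$vectors[, seq_len(k), drop = FALSE],
       scores = mc %*% eg$vectors[, seq_len(k), drop = FALSE],
       explained_variance = eg$values[seq_len(k)] / sum(eg$values))
}

# Align the column signs of `got` to `want` before comparing (principal
# axes are defined up to sign).
align_signs <- function(got, want) {
  for (j in seq_len(ncol(got))) {
    if (sum(got[, j] * want[, j]) < 0) got[, j] <- -got[, j]
  }
  got
}

# Reference sRGB -> CIELAB values (D65) computed with an independent
# color-science implementation; frozen to 4 decimals.
lab_reference <- data.frame(
  r = c(70, 255, 0, 245, 128),
  g = c(80, 255, 0, 245, 0),
  b = c(160, 255, 0, 245, 255),
  L = c(37.0714, 100.0000, 0.0000, 96.5375, 40.9087),
  a = c(20.2313, -0.0025, 0.0000, -0.0024, 83.1665),
  b_lab = c(-44.8171, 0.0047, 0.0000, 0.0045, -93.2866)
)

# Small, fast synthetic configuration for image-heavy tests.
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, image_size = 96L, well_radius = 44,
         colony_count_range = c(10L, 25L),
         colony_radius_meanlog = log(4)),
    list(...))
  do.call(synthetic_config, args)
}
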