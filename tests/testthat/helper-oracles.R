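# Brute-force oracles, written independently of the package internals:
# explicit scalar loops over the defining formulas. Deliberately slow.

oracle_double_center <- function(d) {
  d <- as.matrix(unclass(d))
  n <- nrow(d)
  a <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      a[j, k] <- d[j, k] - mean(d[j, ]) - mean(d[, k]) + mean(d)
    }
  }
  a
}

oracle_u_center <- function(d) {
  d <- as.matrix(unclass(d))
  n <- nrow(d)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a[i, j] <- d[i, j] - sum(d[i, ]) / (n - 2) - sum(d[, j]) / (n - 2) +
        sum(d) / ((n - 1) * (n - 2))
    }
  }
  a
}

oracle_u_inner <- function(a, b) {
  n <- nrow(a)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) total <- total + a[i, j] * b[i, j]
  total / (n * (n - 3))
}

oracle_dcor <- function(dx, dy) {
  a <- oracle_double_center(dx)
  b <- oracle_double_center(dy)
  vxy <- sqrt(max(mean(a * b), 0))
  den <- sqrt(sqrt(max(mean(a * a), 0)) * sqrt(max(mean(b * b), 0)))
  if (den <= 1e-12) 0 else vxy / den
}

oracle_bcdcor <- function(dx, dy) {
  a <- oracle_u_center(dx)
  b <- oracle_u_center(dy)
  den <- sqrt(oracle_u_inner(a, a) * oracle_u_inner(b, b))
  if (!is.finite(den) || den <= 1e-12) 0 else oracle_u_inner(a, b) / den
}

oracle_pdcor <- function(dx, dy, dz) {
  rxy <- oracle_bcdcor(dx, dy)
  rxz <- oracle_bcdcor(dx, dz)
  ryz <- oracle_bcdcor(dy, dz)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (!is.finite(den) || den <= 1e-12) 0 else (rxy - rxz * ryz) / den
}

# Residual-regression construction of the partial correlation.
oracle_partial_residuals <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# Random Euclidean distance matrix on n points in p dimensions.
random_euclidean_dm <- function(n, p = 2) {
  dist_euclidean(matrix(stats::rnorm(n * p), n, p))
}

# Random symmetric nonnegative zero-diagonal matrix (not necessarily
# Euclidean-embeddable).
random_dissimilarity_dm <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dist_matrix(m)
}

# Random sparse-ish abundance table with no all-zero sample.
random_abundance <- function(n, p, max_count = 50) {
  repeat {
    counts <- matrix(stats::rpois(n * p, lambda = 2) *
                       stats::rbinom(n * p, 1, 0.6), n, p)
    if (all(rowSums(counts) > 0)) break
  }
  dimnames(counts) <- list(paste0("s", seq_len(n)), paste0("t", seq_len(p)))
  counts
}

# Star tree: every tip hangs directly off the root.
star_tree <- function(tip_labels, branch_length = 1) {
  k <- length(tip_labels)
  txt <- paste0("(", paste0(tip_labels, ":", branch_length, collapse = ","),
                ");")
  ape::read.tree(text = txt)
}

binom_envelope <- function(p0, n_datasets, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p0 * (1 - p0) / n_datasets)
  c(p0 - half, p0 + half)
}
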