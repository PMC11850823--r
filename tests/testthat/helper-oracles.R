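# Independent hand-formula oracles used to check the implementation.
# These deliberately avoid the code paths they verify.

# Textbook Pearson correlation from raw sums.
pearson_hand <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Two-tailed p for a Pearson correlation via the exact t transform.
pearson_p_hand <- function(r, n) {
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), n - 2)
}

# Pooled-variance unpaired t statistic, by the book.
pooled_t_hand <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# One-sample t statistic against zero.
one_sample_t_hand <- function(a) mean(a) / (stats::sd(a) / sqrt(length(a)))

# BH step-up adjustment written out directly (sorted p, m * p / rank,
# cumulative minimum from the largest rank down, capped at 1).
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Fine-grid trapezoid quadrature of a function over [lo, hi].
quad_fine <- function(f, lo, hi, n = 1000) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Brute-force survivor scan for the expression filter.
filter_brute <- function(counts, min_count, min_samples) {
  keep <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    hits <- 0L
    for (j in seq_len(ncol(counts))) if (counts[i, j] >= min_count) hits <- hits + 1L
    keep[i] <- hits >= min_samples
  }
  rownames(counts)[keep]
}

# Small complete function-table + expression pair for synchrony tests.
toy_sync_data <- function(n = 8, genes = c("g1", "g2"), seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("c%02d", 1:n), sprintf("d%02d", 1:n))
  ft <- data.frame(subject_id = ids,
                   group = rep(c("control", "drinker"), each = n),
                   release = rnorm(2 * n, 1, 0.2),
                   vmax = rnorm(2 * n, 2.5, 0.5))
  ex <- matrix(rnorm(length(genes) * 2 * n), length(genes),
               dimnames = list(genes, ids))
  list(ft = ft, ex = ex)
}
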