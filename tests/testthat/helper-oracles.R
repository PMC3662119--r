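# Independent oracles used by module and acceptance tests.  These stay
# deliberately naive (explicit loops, definitional formulas) so they share no
# code path with the package implementation.

# Exhaustive-search maximum-entropy threshold: for every split point compute
# the two class entropies straight from the definition.
oracle_maxentropy <- function(counts) {
  total <- sum(counts)
  p <- counts / total
  nb <- length(counts)
  best_h <- -Inf
  best_t <- NA_integer_
  for (t in seq_len(nb - 1L)) {
    p_low <- p[1:t]
    p_high <- p[(t + 1L):nb]
    w0 <- sum(p_low)
    w1 <- sum(p_high)
    if (w0 <= 0 || w1 <= 0) next
    q0 <- p_low[p_low > 0] / w0
    q1 <- p_high[p_high > 0] / w1
    h <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
    if (h > best_h + 1e-12) {
      best_h <- h
      best_t <- t - 1L # threshold gray level (low class = value <= t-1)
    }
  }
  best_t
}

# Hand-expanded two-way ANOVA mean squares and ICC(2,1): explicit double sums,
# no matrix shortcuts.
oracle_icc_a1 <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  grand <- sum(x) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) {
    mi <- sum(x[i, ]) / k
    ss_rows <- ss_rows + k * (mi - grand)^2
  }
  ss_cols <- 0
  for (j in seq_len(k)) {
    mj <- sum(x[, j]) / n
    ss_cols <- ss_cols + n * (mj - grand)^2
  }
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_tot <- ss_tot + (x[i, j] - grand)^2
  }
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Type-7 quantile computed longhand from the sorted sample.
oracle_quantile7 <- function(v, prob) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}
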