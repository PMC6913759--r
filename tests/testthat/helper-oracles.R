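# Independent oracles used to check the implementation: each recomputes a
# quantity from its defining formula by a different route than the package.

# Mean absolute consecutive change, written as an explicit loop.
oracle_volatility <- function(x) {
  total <- 0
  for (i in 2:length(x)) total <- total + abs(x[i] - x[i - 1])
  total / (length(x) - 1)
}

# Trend-line endpoints via stats::lm: fitted value at the last observation
# time minus fitted value at the first.
oracle_trend <- function(times, ratings) {
  fit <- stats::lm(ratings ~ times)
  ends <- stats::predict(fit, data.frame(times = c(times[1],
                                                   times[length(times)])))
  d <- unname(ends[2] - ends[1])
  list(delta = d, abs_delta = abs(d))
}

# Exact 1-D k-means by dynamic programming over the sorted values:
# minimizes within-cluster sum of squares over all contiguous partitions.
# Returns the optimal total WSS and, for k = 2, the boundary midpoint.
oracle_kmeans_1d <- function(x, k = 2L) {
  s <- sort(x)
  n <- length(s)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  sse <- function(i, j) { # WSS of s[i..j]
    m <- j - i + 1L
    sum_ <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    sum2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    sum2 - sum_^2 / m
  }
  dp <- matrix(Inf, k, n)
  cut_at <- matrix(NA_integer_, k, n)
  for (j in seq_len(n)) dp[1L, j] <- sse(1L, j)
  if (k > 1L) {
    for (kk in 2L:k) {
      for (j in kk:n) {
        for (i in kk:j) {
          cand <- dp[kk - 1L, i - 1L] + sse(i, j)
          if (cand < dp[kk, j]) {
            dp[kk, j] <- cand
            cut_at[kk, j] <- i
          }
        }
      }
    }
  }
  first_high <- if (k == 2L) cut_at[2L, n] else NA_integer_
  list(
    wss = dp[k, n],
    threshold = if (!is.na(first_high) && first_high > 1L) {
      (s[first_high - 1L] + s[first_high]) / 2
    } else NA_real_)
}

# Entropy / information gain by direct arithmetic on a contingency table.
oracle_entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

oracle_info_gain <- function(x, y) {
  tab <- table(x, y)
  h_y <- oracle_entropy_bits(table(y))
  h_cond <- 0
  for (r in seq_len(nrow(tab))) {
    h_cond <- h_cond + sum(tab[r, ]) / sum(tab) *
      oracle_entropy_bits(tab[r, ])
  }
  h_y - h_cond
}

# Brute-force vote counter for the (>= 3 of 5)-style consolidation rule.
oracle_vote <- function(votes) {
  n_high <- 0L
  for (v in votes) if (v == "high") n_high <- n_high + 1L
  if (n_high > length(votes) - n_high) "high" else "low"
}
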