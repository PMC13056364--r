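# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition, without reusing the package's internals.

# Otsu: exhaustively try every candidate gray level and maximize the
# between-class variance of the split, computing class weights and means
# directly from the quantized values.
brute_force_otsu_level <- function(image) {
  x <- as.numeric(image)
  rng <- range(x)
  v <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * 256), 255)
  best_level <- NA_integer_
  best_bcv <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best_bcv + 1e-12) {
      best_bcv <- bcv
      best_level <- t
    }
  }
  best_level
}

# BH step-up from the definition: q for the i-th smallest p is
# min_{j >= i} m * p_(j) / j, capped at 1.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Welch's t-test from the closed form, scalar arithmetic only.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# strip everything but dimensions, for comparing pixel content across
# channels that differ only in labels
px <- function(m) {
  attributes(m) <- attributes(m)["dim"]
  m
}

# random logical mask of given shape with approximate foreground fraction
random_mask <- function(nr, nc, frac) {
  matrix(runif(nr * nc) < frac, nr, nc)
}
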