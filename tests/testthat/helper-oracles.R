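# Independent brute-force oracles used to check the image primitives and the
# regression fits. These deliberately re-derive each quantity from its
# definition with naive loops, not via the package's code paths.

# Kirsch compass response: explicit loop over the 8 kernels, reflect padding
oracle_kirsch <- function(img) {
  ring <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  base <- c(5, 5, 5, -3, -3, -3, -3, -3)
  kernels <- lapply(0:7, function(k) {
    w <- base[((seq_len(8) - 1 - k) %% 8) + 1]
    K <- matrix(0, 3, 3)
    for (i in 1:8) K[ring[i, 1] + 2, ring[i, 2] + 2] <- w[i]
    K
  })
  H <- nrow(img); W <- ncol(img)
  reflect <- function(i, n) min(max(i, 1), n)
  out <- matrix(0, H, W)
  for (y in 1:H) for (x in 1:W) {
    best <- -Inf
    for (K in kernels) {
      r <- 0
      for (dy in -1:1) for (dx in -1:1) {
        r <- r + K[dy + 2, dx + 2] * img[reflect(y + dy, H), reflect(x + dx, W)]
      }
      best <- max(best, r)
    }
    out[y, x] <- max(best, 0)
  }
  out
}

# exhaustive minimum cross-entropy threshold over the 256 8-bit candidates
oracle_li_exhaustive <- function(v) {
  v <- as.numeric(v)
  ce <- function(t) {
    b <- v[v <= t]; f <- v[v > t]
    tb <- if (length(b) == 0 || sum(b) <= 0) 0 else sum(b) * log(mean(b))
    tf <- if (length(f) == 0 || sum(f) <= 0) 0 else sum(f) * log(mean(f))
    -(tb + tf)
  }
  cand <- (0:255) / 255
  cand[which.min(vapply(cand, ce, numeric(1)))]
}

# population skewness from raw sums
oracle_skewness <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m3 / m2^1.5
}

# closed-form OLS of log10(y / y[anchor]) on t
oracle_log10_ols <- function(t, y, anchor) {
  ly <- log10(y / y[t == anchor])
  slope <- sum((t - mean(t)) * (ly - mean(ly))) / sum((t - mean(t))^2)
  list(slope = slope, t_half = -log10(2) / slope)
}

# small bimodal test image: two Gaussian-ish intensity populations
random_bimodal_image <- function(n = 64, seed = 1, fg_frac = 0.15,
                                 fg_mean = 0.7, bg_mean = 0.15, sd = 0.05) {
  set.seed(seed)
  fg <- stats::runif(n * n) < fg_frac
  v <- ifelse(fg, stats::rnorm(n * n, fg_mean, sd), stats::rnorm(n * n, bg_mean, sd))
  matrix(pmin(pmax(v, 0), 1), n, n)
}
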