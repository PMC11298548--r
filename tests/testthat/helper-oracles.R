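# Independent oracles, deliberately implemented differently from the package.

# interpolated percentile via explicit order-statistic interpolation
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_power <- function(x) sum(x^2) / length(x)

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}

oracle_cosine <- function(x, y)
  sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))

oracle_fold <- function(t1, t2) {
  # walk candidates explicitly instead of modular arithmetic
  d <- abs(t1 - t2)
  while (d >= 180) d <- d - 180
  if (d > 90) 180 - d else d
}

# brute-force Otsu: try every bin edge, maximize between-class variance
oracle_otsu_threshold <- function(img, n_bins = 256) {
  v <- as.vector(img)
  edges <- seq(min(v), max(v), length.out = n_bins + 1)[-1]
  best <- -Inf; best_t <- edges[1]
  for (t in edges[-n_bins]) {
    g1 <- v[v <= t]; g2 <- v[v > t]
    if (!length(g1) || !length(g2)) next
    w1 <- length(g1) / length(v); w2 <- 1 - w1
    bcv <- w1 * w2 * (mean(g1) - mean(g2))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

# MWW statistic written independently (complex-number resultants)
oracle_mww_W <- function(angles_deg, groups) {
  N <- length(angles_deg)
  beta <- 2 * pi * rank(angles_deg) / N
  z <- exp(1i * beta)
  2 * sum(vapply(unique(groups), function(g) {
    zg <- sum(z[groups == g])
    Mod(zg)^2 / sum(groups == g)
  }, 1))
}

# exhaustive two-group permutation p-value by enumeration
oracle_mww_exact_p <- function(a1, a2) {
  pooled <- c(a1, a2)
  n1 <- length(a1); N <- length(pooled)
  Wobs <- oracle_mww_W(pooled, rep(1:2, c(n1, length(a2))))
  idx <- utils::combn(N, n1)
  Wall <- apply(idx, 2, function(i) {
    g <- rep(2L, N); g[i] <- 1L
    oracle_mww_W(pooled, g)
  })
  mean(Wall >= Wobs - 1e-12)
}

# build a dff_trace directly for detector unit tests
make_dff <- function(values, noise_sd, frame_interval = 0.25) {
  structure(list(values = values, baseline = 1, noise_sd = noise_sd,
                 frame_interval = frame_interval, roi_id = "test"),
            class = "dff_trace")
}
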