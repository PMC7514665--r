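# Independent oracles, deliberately written with different algorithms than
# the package implementation (plain R loops over explicit embeddings).

# brute-force pair-counting sample entropy with a fixed tolerance
bruteSampEn <- function(x, m, tol) {
  n <- length(x)
  M <- n - m
  embed_m <- vapply(seq_len(M), function(i) x[i:(i + m - 1)], numeric(m))
  embed_m1 <- vapply(seq_len(M), function(i) x[i:(i + m)], numeric(m + 1))
  embed_m <- matrix(embed_m, nrow = m)
  embed_m1 <- matrix(embed_m1, nrow = m + 1)
  A <- 0L
  B <- 0L
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      if (max(abs(embed_m[, i] - embed_m[, j])) <= tol) B <- B + 1L
      if (max(abs(embed_m1[, i] - embed_m1[, j])) <= tol) A <- A + 1L
    }
  }
  if (B == 0L) NaN else if (A == 0L) log(B) else -log(A / B)
}

# brute-force all-lag Pearson scan using cor()
brutePearsonScan <- function(x, y, L) {
  n <- length(x)
  lags <- -L:L
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      xi <- x[(1 + k):n]
      yi <- y[1:(n - k)]
    } else {
      xi <- x[1:(n + k)]
      yi <- y[(1 - k):n]
    }
    if (length(xi) < 3) return(NA_real_)
    suppressWarnings(stats::cor(xi, yi))
  }, 0)
  best <- which.max(cc)
  list(cmax = cc[best], lag = lags[best], all = cc)
}

# population SD by explicit formula
oraclePopSD <- function(x) sqrt(sum((x - mean(x))^2) / length(x))

# RMS of a steady-state sinusoid segment of a filtered signal
segmentRMS <- function(sig, from, to) {
  x <- fSampEn::samples(sig)
  sqrt(mean(x[from:to]^2))
}
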