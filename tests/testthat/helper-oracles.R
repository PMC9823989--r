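# Independent brute-force oracles, deliberately written as plain loops so they
# share no code path with the package implementations.

oracle_p1 <- function(x) {
  npos <- 0
  nneg <- 0
  for (i in 2:length(x)) {
    d <- x[i] - x[i - 1]
    if (d > 0) npos <- npos + 1
    if (d < 0) nneg <- nneg + 1
  }
  100 * nneg / (nneg + npos)
}

oracle_g1 <- function(x) {
  sp <- 0
  sn <- 0
  for (i in 2:length(x)) {
    d <- x[i] - x[i - 1]
    if (d > 0) sp <- sp + d^2
    if (d < 0) sn <- sn + d^2
  }
  100 * sp / (sp + sn)
}

oracle_corr2 <- function(x) {
  n <- length(x)
  cor(x[seq_len(n - 2)], x[seq(3, n)])
}

# rotate the lag-1 scatter by 45 degrees: SD1 is the RMS distance from the
# identity line, SD2 the residual second moment along it
oracle_sd1_sd2 <- function(x) {
  n <- length(x)
  u <- numeric(n - 1)
  for (i in 1:(n - 1)) u[i] <- (x[i + 1] - x[i]) / sqrt(2)
  sd1 <- sqrt(sum(u^2) / (n - 1))
  m <- mean(x)
  tot <- 0
  for (i in 1:n) tot <- tot + (x[i] - m)^2
  sd2 <- sqrt(2 * tot / n - sd1^2)
  c(SD1 = sd1, SD2 = sd2)
}

# O(n^2) template-counting sample entropy, all loops
oracle_sampen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  count <- function(mm) {
    tot <- 0
    for (i in 1:(n - m)) {
      for (j in 1:(n - m)) {
        if (j <= i) next
        dmax <- 0
        for (k in 0:(mm - 1)) {
          dk <- abs(x[i + k] - x[j + k])
          if (dk > dmax) dmax <- dk
        }
        if (dmax <= r) tot <- tot + 1
      }
    }
    tot
  }
  -log(count(m + 1) / count(m))
}

oracle_sdsd <- function(x) {
  d <- numeric(0)
  for (i in 2:length(x)) d <- c(d, x[i] - x[i - 1])
  sd(d)
}

# direct covariance eigenvector (first principal axis) of a 2-column matrix
oracle_first_eigvec <- function(X) {
  ev <- eigen(cov(X))$vectors[, 1]
  if (ev[1] < 0) ev <- -ev
  ev
}

# equally spaced RR series helper: intervals in ms, beat times consistent
rr_from_intervals <- function(iv, record_id = "test") {
  rr_series(cumsum(iv) / 1000, iv, record_id = record_id)
}

# random plausible RR series
random_rr <- function(n, seed, mean_ms = 900, sd_ms = 40) {
  set.seed(seed)
  iv <- rnorm(n, mean_ms, sd_ms)
  iv[iv < 400] <- 400
  rr_from_intervals(iv)
}
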