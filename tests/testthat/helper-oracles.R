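# Independent brute-force oracles. Deliberately written as plain loops,
# sharing no code with the package implementation.

oracle_xcorr <- function(x, y, max_lag) {
  n <- length(x)
  ex <- 0
  ey <- 0
  for (i in seq_len(n)) {
    ex <- ex + x[i]^2
    ey <- ey + y[i]^2
  }
  lags <- -max_lag:max_lag
  out <- numeric(length(lags))
  if (ex == 0 || ey == 0) return(out)
  for (k in seq_along(lags)) {
    tau <- lags[k]
    s <- 0
    for (i in seq_len(n)) {
      j <- i + tau
      if (j >= 1 && j <= n) s <- s + x[i] * y[j]
    }
    out[k] <- min(s / sqrt(ex * ey), 1)
  }
  out
}

oracle_local_max <- function(corr) {
  best <- NA_real_
  for (i in seq_along(corr)) {
    if (i == 1L || i == length(corr)) next
    if (corr[i] > corr[i - 1L] && corr[i] > corr[i + 1L] &&
        (is.na(best) || corr[i] > best))
      best <- corr[i]
  }
  best
}

oracle_interp <- function(mz, intensity, grid) {
  out <- numeric(length(grid))
  for (g in seq_along(grid)) {
    x <- grid[g]
    if (x < mz[1] || x > mz[length(mz)]) {
      out[g] <- 0
      next
    }
    k <- max(which(mz <= x))
    if (mz[k] == x) out[g] <- intensity[k]
    else out[g] <- intensity[k] + (intensity[k + 1] - intensity[k]) *
        (x - mz[k]) / (mz[k + 1] - mz[k])
  }
  out
}
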