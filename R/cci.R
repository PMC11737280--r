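#' CCI configuration
#'
#' The cross-correlation index is computed over fixed, half-open mass
#' intervals tiling a mass range. Defaults: 500 Da intervals spanning
#' 3000-12,000 Da (18 intervals) and a symmetric lag window of +/-20 grid
#' points (20 Da at the default 1 Da grid step), which absorbs residual
#' calibration shift between spectra.
#'
#' @param mass_min,mass_max CCI mass range bounds in Da.
#' @param width interval width in Da; must divide `mass_max - mass_min`.
#' @param max_lag symmetric lag window half-width in grid points (>= 1).
#' @return an object of class `cci_config`.
#' @export
cci_config <- function(mass_min = 3000, mass_max = 12000, width = 500,
                       max_lag = 20L) {
  stopifnot(max_lag >= 1)
  grid <- make_interval_grid(mass_min, mass_max, width)
  structure(list(mass_min = mass_min, mass_max = mass_max, width = width,
                 max_lag = as.integer(max_lag), intervals = grid$intervals),
            class = "cci_config")
}

#' Build the half-open mass-interval grid
#'
#' @param mass_min,mass_max range bounds in Da; `mass_max - mass_min` must
#'   be an integer multiple of `width`.
#' @param width interval width in Da.
#' @return list with fields `mass_min`, `mass_max`, `width` and
#'   `intervals`, a data.frame of `[lo, hi)` bounds tiling the range.
#' @export
make_interval_grid <- function(mass_min, mass_max, width) {
  stopifnot(mass_max > mass_min, width > 0)
  k <- (mass_max - mass_min) / width
  if (abs(k - round(k)) > 1e-9)
    stop_ccimatch("interval width ", width, " does not divide the mass range [",
                  mass_min, ", ", mass_max, ")")
  k <- as.integer(round(k))
  lo <- mass_min + width * (seq_len(k) - 1)
  list(mass_min = mass_min, mass_max = mass_max, width = width,
       intervals = data.frame(lo = lo, hi = lo + width))
}

#' Normalized cross-correlation of two intensity segments
#'
#' For lags tau = -max_lag..max_lag,
#' `C(tau) = sum_i x[i] * y[i + tau] / sqrt(sum(x^2) * sum(y^2))`,
#' summed over the overlapping index range, without mean-centering. For
#' non-negative inputs all values lie in \[0, 1\] and `C(0)` is exactly 1
#' when `x == y`. If either segment is all-zero, C is identically 0.
#'
#' @param x,y equal-length numeric segments (length >= max_lag + 2).
#' @param max_lag lag window half-width in grid points.
#' @return numeric vector of length `2*max_lag + 1`, names are the lags.
#' @export
normalized_xcorr <- function(x, y, max_lag) {
  n <- length(x)
  if (length(y) != n)
    stop_ccimatch("normalized_xcorr: segments differ in length")
  if (n < max_lag + 2L)
    stop_ccimatch("normalized_xcorr: segment shorter than max_lag + 2")
  lags <- seq(-max_lag, max_lag)
  out <- numeric(length(lags))
  names(out) <- lags
  ex <- sum(x^2)
  ey <- sum(y^2)
  if (ex == 0 || ey == 0) return(out)
  denom <- sqrt(ex * ey)
  for (i in seq_along(lags)) {
    tau <- lags[i]
    v <- if (tau >= 0) sum(x[seq_len(n - tau)] * y[seq_len(n - tau) + tau])
    else sum(x[seq_len(n + tau) - tau] * y[seq_len(n + tau)])
    out[i] <- min(v / denom, 1)
  }
  out
}

#' Largest strict interior local maximum of a correlation sequence
#'
#' A point qualifies if it is strictly greater than both neighbors;
#' endpoints never qualify, so a monotone or flat sequence has no local
#' maximum and `NA` (absent) is returned -- the interval then contributes
#' a factor of 0 to the CCI.
#'
#' @param corr numeric sequence of >= 3 correlation values.
#' @return the largest qualifying value, or `NA_real_` if none.
#' @export
local_max <- function(corr) {
  n <- length(corr)
  if (n < 3L) stop_ccimatch("local_max: need at least 3 lags")
  i <- 2:(n - 1L)
  ok <- corr[i] > corr[i - 1L] & corr[i] > corr[i + 1L]
  if (!any(ok)) return(NA_real_)
  max(corr[i][ok])
}

interval_columns <- function(grid_mz, lo, hi) {
  which(grid_mz >= lo & grid_mz < hi)
}

check_common_grid <- function(a, b, config) {
  if (length(a$grid_mz) != length(b$grid_mz) ||
      max(abs(a$grid_mz - b$grid_mz)) > 1e-9)
    stop_ccimatch("cci: spectra are not on the same uniform grid")
  if (a$grid_mz[1L] > config$mass_min ||
      a$grid_mz[length(a$grid_mz)] < config$mass_max - 1e-9)
    stop_ccimatch("cci: grid does not cover the CCI mass range")
}

#' Cross-correlation index between two processed spectra
#'
#' For each mass interval, computes the normalized cross-correlation
#' function of the two spectra restricted to the interval and takes its
#' largest strict local maximum; the CCI is the product of the per-interval
#' values, defined as 0 whenever any interval has no local maximum. The
#' product is accumulated in log space, so `log10cci` ranges from `-Inf`
#' (too dissimilar) to 0 (identical spectra).
#'
#' @param a,b `processed_spectrum` objects on a common uniform grid
#'   covering the CCI mass range.
#' @param config a [cci_config].
#' @return an object of class `cci_result` with fields `id_a`, `id_b`,
#'   `per_interval_max` (NA = absent), `cci` and `log10cci`.
#' @export
cci <- function(a, b, config = cci_config()) {
  stopifnot(inherits(config, "cci_config"))
  check_common_grid(a, b, config)
  iv <- config$intervals
  per <- rep(NA_real_, nrow(iv))
  for (k in seq_len(nrow(iv))) {
    cols <- interval_columns(a$grid_mz, iv$lo[k], iv$hi[k])
    if (length(cols) < config$max_lag + 2L) next  # flagged: no local maximum
    cc <- normalized_xcorr(a$intensity[cols], b$intensity[cols],
                           config$max_lag)
    per[k] <- local_max(cc)
  }
  log10cci <- if (anyNA(per)) -Inf else sum(log10(per))
  structure(list(id_a = a$spectrum_id, id_b = b$spectrum_id,
                 per_interval_max = per,
                 cci = 10^log10cci, log10cci = log10cci),
            class = "cci_result")
}

#' @export
print.cci_result <- function(x, ...) {
  cat(sprintf("<cci %s vs %s: log10(CCI) = %.3f>\n", x$id_a, x$id_b,
              x$log10cci))
  invisible(x)
}

#' log10 of a CCI value
#'
#' @param cci_value number in \[0, 1\].
#' @return `log10(cci_value)`; 0 maps to `-Inf`, 1 maps to 0.
#' @export
log10_cci <- function(cci_value) {
  if (any(cci_value < 0 | cci_value > 1))
    stop_ccimatch("log10_cci: value outside [0, 1]")
  log10(cci_value)
}

#' Batch log10(CCI) between two sets of spectra
#'
#' Computes the log10(CCI) of every row spectrum against every column
#' spectrum using per-(interval, lag) BLAS matrix products. Results are
#' identical (to floating-point roundoff) to calling [cci] pair by pair;
#' with `Y = NULL` the symmetric all-against-all matrix is returned with
#' an exactly-zero diagonal (self-similarity 1).
#'
#' @param X numeric matrix, one spectrum per row, on the common grid.
#' @param Y optional second matrix on the same grid; `NULL` means `X`.
#' @param grid_mz the common uniform mass grid (columns of `X`).
#' @param config a [cci_config].
#' @return matrix of log10(CCI) values, `nrow(X)` x `nrow(Y)`.
#' @export
cci_cross_matrix <- function(X, Y = NULL, grid_mz, config = cci_config()) {
  stopifnot(is.matrix(X), length(grid_mz) == ncol(X))
  symmetric <- is.null(Y)
  if (symmetric) Y <- X
  stopifnot(ncol(Y) == ncol(X))
  m <- config$max_lag
  iv <- config$intervals
  nx <- nrow(X)
  ny <- nrow(Y)
  logsum <- matrix(0, nx, ny)
  absent <- matrix(FALSE, nx, ny)
  for (k in seq_len(nrow(iv))) {
    cols <- interval_columns(grid_mz, iv$lo[k], iv$hi[k])
    if (length(cols) < m + 2L) {
      absent[] <- TRUE
      break
    }
    Sx <- X[, cols, drop = FALSE]
    Sy <- if (symmetric) Sx else Y[, cols, drop = FALSE]
    L <- length(cols)
    curves <- vector("list", 2L * m + 1L)
    for (tau in 0:m) {
      curves[[m + 1L + tau]] <-
        Sx[, seq_len(L - tau), drop = FALSE] %*%
        t(Sy[, seq_len(L - tau) + tau, drop = FALSE])
      if (tau > 0L)
        curves[[m + 1L - tau]] <-
          Sx[, seq_len(L - tau) + tau, drop = FALSE] %*%
          t(Sy[, seq_len(L - tau), drop = FALSE])
    }
    # energies from the lag-0 product in the symmetric case keep the
    # self-correlation exactly 1
    ex <- if (symmetric) diag(curves[[m + 1L]]) else rowSums(Sx^2)
    ey <- if (symmetric) ex else rowSums(Sy^2)
    best <- matrix(-Inf, nx, ny)
    for (t in 2:(2L * m)) {
      cand <- curves[[t]]
      ok <- cand > curves[[t - 1L]] & cand > curves[[t + 1L]] & cand > best
      best[ok] <- cand[ok]
    }
    denom <- sqrt(outer(ex, ey))
    val <- pmin(best / denom, 1)
    bad <- !is.finite(val) | best == -Inf
    absent <- absent | bad
    val[bad] <- 1  # neutral; pair already marked absent
    logsum <- logsum + log10(val)
  }
  logsum[absent] <- -Inf
  dimnames(logsum) <- list(rownames(X), rownames(Y))
  logsum
}

#' Stack processed spectra into a matrix on their common grid
#'
#' @param spectra list of `processed_spectrum` sharing one grid.
#' @return list with `intensities` (spectra x grid matrix, rownames =
#'   spectrum ids) and `grid_mz`.
#' @export
spectra_matrix <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  grid <- spectra[[1L]]$grid_mz
  for (s in spectra)
    if (length(s$grid_mz) != length(grid) ||
        max(abs(s$grid_mz - grid)) > 1e-9)
      stop_ccimatch("spectra_matrix: spectra are not on a common grid")
  M <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
  rownames(M) <- vapply(spectra, `[[`, character(1), "spectrum_id")
  list(intensities = M, grid_mz = grid)
}
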