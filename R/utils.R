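#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers (the synthetic
#' generator, the simulation engine) never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Empirical quantiles that tolerate -Inf values
#'
#' Linear interpolation between order statistics (type-7 convention), with
#' -Inf ordered below all finite values. Interpolating between -Inf and a
#' finite value yields -Inf, so a median that falls on -Inf is reported as
#' -Inf rather than NaN.
#'
#' @param x numeric vector, may contain `-Inf`; `NA` values are dropped.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles, same length as `probs`.
#' @export
quantile_inf <- function(x, probs) {
  x <- unname(x[!is.na(x)])
  if (length(x) == 0L) stop("quantile_inf(): no non-missing values")
  stopifnot(all(probs >= 0), all(probs <= 1))
  xs <- sort(x)  # sort() places -Inf first
  n <- length(xs)
  h <- (n - 1) * probs
  lo <- pmin(floor(h), n - 1)
  g <- h - lo
  xl <- xs[lo + 1]
  xu <- xs[pmin(lo + 2, n)]
  out <- xl
  interp <- g > 0 & xu != xl
  # (1-g)*(-Inf) + g*finite correctly propagates to -Inf
  out[interp] <- (1 - g[interp]) * xl[interp] + g[interp] * xu[interp]
  out
}

#' Derive a substream seed from a master seed
#'
#' Deterministic integer hash below 2^31 - 1. Used to give each
#' (repeat, specimen) combination its own RNG substream so spot draws are
#' reproducible and identical across thresholds and evaluation modes.
#' @noRd
substream_seed <- function(master, a, b = 0L) {
  # all intermediates stay below 2^53, exact in doubles
  s <- (as.double(master) %% 2147483647) * 48271 + as.double(a) * 100003 +
    as.double(b) * 7919 + 12345
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# let data.table syntax dispatch correctly inside this package
.datatable.aware <- TRUE

stop_ccimatch <- function(...) stop(..., call. = FALSE)
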