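#' Preprocessing configuration
#'
#' Parameters of the raw-to-processed transformation chain:
#' resample onto a uniform mass grid, variance-stabilizing intensity
#' transform, Savitzky-Golay smoothing, SNIP baseline removal,
#' total-ion-current normalization, and optional dataset-level rigid-shift
#' alignment. Defaults follow MALDIquant-style conventions for linear-mode
#' MALDI-TOF protein spectra acquired over 2000-20,000 Da.
#'
#' @param transform intensity transform: `"sqrt"` (default), `"log1p"` or
#'   `"none"`.
#' @param smooth_half_window Savitzky-Golay half window in grid points
#'   (window = 2*hw+1, polynomial order 3). Default 10.
#' @param baseline_method baseline estimator; only `"SNIP"`.
#' @param baseline_iterations SNIP clipping-window iterations. Default 100.
#' @param grid_step uniform grid step in Da. Default 1.
#' @param grid_min,grid_max grid trimming bounds in Da. Default 2000-20,000
#'   (the acquisition mass range).
#' @param align apply dataset-level alignment in [preprocess_spectra].
#' @param align_tolerance maximum rigid mass shift in Da. Default 10.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(transform = c("sqrt", "log1p", "none"),
                              smooth_half_window = 10L,
                              baseline_method = "SNIP",
                              baseline_iterations = 100L,
                              grid_step = 1,
                              grid_min = 2000,
                              grid_max = 20000,
                              align = TRUE,
                              align_tolerance = 10) {
  transform <- match.arg(transform)
  baseline_method <- match.arg(baseline_method, "SNIP")
  stopifnot(grid_min < grid_max, grid_step > 0, smooth_half_window >= 1,
            baseline_iterations >= 1, align_tolerance >= 0)
  structure(list(transform = transform,
                 smooth_half_window = as.integer(smooth_half_window),
                 baseline_method = baseline_method,
                 baseline_iterations = as.integer(baseline_iterations),
                 grid_step = grid_step, grid_min = grid_min,
                 grid_max = grid_max, align = isTRUE(align),
                 align_tolerance = align_tolerance),
            class = "preprocess_config")
}

processed_spectrum <- function(grid_mz, intensity, spectrum_id, provenance) {
  structure(list(grid_mz = grid_mz, intensity = intensity,
                 spectrum_id = spectrum_id, provenance = provenance),
            class = "processed_spectrum")
}

#' @export
print.processed_spectrum <- function(x, ...) {
  cat(sprintf("<processed_spectrum %s: %d grid points, steps: %s>\n",
              x$spectrum_id, length(x$grid_mz),
              paste(x$provenance, collapse = " > ")))
  invisible(x)
}

#' Resample a raw spectrum onto a uniform mass grid
#'
#' Linear interpolation onto `seq(grid_min, grid_max, by = grid_step)`;
#' grid regions not covered by the raw trace are set to 0. Resampling makes
#' cross-correlation lags commensurate across spectra regardless of the
#' acquisition sampling (profile or centroid).
#'
#' @param raw a [raw_spectrum].
#' @param grid_step,grid_min,grid_max grid definition in Da.
#' @return a `processed_spectrum` (pre-normalization).
#' @export
resample_uniform <- function(raw, grid_step = 1, grid_min = 2000,
                             grid_max = 20000) {
  stopifnot(inherits(raw, "raw_spectrum"))
  if (max(raw$mz) < grid_min || min(raw$mz) > grid_max)
    stop_ccimatch("spectrum '", raw$spectrum_id,
                  "' has no coverage of [", grid_min, ", ", grid_max, "] Da")
  grid <- seq(grid_min, grid_max, by = grid_step)
  y <- stats::approx(raw$mz, raw$intensity, xout = grid,
                     method = "linear", yleft = 0, yright = 0)$y
  processed_spectrum(grid, pmax(y, 0), raw$spectrum_id,
                     sprintf("resample(step=%g,min=%g,max=%g)",
                             grid_step, grid_min, grid_max))
}

#' Apply a variance-stabilizing intensity transform
#'
#' @param spectrum a `processed_spectrum`.
#' @param method `"sqrt"`, `"log1p"` or `"none"`.
#' @return the transformed spectrum.
#' @export
transform_intensity <- function(spectrum, method = c("sqrt", "log1p", "none")) {
  method <- match.arg(method)
  if (any(spectrum$intensity < 0))
    stop_ccimatch("transform_intensity: negative intensities")
  spectrum$intensity <- switch(method,
                               sqrt = sqrt(spectrum$intensity),
                               log1p = log1p(spectrum$intensity),
                               none = spectrum$intensity)
  spectrum$provenance <- c(spectrum$provenance,
                           sprintf("transform(%s)", method))
  spectrum
}

# Savitzky-Golay convolution weights for the window center, order 3.
# Symmetric by construction.
sg_weights <- function(half_window, poly_order = 3L) {
  x <- seq(-half_window, half_window)
  V <- outer(x, 0:poly_order, `^`)
  solve(crossprod(V), t(V))[1L, ]
}

#' Savitzky-Golay smoothing
#'
#' Order-3 polynomial smoothing with window `2*half_window + 1`; an
#' order-3 filter reproduces cubics exactly in the window interior. The
#' first and last `half_window` points are left untouched (no partial
#' window) and output is clipped at 0.
#'
#' @param spectrum a `processed_spectrum`.
#' @param half_window half window in grid points.
#' @return the smoothed spectrum.
#' @export
smooth_spectrum <- function(spectrum, half_window = 10L) {
  n <- length(spectrum$intensity)
  if (2L * half_window + 1L > n)
    stop_ccimatch("smooth_spectrum: window longer than spectrum")
  w <- sg_weights(half_window)
  sm <- as.numeric(stats::filter(spectrum$intensity, w, method = "convolution",
                                 sides = 2))
  edge <- c(seq_len(half_window), seq(n - half_window + 1L, n))
  sm[edge] <- spectrum$intensity[edge]
  spectrum$intensity <- pmax(sm, 0)
  spectrum$provenance <- c(spectrum$provenance,
                           sprintf("smooth(SG3,hw=%d)", as.integer(half_window)))
  spectrum
}

# SNIP baseline: iterative clipping y[i] <- min(y[i], (y[i-w]+y[i+w])/2)
# with the window w growing from 1 to `iterations` grid points.
snip_baseline <- function(y, iterations) {
  b <- y
  n <- length(y)
  for (w in seq_len(iterations)) {
    if (2L * w >= n) break
    i <- (w + 1L):(n - w)
    b[i] <- pmin(b[i], (b[i - w] + b[i + w]) / 2)
  }
  b
}

#' SNIP baseline removal
#'
#' Estimates the slowly varying chemical/detector baseline with the SNIP
#' (statistics-sensitive non-linear iterative peak-clipping) algorithm and
#' subtracts it; output is clipped at 0.
#'
#' @param spectrum a `processed_spectrum` on a uniform grid.
#' @param iterations SNIP iteration count (maximum clipping half window in
#'   grid points).
#' @return the baseline-corrected spectrum.
#' @export
remove_baseline <- function(spectrum, iterations = 100L) {
  if (iterations < 1L) stop_ccimatch("remove_baseline: iterations must be >= 1")
  b <- snip_baseline(spectrum$intensity, as.integer(iterations))
  spectrum$intensity <- pmax(spectrum$intensity - b, 0)
  spectrum$provenance <- c(spectrum$provenance,
                           sprintf("baseline(SNIP,iter=%d)",
                                   as.integer(iterations)))
  spectrum
}

#' Total-ion-current normalization
#'
#' Scales the spectrum so intensities sum to one. A spectrum that is
#' all-zero after baseline removal carries no fingerprint and is rejected
#' (callers batch-processing spectra exclude it with a logged reason).
#'
#' @param spectrum a `processed_spectrum`.
#' @return the normalized spectrum (intensity sums to 1 within 1e-9).
#' @export
normalize_tic <- function(spectrum) {
  s <- sum(spectrum$intensity)
  if (!is.finite(s) || s <= 0)
    stop_ccimatch("normalize_tic: degenerate (all-zero) spectrum '",
                  spectrum$spectrum_id, "'")
  spectrum$intensity <- spectrum$intensity / s
  spectrum$provenance <- c(spectrum$provenance, "normalize(TIC)")
  spectrum
}

#' Rigid-shift alignment of a set of processed spectra
#'
#' For each spectrum, finds the single global mass shift (whole grid
#' points, bounded by `tolerance`) that maximizes its normalized
#' cross-correlation with the intensity-mean reference spectrum, applies
#' it (zero-padding the vacated edge) and renormalizes. A shift hitting
#' the tolerance bound is clamped there and reported with a message.
#'
#' @param spectra list of `processed_spectrum` on one common grid.
#' @param tolerance maximum |shift| in Da.
#' @return the aligned list, same order.
#' @export
align_spectra <- function(spectra, tolerance = 10) {
  if (length(spectra) < 2L) return(spectra)
  grid <- spectra[[1L]]$grid_mz
  for (s in spectra)
    if (!isTRUE(all.equal(s$grid_mz, grid, tolerance = 1e-9)))
      stop_ccimatch("align_spectra: spectra are not on a common grid")
  step <- grid[2L] - grid[1L]
  max_shift <- as.integer(floor(tolerance / step))
  X <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
  total <- colSums(X)
  n <- length(total)
  out <- spectra
  for (k in seq_along(spectra)) {
    y <- spectra[[k]]$intensity
    # leave-one-out mean reference: the spectrum's own (possibly shifted)
    # copy must not pull the alignment target toward itself
    ref <- (total - y) / (length(spectra) - 1L)
    ey <- sum(y^2)
    if (ey == 0 || sum(ref^2) == 0) next
    best <- 0
    best_s <- 0L
    for (s in seq(-max_shift, max_shift)) {
      # y shifted by +s grid points compared against ref
      if (s >= 0) v <- sum(ref[(1 + s):n] * y[1:(n - s)])
      else v <- sum(ref[1:(n + s)] * y[(1 - s):n])
      if (v > best) {
        best <- v
        best_s <- s
      }
    }
    if (abs(best_s) == max_shift && max_shift > 0)
      message("align_spectra: '", spectra[[k]]$spectrum_id,
              "' shift clamped at tolerance bound (", best_s * step, " Da)")
    if (best_s != 0L) {
      if (best_s > 0) y <- c(rep(0, best_s), y[1:(n - best_s)])
      else y <- c(y[(1 - best_s):n], rep(0, -best_s))
      sy <- sum(y)
      if (sy > 0 && abs(sum(spectra[[k]]$intensity) - 1) < 1e-6) y <- y / sy
      out[[k]]$intensity <- y
    }
    out[[k]]$provenance <- c(out[[k]]$provenance,
                             sprintf("align(shift=%+d)", best_s))
  }
  out
}

#' Full preprocessing chain for one raw spectrum
#'
#' Applies, in this fixed order: resample, intensity transform, smoothing,
#' baseline removal, TIC normalization. Each step is recorded in the
#' spectrum's provenance. Dataset-level alignment is applied afterwards by
#' [preprocess_spectra] when `config$align` is `TRUE`.
#'
#' @param raw a [raw_spectrum].
#' @param config a [preprocess_config].
#' @return a `processed_spectrum` whose intensities sum to 1.
#' @export
preprocess_pipeline <- function(raw, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  s <- resample_uniform(raw, config$grid_step, config$grid_min, config$grid_max)
  s <- transform_intensity(s, config$transform)
  s <- smooth_spectrum(s, config$smooth_half_window)
  s <- remove_baseline(s, config$baseline_iterations)
  normalize_tic(s)
}

#' Preprocess a batch of raw spectra
#'
#' Runs [preprocess_pipeline] on every spectrum, excluding any that come
#' out all-zero (degenerate) with a warning naming them, then applies
#' rigid-shift alignment across the batch if configured.
#'
#' @param raws list of [raw_spectrum].
#' @param config a [preprocess_config].
#' @return list of `processed_spectrum`.
#' @export
preprocess_spectra <- function(raws, config = preprocess_config()) {
  out <- list()
  dropped <- character()
  for (r in raws) {
    p <- tryCatch(preprocess_pipeline(r, config), error = function(e) e)
    if (inherits(p, "error")) dropped <- c(dropped, r$spectrum_id)
    else out[[length(out) + 1L]] <- p
  }
  if (length(dropped) > 0)
    warning("excluded degenerate spectra: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  if (isTRUE(config$align) && length(out) >= 2L)
    out <- align_spectra(out, config$align_tolerance)
  out
}
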