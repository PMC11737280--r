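#' Simulation configuration for performance evaluation
#'
#' @param n_spots technical replicates sampled per test specimen and
#'   repeat (without replacement from the specimen's available spots).
#' @param threshold identification threshold on the log10(CCI) scale.
#' @param n_repeats number of simulation repeats (default 1000).
#' @param seed master seed; every (repeat, specimen) spot draw uses its
#'   own substream derived from it.
#' @param mode `"standard"`, or `"unreferenced"` to disable same-species
#'   reference spectra for each query (emulating queries of species
#'   absent from the database, forcing FP or TN).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_spots = 1L, threshold = -14,
                              n_repeats = 1000L, seed = 1L,
                              mode = c("standard", "unreferenced")) {
  mode <- match.arg(mode)
  stopifnot(n_spots >= 1L, n_repeats >= 1L)
  structure(list(n_spots = as.integer(n_spots), threshold = threshold,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 mode = mode),
            class = "simulation_config")
}

#' Classification metrics from confusion counts
#'
#' @param tp,tn,fp,fn non-negative counts, total > 0.
#' @return named numeric vector: `sensitivity` = TP/(TP+FN),
#'   `specificity` = TN/(TN+FP), `ppv` = TP/(TP+FP), `npv` = TN/(TN+FN),
#'   `accuracy` = (TP+TN)/total. Ratios with a zero denominator are `NA`
#'   (undefined/absent).
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop_ccimatch("compute_metrics: no evaluated queries")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = (tp + tn) / total)
}

#' Equal-tailed credible interval of per-repeat metric samples
#'
#' Empirical percentiles (linear interpolation between order statistics)
#' of the metric values across simulation repeats.
#'
#' @param samples numeric vector of per-repeat values; `NA` (undefined in
#'   a repeat) are dropped.
#' @param level interval mass (default 0.95).
#' @return named numeric vector `(low, median, high)`.
#' @export
credible_interval <- function(samples, level = 0.95) {
  samples <- samples[!is.na(samples)]
  if (length(samples) == 0L)
    stop_ccimatch("credible_interval: no finite samples")
  qs <- quantile_inf(samples, c((1 - level) / 2, 0.5, (1 + level) / 2))
  c(low = qs[1L], median = qs[2L], high = qs[3L])
}

#' Precompute per-query-spectrum best matches against a database
#'
#' For every test spectrum: the best (highest log10(CCI)) reference
#' spectrum overall, and the best with same-species references disabled.
#' This table is all the simulation engine needs, so repeats reduce to
#' table lookups.
#'
#' @param test_panel a `reference_db`-like panel of labelled test spectra.
#' @param db the reference `reference_db`.
#' @param config a [cci_config].
#' @return data.frame, one row per test spectrum.
#' @export
prepare_query_best <- function(test_panel, db, config = cci_config()) {
  M <- cci_cross_matrix(test_panel$intensities, db$intensities, db$grid_mz,
                        config)
  rmeta <- db$meta
  ord <- order(rmeta$spectrum_id)  # lexicographic tie-break
  tm <- test_panel$meta
  n <- nrow(tm)
  best_val <- bestu_val <- rep(-Inf, n)
  best_species <- bestu_species <- best_ref <- bestu_ref <- rep(NA_character_, n)
  u_eligible <- rep(FALSE, n)
  for (i in seq_len(n)) {
    row <- M[i, ]
    j <- ord[which.max(row[ord])]
    best_val[i] <- row[j]
    best_species[i] <- rmeta$species_label[j]
    best_ref[i] <- rmeta$spectrum_id[j]
    other <- ord[rmeta$species_label[ord] != tm$species_label[i]]
    if (length(other) > 0L) {
      u_eligible[i] <- TRUE
      j2 <- other[which.max(row[other])]
      bestu_val[i] <- row[j2]
      bestu_species[i] <- rmeta$species_label[j2]
      bestu_ref[i] <- rmeta$spectrum_id[j2]
    }
  }
  data.frame(spectrum_id = tm$spectrum_id, specimen_id = tm$specimen_id,
             spot_index = tm$spot_index, species = tm$species_label,
             best_val = best_val, best_species = best_species,
             best_ref = best_ref, bestu_val = bestu_val,
             bestu_species = bestu_species, bestu_ref = bestu_ref,
             u_eligible = u_eligible, stringsAsFactors = FALSE)
}

# Core simulation engine shared by the standard and unreferenced modes.
simulate_engine <- function(query_best, db_species_set, config) {
  unref <- config$mode == "unreferenced"
  val_col <- if (unref) "bestu_val" else "best_val"
  sp_col <- if (unref) "bestu_species" else "best_species"
  ref_col <- if (unref) "bestu_ref" else "best_ref"
  qb <- query_best
  if (unref) {
    noref <- unique(qb$specimen_id[!qb$u_eligible])
    if (length(noref) > 0)
      # their best disabled-match is -Inf: always TN at a finite threshold
      message("unreferenced mode: specimen(s) whose species spans the whole ",
              "database (no eligible reference): ",
              paste(noref, collapse = ", "))
  }
  specimens <- sort(unique(qb$specimen_id))
  if (length(specimens) == 0L)
    stop_ccimatch("simulate: no evaluable specimens")
  by_spec <- lapply(specimens, function(s) {
    rows <- qb[qb$specimen_id == s, , drop = FALSE]
    rows[order(rows$spot_index), , drop = FALSE]
  })
  true_species <- vapply(by_spec, function(d) d$species[1L], character(1))
  referenced <- true_species %in% db_species_set
  samples <- matrix(NA_real_, config$n_repeats, 5,
                    dimnames = list(NULL, c("sensitivity", "specificity",
                                            "ppv", "npv", "accuracy")))
  counts <- matrix(0L, config$n_repeats, 4,
                   dimnames = list(NULL, c("TP", "TN", "FP", "FN")))
  for (r in seq_len(config$n_repeats)) {
    tp <- tn <- fp <- fn <- 0L
    for (s in seq_along(by_spec)) {
      d <- by_spec[[s]]
      k <- min(config$n_spots, nrow(d))
      pick <- with_seed(substream_seed(config$seed, r, s),
                        sample.int(nrow(d), k))
      vals <- d[[val_col]][pick]
      top <- which(vals == max(vals))
      if (length(top) > 1L) top <- top[order(d[[ref_col]][pick][top])][1L]
      v <- vals[top]
      hat <- d[[sp_col]][pick][top]
      identified <- v >= config$threshold
      if (unref) {
        # same-species matches are disabled: result is FP or TN by design
        if (identified) fp <- fp + 1L else tn <- tn + 1L
      } else if (identified) {
        if (identical(hat, true_species[s])) tp <- tp + 1L else fp <- fp + 1L
      } else {
        if (referenced[s]) fn <- fn + 1L else tn <- tn + 1L
      }
    }
    counts[r, ] <- c(tp, tn, fp, fn)
    samples[r, ] <- compute_metrics(tp, tn, fp, fn)
  }
  list(samples = samples, counts = counts, n_specimens = length(by_spec))
}

summarize_samples <- function(samples, config) {
  out <- lapply(colnames(samples), function(m) {
    v <- samples[, m]
    n_dropped <- sum(is.na(v))
    if (n_dropped == length(v))
      return(data.frame(metric = m, median = NA_real_, cri_low = NA_real_,
                        cri_high = NA_real_, n_repeats = length(v),
                        n_dropped = n_dropped))
    ci <- credible_interval(v)
    data.frame(metric = m, median = ci[["median"]], cri_low = ci[["low"]],
               cri_high = ci[["high"]], n_repeats = length(v),
               n_dropped = n_dropped)
  })
  out <- do.call(rbind, out)
  out$threshold <- config$threshold
  out$n_spots <- config$n_spots
  rownames(out) <- NULL
  out
}

#' Simulate identification performance over repeated spot draws
#'
#' Per repeat: sample `n_spots` spots per test specimen (without
#' replacement, one RNG substream per repeat x specimen), identify the
#' specimen by highest CCI, classify against the molecular label, and
#' compute metrics over the whole panel. Across repeats: median and
#' equal-tailed 95% credible interval per metric.
#'
#' @param test_panel a `reference_db`-like panel of labelled test spectra.
#' @param db the reference `reference_db`.
#' @param config a [simulation_config].
#' @param cci_cfg a [cci_config].
#' @param query_best optional precomputed table from [prepare_query_best]
#'   (computed if `NULL`).
#' @return an object of class `performance_estimate`: a data.frame of
#'   per-metric summaries, with per-repeat samples in
#'   `attr(, "samples")` and confusion counts in `attr(, "counts")`.
#' @export
simulate_performance <- function(test_panel, db,
                                 config = simulation_config(),
                                 cci_cfg = cci_config(),
                                 query_best = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  qb <- query_best %||% prepare_query_best(test_panel, db, cci_cfg)
  res <- simulate_engine(qb, db$species_set, config)
  out <- summarize_samples(res$samples, config)
  attr(out, "samples") <- res$samples
  attr(out, "counts") <- res$counts
  attr(out, "n_specimens") <- res$n_specimens
  class(out) <- c("performance_estimate", class(out))
  out
}

#' Specificity for queries of unreferenced species
#'
#' Runs the simulation with all same-species reference spectra disabled
#' for each query, so every result is forced to be FP or TN; the reported
#' specificity estimates the probability that a query of a species absent
#' from the database is (correctly) not identified.
#'
#' @inheritParams simulate_performance
#' @return a `performance_estimate` (the `specificity` row is the
#'   estimate of interest; sensitivity/ppv are undefined by construction).
#' @export
simulate_unreferenced_specificity <- function(test_panel, db,
                                              config = simulation_config(),
                                              cci_cfg = cci_config(),
                                              query_best = NULL) {
  config$mode <- "unreferenced"
  simulate_performance(test_panel, db, config, cci_cfg, query_best)
}

#' Sensitivity/specificity sweep over identification thresholds
#'
#' For each threshold, pairs the standard-mode sensitivity with the
#' unreferenced-mode specificity (medians and 95% CrIs), sharing the same
#' seed so spot draws are identical across thresholds and modes. This is
#' the ROC view of the identification pipeline.
#'
#' @param test_panel,db as in [simulate_performance].
#' @param thresholds numeric vector of log10(CCI) thresholds.
#' @param n_spots,n_repeats,seed simulation parameters.
#' @param cci_cfg a [cci_config].
#' @return data.frame, one row per threshold: sensitivity and specificity
#'   medians with CrI bounds.
#' @export
threshold_sweep <- function(test_panel, db, thresholds, n_spots = 1L,
                            n_repeats = 1000L, seed = 1L,
                            cci_cfg = cci_config()) {
  qb <- prepare_query_best(test_panel, db, cci_cfg)
  rows <- lapply(thresholds, function(thr) {
    cfg <- simulation_config(n_spots = n_spots, threshold = thr,
                             n_repeats = n_repeats, seed = seed)
    std <- simulate_performance(test_panel, db, cfg, cci_cfg, qb)
    unr <- simulate_unreferenced_specificity(test_panel, db, cfg, cci_cfg, qb)
    sens <- std[std$metric == "sensitivity", ]
    spec <- unr[unr$metric == "specificity", ]
    data.frame(threshold = thr,
               sensitivity = sens$median, sens_cri_low = sens$cri_low,
               sens_cri_high = sens$cri_high,
               specificity = spec$median, spec_cri_low = spec$cri_low,
               spec_cri_high = spec$cri_high)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
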