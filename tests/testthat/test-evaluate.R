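test_that("compute_metrics matches direct arithmetic", {
  m <- compute_metrics(96, 0, 0, 4)
  expect_equal(m[["sensitivity"]], 0.96)
  expect_equal(m[["accuracy"]], 0.96)
  expect_true(is.na(m[["specificity"]]))

  m <- compute_metrics(0, 10, 0, 0)
  expect_equal(m[["specificity"]], 1)
  expect_true(is.na(m[["sensitivity"]]))

  set.seed(17)
  for (rep in 1:25) {
    k <- sample(0:50, 4, replace = TRUE)
    if (sum(k) == 0) next
    m <- compute_metrics(k[1], k[2], k[3], k[4])
    ref <- c(if (k[1] + k[4] > 0) k[1] / (k[1] + k[4]) else NA,
             if (k[2] + k[3] > 0) k[2] / (k[2] + k[3]) else NA,
             if (k[1] + k[3] > 0) k[1] / (k[1] + k[3]) else NA,
             if (k[2] + k[4] > 0) k[2] / (k[2] + k[4]) else NA,
             (k[1] + k[2]) / sum(k))
    expect_equal(unname(m), ref)
  }
  expect_error(compute_metrics(0, 0, 0, 0), "no evaluated")
})

test_that("credible_interval follows the order-statistic definition", {
  ci <- credible_interval(rep(0.9, 50))
  expect_identical(unname(ci), c(0.9, 0.9, 0.9))

  samples <- seq(0, 1, length.out = 1000)
  ci <- credible_interval(samples)
  expect_equal(ci[["low"]], 0.025, tolerance = 1.5 / 999)
  expect_equal(ci[["high"]], 0.975, tolerance = 1.5 / 999)
  expect_equal(ci[["median"]], 0.5, tolerance = 1e-12)

  set.seed(2)
  x <- runif(37)
  ci <- credible_interval(x)
  expect_gte(ci[["low"]], min(x))
  expect_lte(ci[["high"]], max(x))
  expect_error(credible_interval(NA_real_), "no finite")
})

test_that("quantile_inf agrees with stats::quantile on finite data", {
  set.seed(5)
  x <- rnorm(101)
  p <- c(0.025, 0.25, 0.5, 0.975)
  expect_equal(quantile_inf(x, p), unname(quantile(x, p)), tolerance = 1e-12)
  # and orders -Inf below everything without producing NaN
  expect_identical(quantile_inf(c(-Inf, -Inf, -1), 0.5), -Inf)
  expect_identical(quantile_inf(c(-Inf, -4, -1), 0.5), -4)
})

test_that("the simulation is deterministic under the master seed", {
  w <- .mini_world()
  qb <- prepare_query_best(w$test, w$ref, w$cci_cfg)
  # a threshold inside the best-value distribution makes per-repeat
  # outcomes depend on the sampled spots, so seeds are distinguishable
  thr <- quantile_inf(qb$best_val, 0.5)
  cfg <- simulation_config(n_spots = 1, n_repeats = 25, seed = 7,
                           threshold = thr)
  a <- simulate_performance(w$test, w$ref, cfg, w$cci_cfg, qb)
  b <- simulate_performance(w$test, w$ref, cfg, w$cci_cfg, qb)
  expect_identical(attr(a, "samples"), attr(b, "samples"))
  expect_identical(as.data.frame(a), as.data.frame(b))
  cfg$seed <- 8L
  c3 <- simulate_performance(w$test, w$ref, cfg, w$cci_cfg, qb)
  expect_false(identical(attr(a, "samples"), attr(c3, "samples")))
})

test_that("a separable panel with all spots gives perfect metrics", {
  w <- .mini_world()
  spots <- max(w$test$meta$spot_index)
  est <- simulate_performance(w$test, w$ref,
                              simulation_config(n_spots = spots,
                                                n_repeats = 1, threshold = -14),
                              w$cci_cfg)
  df <- as.data.frame(est)
  expect_equal(df$median[df$metric == "sensitivity"], 1)
  expect_equal(df$median[df$metric == "accuracy"], 1)
  counts <- attr(est, "counts")
  expect_equal(sum(counts), nrow(counts) * attr(est, "n_specimens"))
})

test_that("per-repeat confusion counts always partition the panel", {
  w <- .mini_world()
  qb <- prepare_query_best(w$test, w$ref, w$cci_cfg)
  for (mode in c("standard", "unreferenced")) {
    est <- simulate_performance(w$test, w$ref,
                                simulation_config(n_repeats = 10, mode = mode),
                                w$cci_cfg, qb)
    counts <- attr(est, "counts")
    expect_true(all(rowSums(counts) == attr(est, "n_specimens")))
  }
})

test_that("unreferenced mode forces FP-or-TN and its boundary cases", {
  w <- .mini_world()
  # one-species database queried with its own species: all references
  # disabled, so every result is TN at any finite threshold
  keep <- w$ref$meta$species_label == "sp01"
  one <- w$ref
  one$intensities <- one$intensities[keep, , drop = FALSE]
  one$meta <- one$meta[keep, ]
  one$species_set <- "sp01"
  tkeep <- w$test$meta$species_label == "sp01"
  tq <- w$test
  tq$intensities <- tq$intensities[tkeep, , drop = FALSE]
  tq$meta <- tq$meta[tkeep, ]
  expect_message(
    est <- simulate_unreferenced_specificity(
      tq, one, simulation_config(n_repeats = 5, threshold = -14)),
    "spans the whole database")
  df <- as.data.frame(est)
  expect_equal(df$median[df$metric == "specificity"], 1)

  # threshold -Inf identifies everything (finite best): specificity 0
  est <- simulate_unreferenced_specificity(
    w$test, w$ref, simulation_config(n_repeats = 5, threshold = -Inf),
    w$cci_cfg)
  df <- as.data.frame(est)
  expect_equal(df$median[df$metric == "specificity"], 0)
  # no TP or FN can occur by construction: sensitivity undefined, ppv 0
  expect_true(is.na(df$median[df$metric == "sensitivity"]))
  expect_equal(df$median[df$metric == "ppv"], 0)
})

test_that("thresholds and spot counts move the metrics monotonically", {
  w <- .mini_world()
  qb <- prepare_query_best(w$test, w$ref, w$cci_cfg)
  thresholds <- c(-14, -13, -12, -6, -3)
  sens <- spec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    cfg <- simulation_config(n_repeats = 20, threshold = thresholds[i],
                             seed = 3)
    s1 <- as.data.frame(simulate_performance(w$test, w$ref, cfg, w$cci_cfg, qb))
    s2 <- as.data.frame(simulate_unreferenced_specificity(w$test, w$ref, cfg,
                                                          w$cci_cfg, qb))
    sens[i] <- s1$median[s1$metric == "sensitivity"]
    spec[i] <- s2$median[s2$metric == "specificity"]
  }
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))

  # sensitivity weakly increases with the number of spots
  sens_spots <- vapply(c(1, 2, 3), function(ns) {
    cfg <- simulation_config(n_spots = ns, n_repeats = 20, threshold = -6,
                             seed = 3)
    df <- as.data.frame(simulate_performance(w$test, w$ref, cfg, w$cci_cfg, qb))
    df$median[df$metric == "sensitivity"]
  }, numeric(1))
  expect_true(all(diff(sens_spots) >= 0))
})

test_that("threshold_sweep is consistent with single simulations", {
  w <- .mini_world()
  sw <- threshold_sweep(w$test, w$ref, c(-14, -6), n_spots = 1,
                        n_repeats = 15, seed = 11, cci_cfg = w$cci_cfg)
  expect_equal(nrow(sw), 2L)
  cfg <- simulation_config(n_spots = 1, n_repeats = 15, threshold = -14,
                           seed = 11)
  std <- as.data.frame(simulate_performance(w$test, w$ref, cfg, w$cci_cfg))
  expect_equal(sw$sensitivity[1], std$median[std$metric == "sensitivity"])
  unr <- as.data.frame(simulate_unreferenced_specificity(w$test, w$ref, cfg,
                                                         w$cci_cfg))
  expect_equal(sw$specificity[1], unr$median[unr$metric == "specificity"])
})

test_that("estimated accuracy covers the constructed truth across seeds", {
  # low-noise worlds are built to be perfectly separable (truth = 1);
  # the 95% CrI of the estimated accuracy must cover it in >= 90% of seeds
  covered <- 0L
  n_seeds <- 10L
  for (seed in seq_len(n_seeds)) {
    panels <- generate_panels(mini_gen_config(seed = 100L + seed))
    pp <- mini_pp_config()
    ref <- build_database(preprocess_spectra(panels$reference$spectra, pp),
                          panels$reference$meta)
    test <- build_database(preprocess_spectra(panels$test$spectra, pp),
                           panels$test$meta)
    est <- simulate_performance(test, ref,
                                simulation_config(n_repeats = 50, seed = seed),
                                mini_cci_config())
    df <- as.data.frame(est)
    acc <- df[df$metric == "accuracy", ]
    if (acc$cri_low <= 1 && acc$cri_high >= 1) covered <- covered + 1L
  }
  expect_gte(covered / n_seeds, 0.9)
})
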