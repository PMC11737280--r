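make_toy_db <- function(n_specimens = 2, spots = 2, species = rep("sp01", n_specimens),
                        prefix = "T", seed = 8) {
  set.seed(seed)
  tpls <- mini_templates()
  specs <- list()
  meta <- list()
  for (i in seq_len(n_specimens)) {
    tpl <- render_template(tpls[[match(species[i], c("sp01", "sp02", "sp03"))]],
                           mini_grid)
    for (k in seq_len(spots)) {
      id <- sprintf("%s%02d_%02d", prefix, i, k)
      specs[[length(specs) + 1L]] <-
        quick_processed(tpl + abs(rnorm(length(mini_grid), 0, 2)),
                        mini_grid, id)
      meta[[length(meta) + 1L]] <-
        data.frame(spectrum_id = id, specimen_id = sprintf("%s%02d", prefix, i),
                   spot_index = k, species_label = species[i],
                   panel = "reference")
    }
  }
  build_database(specs, do.call(rbind, meta))
}

test_that("build_database indexes spectra and validates labels", {
  db <- make_toy_db(2, 2)
  expect_equal(nrow(db$meta), 4L)
  expect_equal(length(unique(db$meta$specimen_id)), 2L)
  expect_identical(db$species_set, "sp01")

  bad_meta <- db$meta
  bad_meta$species_label[2] <- "sp02"  # same specimen, two labels
  specs <- lapply(seq_len(nrow(db$meta)), function(i)
    quick_processed(db$intensities[i, ], db$grid_mz, db$meta$spectrum_id[i]))
  expect_error(build_database(specs, bad_meta), "conflicting")

  # spectra without metadata are excluded with a warning
  expect_warning(db2 <- build_database(specs, db$meta[-1, ]), "without metadata")
  expect_equal(nrow(db2$meta), 3L)
})

test_that("a generated multi-species panel carries its species set", {
  cfg <- mini_gen_config(n_species = 5L, specimens_per_species = 1L,
                         spots_per_specimen = 1L)
  panels <- generate_panels(cfg)
  specs <- lapply(panels$reference$spectra, function(r)
    normalize_tic(resample_uniform(r, 1, 2500, 6500)))
  db <- build_database(specs, panels$reference$meta)
  expect_length(db$species_set, 5L)
})

test_that("pair enumeration counts and categories partition", {
  w <- .mini_world()
  # n = 2 -> 1 pair
  expect_equal(nrow(pair_index_table(w$ref$meta[1:2, ])), 1L)
  # n = 10 -> 45 pairs; categories partition them
  p10 <- pair_index_table(w$ref$meta[1:10, ])
  expect_equal(nrow(p10), 45L)
  expect_equal(sum(table(p10$category)), 45L)
  expect_true(all(p10$category %in%
                    c("replicate", "same_species", "different_species")))
  # full mini panel: n(n-1)/2
  n <- nrow(w$ref$meta)
  pairs <- all_pairs_cci(w$ref, w$cci_cfg)
  expect_equal(nrow(pairs), n * (n - 1) / 2)
})

test_that("cross_panel_cci yields the full query x reference product", {
  w <- .mini_world()
  ct <- cross_panel_cci(w$test, w$ref, w$cci_cfg)
  expect_equal(nrow(ct), nrow(w$test$meta) * nrow(w$ref$meta))
  # 7 x 13 product-count oracle on subsets
  q <- w$test
  q$intensities <- q$intensities[1:7, , drop = FALSE]
  q$meta <- q$meta[1:7, ]
  r <- w$ref
  r$intensities <- r$intensities[1:13, , drop = FALSE]
  r$meta <- r$meta[1:13, ]
  expect_equal(nrow(cross_panel_cci(q, r, w$cci_cfg)), 91L)
  r$intensities <- r$intensities[1, , drop = FALSE]
  r$meta <- r$meta[1, ]
  q$intensities <- q$intensities[1, , drop = FALSE]
  q$meta <- q$meta[1, ]
  expect_equal(nrow(cross_panel_cci(q, r, w$cci_cfg)), 1L)
})

test_that("summarize_similarity handles constants and -Inf medians", {
  p <- data.frame(category = rep("replicate", 3), log10cci = rep(-5, 3))
  s <- summarize_similarity(p)
  r <- s[s$category == "replicate", ]
  expect_identical(c(r$median_log10cci, r$iqr_low, r$iqr_high), c(-5, -5, -5))
  expect_equal(r$n_pairs, 3L)

  p <- data.frame(category = rep("different_species", 3),
                  log10cci = c(-Inf, -10, -2))
  s <- summarize_similarity(p)
  expect_identical(s$median_log10cci[s$category == "different_species"], -10)
  p$log10cci <- c(-Inf, -Inf, -2)
  s <- summarize_similarity(p)
  expect_identical(s$median_log10cci[s$category == "different_species"], -Inf)
  expect_equal(s$n_pairs[s$category == "replicate"], 0L)
})

test_that("the synthetic panel reproduces the similarity hierarchy", {
  w <- .mini_world()
  s <- summarize_similarity(all_pairs_cci(w$ref, w$cci_cfg))
  med <- setNames(s$median_log10cci, s$category)
  expect_gt(med[["replicate"]], med[["same_species"]])
  expect_gt(med[["same_species"]], med[["different_species"]])
})

test_that("specimen_median_matrix is symmetric with block structure", {
  w <- .mini_world()
  M <- specimen_median_matrix(w$ref, w$cci_cfg)
  expect_identical(M, t(M))
  meta <- w$ref$meta
  sp_of <- setNames(meta$species_label, meta$specimen_id)[rownames(M)]
  same_block <- outer(sp_of, sp_of, `==`) & upper.tri(M)
  diff_block <- !outer(sp_of, sp_of, `==`) & upper.tri(M)
  expect_gt(min(M[same_block]), max(M[diff_block]))
  # within-specimen medians (diagonal) dominate everything
  expect_gt(min(diag(M)), max(M[upper.tri(M)]))

  # single specimen, 3 spots: the 1x1 matrix holds the replicate median
  one <- make_toy_db(1, 3, prefix = "U")
  M1 <- specimen_median_matrix(one, w$cci_cfg)
  expect_equal(dim(M1), c(1L, 1L))
  pairs <- all_pairs_cci(one, w$cci_cfg)
  expect_equal(M1[1, 1], median(pairs$log10cci))
  expect_equal(nrow(pairs), 3L)
})

test_that("bank_to_bank_best_match respects disable flags", {
  w <- .mini_world()
  # two specimens of one species match each other: concordance 100%
  two <- make_toy_db(2, 2, prefix = "V")
  bm <- bank_to_bank_best_match(two, disable_self = TRUE,
                                disable_same_specimen = TRUE,
                                config = w$cci_cfg)
  expect_true(all(bm$same_species))
  expect_true(all(bm$eligible))

  # one-species database with same-species matching disabled: ineligible
  bm <- bank_to_bank_best_match(two, disable_same_species = TRUE,
                                config = w$cci_cfg)
  expect_false(any(bm$eligible))
  expect_true(all(is.na(bm$best_species)))

  # well-separated panel: species concordance >= 95%
  bm <- bank_to_bank_best_match(w$ref, disable_self = TRUE,
                                disable_same_specimen = TRUE,
                                config = w$cci_cfg)
  expect_gte(mean(bm$same_species), 0.95)
  expect_false(any(bm$singleton_species))
})

test_that("qc_filter removes low-repeatability spectra", {
  w <- .mini_world()
  # cutoff -Inf removes nothing
  out <- qc_filter(w$ref, -Inf, w$cci_cfg)
  expect_equal(nrow(out$db$meta), nrow(w$ref$meta))
  expect_false(any(out$report$removed))

  # cutoff 0 removes everything (with warnings about lost species)
  expect_warning(out <- qc_filter(w$ref, 0, w$cci_cfg), "removed every")
  expect_equal(nrow(out$db$meta), 0L)

  # a heavily corrupted spectrum is the one removed at a mid cutoff
  db <- w$ref
  set.seed(30)
  noise <- abs(rnorm(ncol(db$intensities), 0, 1))
  db$intensities[5, ] <- noise / sum(noise)
  rep_med <- qc_filter(db, -Inf, w$cci_cfg)$report$median_replicate_log10cci
  cutoff <- (sort(rep_med)[1] + sort(rep_med)[2]) / 2
  out <- qc_filter(db, cutoff, w$cci_cfg)
  expect_identical(out$report$spectrum_id[out$report$removed],
                   db$meta$spectrum_id[5])
})

test_that("merge_databases unions content and rejects collisions", {
  w <- .mini_world()
  a <- make_toy_db(2, 2, prefix = "A")
  b <- make_toy_db(3, 2, species = rep("sp02", 3), prefix = "B")
  ab <- merge_databases(a, b)
  expect_equal(nrow(ab$meta), nrow(a$meta) + nrow(b$meta))
  expect_identical(ab$species_set, c("sp01", "sp02"))
  expect_equal(length(unique(ab$meta$specimen_id)), 5L)

  # commutative in content
  ba <- merge_databases(b, a)
  expect_identical(sort(ba$meta$spectrum_id), sort(ab$meta$spectrum_id))
  expect_equal(ba$intensities[rownames(ab$intensities), ], ab$intensities)

  # identity under empty merge
  suppressWarnings(empty <- qc_filter(a, 0, w$cci_cfg)$db)
  expect_identical(merge_databases(a, empty)$meta, a$meta)

  expect_error(merge_databases(a, a), "collision")
})

test_that("save_database / load_database round trip", {
  db <- make_toy_db(2, 2, prefix = "W")
  dir <- withr::local_tempdir()
  save_database(db, dir)
  back <- load_database(dir)
  expect_equal(back$grid_mz, db$grid_mz)
  expect_identical(back$meta$spectrum_id, db$meta$spectrum_id)
  expect_equal(unname(back$intensities), unname(db$intensities),
               tolerance = 1e-12)
  expect_identical(back$species_set, db$species_set)
})
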