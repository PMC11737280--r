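# Small shared synthetic worlds for module tests. A reduced mass range
# (2500-6500 Da acquisition, CCI over 3000-6000 Da) keeps preprocessing
# cheap; the full-range defaults are exercised in test-acceptance.R.

mini_gen_config <- function(...) {
  defaults <- list(n_species = 3L, specimens_per_species = 2L,
                   test_specimens_per_species = 1L, spots_per_specimen = 3L,
                   seed = 42L, mz_min = 2500, mz_max = 6500)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

mini_pp_config <- function(...) {
  preprocess_config(grid_min = 2500, grid_max = 6500, ...)
}

mini_cci_config <- function(...) {
  cci_config(mass_min = 3000, mass_max = 6000, width = 500, ...)
}

# cached at helper scope: built once per test run
.mini_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panels <- generate_panels(mini_gen_config())
      pp <- mini_pp_config()
      ref <- build_database(preprocess_spectra(panels$reference$spectra, pp),
                            panels$reference$meta)
      test <- build_database(preprocess_spectra(panels$test$spectra, pp),
                             panels$test$meta)
      cache <<- list(panels = panels, ref = ref, test = test,
                     cci_cfg = mini_cci_config(), pp = pp)
    }
    cache
  }
})

# a quick processed spectrum from a rendered template (resample +
# normalize only; enough for CCI-level tests)
quick_processed <- function(intensity, grid, id) {
  s <- resample_uniform(raw_spectrum(grid, pmax(intensity, 0), id),
                        grid[2] - grid[1], grid[1], grid[length(grid)])
  normalize_tic(s)
}

mini_grid <- seq(2500, 6500, by = 1)

# noise-free species profiles on the mini grid
mini_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_species_templates(mini_gen_config())
    cache
  }
})
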