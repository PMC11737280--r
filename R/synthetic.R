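#' Synthetic-panel generator configuration
#'
#' The generator emulates the statistical structure the matching method
#' assumes: each species has a fixed protein-fingerprint template (a set
#' of Gaussian peaks), specimens of a species vary by multiplicative peak
#' height jitter, and technical replicates (spots) of a specimen vary by
#' additive detector noise, a per-spot mass-calibration drift and a
#' slowly varying chemical baseline.
#'
#' Defaults state a low-noise world: 10 species, 2 reference specimens and
#' 3 test specimens per species, 10 spots per specimen (as in standard
#' MALDI-TOF practice for arthropod fingerprinting), lognormal specimen
#' jitter sd 0.3, additive noise at 3% of the mean peak height, 1.5 Da
#' calibration drift and a baseline of ~20% of the mean peak height.
#'
#' @param n_species number of species templates.
#' @param specimens_per_species reference-panel specimens per species.
#' @param test_specimens_per_species test-panel specimens per species.
#' @param spots_per_specimen technical replicates per specimen (default 10).
#' @param specimen_jitter sd (log scale) of per-specimen peak-height
#'   multipliers.
#' @param spot_noise additive noise scale, relative to the mean peak height.
#' @param mass_drift sd of the per-spot mass-calibration shift (Da),
#'   truncated at +/-5 Da.
#' @param baseline_amplitude baseline height in raw intensity units (mean
#'   peak height is 100).
#' @param fraction_unreferenced share of species held out of the reference
#'   panel (their test specimens are queries of unreferenced species).
#' @param sibling_pair make species 1 and 2 a sibling pair sharing most
#'   peaks (emulating sibling species complexes).
#' @param max_template_cosine ceiling on pairwise cosine similarity of
#'   non-sibling templates.
#' @param seed master seed; generation is fully deterministic given it.
#' @param mz_min,mz_max,mz_step raw acquisition grid (Da).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_species = 10L, specimens_per_species = 2L,
                             test_specimens_per_species = 3L,
                             spots_per_specimen = 10L,
                             specimen_jitter = 0.3, spot_noise = 0.03,
                             mass_drift = 1.5, baseline_amplitude = 20,
                             fraction_unreferenced = 0,
                             sibling_pair = FALSE,
                             max_template_cosine = 0.7, seed = 1L,
                             mz_min = 2000, mz_max = 20000, mz_step = 1) {
  stopifnot(n_species >= 1L, specimens_per_species >= 1L,
            spots_per_specimen >= 1L, specimen_jitter >= 0, spot_noise >= 0,
            mass_drift >= 0, baseline_amplitude >= 0,
            fraction_unreferenced >= 0, fraction_unreferenced <= 1)
  structure(list(n_species = as.integer(n_species),
                 specimens_per_species = as.integer(specimens_per_species),
                 test_specimens_per_species =
                   as.integer(test_specimens_per_species),
                 spots_per_specimen = as.integer(spots_per_specimen),
                 specimen_jitter = specimen_jitter, spot_noise = spot_noise,
                 mass_drift = mass_drift,
                 baseline_amplitude = baseline_amplitude,
                 fraction_unreferenced = fraction_unreferenced,
                 sibling_pair = isTRUE(sibling_pair),
                 max_template_cosine = max_template_cosine,
                 seed = as.integer(seed),
                 mz_min = mz_min, mz_max = mz_max, mz_step = mz_step),
            class = "generator_config")
}

MEAN_PEAK_HEIGHT <- 100

# one species fingerprint: 1-3 peaks per 500 Da CCI interval (3000-12,000)
# plus a few peaks outside the CCI range, so every interval is informative.
random_template <- function(label) {
  lo <- seq(3000, 11500, by = 500)
  masses <- unlist(lapply(lo, function(l) {
    k <- sample.int(3L, 1L)
    sort(stats::runif(k, l + 25, l + 475))
  }))
  extra <- stats::runif(3L, 12500, 18000)
  masses <- sort(c(masses, extra))
  n <- length(masses)
  heights <- stats::rlnorm(n, meanlog = log(MEAN_PEAK_HEIGHT), sdlog = 0.5)
  widths <- 2 + 5e-4 * masses  # broader peaks at higher mass, linear-mode like
  structure(list(species_label = label, peak_masses = masses,
                 peak_heights = heights, peak_widths = widths),
            class = "species_template")
}

#' Render the noise-free profile of a species template
#'
#' Sum of Gaussian peaks on the acquisition grid; heights can be
#' modulated per peak and all peaks rigidly shifted in mass.
#'
#' @param template a `species_template`.
#' @param grid m/z grid (Da).
#' @param height_mult per-peak height multipliers (recycled).
#' @param mass_shift rigid shift in Da.
#' @return numeric intensity vector on `grid`.
#' @export
render_template <- function(template, grid, height_mult = 1, mass_shift = 0) {
  y <- numeric(length(grid))
  h <- rep_len(height_mult, length(template$peak_masses))
  step <- grid[2L] - grid[1L]
  for (p in seq_along(template$peak_masses)) {
    mu <- template$peak_masses[p] + mass_shift
    sd <- template$peak_widths[p]
    i0 <- max(1L, floor((mu - 6 * sd - grid[1L]) / step) + 1L)
    i1 <- min(length(grid), ceiling((mu + 6 * sd - grid[1L]) / step) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    y[idx] <- y[idx] +
      template$peak_heights[p] * h[p] * exp(-0.5 * ((grid[idx] - mu) / sd)^2)
  }
  y
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

#' Generate species fingerprint templates
#'
#' Seeded and reproducible. Non-sibling templates are regenerated (up to
#' 25 attempts each) until all pairwise cosine similarities of their
#' rendered profiles fall below `config$max_template_cosine`. With
#' `sibling_pair = TRUE`, species 2 is derived from species 1 by
#' re-drawing ~20% of its peaks, so the pair is much more similar than
#' any other pair (sibling-complex emulation) and exempt from the ceiling.
#'
#' @param config a [generator_config].
#' @return list of `species_template` (labels `sp01`, `sp02`, ...).
#' @export
make_species_templates <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    grid <- seq(config$mz_min, config$mz_max, by = 2)
    labels <- sprintf("sp%02d", seq_len(config$n_species))
    templates <- list()
    profiles <- list()
    for (s in seq_len(config$n_species)) {
      if (config$sibling_pair && s == 2L) {
        templates[[2L]] <- sibling_of(templates[[1L]], labels[2L])
        profiles[[2L]] <- render_template(templates[[2L]], grid)
        next
      }
      ok <- FALSE
      for (try in seq_len(25L)) {
        cand <- random_template(labels[s])
        prof <- render_template(cand, grid)
        others <- if (config$sibling_pair && s > 2L)
          profiles[-2L] else profiles
        sims <- vapply(others, cosine_sim, numeric(1), b = prof)
        if (all(sims < config$max_template_cosine)) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop_ccimatch("make_species_templates: could not satisfy cosine ",
                      "ceiling ", config$max_template_cosine)
      templates[[s]] <- cand
      profiles[[s]] <- prof
    }
    templates
  })
}

sibling_of <- function(template, label) {
  n <- length(template$peak_masses)
  redraw <- sample.int(n, max(1L, round(0.2 * n)))
  masses <- template$peak_masses
  masses[redraw] <- masses[redraw] + stats::runif(length(redraw), -120, 120)
  o <- order(masses)
  structure(list(species_label = label, peak_masses = masses[o],
                 peak_heights = (template$peak_heights *
                                   stats::rlnorm(n, 0, 0.2))[o],
                 peak_widths = (2 + 5e-4 * masses)[o]),
            class = "species_template")
}

#' Generate one raw spectrum from a template
#'
#' Peak heights x specimen multipliers, rigid per-spot mass drift, a
#' slowly varying polynomial baseline and non-negative (zero-truncated
#' Gaussian) additive noise, sampled on the acquisition grid. With all
#' effects zero, returns the pure template profile. Noise is drawn from
#' the current RNG stream.
#'
#' @param template a `species_template`.
#' @param specimen_effects per-peak height multipliers (default 1).
#' @param spot_effects list with `mass_shift` (Da), `noise_scale`
#'   (raw units) and `baseline_amplitude` (raw units), all default 0.
#' @param config a [generator_config] (grid definition).
#' @param spectrum_id identifier.
#' @return a [raw_spectrum].
#' @export
generate_spectrum <- function(template, specimen_effects = 1,
                              spot_effects = list(), config = generator_config(),
                              spectrum_id = template$species_label) {
  shift <- spot_effects$mass_shift %||% 0
  noise_scale <- spot_effects$noise_scale %||% 0
  base_amp <- spot_effects$baseline_amplitude %||% 0
  grid <- seq(config$mz_min, config$mz_max, by = config$mz_step)
  y <- render_template(template, grid, specimen_effects, shift)
  if (base_amp > 0) {
    u <- (grid - config$mz_min) / (config$mz_max - config$mz_min)
    y <- y + base_amp * (1 - 1.6 * u + 0.66 * u^2)
  }
  if (noise_scale > 0)
    y <- y + pmax(stats::rnorm(length(grid), 0, noise_scale), 0)
  raw_spectrum(grid, y, spectrum_id)
}

#' Generate labelled reference and test panels
#'
#' Builds the species templates, assigns disjoint specimens to the
#' reference and test panels, holds `fraction_unreferenced` of the
#' species out of the reference panel entirely, and renders every spot's
#' raw spectrum. Fully deterministic under `config$seed`.
#'
#' @param config a [generator_config].
#' @return an object of class `synthetic_panels`: lists `reference` and
#'   `test` (each with `spectra`, a list of [raw_spectrum], and `meta`),
#'   plus `templates` and `unreferenced_species`.
#' @export
generate_panels <- function(config = generator_config()) {
  templates <- make_species_templates(config)
  n_unref <- round(config$fraction_unreferenced * config$n_species)
  unref <- if (n_unref > 0)
    vapply(templates, `[[`, character(1), "species_label") |>
      utils::tail(n_unref) else character(0)
  if (n_unref == config$n_species && config$test_specimens_per_species > 0)
    warning("every test species is unreferenced: no true positive possible",
            call. = FALSE)
  with_seed(substream_seed(config$seed, 1L, 1L), {
    make_panel <- function(panel, n_specimens) {
      spectra <- list()
      meta <- list()
      for (s in seq_along(templates)) {
        tpl <- templates[[s]]
        if (panel == "reference" && tpl$species_label %in% unref) next
        for (sp in seq_len(n_specimens)) {
          specimen_id <- sprintf("%s_%s_%02d",
                                 toupper(substr(panel, 1, 3)),
                                 tpl$species_label, sp)
          mult <- stats::rlnorm(length(tpl$peak_masses), 0,
                                config$specimen_jitter)
          for (spot in seq_len(config$spots_per_specimen)) {
            drift <- max(-5, min(5, stats::rnorm(1, 0, config$mass_drift)))
            eff <- list(mass_shift = drift,
                        noise_scale = config$spot_noise * MEAN_PEAK_HEIGHT,
                        baseline_amplitude =
                          config$baseline_amplitude * stats::runif(1, 0.8, 1.2))
            sid <- sprintf("%s_%02d", specimen_id, spot)
            spectra[[length(spectra) + 1L]] <-
              generate_spectrum(tpl, mult, eff, config, sid)
            meta[[length(meta) + 1L]] <-
              data.frame(spectrum_id = sid, specimen_id = specimen_id,
                         spot_index = spot,
                         species_label = tpl$species_label, panel = panel,
                         stringsAsFactors = FALSE)
          }
        }
      }
      if (length(meta) == 0L)
        meta <- list(data.frame(spectrum_id = character(),
                                specimen_id = character(),
                                spot_index = integer(),
                                species_label = character(),
                                panel = character()))
      list(spectra = spectra, meta = do.call(rbind, meta))
    }
    structure(list(reference = make_panel("reference",
                                          config$specimens_per_species),
                   test = make_panel("test",
                                     config$test_specimens_per_species),
                   templates = templates, unreferenced_species = unref,
                   config = config),
              class = "synthetic_panels")
  })
}

#' @export
print.synthetic_panels <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_panels: %d species (%d unreferenced), ",
                     "%d reference + %d test spectra>\n"),
              x$config$n_species, length(x$unreferenced_species),
              length(x$reference$spectra), length(x$test$spectra)))
  invisible(x)
}
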