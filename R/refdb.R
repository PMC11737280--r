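#' Build a labelled reference (or test) spectra database
#'
#' Bundles preprocessed spectra with their metadata. Spectra without a
#' metadata record, and metadata rows without a spectrum, are dropped with
#' a warning naming them; a specimen carrying two different species labels
#' is a consistency error.
#'
#' @param spectra list of `processed_spectrum` on a common grid.
#' @param meta metadata data.frame (see [read_metadata]).
#' @return an object of class `reference_db` with fields `intensities`
#'   (spectra x grid matrix), `grid_mz`, `meta` and `species_set`.
#' @export
build_database <- function(spectra, meta) {
  meta <- validate_metadata(meta)
  sm <- spectra_matrix(spectra)
  ids <- rownames(sm$intensities)
  no_meta <- setdiff(ids, meta$spectrum_id)
  if (length(no_meta) > 0)
    warning("spectra without metadata excluded: ",
            paste(no_meta, collapse = ", "), call. = FALSE)
  no_spec <- setdiff(meta$spectrum_id, ids)
  if (length(no_spec) > 0)
    warning("metadata without spectra dropped: ",
            paste(no_spec, collapse = ", "), call. = FALSE)
  keep <- intersect(ids, meta$spectrum_id)
  if (length(keep) == 0L) stop_ccimatch("build_database: no usable spectra")
  meta <- meta[match(keep, meta$spectrum_id), , drop = FALSE]
  rownames(meta) <- NULL
  bad <- tapply(meta$species_label, meta$specimen_id,
                function(x) length(unique(x)) > 1L)
  if (any(bad))
    stop_ccimatch("specimen(s) with conflicting species labels: ",
                  paste(names(bad)[bad], collapse = ", "))
  structure(list(intensities = sm$intensities[keep, , drop = FALSE],
                 grid_mz = sm$grid_mz, meta = meta,
                 species_set = sort(unique(meta$species_label))),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db: %d spectra, %d specimens, %d species>\n",
              nrow(x$meta), length(unique(x$meta$specimen_id)),
              length(x$species_set)))
  spp <- table(tapply(x$meta$species_label, x$meta$specimen_id, `[`, 1L))
  cat("  specimens per species:",
      paste(sprintf("%s=%d", names(spp), spp), collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate all distinct unordered spectrum pairs with their category
#'
#' Pure metadata operation (no CCI computed): yields exactly
#' `n * (n - 1) / 2` rows for `n` spectra, each categorized as
#' `replicate` (same specimen), `same_species` (different specimens of one
#' species) or `different_species` -- the three categories partition all
#' pairs.
#'
#' @param meta metadata data.frame with one row per spectrum.
#' @return data.frame with `id_a`, `id_b` (indices `i < j` in `meta`
#'   order) and `category`.
#' @export
pair_index_table <- function(meta) {
  n <- nrow(meta)
  if (n < 2L) return(data.frame(id_a = character(), id_b = character(),
                                category = character()))
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  same_specimen <- meta$specimen_id[i] == meta$specimen_id[j]
  same_species <- meta$species_label[i] == meta$species_label[j]
  category <- ifelse(same_specimen, "replicate",
                     ifelse(same_species, "same_species", "different_species"))
  data.frame(id_a = meta$spectrum_id[i], id_b = meta$spectrum_id[j],
             category = category, stringsAsFactors = FALSE)
}

#' log10(CCI) of every distinct unordered spectrum pair in a database
#'
#' @param db a `reference_db`.
#' @param config a [cci_config].
#' @return data.frame: `id_a`, `id_b`, `category`, `log10cci`, with
#'   exactly `n(n-1)/2` rows.
#' @export
all_pairs_cci <- function(db, config = cci_config()) {
  pairs <- pair_index_table(db$meta)
  M <- cci_cross_matrix(db$intensities, NULL, db$grid_mz, config)
  ia <- match(pairs$id_a, rownames(M))
  ib <- match(pairs$id_b, rownames(M))
  pairs$log10cci <- M[cbind(ia, ib)]
  pairs
}

#' log10(CCI) of every query spectrum against every reference spectrum
#'
#' @param queries a `reference_db`-like panel of query spectra, or a list
#'   of `processed_spectrum`.
#' @param db the reference `reference_db`.
#' @param config a [cci_config].
#' @return data.frame: `id_query`, `id_reference`, `log10cci`, with
#'   exactly `n_query * n_reference` rows.
#' @export
cross_panel_cci <- function(queries, db, config = cci_config()) {
  q <- if (inherits(queries, "reference_db"))
    list(intensities = queries$intensities, grid_mz = queries$grid_mz)
  else spectra_matrix(queries)
  if (max(abs(q$grid_mz - db$grid_mz)) > 1e-9)
    stop_ccimatch("cross_panel_cci: incompatible grids")
  M <- cci_cross_matrix(q$intensities, db$intensities, db$grid_mz, config)
  data.frame(id_query = rep(rownames(M), times = ncol(M)),
             id_reference = rep(colnames(M), each = nrow(M)),
             log10cci = as.vector(M), stringsAsFactors = FALSE)
}

#' Summarize pairwise similarity by pair category
#'
#' Median and interquartile range of log10(CCI) per category, with `-Inf`
#' ordered below all finite values (a median landing on `-Inf` is reported
#' as `-Inf`). Categories measure repeatability (replicate pairs),
#' reproducibility (same-species pairs) and specificity
#' (different-species pairs).
#'
#' @param pairs data.frame from [all_pairs_cci] (columns `category`,
#'   `log10cci`).
#' @return data.frame: `category`, `median_log10cci`, `iqr_low`,
#'   `iqr_high`, `n_pairs`.
#' @export
summarize_similarity <- function(pairs) {
  cats <- c("replicate", "same_species", "different_species")
  out <- lapply(cats, function(cat) {
    v <- pairs$log10cci[pairs$category == cat]
    if (length(v) == 0L)
      return(data.frame(category = cat, median_log10cci = NA_real_,
                        iqr_low = NA_real_, iqr_high = NA_real_, n_pairs = 0L))
    qs <- quantile_inf(v, c(0.25, 0.5, 0.75))
    data.frame(category = cat, median_log10cci = qs[2L], iqr_low = qs[1L],
               iqr_high = qs[3L], n_pairs = length(v))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Median log10(CCI) matrix collated by specimen
#'
#' Symmetric specimen x specimen matrix of median pairwise log10(CCI);
#' the diagonal holds within-specimen (technical replicate) medians. This
#' is the heat-map statistic summarizing repeatability (diagonal),
#' reproducibility (within-species blocks) and specificity (off-blocks).
#'
#' @param db a `reference_db`.
#' @param config a [cci_config].
#' @return numeric matrix with specimen ids as dimnames.
#' @export
specimen_median_matrix <- function(db, config = cci_config()) {
  pairs <- all_pairs_cci(db, config)
  spec_of <- stats::setNames(db$meta$specimen_id, db$meta$spectrum_id)
  sa <- spec_of[pairs$id_a]
  sb <- spec_of[pairs$id_b]
  # order each specimen pair canonically so (A,B) and (B,A) pool together
  lo <- pmin(sa, sb)
  hi <- pmax(sa, sb)
  dt <- data.table::data.table(lo = lo, hi = hi, v = pairs$log10cci)
  agg <- dt[, list(med = quantile_inf(v, 0.5)), by = c("lo", "hi")]
  specimens <- sort(unique(db$meta$specimen_id))
  M <- matrix(NA_real_, length(specimens), length(specimens),
              dimnames = list(specimens, specimens))
  i <- match(agg$lo, specimens)
  j <- match(agg$hi, specimens)
  M[cbind(i, j)] <- agg$med
  M[cbind(j, i)] <- agg$med
  M
}

#' Best match of every database spectrum against the rest of the database
#'
#' For each spectrum, the other database spectrum with the highest CCI,
#' subject to the disable flags; ties broken by lexicographic spectrum id.
#' Records whether the match is the spectrum's own species and flags
#' species represented by a single specimen (which cannot self-match once
#' same-specimen comparisons are disabled).
#'
#' @param db a `reference_db`.
#' @param disable_self exclude the spectrum itself (default `TRUE`).
#' @param disable_same_specimen exclude technical replicates of the same
#'   specimen.
#' @param disable_same_species exclude all spectra of the same species
#'   (unreferenced-query emulation).
#' @param config a [cci_config].
#' @return data.frame: `spectrum_id`, `species`, `best_spectrum_id`,
#'   `best_species`, `best_log10cci`, `same_species`, `singleton_species`,
#'   `eligible`.
#' @export
bank_to_bank_best_match <- function(db, disable_self = TRUE,
                                    disable_same_specimen = FALSE,
                                    disable_same_species = FALSE,
                                    config = cci_config()) {
  M <- cci_cross_matrix(db$intensities, NULL, db$grid_mz, config)
  meta <- db$meta
  ord <- order(meta$spectrum_id)  # lexicographic tie-break
  n_specimens <- tapply(meta$specimen_id, meta$species_label,
                        function(x) length(unique(x)))
  out <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    elig <- rep(TRUE, nrow(meta))
    if (disable_self) elig[i] <- FALSE
    if (disable_same_specimen)
      elig[meta$specimen_id == meta$specimen_id[i]] <- FALSE
    if (disable_same_species)
      elig[meta$species_label == meta$species_label[i]] <- FALSE
    rec <- data.frame(spectrum_id = meta$spectrum_id[i],
                      species = meta$species_label[i],
                      best_spectrum_id = NA_character_,
                      best_species = NA_character_,
                      best_log10cci = NA_real_, same_species = NA,
                      singleton_species =
                        n_specimens[[meta$species_label[i]]] == 1L,
                      eligible = any(elig), stringsAsFactors = FALSE)
    if (any(elig)) {
      cand <- ord[elig[ord]]
      j <- cand[which.max(M[i, cand])]
      rec$best_spectrum_id <- meta$spectrum_id[j]
      rec$best_species <- meta$species_label[j]
      rec$best_log10cci <- M[i, j]
      rec$same_species <- meta$species_label[j] == meta$species_label[i]
    }
    out[[i]] <- rec
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Filter out spectra with low technical repeatability
#'
#' Computes, for each spectrum, the median log10(CCI) over its replicate
#' pairs (other spots of the same specimen) and removes spectra below the
#' cutoff. Warns when a species loses all of its spectra.
#'
#' @param db a `reference_db`.
#' @param replicate_median_cutoff log10(CCI) cutoff; `-Inf` keeps all.
#' @param config a [cci_config].
#' @return list with `db` (filtered `reference_db`) and `report`
#'   (data.frame: `spectrum_id`, `median_replicate_log10cci`, `removed`).
#' @export
qc_filter <- function(db, replicate_median_cutoff, config = cci_config()) {
  meta <- db$meta
  med <- rep(NA_real_, nrow(meta))
  for (sp in unique(meta$specimen_id)) {
    idx <- which(meta$specimen_id == sp)
    if (length(idx) < 2L) next
    M <- cci_cross_matrix(db$intensities[idx, , drop = FALSE], NULL,
                          db$grid_mz, config)
    for (k in seq_along(idx))
      med[idx[k]] <- quantile_inf(M[k, -k], 0.5)
  }
  removed <- !is.na(med) & med < replicate_median_cutoff
  report <- data.frame(spectrum_id = meta$spectrum_id,
                       median_replicate_log10cci = med,
                       removed = removed, stringsAsFactors = FALSE)
  lost <- setdiff(db$species_set,
                  unique(meta$species_label[!removed]))
  if (length(lost) > 0)
    warning("qc_filter removed every spectrum of: ",
            paste(lost, collapse = ", "), call. = FALSE)
  keep <- meta$spectrum_id[!removed]
  filtered <- db
  filtered$intensities <- db$intensities[keep, , drop = FALSE]
  filtered$meta <- meta[!removed, , drop = FALSE]
  rownames(filtered$meta) <- NULL
  filtered$species_set <- sort(unique(filtered$meta$species_label))
  list(db = filtered, report = report)
}

#' Merge two databases (database upgrade)
#'
#' Union of spectra and metadata; grids must match and spectrum ids must
#' be disjoint. Content is commutative in the inputs.
#'
#' @param db_a,db_b `reference_db` objects on the same grid.
#' @return the merged `reference_db`.
#' @export
merge_databases <- function(db_a, db_b) {
  if (nrow(db_b$meta) == 0L) return(db_a)
  if (length(db_a$grid_mz) != length(db_b$grid_mz) ||
      max(abs(db_a$grid_mz - db_b$grid_mz)) > 1e-9)
    stop_ccimatch("merge_databases: incompatible grids")
  clash <- intersect(db_a$meta$spectrum_id, db_b$meta$spectrum_id)
  if (length(clash) > 0)
    stop_ccimatch("merge_databases: spectrum id collision: ",
                  paste(clash, collapse = ", "))
  meta <- rbind(db_a$meta, db_b$meta)
  bad <- tapply(meta$species_label, meta$specimen_id,
                function(x) length(unique(x)) > 1L)
  if (any(bad))
    stop_ccimatch("merge_databases: conflicting species labels for: ",
                  paste(names(bad)[bad], collapse = ", "))
  out <- db_a
  out$intensities <- rbind(db_a$intensities, db_b$intensities)
  out$meta <- meta
  rownames(out$meta) <- NULL
  out$species_set <- sort(unique(meta$species_label))
  out
}

#' Persist a database to a directory
#'
#' Writes `grid.json` (grid definition), `meta.tsv` and `intensities.tsv`
#' (one row per spectrum, full precision) -- all plain text.
#'
#' @param db a `reference_db`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_database <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(grid_min = db$grid_mz[1L],
                            grid_max = db$grid_mz[length(db$grid_mz)],
                            grid_step = db$grid_mz[2L] - db$grid_mz[1L],
                            n_points = length(db$grid_mz)),
                       file.path(dir, "grid.json"), auto_unbox = TRUE,
                       digits = NA)
  data.table::fwrite(db$meta, file.path(dir, "meta.tsv"), sep = "\t")
  wide <- data.table::data.table(spectrum_id = rownames(db$intensities))
  wide <- cbind(wide, data.table::as.data.table(db$intensities))
  data.table::fwrite(wide, file.path(dir, "intensities.tsv"), sep = "\t")
  invisible(dir)
}

#' Load a database written by [save_database]
#' @param dir database directory.
#' @return a `reference_db`.
#' @export
load_database <- function(dir) {
  if (!file.exists(file.path(dir, "grid.json")))
    stop_ccimatch("not a database directory (no grid.json): ", dir)
  g <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  meta <- read_metadata(file.path(dir, "meta.tsv"))
  wide <- data.table::fread(file.path(dir, "intensities.tsv"), sep = "\t")
  ids <- as.character(wide[[1L]])
  M <- as.matrix(wide[, -1L, with = FALSE])
  dimnames(M) <- list(ids, NULL)
  grid <- seq(g$grid_min, by = g$grid_step, length.out = g$n_points)
  structure(list(intensities = M, grid_mz = grid,
                 meta = meta[match(ids, meta$spectrum_id), , drop = FALSE],
                 species_set = sort(unique(meta$species_label))),
            class = "reference_db")
}
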