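#' Identify one specimen from its replicate spectra
#'
#' The identification result is the reference spectrum giving the highest
#' CCI over all (selected spot x reference spectrum) pairs. The specimen
#' is `identified` iff the best log10(CCI) is at or above the threshold
#' (a value exactly at the threshold identifies); otherwise
#' `no_identification` and no species is reported. Ties are broken by
#' lexicographic reference spectrum id.
#'
#' @param spectra list of `processed_spectrum` (the selected spots of one
#'   specimen), or a single `processed_spectrum`.
#' @param db a `reference_db`.
#' @param threshold identification threshold on the log10(CCI) scale
#'   (default -14).
#' @param config a [cci_config].
#' @return an object of class `match_result`: `spots_used`,
#'   `best_reference_spectrum_id`, `best_species`, `best_log10cci`,
#'   `decision`.
#' @export
identify_specimen <- function(spectra, db, threshold = -14,
                              config = cci_config()) {
  if (inherits(spectra, "processed_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L, nrow(db$meta) >= 1L)
  q <- spectra_matrix(spectra)
  M <- cci_cross_matrix(q$intensities, db$intensities, db$grid_mz, config)
  ord <- order(db$meta$spectrum_id)
  best_val <- -Inf
  best_j <- ord[1L]
  best_row <- 1L
  for (i in seq_len(nrow(M))) {
    j <- ord[which.max(M[i, ord])]
    if (M[i, j] > best_val) {
      best_val <- M[i, j]
      best_j <- j
      best_row <- i
    }
  }
  # decision is a plain >= on the log10 scale: a value exactly at the
  # threshold identifies; -Inf only identifies at threshold -Inf
  identified <- best_val >= threshold
  structure(list(spots_used = rownames(q$intensities),
                 best_reference_spectrum_id =
                   if (identified) db$meta$spectrum_id[best_j] else NA_character_,
                 best_species =
                   if (identified) db$meta$species_label[best_j] else NA_character_,
                 best_log10cci = best_val,
                 decision = if (identified) "identified" else "no_identification"),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %s%s, best log10(CCI) = %.3f, %d spot(s)>\n",
              x$decision,
              if (x$decision == "identified")
                paste0(" as ", x$best_species) else "",
              x$best_log10cci, length(x$spots_used)))
  invisible(x)
}

#' Classify an identification result against the molecular reference
#'
#' With PCR species as truth: `TP` = identified as the true species;
#' `FP` = identified as another species; `TN` = not identified and the
#' true species is absent from the database; `FN` = not identified but
#' the true species is referenced.
#'
#' @param match a `match_result` (or any list with `decision` and
#'   `best_species`).
#' @param true_species the molecularly determined species label.
#' @param db_species_set species labels present in the reference database.
#' @return one of `"TP"`, `"TN"`, `"FP"`, `"FN"`.
#' @export
classify_result <- function(match, true_species, db_species_set) {
  identified <- identical(match$decision, "identified")
  if (identified) {
    if (identical(match$best_species, true_species)) "TP" else "FP"
  } else {
    if (true_species %in% db_species_set) "FN" else "TN"
  }
}
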