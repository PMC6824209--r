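#' Build a benchmark query set from spectral and biological-source tables
#'
#' Joins a structure--spectrum table with a structure--source table on the
#' 14-character short InChIKey and applies the benchmark eligibility rules:
#' structures associated with more than one distinct lineage are dropped
#' entirely (the benchmark requires a *unique* biological source per
#' structure); lineages not complete down to the species level (empty family,
#' genus or species) are dropped; and multiple spectra of the same structure
#' are collapsed to one query, keeping the first by input order and recording
#' the discarded spectrum ids.
#'
#' @param spectral_table data frame with columns `spectrum_id`, `short_ik`
#'   (full InChIKeys accepted) and optionally `precursor_mz`.
#' @param source_table data frame with `short_ik` plus lineage columns
#'   (dedicated or pipe-delimited `lineage`).
#' @return a list with `queries` (a query tibble: `query_id`,
#'   `true_short_ik`, lineage columns, `parent_mass`), `report` (named counts
#'   at each step) and `discarded_spectra` (spectrum ids dropped at the
#'   collapse step).
#' @export
build_benchmark <- function(spectral_table, source_table) {
  spectral_table <- tibble::as_tibble(spectral_table)
  source_table <- tibble::as_tibble(source_table)
  stopifnot(all(c("spectrum_id", "short_ik") %in% names(spectral_table)),
            "short_ik" %in% names(source_table))

  spectral_table$short_ik <- shorten_inchikey(spectral_table$short_ik)
  src <- dplyr::bind_cols(
    tibble::tibble(short_ik = shorten_inchikey(source_table$short_ik)),
    extract_lineage_cols(source_table))
  src <- dplyr::distinct(src)

  report <- c(spectra_in = nrow(spectral_table), structures_in_sources =
                length(unique(src$short_ik)))

  # unique-biological-source rule: any structure with >1 distinct lineage out
  n_lineages <- table(src$short_ik)
  ambiguous <- names(n_lineages)[n_lineages > 1L]
  src <- src[!src$short_ik %in% ambiguous, , drop = FALSE]
  report["dropped_ambiguous_source"] <- length(ambiguous)

  # sources must be complete down to the species level
  complete <- nzchar(src$family) & nzchar(src$genus) & nzchar(src$species)
  report["dropped_incomplete_lineage"] <- sum(!complete)
  src <- src[complete, , drop = FALSE]

  joined <- dplyr::inner_join(spectral_table, src, by = "short_ik")
  report["spectra_joined"] <- nrow(joined)

  # one query per structure: first spectrum by input order
  first <- !duplicated(joined$short_ik)
  discarded <- joined$spectrum_id[!first]
  joined <- joined[first, , drop = FALSE]
  report["dropped_duplicate_spectra"] <- length(discarded)
  report["queries_out"] <- nrow(joined)

  queries <- tibble::tibble(
    query_id = as.character(joined$spectrum_id),
    true_short_ik = joined$short_ik,
    parent_mass = if ("precursor_mz" %in% names(joined))
      joined$precursor_mz else NA_real_,
    molecular_formula = NA_character_
  )
  queries <- dplyr::bind_cols(queries, joined[lineage_ranks])
  list(queries = queries, report = report, discarded_spectra = discarded)
}
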