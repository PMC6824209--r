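#' @importFrom dplyr arrange bind_rows distinct filter group_by left_join
#'   mutate n rename row_number select semi_join slice summarise ungroup
#' @importFrom tidyr nest unnest
NULL

candidate_dialects <- c("generic", "isdb", "msfinder", "sirius")

# column-name aliases accepted on ingestion, first match wins
query_id_aliases <- c("query_id", "cluster_id", "clusterid", "ccmslib",
                      "spectrum_id")
ik_aliases <- c("candidate_short_ik", "short_inchikey", "short_ik",
                "inchikey", "inchi_key")
score_aliases <- c("raw_score", "score", "spectral_score")

find_column <- function(nms, aliases) {
  hit <- match(aliases, tolower(nms))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Shorten an InChIKey to its 14-character connectivity block
#'
#' The first 14 characters of an InChIKey hash the molecular connectivity
#' without stereochemistry and are the join key used throughout the package
#' (stereoisomers are not distinguishable from MS/MS spectra). Accepts either
#' a full 27-character key (`XXXXXXXXXXXXXX-XXXXXXXXXX-X`) or an already
#' shortened 14-character block; idempotent.
#'
#' @param ik character vector of InChIKeys.
#' @return character vector of 14-character short keys.
#' @examples
#' shorten_inchikey("MUMCCPUVOAUBAN-UHFFFAOYSA-N")  # "MUMCCPUVOAUBAN"
#' @export
shorten_inchikey <- function(ik) {
  ik <- toupper(trimws(as.character(ik)))
  full <- grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", ik)
  short <- grepl("^[A-Z]{14}$", ik)
  bad <- !(full | short)
  if (any(bad)) {
    stop("not a valid InChIKey (full or 14-character short form): ",
         paste(utils::head(ik[bad], 5L), collapse = ", "), call. = FALSE)
  }
  substr(ik, 1L, 14L)
}

# turn flat rows with lineage columns (or a pipe-delimited `lineage` column)
# into per-row lineage tibbles; missing columns become empty strings
extract_lineage_cols <- function(df) {
  if ("lineage" %in% names(df) && !any(lineage_ranks %in% names(df))) {
    parts <- strsplit(ifelse(is.na(df$lineage), "", df$lineage), "|",
                      fixed = TRUE)
    mat <- t(vapply(parts, function(p) {
      p <- c(p, rep("", 7L))[1:7]
      canonicalize_name(p)
    }, character(7L)))
    colnames(mat) <- lineage_ranks
    return(tibble::as_tibble(mat))
  }
  out <- tibble::tibble(.rows = nrow(df))
  for (rk in lineage_ranks) {
    out[[rk]] <- if (rk %in% names(df)) canonicalize_name(df[[rk]]) else
      rep("", nrow(df))
  }
  out
}

# nest per-source lineage rows into a `sources` list-column so that
# (query_id, candidate_short_ik) pairs become unique
nest_sources <- function(df) {
  lin <- extract_lineage_cols(df)
  flat <- dplyr::bind_cols(
    df[setdiff(names(df), c(lineage_ranks, "lineage"))], lin)
  has_source <- rowSums(matrix(nzchar(as.matrix(lin)), nrow = nrow(lin))) > 0
  keys <- c("query_id", "candidate_short_ik")
  meta <- flat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::all_of(lineage_ranks))
  src <- flat[has_source, c(keys, lineage_ranks)]
  nested <- src |>
    dplyr::distinct() |>
    tidyr::nest(sources = dplyr::all_of(lineage_ranks))
  out <- dplyr::left_join(meta, nested, by = keys)
  empty <- tibble::as_tibble(stats::setNames(
    as.list(rep(list(character(0)), 7L)), lineage_ranks))
  out$sources <- lapply(out$sources, function(s) s %||% empty)
  out
}

#' Read a candidate-annotation table
#'
#' Reads a delimited UTF-8 file with one row per query--candidate(--source)
#' triple into the standardized candidate tibble: `query_id`,
#' `candidate_short_ik`, `raw_score`, `tool`, `molecule_name` and a `sources`
#' list-column of lineage tibbles. Full InChIKeys are shortened on the fly;
#' rows whose score does not parse as a number are rejected with row-numbered
#' diagnostics; duplicate (query, candidate) rows are merged, pooling their
#' source lineages.
#'
#' All supported dialects (`isdb`, `msfinder`, `sirius`, `generic`) score
#' higher-is-better after ingestion; Sirius' probabilistic scores are
#' negative-to-zero but already ordered that way, so no transform is applied.
#'
#' @param path delimited text file (TSV by default, CSV by extension or
#'   `delim = ","`). Lineages come either as seven dedicated columns
#'   (`kingdom` ... `species`) or as a single pipe-delimited `lineage` column.
#' @param dialect one of `"generic"`, `"isdb"`, `"msfinder"`, `"sirius"`.
#' @param delim field delimiter override.
#' @return a candidate tibble, one row per (query, candidate) pair.
#' @export
read_candidates <- function(path, dialect = "generic", delim = NULL) {
  if (!is.character(dialect) || length(dialect) != 1L ||
      !dialect %in% candidate_dialects) {
    stop("unknown dialect '", paste(dialect, collapse = ","),
         "'; valid dialects: ", paste(candidate_dialects, collapse = ", "),
         call. = FALSE)
  }
  df <- read_delim_table(path, delim)
  nms <- names(df)
  iq <- find_column(nms, query_id_aliases)
  ik <- find_column(nms, ik_aliases)
  is <- find_column(nms, score_aliases)
  if (is.na(iq)) stop("missing mandatory column: query id (one of ",
                      paste(query_id_aliases, collapse = ", "), ")",
                      call. = FALSE)
  if (is.na(ik)) stop("missing mandatory column: short InChIKey (one of ",
                      paste(ik_aliases, collapse = ", "), ")", call. = FALSE)
  if (is.na(is)) stop("missing mandatory column: score (one of ",
                      paste(score_aliases, collapse = ", "), ")",
                      call. = FALSE)
  score <- suppressWarnings(as.numeric(df[[is]]))
  bad <- is.na(score)
  if (any(bad)) {
    warning("rejected ", sum(bad), " row(s) with unparseable score ",
            "(data row ", paste(utils::head(which(bad), 10L), collapse = ", "),
            ")", call. = FALSE)
  }
  name_col <- find_column(nms, c("molecule_name", "molecule", "name"))
  flat <- tibble::tibble(
    query_id = as.character(df[[iq]]),
    candidate_short_ik = shorten_inchikey(df[[ik]]),
    raw_score = score,
    tool = dialect,
    molecule_name = if (is.na(name_col)) NA_character_ else
      as.character(df[[name_col]])
  )
  flat <- dplyr::bind_cols(flat, extract_lineage_cols(df))
  flat <- flat[!bad, , drop = FALSE]
  nest_sources(flat)
}

#' Write a candidate table
#'
#' Inverse of [read_candidates()]: unnests the `sources` list-column back to
#' one row per (query, candidate, source), writing dedicated lineage columns.
#' Candidates without any recorded source get a single row with empty lineage
#' fields.
#'
#' @param x a candidate tibble.
#' @param path output path (TSV by default, CSV by extension).
#' @param delim field delimiter override.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(x, path, delim = NULL) {
  rows <- lapply(seq_len(nrow(x)), function(i) {
    src <- x$sources[[i]]
    if (is.null(src) || nrow(src) == 0L) {
      src <- tibble::as_tibble(stats::setNames(as.list(rep("", 7L)),
                                               lineage_ranks))
    }
    dplyr::bind_cols(
      x[rep(i, nrow(src)), setdiff(names(x), "sources"), drop = FALSE], src)
  })
  write_delim_table(dplyr::bind_rows(rows), path, delim)
}

#' Read a query-metadata table
#'
#' Columns: `query_id`, `true_short_ik` (may be empty outside benchmarking),
#' the query organism lineage (dedicated columns or pipe-delimited `lineage`),
#' and optional `parent_mass` and `molecular_formula`.
#'
#' @param path delimited text file.
#' @param delim field delimiter override.
#' @return a query tibble, one row per query spectrum.
#' @export
read_queries <- function(path, delim = NULL) {
  df <- read_delim_table(path, delim)
  iq <- find_column(names(df), query_id_aliases)
  if (is.na(iq)) stop("missing mandatory column: query id", call. = FALSE)
  ik_col <- find_column(names(df), c("true_short_ik", "true_inchikey"))
  truth <- if (is.na(ik_col)) rep("", nrow(df)) else {
    raw <- ifelse(is.na(df[[ik_col]]) | df[[ik_col]] == "", "",
                  df[[ik_col]])
    ifelse(nzchar(raw), vapply(raw, function(k)
      if (nzchar(k)) shorten_inchikey(k) else "", character(1L),
      USE.NAMES = FALSE), "")
  }
  out <- tibble::tibble(
    query_id = as.character(df[[iq]]),
    true_short_ik = truth,
    parent_mass = if ("parent_mass" %in% names(df))
      suppressWarnings(as.numeric(df$parent_mass)) else NA_real_,
    molecular_formula = if ("molecular_formula" %in% names(df))
      as.character(df$molecular_formula) else NA_character_
  )
  out <- dplyr::bind_cols(out, extract_lineage_cols(df))
  if (anyDuplicated(out$query_id)) {
    stop("duplicated query_id in query table", call. = FALSE)
  }
  out
}

#' Write a query-metadata table
#'
#' @param x a query tibble as returned by [read_queries()].
#' @param path output path.
#' @param delim field delimiter override.
#' @return `path`, invisibly.
#' @export
write_queries <- function(x, path, delim = NULL) {
  write_delim_table(x, path, delim)
}
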