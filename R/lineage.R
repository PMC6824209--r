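#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

#' Names of the taxonomic ranks carried by a lineage, from kingdom to species
#'
#' Only `family`, `genus` and `species` participate in scoring; the upper
#' ranks are carried for provenance and reporting.
#'
#' @export
lineage_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
                   "species")

# ranks that can earn a taxonomic bonus, shallow to deep
score_ranks <- c("family", "genus", "species")

#' Canonicalize a taxon name
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space, and maps placeholder tokens (`"NA"`, `"N/A"`, `"-"`, `""`,
#' and `NA`) to the empty string, which throughout the package means "unknown
#' at this rank". The display form (capitalisation) is preserved; use
#' [name_key()] for the case-insensitive comparison form.
#'
#' @param x character vector of raw names.
#' @return character vector of the same length, canonical display form.
#' @examples
#' canonicalize_name("  Glaucium  ")   # "Glaucium"
#' canonicalize_name(c("NA", "n/a"))   # c("", "")
#' @export
canonicalize_name <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- gsub("\\s+", " ", trimws(x))
  x[toupper(x) %in% c("", "NA", "N/A", "-")] <- ""
  x
}

#' Case-folded comparison key of a taxon name
#'
#' Two names refer to the same taxon for matching purposes iff their keys are
#' equal and non-empty.
#'
#' @param x character vector of names (raw or canonical).
#' @return lower-cased canonical form.
#' @export
name_key <- function(x) {
  tolower(canonicalize_name(x))
}

#' Construct a resolved taxonomic lineage
#'
#' A lineage is a named character vector over the seven ranks in
#' [lineage_ranks]. Empty strings mean the rank is unknown (or deliberately
#' degraded). When both `genus` and `species` are given, the first
#' whitespace-separated token of the species binomial must equal the genus.
#'
#' @param kingdom,phylum,class,order,family,genus,species rank names; any may
#'   be omitted or empty.
#' @return a `taxon_lineage`: named character vector of length 7.
#' @examples
#' taxon_lineage(family = "Papaveraceae", genus = "Glaucium",
#'               species = "Glaucium grandiflorum")
#' @export
taxon_lineage <- function(kingdom = "", phylum = "", class = "", order = "",
                          family = "", genus = "", species = "") {
  out <- canonicalize_name(c(kingdom, phylum, class, order, family, genus,
                             species))
  names(out) <- lineage_ranks
  if (nzchar(out[["species"]]) && nzchar(out[["genus"]])) {
    first_token <- strsplit(out[["species"]], " ", fixed = TRUE)[[1L]][1L]
    if (name_key(first_token) != name_key(out[["genus"]])) {
      stop("binomial inconsistency: species '", out[["species"]],
           "' does not start with genus '", out[["genus"]], "'",
           call. = FALSE)
    }
  }
  structure(out, class = c("taxon_lineage", "character"))
}

#' @export
print.taxon_lineage <- function(x, ...) {
  shown <- ifelse(nzchar(x), x, "?")
  cat("<taxon_lineage> ", paste(shown, collapse = " | "), "\n", sep = "")
  invisible(x)
}

# Coerce a lineage-like thing (taxon_lineage, named vector, 1-row data frame)
# to a plain named character vector over lineage_ranks.
as_lineage_fields <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- unlist(x[intersect(names(x), lineage_ranks)])
  }
  out <- stats::setNames(rep("", length(lineage_ranks)), lineage_ranks)
  got <- intersect(names(x), lineage_ranks)
  if (length(got) == 0L && length(x) == length(lineage_ranks)) {
    # unnamed length-7 vector, assume rank order
    out[] <- canonicalize_name(x)
    return(out)
  }
  out[got] <- canonicalize_name(x[got])
  out
}

#' Exact per-level match between two biological sources
#'
#' Compares two lineages at the family, genus and species levels. A level
#' matches iff both sides are non-empty there and equal under the
#' case-insensitive comparison form ([name_key()]); an unknown (empty) rank on
#' either side never matches. Species are compared as full binomial strings.
#'
#' @param query,source lineages ([taxon_lineage()] or anything coercible).
#' @return named logical vector `c(family=, genus=, species=)`.
#' @examples
#' q <- taxon_lineage(family = "Papaveraceae", genus = "Glaucium",
#'                    species = "Glaucium grandiflorum")
#' s <- taxon_lineage(family = "Papaveraceae", genus = "Glaucium",
#'                    species = "Glaucium oxylobum")
#' match_levels(q, s)  # family TRUE, genus TRUE, species FALSE
#' @export
match_levels <- function(query, source) {
  q <- name_key(as_lineage_fields(query)[score_ranks])
  s <- name_key(as_lineage_fields(source)[score_ranks])
  stats::setNames(nzchar(q) & nzchar(s) & q == s, score_ranks)
}

#' Taxonomic bonus of a candidate given its recorded biological sources
#'
#' Each scoring rank (family, genus, species) earns its weight if *any* of
#' the candidate's recorded sources matches the query organism exactly at
#' that rank; the bonus actually added to the spectral score is the maximum
#' over the three ranks (the score of the shortest taxonomic distance).
#'
#' @param query the query organism's lineage.
#' @param sources a list of lineages, or a data frame with lineage columns
#'   (one row per recorded source). May be empty.
#' @param weights a [weight_vector()].
#' @return named numeric vector
#'   `c(family_score=, genus_score=, species_score=, max_taxo_score=)`.
#' @examples
#' q <- taxon_lineage(family = "Papaveraceae", genus = "Glaucium",
#'                    species = "Glaucium grandiflorum")
#' s <- taxon_lineage(family = "Papaveraceae", genus = "Glaucium",
#'                    species = "Glaucium oxylobum")
#' taxonomic_bonus(q, list(s), weight_vector(0.81, 1.62, 2.55))
#' # family 0.81, genus 1.62, species 0, max 1.62
#' @export
taxonomic_bonus <- function(query, sources, weights = default_weights()) {
  weights <- as_weight_vector(weights)
  if (is.data.frame(sources)) {
    sources <- split_lineage_rows(sources)
  }
  hit <- c(family = FALSE, genus = FALSE, species = FALSE)
  for (src in sources) {
    hit <- hit | match_levels(query, src)
    if (all(hit)) break
  }
  per_level <- ifelse(hit, unclass(weights), 0)
  c(family_score  = per_level[["family"]],
    genus_score   = per_level[["genus"]],
    species_score = per_level[["species"]],
    max_taxo_score = max(per_level, 0))
}

# split a data frame with lineage columns into a list of named vectors
split_lineage_rows <- function(df) {
  if (nrow(df) == 0L) return(list())
  cols <- intersect(lineage_ranks, names(df))
  lapply(seq_len(nrow(df)), function(i) {
    unlist(df[i, cols, drop = FALSE])
  })
}

#' Resolve a raw organism name against a local taxonomy table
#'
#' Offline replacement for name-resolution services: the table maps both
#' accepted names and synonyms to an accepted name and its full lineage.
#' Lookup is on the case-insensitive canonical form.
#'
#' @param raw_name the name to resolve.
#' @param taxonomy_table a data frame with columns `input_name`,
#'   `accepted_name` and the seven [lineage_ranks] (see [read_taxonomy()]).
#' @return a list of class `lineage_resolution` with fields `resolved`
#'   (logical), `input` (the raw name), `accepted_name` and `lineage`
#'   (a [taxon_lineage()], or `NULL` when unresolved). Unknown names are an
#'   explicit unresolved outcome, not an error: the caller decides whether to
#'   drop the record or keep it with an empty lineage.
#' @export
resolve_lineage <- function(raw_name, taxonomy_table) {
  stopifnot(is.data.frame(taxonomy_table),
            all(c("input_name", "accepted_name") %in% names(taxonomy_table)))
  key <- name_key(raw_name)
  idx <- match(key, name_key(taxonomy_table$input_name))
  if (is.na(idx) || !nzchar(key)) {
    return(structure(list(resolved = FALSE, input = raw_name,
                          accepted_name = NA_character_, lineage = NULL),
                     class = "lineage_resolution"))
  }
  row <- taxonomy_table[idx, ]
  lin <- do.call(taxon_lineage, as.list(as_lineage_fields(row)))
  structure(list(resolved = TRUE, input = raw_name,
                 accepted_name = canonicalize_name(row$accepted_name),
                 lineage = lin),
            class = "lineage_resolution")
}

#' @export
print.lineage_resolution <- function(x, ...) {
  if (x$resolved) {
    cat("<resolved> ", x$input, " -> ", x$accepted_name, "\n", sep = "")
    print(x$lineage)
  } else {
    cat("<unresolved> ", x$input, "\n", sep = "")
  }
  invisible(x)
}

#' Read a taxonomy table
#'
#' Tab-separated UTF-8 file with header columns `input_name`, `accepted_name`,
#' `kingdom`, `phylum`, `class`, `order`, `family`, `genus`, `species`; one
#' row per input name, synonyms repeating the accepted lineage.
#'
#' @param path file path.
#' @return a tibble with canonicalized name columns.
#' @export
read_taxonomy <- function(path) {
  df <- read_delim_table(path, delim = "\t")
  need <- c("input_name", "accepted_name", lineage_ranks)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("taxonomy table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df[need] <- lapply(df[need], canonicalize_name)
  as_tibble(df[need])
}

#' Write a taxonomy table
#'
#' @param x a taxonomy tibble as returned by [read_taxonomy()] or
#'   [generate_taxonomy()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(x, path) {
  write_delim_table(x, path)
}
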