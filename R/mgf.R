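#' Read a Mascot Generic Format (MGF) spectral library
#'
#' Line-oriented parser for `BEGIN IONS`/`END IONS` blocks with `KEY=value`
#' headers and `m/z intensity` peak lines; tolerant of blank lines and `#`
#' comment lines between and inside blocks. Recognised headers: `TITLE`,
#' `PEPMASS` (first token), `ADDUCT` (or `ION`), `IONMODE`, `NAME`, `SCANS`,
#' `SPECTRUMID`, `SMILES`, `INCHI`. The spectrum identifier is `SPECTRUMID`
#' if present, else `SCANS`, else `TITLE`.
#'
#' @param path MGF file.
#' @return a spectra tibble with columns `spectrum_id`, `precursor_mz`,
#'   `adduct`, `name`, `smiles`, `inchi` and a `peaks` list-column of
#'   two-column tibbles (`mz`, `intensity`), peaks sorted by m/z.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  entries <- lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    is_header <- grepl("=", block, fixed = TRUE) &
      !grepl("^[0-9.+-]", block)
    headers <- block[is_header]
    kv <- regmatches(headers, regexpr("=", headers, fixed = TRUE),
                     invert = TRUE)
    keys <- toupper(vapply(kv, `[`, character(1L), 1L))
    vals <- trimws(vapply(kv, `[`, character(1L), 2L))
    get <- function(k) {
      i <- match(k, keys)
      if (is.na(i)) NA_character_ else vals[i]
    }
    peak_lines <- block[!is_header]
    peaks <- if (length(peak_lines) > 0L) {
      mat <- do.call(rbind, lapply(strsplit(peak_lines, "[ \t]+"), function(p)
        as.numeric(p[1:2])))
      tibble::tibble(mz = mat[, 1L], intensity = mat[, 2L])
    } else {
      tibble::tibble(mz = numeric(0), intensity = numeric(0))
    }
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    pep <- get("PEPMASS")
    tibble::tibble(
      spectrum_id = get("SPECTRUMID") %|na|% get("SCANS") %|na|% get("TITLE"),
      precursor_mz = if (is.na(pep)) NA_real_ else
        as.numeric(strsplit(pep, "[ \t]+")[[1L]][1L]),
      adduct = get("ADDUCT") %|na|% get("ION"),
      ionmode = get("IONMODE"),
      name = get("NAME"),
      smiles = get("SMILES"),
      inchi = get("INCHI"),
      peaks = list(peaks)
    )
  })
  dplyr::bind_rows(entries)
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Write spectra to a Mascot Generic Format file
#'
#' @param x a spectra tibble as returned by [read_mgf()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(x, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines("BEGIN IONS", con)
    put <- function(key, val) {
      if (!is.null(val) && length(val) == 1L && !is.na(val) && nzchar(val)) {
        writeLines(paste0(key, "=", val), con)
      }
    }
    put("SPECTRUMID", x$spectrum_id[i])
    put("TITLE", x$spectrum_id[i])
    put("PEPMASS", format(x$precursor_mz[i], digits = 10))
    put("ADDUCT", x$adduct[i])
    if ("ionmode" %in% names(x)) put("IONMODE", x$ionmode[i])
    if ("name" %in% names(x)) put("NAME", x$name[i])
    if ("smiles" %in% names(x)) put("SMILES", x$smiles[i])
    if ("inchi" %in% names(x)) put("INCHI", x$inchi[i])
    pk <- x$peaks[[i]]
    pk <- pk[order(pk$mz), , drop = FALSE]
    if (nrow(pk) > 0L) {
      writeLines(paste(format(pk$mz, digits = 10, trim = TRUE),
                       format(pk$intensity, digits = 10, trim = TRUE)), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

# does the entry carry an explicit protonated-adduct annotation?
is_protonated <- function(x) {
  fields <- c(x$adduct, x$name, x$spectrum_id)
  fields <- fields[!is.na(fields)]
  any(grepl("[M+H]+", fields, fixed = TRUE)) ||
    any(name_key(fields) %in% c("m+h", "[m+h]", "m + h"))
}

#' Filter a spectral library for benchmarking
#'
#' Applies the standard curation rules for building an MS/MS benchmark from
#' heterogeneous public libraries: spectra with fewer than `min_fragments`
#' peaks are dropped; spectra with more than `max_fragments` peaks are
#' truncated to the `max_fragments` most intense (ties at the cutoff keep the
#' lower-m/z peak, a deterministic rule); precursor masses must lie within
#' `[mass_low, mass_high]` Da; and, when `protonated_only`, entries without an
#' explicit `[M+H]+` adduct annotation are dropped.
#'
#' @param entries spectra tibble from [read_mgf()].
#' @param min_fragments minimum peak count (default 6).
#' @param max_fragments maximum retained peak count (default 500).
#' @param mass_low,mass_high precursor window in Da (default 100--1500).
#' @param protonated_only keep only `[M+H]+` entries (default `TRUE`).
#' @return a list with `spectra` (the kept, possibly truncated entries, peaks
#'   re-sorted by m/z) and `report`, a named integer vector counting `input`,
#'   `dropped_min_fragments`, `dropped_mass_range`, `dropped_adduct`,
#'   `truncated` and `kept`. The drop counts plus `kept` sum to `input`.
#' @export
filter_spectra <- function(entries, min_fragments = 6L, max_fragments = 500L,
                           mass_low = 100, mass_high = 1500,
                           protonated_only = TRUE) {
  n <- nrow(entries)
  report <- c(input = n, dropped_min_fragments = 0L, dropped_mass_range = 0L,
              dropped_adduct = 0L, truncated = 0L, kept = 0L)
  if (n == 0L) {
    return(list(spectra = entries, report = report))
  }
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    npk <- nrow(entries$peaks[[i]])
    if (npk < min_fragments) {
      keep[i] <- FALSE
      report["dropped_min_fragments"] <- report["dropped_min_fragments"] + 1L
      next
    }
    pm <- entries$precursor_mz[i]
    if (is.na(pm) || pm < mass_low || pm > mass_high) {
      keep[i] <- FALSE
      report["dropped_mass_range"] <- report["dropped_mass_range"] + 1L
      next
    }
    if (protonated_only && !is_protonated(entries[i, ])) {
      keep[i] <- FALSE
      report["dropped_adduct"] <- report["dropped_adduct"] + 1L
      next
    }
    if (npk > max_fragments) {
      pk <- entries$peaks[[i]]
      sel <- order(-pk$intensity, pk$mz)[seq_len(max_fragments)]
      pk <- pk[sel, , drop = FALSE]
      entries$peaks[[i]] <- pk[order(pk$mz), , drop = FALSE]
      report["truncated"] <- report["truncated"] + 1L
    }
  }
  out <- entries[keep, , drop = FALSE]
  report["kept"] <- nrow(out)
  list(spectra = out, report = report)
}
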