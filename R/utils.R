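# shared internal helpers

# round half away from zero (the printed-percentage convention: 84.75 -> 84.8),
# unlike base round()'s round-half-even
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# delimiter from a path extension unless given explicitly
infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- infer_delim(path, delim)
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = "",
                          fileEncoding = "UTF-8", colClasses = "character")
  tibble::as_tibble(df)
}

write_delim_table <- function(x, path, delim = NULL) {
  delim <- infer_delim(path, delim)
  utils::write.table(x, path, sep = delim, quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}
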