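# monoisotopic masses of principal isotopes (CODATA/IUPAC values)
monoisotopic_masses <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Cl = 34.96885271,
  Br = 78.9183376,
  F  = 18.99840320,
  I  = 126.904468,
  Na = 22.98976928,
  K  = 38.96370649,
  Si = 27.97692653,
  B  = 11.00930536,
  Se = 79.9165218
)

#' Mass of a proton in Da
#' @export
proton_mass <- 1.007276

#' Monoisotopic mass of a molecular formula
#'
#' Parses a Hill-notation molecular formula (e.g. `"C32H49NO9"`) and returns
#' the sum of count times principal-isotope mass over the shipped element
#' table (C, H, N, O, P, S, halogens and a few common others).
#'
#' @param formula a single formula string.
#' @return monoisotopic mass in Da.
#' @examples
#' formula_monoisotopic_mass("C32H49NO9")  # 591.3407
#' formula_monoisotopic_mass("C6H12O6")    # 180.0634
#' @export
formula_monoisotopic_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  f <- gsub("[ _]", "", formula)
  if (!nzchar(f)) {
    stop("empty molecular formula", call. = FALSE)
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1L]]
  parts <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1L]]
  if (sum(attr(tokens, "match.length")) != nchar(f)) {
    stop("malformed molecular formula: '", formula, "'", call. = FALSE)
  }
  total <- 0
  for (p in parts) {
    elem <- sub("[0-9]+$", "", p)
    cnt_str <- sub("^[A-Za-z]+", "", p)
    cnt <- if (nzchar(cnt_str)) as.integer(cnt_str) else 1L
    if (!elem %in% names(monoisotopic_masses)) {
      stop("unknown element symbol '", elem, "' in formula '", formula, "'",
           call. = FALSE)
    }
    total <- total + cnt * monoisotopic_masses[[elem]]
  }
  total
}

#' Flag entries whose experimental parent mass contradicts their formula
#'
#' Compares the experimental precursor m/z of a (protonated) spectrum entry
#' with the exact `[M+H]+` mass computed from its molecular formula
#' (monoisotopic mass plus the proton mass, 1.007276 Da). Entries whose
#' absolute difference exceeds `tolerance` (strictly) are flagged as
#' problematic library entries that no annotation tool can match correctly.
#'
#' @param precursor_mz experimental parent ion m/z in Da (or a spectra-tibble
#'   row, from which `precursor_mz` is taken).
#' @param formula molecular formula of the documented structure.
#' @param tolerance flagging threshold in Da (default 0.01).
#' @return a list with `flagged` (logical), `difference` (signed
#'   observed - expected, Da) and `expected_mz`.
#' @examples
#' flag_parent_mass_mismatch(632.386, "C32H49NO9")  # flagged, ~ +40 Da
#' @export
flag_parent_mass_mismatch <- function(precursor_mz, formula,
                                      tolerance = 0.01) {
  if (is.data.frame(precursor_mz)) {
    precursor_mz <- precursor_mz$precursor_mz
  }
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L)
  expected <- formula_monoisotopic_mass(formula) + proton_mass
  diff <- precursor_mz - expected
  # strict inequality, with a 1e-9 Da guard so values sitting exactly on the
  # threshold are not flagged through floating-point noise
  list(flagged = abs(diff) - tolerance > 1e-9, difference = diff,
       expected_mz = expected)
}
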