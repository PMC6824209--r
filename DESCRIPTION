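Package: taxoscore
Title: Taxonomically Informed Scoring for MS/MS Metabolite Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-ranks candidate structures returned by computational MS/MS
    metabolite annotation tools by combining their normalized spectral scores
    with a chemotaxonomic bonus that reflects the taxonomic distance (family,
    genus, species) between the biological source of the queried spectrum and
    the recorded sources of each candidate structure. Includes readers for
    standardized candidate tables and MGF spectral libraries, benchmark-set
    construction utilities (short-InChIKey joins, spectrum filtering,
    parent-mass quality control), precision/recall/F1 benchmarking with
    multi-tool overlap summaries, per-level weight optimization through
    randomized metadata degradation, and a synthetic data generator with
    controlled chemotaxonomic signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
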