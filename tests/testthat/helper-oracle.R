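# Brute-force re-ranking oracle: insertion sort with the pairwise comparator
# written straight from the ranking definition (higher combined score first;
# ties by better initial rank, then lexicographic short InChIKey). Kept
# independent of the package's vectorized order() path.
oracle_rerank <- function(df) {
  before <- function(i, j) {
    if (df$combined_score[i] != df$combined_score[j]) {
      return(df$combined_score[i] > df$combined_score[j])
    }
    if (df$initial_rank[i] != df$initial_rank[j]) {
      return(df$initial_rank[i] < df$initial_rank[j])
    }
    df$candidate_short_ik[i] < df$candidate_short_ik[j]
  }
  idx <- integer(0)
  for (i in seq_len(nrow(df))) {
    pos <- 1L
    while (pos <= length(idx) && before(idx[pos], i)) pos <- pos + 1L
    idx <- append(idx, i, after = pos - 1L)
  }
  out <- df[idx, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  out
}

# random scored candidate list for oracle comparisons; ties are made likely
# by drawing scores from a coarse grid
random_scored_candidates <- function(n) {
  norm <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
  bonus <- sample(c(0, 1, 2, 3), n, replace = TRUE)
  ord <- order(-norm, seq_len(n))
  initial <- integer(n)
  initial[ord] <- seq_len(n)
  tibble::tibble(
    query_id = "q",
    candidate_short_ik = replicate(n, paste(sample(LETTERS[1:4], 14,
                                                   replace = TRUE),
                                            collapse = "")),
    normalized_score = norm,
    max_taxo_score = bonus,
    combined_score = norm + bonus,
    initial_rank = initial
  )
}

# a tiny lineage shorthand for tests
lin <- function(family = "", genus = "", species = "") {
  taxon_lineage(family = family, genus = genus, species = species)
}
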