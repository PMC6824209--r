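#' Configuration of the synthetic benchmark generator
#'
#' Describes a controlled chemotaxonomic world: a balanced plant-like
#' taxonomy, a set of benchmark queries each with one true candidate and
#' several decoys, tunable spectral-score noise, and probabilistic control of
#' how often the true candidate's recorded biological source matches the
#' query organism at exactly the species, genus or family depth -- and of how
#' often decoys share the query's family or genus (congeneric and confamilial
#' decoys are what make the per-level weights compete).
#'
#' The defaults emulate the statistical shape of a real natural-product
#' benchmark: sources documented mostly to the species level, the correct
#' candidate usually outranked spectrally by a moderate margin
#' (`true_score_deficit`), and plant-family-level chemical overlap among
#' candidates.
#'
#' @param seed integer generator seed.
#' @param n_families,genera_per_family,species_per_genus taxonomy shape
#'   (defaults 8 x 4 x 4 = 128 species).
#' @param n_queries number of benchmark queries (default 80).
#' @param candidates_per_query candidates returned per query, true candidate
#'   included (default 5).
#' @param p_true_source_species,p_true_source_genus,p_true_source_family
#'   probabilities that the true candidate's recorded source matches the
#'   query organism at exactly that depth (defaults 0.55 / 0.25 / 0.10; the
#'   remainder is an unrelated source). Must sum to at most 1.
#' @param p_decoy_match probability a decoy's source shares the query's
#'   family without sharing its genus (default 0.30).
#' @param p_decoy_genus probability a decoy's source shares the query's genus
#'   (a different species; implies sharing the family; default 0.15).
#'   `p_decoy_match + p_decoy_genus` must be at most 1.
#' @param score_noise_sd Gaussian noise on the true candidate's raw score
#'   (default 0.10).
#' @param true_score_deficit how far the true candidate's raw score sits
#'   below the best decoy's, in the decoys' uniform(0, 1) raw-score units
#'   (default 0.30).
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_families = 8L, genera_per_family = 4L,
                              species_per_genus = 4L,
                              n_queries = 80L, candidates_per_query = 5L,
                              p_true_source_species = 0.55,
                              p_true_source_genus = 0.25,
                              p_true_source_family = 0.10,
                              p_decoy_match = 0.30,
                              p_decoy_genus = 0.15,
                              score_noise_sd = 0.10,
                              true_score_deficit = 0.30) {
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              genera_per_family = as.integer(genera_per_family),
              species_per_genus = as.integer(species_per_genus),
              n_queries = as.integer(n_queries),
              candidates_per_query = as.integer(candidates_per_query),
              p_true_source_species = p_true_source_species,
              p_true_source_genus = p_true_source_genus,
              p_true_source_family = p_true_source_family,
              p_decoy_match = p_decoy_match,
              p_decoy_genus = p_decoy_genus,
              score_noise_sd = score_noise_sd,
              true_score_deficit = true_score_deficit)
  counts <- c("n_families", "genera_per_family", "species_per_genus",
              "n_queries", "candidates_per_query")
  if (any(vapply(cfg[counts], function(x) x < 1L, logical(1L)))) {
    stop("all counts must be positive", call. = FALSE)
  }
  probs <- unlist(cfg[c("p_true_source_species", "p_true_source_genus",
                        "p_true_source_family", "p_decoy_match",
                        "p_decoy_genus")])
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$p_true_source_species + cfg$p_true_source_genus +
      cfg$p_true_source_family > 1 + 1e-12) {
    stop("true-source depth probabilities must sum to at most 1",
         call. = FALSE)
  }
  if (cfg$p_decoy_match + cfg$p_decoy_genus > 1 + 1e-12) {
    stop("decoy match probabilities must sum to at most 1", call. = FALSE)
  }
  if (cfg$score_noise_sd < 0) {
    stop("score_noise_sd must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Generate a balanced synthetic taxonomy table
#'
#' Species names are structured so the depth of any match is visually
#' auditable: family `Fam03`, genus `Fam03gen02` (one token, so binomials
#' stay consistent), species `Fam03gen02 sp05`. Ten percent of the species
#' (seeded choice) are additionally emitted under a synonym name
#' (`... syn05`) mapping to the accepted lineage, so synonym resolution can
#' be exercised offline.
#'
#' @param config a [simulation_config()].
#' @return a taxonomy tibble (`input_name`, `accepted_name`, the seven
#'   lineage columns), accepted rows first, synonym rows appended.
#' @export
generate_taxonomy <- function(config = simulation_config()) {
  grid <- expand.grid(sp = seq_len(config$species_per_genus),
                      gn = seq_len(config$genera_per_family),
                      fm = seq_len(config$n_families))
  family <- sprintf("Fam%02d", grid$fm)
  genus <- sprintf("Fam%02dgen%02d", grid$fm, grid$gn)
  species <- sprintf("%s sp%02d", genus, grid$sp)
  accepted <- tibble::tibble(
    input_name = species, accepted_name = species,
    kingdom = "Plantae", phylum = "Tracheophyta", class = "Magnoliopsida",
    order = sprintf("Ord%02d", grid$fm), family = family, genus = genus,
    species = species)
  n_syn <- max(1L, floor(nrow(accepted) / 10))
  syn_idx <- withr::with_seed(config$seed,
                              sort(sample(nrow(accepted), n_syn)))
  synonyms <- accepted[syn_idx, ]
  synonyms$input_name <- sub(" sp", " syn", synonyms$species, fixed = TRUE)
  dplyr::bind_rows(accepted, synonyms)
}

# deterministic unique 14-uppercase-letter pseudo-InChIKeys
make_short_iks <- function(n) {
  out <- character(n)
  seen <- new.env(hash = TRUE)
  i <- 0L
  while (i < n) {
    k <- paste(sample(LETTERS, 14L, replace = TRUE), collapse = "")
    if (is.null(seen[[k]])) {
      seen[[k]] <- TRUE
      i <- i + 1L
      out[i] <- k
    }
  }
  out
}

# draw a source lineage at a controlled match depth relative to `org`
# (a row of the accepted taxonomy); depth: "species", "genus", "family", "none"
draw_source_at_depth <- function(depth, org, taxonomy) {
  pick <- function(pool) pool[sample(nrow(pool), 1L), ]
  row <- switch(depth,
    species = org,
    genus = {
      pool <- taxonomy[taxonomy$genus == org$genus &
                         taxonomy$species != org$species, ]
      if (nrow(pool) == 0L) org else pick(pool)
    },
    family = {
      pool <- taxonomy[taxonomy$family == org$family &
                         taxonomy$genus != org$genus, ]
      if (nrow(pool) == 0L) org else pick(pool)
    },
    none = {
      pool <- taxonomy[taxonomy$family != org$family, ]
      if (nrow(pool) == 0L) org else pick(pool)
    })
  row[lineage_ranks]
}

#' Generate a complete synthetic benchmark fixture
#'
#' Builds, from one seeded configuration, everything the pipeline consumes:
#' a taxonomy table, a query table (one organism and true short InChIKey per
#' query), a candidate table (one true candidate plus decoys per query, raw
#' scores drawn so the true candidate trails the best decoy by
#' `true_score_deficit` before noise), a structure--source table, and an MGF
#' spectra tibble whose entries pass [filter_spectra()] defaults (8 peaks,
#' `[M+H]+`, in-range parent mass). Identical seeds give identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `queries`, `candidates`, `sources`, `spectra`,
#'   `taxonomy` and the `config` used.
#' @export
generate_benchmark_fixture <- function(config = simulation_config()) {
  taxonomy <- generate_taxonomy(config)
  accepted <- taxonomy[taxonomy$input_name == taxonomy$accepted_name, ]
  withr::with_seed(config$seed + 1L, {
    n <- config$n_queries
    k <- config$candidates_per_query
    org_idx <- sample(nrow(accepted), n, replace = TRUE)
    iks <- make_short_iks(n * k)
    depth_levels <- c("species", "genus", "family", "none")
    depth_probs <- c(config$p_true_source_species, config$p_true_source_genus,
                     config$p_true_source_family,
                     1 - config$p_true_source_species -
                       config$p_true_source_genus - config$p_true_source_family)
    queries <- list(); cand_rows <- list(); src_rows <- list(); spec <- list()
    for (i in seq_len(n)) {
      org <- accepted[org_idx[i], ]
      qid <- sprintf("CCMSLIB%08d", i)
      truth_ik <- iks[(i - 1L) * k + 1L]
      decoy_iks <- iks[(i - 1L) * k + seq(2L, k)]
      parent_mass <- stats::runif(1L, 150, 900)
      queries[[i]] <- dplyr::bind_cols(
        tibble::tibble(query_id = qid, true_short_ik = truth_ik,
                       parent_mass = parent_mass,
                       molecular_formula = NA_character_),
        org[lineage_ranks])
      decoy_scores <- stats::runif(k - 1L)
      true_score <- max(decoy_scores) - config$true_score_deficit +
        stats::rnorm(1L, 0, config$score_noise_sd)
      true_depth <- sample(depth_levels, 1L, prob = depth_probs)
      lineages <- vector("list", k)
      lineages[[1L]] <- draw_source_at_depth(true_depth, org, accepted)
      for (j in seq_len(k - 1L)) {
        u <- stats::runif(1L)
        decoy_depth <- if (u < config$p_decoy_genus) "genus" else
          if (u < config$p_decoy_genus + config$p_decoy_match) "family" else
            "none"
        lineages[[j + 1L]] <- draw_source_at_depth(decoy_depth, org, accepted)
      }
      all_iks <- c(truth_ik, decoy_iks)
      cand_rows[[i]] <- tibble::tibble(
        query_id = qid, candidate_short_ik = all_iks,
        raw_score = c(true_score, decoy_scores), tool = "generic",
        molecule_name = NA_character_,
        sources = lineages)
      src_rows[[i]] <- dplyr::bind_cols(
        tibble::tibble(short_ik = all_iks), dplyr::bind_rows(lineages))
      mz <- sort(stats::runif(8L, 50, parent_mass))
      spec[[i]] <- tibble::tibble(
        spectrum_id = qid, precursor_mz = parent_mass, adduct = "[M+H]+",
        ionmode = "positive", name = NA_character_, smiles = NA_character_,
        inchi = NA_character_,
        peaks = list(tibble::tibble(mz = mz,
                                    intensity = stats::runif(8L, 1, 100))))
    }
    list(queries = dplyr::bind_rows(queries),
         candidates = dplyr::bind_rows(cand_rows),
         sources = dplyr::bind_rows(src_rows),
         spectra = dplyr::bind_rows(spec),
         taxonomy = taxonomy,
         config = config)
  })
}

#' The published worked example: five candidates for a Glaucium grandiflorum
#' feature
#'
#' The five-candidate annotation list for the feature at m/z 342.1670
#' (predicentrine, the correct structure, initially ranked 9th of 50 by
#' spectral score alone). Normalized spectral scores and initial ranks are
#' carried as printed -- they derive from the full 50-candidate list, so they
#' cannot be recomputed from these five rows -- which is why this fixture
#' feeds [combine_scores()] + [rerank()] directly rather than
#' [score_pipeline()].
#'
#' @return list with `query` (one-row query tibble, organism *Glaucium
#'   grandiflorum*, truth `OUTYMWDDJORZOH`) and `candidates` (five rows with
#'   `normalized_score`, `initial_rank` and source lineages set).
#' @export
table1_fixture <- function() {
  query <- tibble::tibble(
    query_id = "1772", true_short_ik = "OUTYMWDDJORZOH",
    parent_mass = 342.1670, molecular_formula = NA_character_,
    kingdom = "Plantae", phylum = "Tracheophyta", class = "Magnoliopsida",
    order = "Ranunculales", family = "Papaveraceae", genus = "Glaucium",
    species = "Glaucium grandiflorum")
  src <- function(family, genus, species) {
    list(tibble::tibble(kingdom = "Plantae", phylum = "Tracheophyta",
                        class = "Magnoliopsida", order = "Ranunculales",
                        family = family, genus = genus,
                        species = canonicalize_name(species)))
  }
  candidates <- tibble::tibble(
    query_id = "1772",
    candidate_short_ik = c("OUTYMWDDJORZOH", "QELDJEKNFOQJOY",
                           "KDFKJOFJHSVROC", "JADHMUPTWPBTMT",
                           "WNBUTZHPPULVTP"),
    molecule_name = c("Predicentrine", "Isocorydine", "Isocorypalmine",
                      "Secosarcocapnidine Me ether, N-De-Me",
                      "Secocularidine Me ether, N-de-Me"),
    raw_score = c(0.36, 0.34, 0.30, 0.40, 0.39),
    normalized_score = c(0.23, 0.22, 0.14, 0.32, 0.29),
    initial_rank = c(9L, 11L, 28L, 1L, 2L),
    tool = "isdb",
    sources = c(src("Papaveraceae", "Glaucium", "Glaucium oxylobum"),
                src("Papaveraceae", "Glaucium", "NA"),
                src("Papaveraceae", "Glaucium", "Glaucium fimbrilligerum"),
                src("Papaveraceae", "Sarcocapnos", "Sarcocapnos crassifolia"),
                src("Papaveraceae", "Ceratocapnos", "Ceratocapnos claviculata"))
  )
  list(query = query, candidates = candidates)
}
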