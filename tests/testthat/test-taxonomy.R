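test_that("canonicalize_name strips, collapses and maps unknown placeholders", {
  expect_equal(canonicalize_name("  Glaucium  "), "Glaucium")
  expect_equal(canonicalize_name("Glaucium   grandiflorum"),
               "Glaucium grandiflorum")
  expect_equal(canonicalize_name(c("NA", "N/A", "-", "", NA)),
               rep("", 5L))
  # display form keeps case; the comparison key folds it
  expect_equal(canonicalize_name("papaveraceae"), "papaveraceae")
  expect_equal(name_key("papaveraceae"), name_key("Papaveraceae"))
})

test_that("taxon_lineage enforces binomial consistency", {
  l <- taxon_lineage(family = "Papaveraceae", genus = "Glaucium",
                     species = "Glaucium grandiflorum")
  expect_s3_class(l, "taxon_lineage")
  expect_equal(l[["species"]], "Glaucium grandiflorum")
  expect_error(taxon_lineage(genus = "Glaucium", species = "Papaver rhoeas"),
               "binomial")
  # unknown genus puts no constraint on the binomial
  expect_silent(taxon_lineage(species = "Papaver rhoeas"))
})

test_that("match_levels matches exactly, per level, empty never matches", {
  q <- lin("Papaveraceae", "Glaucium", "Glaucium grandiflorum")
  expect_equal(match_levels(q, lin("Papaveraceae", "Glaucium",
                                   "Glaucium oxylobum")),
               c(family = TRUE, genus = TRUE, species = FALSE))
  expect_equal(match_levels(q, q),
               c(family = TRUE, genus = TRUE, species = TRUE))
  expect_equal(match_levels(q, lin("Ranunculaceae", "Pulsatilla",
                                   "Pulsatilla cernua")),
               c(family = FALSE, genus = FALSE, species = FALSE))
  # empty on either side yields FALSE at that level
  expect_false(match_levels(q, lin("Papaveraceae", "Glaucium"))[["species"]])
  expect_false(match_levels(lin(), lin())[["family"]])
})

test_that("match_levels is symmetric and case-insensitive", {
  a <- lin("Papaveraceae", "Glaucium", "Glaucium grandiflorum")
  b <- lin("papaveraceae", "GLAUCIUM", "glaucium OXYLOBUM")
  expect_equal(match_levels(a, b), match_levels(b, a))
  expect_true(all(match_levels(a, b)[c("family", "genus")]))
})

test_that("taxonomic_bonus reproduces the worked per-level scores", {
  q <- lin("Papaveraceae", "Glaucium", "Glaucium grandiflorum")
  w <- weight_vector(0.81, 1.62, 2.55)
  # genus-level deepest match
  expect_equal(
    taxonomic_bonus(q, list(lin("Papaveraceae", "Glaucium",
                                "Glaucium oxylobum")), w),
    c(family_score = 0.81, genus_score = 1.62, species_score = 0,
      max_taxo_score = 1.62))
  # family-level only
  expect_equal(
    taxonomic_bonus(q, list(lin("Papaveraceae", "Sarcocapnos",
                                "Sarcocapnos crassifolia")), w),
    c(family_score = 0.81, genus_score = 0, species_score = 0,
      max_taxo_score = 0.81))
  # no sources at all
  expect_equal(taxonomic_bonus(q, list(), w),
               c(family_score = 0, genus_score = 0, species_score = 0,
                 max_taxo_score = 0))
})

test_that("taxonomic_bonus is monotone in the source list and max-closed", {
  withr::with_seed(99, {
    pool <- list(lin("Fam01", "Fam01gen01", "Fam01gen01 sp01"),
                 lin("Fam01", "Fam01gen02", "Fam01gen02 sp01"),
                 lin("Fam02", "Fam02gen01", "Fam02gen01 sp01"),
                 lin("Fam01", "Fam01gen01", "Fam01gen01 sp02"))
    q <- lin("Fam01", "Fam01gen01", "Fam01gen01 sp01")
    for (rep in 1:25) {
      w <- weight_vector(runif(1, 0, 3), runif(1, 0, 3), runif(1, 0, 3))
      srcs <- pool[sample(4, sample(0:4, 1))]
      base <- taxonomic_bonus(q, srcs, w)
      more <- taxonomic_bonus(q, c(srcs, pool[sample(4, 1)]), w)
      expect_true(all(more >= base))
      expect_true(base[["max_taxo_score"]] %in%
                    c(0, w[["family"]], w[["genus"]], w[["species"]]))
    }
    # hierarchy-consistent weights: max equals weight of the deepest match
    w <- weight_vector(1, 2, 3)
    hit <- taxonomic_bonus(q, pool[1], w)
    expect_equal(hit[["max_taxo_score"]], w[["species"]])
    hit <- taxonomic_bonus(q, pool[4], w)
    expect_equal(hit[["max_taxo_score"]], w[["genus"]])
  })
})

test_that("resolve_lineage resolves synonyms and reports unknown names", {
  tab <- tibble::tibble(
    input_name = c("Pulsatilla cernua", "Pulsatilla koreana"),
    accepted_name = "Pulsatilla cernua",
    kingdom = "Plantae", phylum = "Tracheophyta", class = "Magnoliopsida",
    order = "Ranunculales", family = "Ranunculaceae", genus = "Pulsatilla",
    species = "Pulsatilla cernua")
  syn <- resolve_lineage("Pulsatilla koreana", tab)
  expect_true(syn$resolved)
  expect_equal(syn$accepted_name, "Pulsatilla cernua")
  expect_equal(syn$lineage[["species"]], "Pulsatilla cernua")
  expect_equal(syn$lineage[["family"]], "Ranunculaceae")
  # accepted name maps to itself, lookup is case-insensitive
  acc <- resolve_lineage("  pulsatilla CERNUA ", tab)
  expect_true(acc$resolved)
  expect_equal(acc$lineage, syn$lineage)
  # unknown name is an explicit unresolved outcome carrying the input
  un <- resolve_lineage("Glaucium flavum", tab)
  expect_false(un$resolved)
  expect_equal(un$input, "Glaucium flavum")
  expect_null(un$lineage)
})

test_that("taxonomy tables round-trip through disk", {
  tax <- generate_taxonomy(simulation_config(seed = 3, n_families = 2,
                                             genera_per_family = 2,
                                             species_per_genus = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, path)
  back <- read_taxonomy(path)
  expect_equal(as.data.frame(back), as.data.frame(tax))
  expect_error(read_taxonomy(withr::local_tempfile(fileext = ".tsv")),
               "not found")
})

test_that("weight vectors validate and classify hierarchy consistency", {
  expect_true(weights_consistent(default_weights()))
  expect_true(weights_consistent(optimized_weights()))
  expect_false(weights_consistent(weight_vector(3, 2, 1)))
  expect_error(weight_vector(-1, 0, 0), "non-negative")
  expect_equal(as.numeric(optimized_weights()), c(0.81, 1.62, 2.55))
})
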