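---
title: "Taxonomically informed scoring: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxonomically informed scoring: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxoscore)
```

## The annotation problem and the scoring model

Computational MS/MS annotation tools return, for each queried spectrum, a
list of candidate structures ranked by a tool-native score (a cosine
similarity, a 1–10 composite, a negative log-probability, ...). For
specialized metabolites these spectral scores alone often leave the correct
structure buried below isomeric or spectrally similar decoys. Because
specialized metabolites are strongly tied to the taxonomy of their producers,
the biological source of a candidate structure is an informative attribute
that is orthogonal to spectral similarity.

`taxoscore` implements this idea as an additive metascore component. For one
query with candidates $i = 1, \dots, n$ and tool scores $s_i$:

1. **Normalization.** $\tilde s_i = (s_i - \min_j s_j) / (\max_j s_j -
   \min_j s_j)$, so every tool lands on $[0, 1]$ with 0 the worst and 1 the
   best candidate. Any dialect whose scores are ordered higher-is-better
   (including negative-to-zero scales) needs no further transform; the
   normalization is invariant to positive affine changes of scale.
2. **Taxonomic bonus.** Let $q$ be the query organism's lineage and
   $\mathcal{S}_i$ the candidate's recorded source lineages. For each rank
   $\ell \in \{\text{family}, \text{genus}, \text{species}\}$ with weight
   $w_\ell$, the candidate earns $w_\ell$ if any source in $\mathcal{S}_i$
   matches $q$ exactly at $\ell$. The bonus added is the maximum earned
   weight — the score of the shortest taxonomic distance:
   $b_i = \max_\ell w_\ell \, [\exists\, s \in \mathcal{S}_i : s_\ell = q_\ell \neq \varnothing]$.
3. **Combination and re-ranking.** $c_i = \tilde s_i + b_i$, plain addition
   with no re-normalization (keeping the spectral and taxonomic components
   independent); candidates are re-ranked by descending $c_i$.

Matching is *exact string equality* after canonicalization (whitespace
collapse, case folding, placeholder tokens mapped to "unknown"); no
phylogenetic or within-taxon distances are used. Species are compared as
full binomials, and an unknown rank on either side never matches, so
degraded or incomplete metadata can only withhold a bonus, never grant one.

## The weights and their derivation

Because normalized scores live in $[0, 1]$, the smallest bonus that lets the
*worst* candidate reach the top combined score is 1; against a best
candidate already carrying a family bonus of 1 it is 2; against a
genus-bonused best, 3 (`min_outranking_bonus()`). That minimal-dominance
argument produces the default weights $(w_f, w_g, w_s) = (1, 2, 3)$:
each deeper taxonomic level dominates the shallower one. "Reaching" the top
score is treated as sufficient; exact ties are then resolved by the
deterministic tie rules below, a distinction the construction deliberately
leaves at the infinitesimal level.

The package also ships the preset `optimized_weights()` $(0.81, 1.62,
2.55)$, obtained on a large degraded-metadata benchmark; such optimized
values are training-set dependent and their transferable content is the
*ordering* $w_f < w_g < w_s$, which `optimize_weights()` lets you re-derive
on your own data.

## Numerical and procedural choices

* **Degenerate normalization.** A single candidate, or all raw scores equal,
  normalizes to 1 for every candidate: a lone candidate is the best
  candidate. This also keeps the zero-weights limit an exact identity.
* **Tie-breaking after combination** is unspecified in the underlying
  scoring scheme; `rerank()` uses descending combined score, then better
  initial (spectral) rank, then lexicographic short InChIKey — fully
  deterministic and verified against a brute-force sort-by-definition oracle.
* **Initial ranks** are assigned by descending normalized score, stable in
  input order on ties. Worked-example tables that carry printed initial
  ranks from a longer candidate list keep them as given.
* **MGF truncation ties.** When truncating a spectrum to the 500 most
  intense peaks, ties at the cutoff keep the lower-m/z peak first.
* **Parent-mass QC.** The expected protonated mass is the formula's
  monoisotopic mass plus 1.007276 Da; flagging uses a strict `> 0.01` Da
  rule with a $10^{-9}$ Da guard so boundary values are not flagged through
  floating-point noise.
* **Benchmark construction.** Structures with more than one distinct
  recorded lineage are excluded (the benchmark needs a unique source);
  lineages must be complete down to the species level (family, genus *and*
  species non-empty); multiple spectra of one structure collapse to the
  first by input order, a stable stand-in for an unstated choice.
* **False negatives.** `confusion_counts()` counts as `fn` only queries
  whose correct structure is present at rank > 1; queries whose correct
  structure never appears among the candidates are reported separately as
  `absent`, so either convention can be recomputed. Percentages are rounded
  half-up to one decimal, the printed convention.
* **Top-k curves.** "Remaining improvement potential" is summarized as the
  cumulative count of queries with the correct structure at rank $\le k$,
  the standard surrogate for ranked-annotation ROC-style displays.

## Weight optimization under metadata degradation

Real candidate metadata is rarely complete to the species level. To optimize
weights under realistic incompleteness, `degrade_metadata()` randomly splits
the queries into four equal blocks (remainder to the earlier blocks) and
blanks the candidate source lineages of block 1 at the species level, block
2 at genus+species, block 3 at family+genus+species, leaving block 4 intact.
Assignment is by query — all candidate rows of a query share its block, which
keeps the rank-1-hits objective well defined — and is a pure function of the
seed and the sorted query ids.

The objective `objective_rank1_hits()` counts correct structures at final
rank 1. Three optimizers share it: an exhaustive **grid** (the testable
oracle; step 0.25 by default), uniform **random** search, and a sequential
**surrogate** search (expected improvement on a radial-basis model:
inverse-distance-weighted mean, distance-to-nearest-point uncertainty,
exploration constant $\kappa = 5.152$, 10 initial points, 100 iterations,
bounds $[0, 3]$ per axis). The surrogate contract is deliberately modest: it
honours bounds/seeds/budgets, never reports a point worse than the best it
evaluated, and evaluates the same pure objective as the grid. Because the
objective is integer-valued and plateaus widely, the reported optimum among
tied maxima is the point with the smallest weight sum (then lexicographic) —
the *minimal* bonus achieving the maximum, mirroring the minimal-dominance
derivation of the defaults. Repeated runs on independently degraded
replicates are combined by `repeat_and_average()` (component-wise mean of the
best points, per-axis spread reported).

## What the synthetic generator emulates — and what it does not

`generate_benchmark_fixture()` builds a self-contained benchmark with
controlled chemotaxonomic signal. Its defaults are the package's study
conditions:

* a balanced plant-like taxonomy of 8 families × 4 genera × 4 species, with
  10% of species also reachable through a synonym;
* 80 queries with 5 candidates each (annotation tools are typically used
  with a short kept list of best hits);
* the true candidate's recorded source matches the query organism at
  exactly species / genus / family depth with probabilities 0.55 / 0.25 /
  0.10 (sources in curated natural-product databases are mostly documented
  to species level), otherwise it is unrelated;
* decoys share the query's genus with probability 0.15 and (otherwise) its
  family with probability 0.30 — congeneric and confamilial decoys are
  ubiquitous in natural-product candidate lists, and they are what makes the
  three weights *compete*: without congeneric decoys nothing separates
  $w_s$ from $w_g$ in the objective, and the recovered ordering would be an
  artifact of tie-breaking;
* decoy raw scores are uniform on $(0, 1)$ and the true candidate sits
  `true_score_deficit` = 0.3 below the best decoy with Gaussian noise 0.1,
  so the correct structure is usually — not always — spectrally outranked,
  emulating the low rank-1 rate of spectral-only annotation.

Spectra are generated with 8 placeholder peaks and an `[M+H]+` annotation so
they pass the library filters; peak content carries no chemical information.
The generator does not emulate fragmentation chemistry, instrument-type
mixtures, mass or compound-class distributions, unbalanced real taxonomies,
or correlated scores between tools. Passing tests on synthetic data
therefore validate the *mechanics and the qualitative behaviour* of the
scoring system (bonuses help exactly when chemotaxonomic signal exists, the
weight hierarchy is recoverable by optimization), not the quantitative gains
reported on any real benchmark.

With these conditions, the package's acceptance checks run at desk scale:
the before/after comparison uses one 80-query fixture, and the
weight-ordering recovery uses a grid of step 0.5 on four degradation
replicates of that fixture (each grid is $7^3 = 343$ evaluations of the
precomputed objective, a few hundred milliseconds in total).

## Known limitations

* Bonuses reward only exact identity at three ranks; organisms just across
  a family boundary, convergent biosynthesis, and widely distributed
  metabolites (a compound reported from dozens of families) receive no
  credit or undeserved credit, respectively. Continuous taxonomic distances
  are out of scope by design.
* The scoring quality is bounded by the completeness and correctness of the
  structure–source table; name resolution is table-driven and offline, so an
  out-of-date synonym table silently withholds bonuses.
* Infraspecific ranks (subspecies, varieties) are not modelled; species
  comparison uses the full binomial string as stored.
* Optimized weights are training-set artifacts; only their ordering should
  be interpreted.

## A worked example

```{r table1}
fx <- table1_fixture()
scored <- rerank(combine_scores(fx$candidates, fx$query, optimized_weights()))
scored[, c("molecule_name", "normalized_score", "max_taxo_score",
           "combined_score", "initial_rank", "final_rank")]
```

The correct structure (predicentrine, a *Glaucium* aporphine alkaloid)
carries a genus-level source match, gains 1.62, and moves from spectral rank
9 to combined rank 1.
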