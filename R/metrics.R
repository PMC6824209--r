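#' Rank of the correct structure in a scored candidate list
#'
#' Correctness is assessed by short-InChIKey equality (no stereoisomer
#' distinction is possible from MS/MS data). Returns the 1-based initial or
#' final rank of the first candidate matching the true short InChIKey, or
#' `NA` when the correct structure is absent from the candidate list.
#'
#' @param ranked_candidates one query's scored tibble ([score_pipeline()]
#'   output or [rerank()] output).
#' @param true_short_ik 14-character short InChIKey of the true structure.
#' @param use_final use `final_rank` (default) or `initial_rank`.
#' @return integer rank, or `NA_integer_` when absent.
#' @export
rank_of_correct <- function(ranked_candidates, true_short_ik,
                            use_final = TRUE) {
  truth <- shorten_inchikey(true_short_ik)
  hit <- ranked_candidates$candidate_short_ik == truth
  if (!any(hit)) return(NA_integer_)
  col <- if (use_final) "final_rank" else "initial_rank"
  as.integer(min(ranked_candidates[[col]][hit]))
}

#' Per-query ranks of the correct structure for a whole benchmark
#'
#' @param scored output of [score_pipeline()] over benchmark queries.
#' @param queries query tibble with `true_short_ik`.
#' @param use_final use final (default) or initial ranks.
#' @return tibble with `query_id` and `rank` (`NA` = correct structure absent
#'   from that query's candidates); one row per query that has candidates.
#' @export
correct_ranks <- function(scored, queries, use_final = TRUE) {
  qids <- unique(scored$query_id)
  truth <- queries$true_short_ik[match(qids, queries$query_id)]
  rank <- vapply(seq_along(qids), function(i) {
    rank_of_correct(scored[scored$query_id == qids[i], , drop = FALSE],
                    truth[i], use_final = use_final)
  }, integer(1L))
  tibble::tibble(query_id = qids, rank = rank)
}

#' Confusion counts at rank 1
#'
#' Over queries that returned at least one candidate: `tp` counts correct
#' structures at rank 1, `fn` correct structures present but at rank > 1, and
#' `fp` queries whose rank-1 candidate is wrong (`fp = queries - tp`, so
#' `tp + fp` equals the number of queries with candidates). Queries whose
#' correct structure appears at no rank at all are counted separately as
#' `absent` and excluded from `fn`, so either false-negative convention can
#' be recomputed from the report.
#'
#' @param per_query_ranks integer vector of ranks, `NA` = absent (e.g. the
#'   `rank` column of [correct_ranks()]).
#' @return a `confusion_counts` list with `tp`, `fp`, `fn`, `absent`,
#'   `n_queries`.
#' @examples
#' confusion_counts(c(1, 1, 3, NA))  # tp 2, fp 2, fn 1, absent 1
#' @export
confusion_counts <- function(per_query_ranks) {
  r <- as.integer(per_query_ranks)
  n <- length(r)
  tp <- sum(r == 1L, na.rm = TRUE)
  fn <- sum(r > 1L, na.rm = TRUE)
  structure(list(tp = tp, fp = n - tp, fn = fn, absent = sum(is.na(r)),
                 n_queries = n),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion at rank 1> tp %d | fp %d | fn %d | absent %d (n = %d)\n",
              x$tp, x$fp, x$fn, x$absent, x$n_queries))
  invisible(x)
}

#' Precision, recall and F1 score from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`, and F1 is their
#' harmonic mean. Degenerate 0/0 ratios are returned as 0 with the
#' `degenerate` flag set.
#'
#' @param counts a [confusion_counts()] object (or a list with `tp`, `fp`,
#'   `fn`).
#' @return list with `precision`, `recall`, `f1`, `degenerate`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  degenerate <- FALSE
  ratio <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      0
    } else num / den
  }
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- ratio(2 * precision * recall, precision + recall)
  if (degenerate) {
    warning("degenerate 0/0 ratio in precision/recall/F1; reported as 0",
            call. = FALSE)
  }
  list(precision = precision, recall = recall, f1 = f1,
       degenerate = degenerate)
}

#' Multi-tool overlap of correct rank-1 annotations
#'
#' Computes all exclusive Venn regions over the per-tool sets of queries
#' annotated correctly at rank 1, the union count, and the union as a
#' percentage of the benchmark (rounded half-up to one decimal, the printed
#' convention).
#'
#' @param correct_at_rank1_sets named list, one character vector of query ids
#'   per tool.
#' @param total_queries size of the benchmark universe.
#' @return list with `regions` (named counts; names like `"isdb&sirius"`
#'   denote queries in exactly that tool combination), `union_count` and
#'   `union_fraction` (percent).
#' @examples
#' overlap_summary(list(a = "q1", b = c("q1", "q2")), total_queries = 4)
#' @export
overlap_summary <- function(correct_at_rank1_sets, total_queries) {
  sets <- lapply(correct_at_rank1_sets, function(s) unique(as.character(s)))
  tools <- names(sets)
  if (is.null(tools) || any(!nzchar(tools))) {
    stop("correct_at_rank1_sets must be a named list", call. = FALSE)
  }
  universe <- unique(unlist(sets, use.names = FALSE))
  if (total_queries < length(universe)) {
    stop("total_queries (", total_queries, ") smaller than the union (",
         length(universe), ")", call. = FALSE)
  }
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, ncol = length(sets),
                       dimnames = list(NULL, tools))
  k <- length(tools)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  regions <- apply(combos, 1L, function(inc) {
    sum(apply(membership, 1L, function(m) all(m == inc)))
  })
  names(regions) <- apply(combos, 1L, function(inc)
    paste(tools[as.logical(inc)], collapse = "&"))
  list(regions = regions,
       union_count = length(universe),
       union_fraction = round_half_up(100 * length(universe) / total_queries,
                                      1L))
}

#' Cumulative top-k correct-hit curve
#'
#' For each k from 1 to `k_max`, the number of queries whose correct
#' structure sits at rank <= k: the standard summary of how much correct
#' annotation remains just below the first rank.
#'
#' @param per_query_ranks integer ranks, `NA` = absent.
#' @param k_max largest k.
#' @return tibble with columns `k` and `hits` (non-decreasing; `hits[1]` is
#'   the rank-1 true-positive count).
#' @examples
#' topk_recall_curve(c(1, 2, 2, 5), k_max = 5)
#' @export
topk_recall_curve <- function(per_query_ranks, k_max) {
  stopifnot(k_max >= 1L)
  r <- as.integer(per_query_ranks)
  tibble::tibble(
    k = seq_len(k_max),
    hits = vapply(seq_len(k_max), function(k) sum(r <= k, na.rm = TRUE),
                  integer(1L))
  )
}

#' Benchmark one or more candidate sets before and after taxonomic scoring
#'
#' Convenience wrapper: runs [score_pipeline()] per tool with the given
#' weights, computes confusion counts and precision/recall/F1 on both the
#' initial (spectral-only) and final (taxonomically informed) rankings, and
#' summarises the multi-tool overlap of correct rank-1 annotations after
#' re-ranking.
#'
#' @param candidate_sets named list of candidate tibbles, one per tool.
#' @param queries query tibble with `true_short_ik` and organism lineage.
#' @param weights a [weight_vector()].
#' @param k_max depth of the top-k curves (default 10).
#' @return list with `per_tool` (tibble of counts and rates before/after),
#'   `overlap_before`, `overlap_after`, and `curves` (per tool/phase top-k
#'   tibbles).
#' @export
benchmark_tools <- function(candidate_sets, queries,
                            weights = default_weights(), k_max = 10L) {
  stopifnot(length(candidate_sets) > 0L, !is.null(names(candidate_sets)))
  total <- nrow(queries)
  rows <- list(); curves <- list()
  sets_before <- list(); sets_after <- list()
  for (tool in names(candidate_sets)) {
    scored <- score_pipeline(candidate_sets[[tool]], queries, weights)
    for (phase in c("before", "after")) {
      use_final <- phase == "after"
      cr <- correct_ranks(scored, queries, use_final = use_final)
      cc <- confusion_counts(cr$rank)
      prf <- suppressWarnings(precision_recall_f1(cc))
      rows[[paste(tool, phase)]] <- tibble::tibble(
        tool = tool, phase = phase, tp = cc$tp, fp = cc$fp, fn = cc$fn,
        absent = cc$absent, n_queries = cc$n_queries,
        precision = prf$precision, recall = prf$recall, f1 = prf$f1)
      curves[[paste(tool, phase)]] <- dplyr::mutate(
        topk_recall_curve(cr$rank, k_max), tool = tool, phase = phase)
      hits <- cr$query_id[!is.na(cr$rank) & cr$rank == 1L]
      if (use_final) sets_after[[tool]] <- hits else
        sets_before[[tool]] <- hits
    }
  }
  list(per_tool = dplyr::bind_rows(rows),
       overlap_before = overlap_summary(sets_before, total),
       overlap_after = overlap_summary(sets_after, total),
       curves = dplyr::bind_rows(curves))
}
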