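degradation_blocks <- c("strip_species", "strip_genus_species", "strip_all",
                        "intact")

# ranks blanked by each block
block_strip <- list(
  strip_species = "species",
  strip_genus_species = c("genus", "species"),
  strip_all = c("family", "genus", "species"),
  intact = character(0)
)

#' Randomly degrade the taxonomic metadata of candidate annotations
#'
#' Emulates incomplete "real life" source metadata for weight optimization:
#' queries are randomly split into four equal blocks (remainder spread over
#' the earlier blocks) and the recorded source lineages of *all* candidates
#' of a query are blanked at, respectively, the species level; the genus and
#' species levels; the family, genus and species levels; the fourth block is
#' left intact. Assignment is a pure function of `seed` and the sorted query
#' id list, so a plan is exactly reproducible; the inputs are not modified.
#'
#' @param candidates candidate tibble with a `sources` list-column.
#' @param queries query tibble (defines the block universe).
#' @param seed integer seed for the block randomization.
#' @return list with `candidates` (degraded copy) and `plan` (tibble
#'   `query_id`, `block`, with the seed as an attribute).
#' @export
degrade_metadata <- function(candidates, queries, seed) {
  stopifnot(nrow(queries) > 0L)
  qids <- sort(unique(queries$query_id))
  n <- length(qids)
  sizes <- rep(n %/% 4L, 4L)
  extra <- n %% 4L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  perm <- withr::with_seed(seed, sample(qids))
  block <- rep(degradation_blocks, times = sizes)
  plan <- tibble::tibble(query_id = perm, block = block)
  plan <- plan[order(plan$query_id), , drop = FALSE]
  attr(plan, "seed") <- seed

  out <- candidates
  blk <- plan$block[match(out$query_id, plan$query_id)]
  for (i in seq_len(nrow(out))) {
    strip <- block_strip[[blk[i] %||% "intact"]]
    if (length(strip) == 0L) next
    src <- out$sources[[i]]
    if (!is.null(src) && nrow(src) > 0L) {
      src[strip] <- ""
      out$sources[[i]] <- src
    }
  }
  list(candidates = out, plan = plan)
}

# Pre-resolve everything weight-independent once: per-(query, candidate)
# match indicators, normalized scores, initial ranks, truth flags. Makes the
# optimization objective a cheap pure function of the three weights.
prepare_objective_table <- function(candidates, queries) {
  orphans <- setdiff(unique(candidates$query_id), queries$query_id)
  if (length(orphans) > 0L) {
    stop("candidate query_id(s) absent from the query table: ",
         paste(utils::head(orphans, 10L), collapse = ", "), call. = FALSE)
  }
  cand <- normalize_scores(candidates)
  qidx <- match(cand$query_id, queries$query_id)
  qlin <- lapply(seq_len(nrow(queries)), function(i)
    stats::setNames(name_key(as_lineage_fields(queries[i, ])[score_ranks]),
                    score_ranks))
  m <- matrix(FALSE, nrow = nrow(cand), ncol = 3L,
              dimnames = list(NULL, score_ranks))
  for (i in seq_len(nrow(cand))) {
    src <- cand$sources[[i]]
    if (is.null(src) || nrow(src) == 0L) next
    q <- qlin[[qidx[i]]]
    for (rk in score_ranks) {
      s <- name_key(src[[rk]])
      m[i, rk] <- any(nzchar(s) & nzchar(q[[rk]]) & s == q[[rk]])
    }
  }
  init <- stats::ave(-cand$normalized_score, cand$query_id,
                     FUN = function(x) rank(x, ties.method = "first"))
  list(qidx = qidx,
       ik = cand$candidate_short_ik,
       normalized = cand$normalized_score,
       initial_rank = init,
       match = m,
       is_true = cand$candidate_short_ik ==
         queries$true_short_ik[qidx])
}

# rank-1 hit count for one weight triple on a prepared table
objective_from_prepared <- function(prep, w) {
  bonus <- pmax(prep$match[, "family"] * w[1L],
                prep$match[, "genus"] * w[2L],
                prep$match[, "species"] * w[3L])
  combined <- prep$normalized + bonus
  ord <- order(prep$qidx, -combined, prep$initial_rank, prep$ik,
               method = "radix")
  first <- ord[!duplicated(prep$qidx[ord])]
  sum(prep$is_true[first])
}

#' Number of correct annotations at rank 1 under a given weight vector
#'
#' The black-box objective of the weight optimization: runs the full scoring
#' pipeline with `weights` and counts the queries whose correct structure
#' (by short InChIKey) lands at final rank 1. Pure and deterministic.
#'
#' @param weights a [weight_vector()] (or numeric triple).
#' @param candidates candidate tibble.
#' @param queries query tibble with `true_short_ik`.
#' @return integer hit count.
#' @export
objective_rank1_hits <- function(weights, candidates, queries) {
  w <- as_weight_vector(weights)
  prep <- prepare_objective_table(candidates, queries)
  objective_from_prepared(prep, as.numeric(w))
}

#' Optimize the per-level bonus weights
#'
#' Maximizes the rank-1 hit count over the weight cube. Three strategies:
#' `"grid"` evaluates an exhaustive lattice with spacing `grid_step` (the
#' testable oracle), `"random"` samples `n_init + n_iter` uniform points, and
#' `"surrogate"` runs a sequential expected-improvement search (`n_init`
#' random points, then `n_iter` acquisitions from a radial-basis surrogate:
#' inverse-distance-weighted mean, distance-based uncertainty, exploration
#' constant `kappa`). All strategies evaluate the same pure objective, never
#' return a point worse than the best evaluated, and are deterministic given
#' `seed`.
#'
#' Ties on the maximum are resolved toward the smallest weight sum (then
#' lexicographically): the minimal bonus achieving the maximum, mirroring the
#' minimal-dominance construction of the default weights.
#'
#' @param candidates,queries the (possibly degraded) annotation dataset.
#' @param method `"grid"`, `"random"` or `"surrogate"`.
#' @param bounds length-2 numeric, identical per axis (default `c(0, 3)`).
#' @param grid_step lattice spacing for `"grid"` (default 0.25).
#' @param n_init,n_iter initial random points and sequential iterations
#'   (defaults 10 and 100).
#' @param kappa exploration constant of the surrogate acquisition
#'   (default 5.152).
#' @param seed integer seed for the stochastic strategies.
#' @return an `optimization_trace`: list with `trace` (tibble of evaluated
#'   points and objective values), `best` (a [weight_vector()]),
#'   `best_objective`, `method`, `bounds`, `seed`.
#' @export
optimize_weights <- function(candidates, queries,
                             method = c("grid", "random", "surrogate"),
                             bounds = c(0, 3), grid_step = 0.25,
                             n_init = 10L, n_iter = 100L, kappa = 5.152,
                             seed = 1L) {
  method <- match.arg(method)
  if (length(bounds) != 2L || !is.numeric(bounds) || bounds[1L] >= bounds[2L]) {
    stop("bounds must be an increasing numeric pair", call. = FALSE)
  }
  if (method != "grid" && (n_init < 1L || n_iter < 0L)) {
    stop("n_init must be >= 1 and n_iter >= 0", call. = FALSE)
  }
  if (method == "grid" && grid_step <= 0) {
    stop("grid_step must be positive", call. = FALSE)
  }
  prep <- prepare_objective_table(candidates, queries)
  f <- function(w) objective_from_prepared(prep, w)

  pts <- switch(method,
    grid = {
      axis <- seq(bounds[1L], bounds[2L], by = grid_step)
      as.matrix(expand.grid(w_family = axis, w_genus = axis,
                            w_species = axis))
    },
    random = withr::with_seed(seed, matrix(
      stats::runif(3L * (n_init + n_iter), bounds[1L], bounds[2L]),
      ncol = 3L, dimnames = list(NULL, c("w_family", "w_genus", "w_species")))),
    surrogate = NULL)

  if (method %in% c("grid", "random")) {
    obj <- apply(pts, 1L, f)
  } else {
    res <- withr::with_seed(seed,
      surrogate_search(f, bounds, n_init, n_iter, kappa))
    pts <- res$pts
    obj <- res$obj
  }
  trace <- tibble::as_tibble(pts)
  trace$objective <- obj
  best_i <- pick_best(pts, obj)
  structure(list(trace = trace,
                 best = weight_vector(pts[best_i, 1L], pts[best_i, 2L],
                                      pts[best_i, 3L]),
                 best_objective = obj[best_i],
                 method = method, bounds = bounds, seed = seed),
            class = "optimization_trace")
}

# argmax with parsimony tie-break: smallest weight sum, then lexicographic
pick_best <- function(pts, obj) {
  top <- which(obj == max(obj))
  o <- order(rowSums(pts[top, , drop = FALSE]),
             pts[top, 1L], pts[top, 2L], pts[top, 3L])
  top[o[1L]]
}

# sequential expected-improvement search on a radial-basis surrogate
surrogate_search <- function(f, bounds, n_init, n_iter, kappa) {
  rand_pts <- function(n) matrix(stats::runif(3L * n, bounds[1L], bounds[2L]),
                                 ncol = 3L)
  pts <- rand_pts(n_init)
  obj <- apply(pts, 1L, f)
  for (it in seq_len(n_iter)) {
    pool <- rand_pts(256L)
    d <- as.matrix(stats::dist(rbind(pool, pts)))
    d <- d[seq_len(nrow(pool)), nrow(pool) + seq_len(nrow(pts)), drop = FALSE]
    w <- 1 / (d + 1e-9)^2
    mu <- as.numeric(w %*% obj) / rowSums(w)
    sd_obj <- stats::sd(obj)
    if (!is.finite(sd_obj) || sd_obj == 0) sd_obj <- 1
    sigma <- sd_obj * apply(d, 1L, min) / (diff(bounds) + 1e-9)
    best <- max(obj)
    z <- (mu - best) / (sigma + 1e-12)
    # expected improvement plus a kappa-weighted exploration term, so flat
    # plateaus (integer-valued objective) still get explored
    ei <- (mu - best) * stats::pnorm(z) + sigma * stats::dnorm(z) +
      kappa * sigma
    nxt <- pool[which.max(ei), , drop = FALSE]
    pts <- rbind(pts, nxt)
    obj <- c(obj, f(as.numeric(nxt)))
  }
  colnames(pts) <- c("w_family", "w_genus", "w_species")
  list(pts = pts, obj = obj)
}

#' @export
print.optimization_trace <- function(x, ...) {
  cat(sprintf("<optimization trace> method %s | %d evaluations | best %d hits\n",
              x$method, nrow(x$trace), x$best_objective))
  print(x$best)
  invisible(x)
}

#' Average the best weights across repeated optimization runs
#'
#' Component-wise arithmetic mean of each run's best point, with the
#' per-axis spread (standard deviation, 0 for a single run) reported
#' alongside.
#'
#' @param runs list of `optimization_trace` objects (at least one).
#' @return list with `weights` (a [weight_vector()]), `spread` (named
#'   per-axis sd) and `n_runs`.
#' @export
repeat_and_average <- function(runs) {
  if (length(runs) == 0L) {
    stop("need at least one optimization run to average", call. = FALSE)
  }
  bests <- do.call(rbind, lapply(runs, function(r) as.numeric(r$best)))
  colnames(bests) <- c("family", "genus", "species")
  avg <- colMeans(bests)
  spread <- if (nrow(bests) > 1L) apply(bests, 2L, stats::sd) else
    stats::setNames(rep(0, 3L), colnames(bests))
  list(weights = weight_vector(avg[["family"]], avg[["genus"]],
                               avg[["species"]]),
       spread = spread, n_runs = length(runs))
}
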