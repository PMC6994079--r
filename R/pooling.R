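# Partitioning primer pairs into subpools by randomized hill climbing.
#
# Every interaction value is mapped to an integer "range" (the score itself,
# or int(-2 * dG) for free energies, i.e. 0.5 kcal/mol ranges).  A pair's
# pool score is a 4-tuple over the interactions between its two primers and
# the primers of every OTHER pair sharing its pool:
#   d1 = worst range present, d2 = count at d1, d3 = count at d1 - 1,
#   d4 = count at d1 - 2;
# tuples compare lexicographically and counters saturate at 65535.
# Zero-range (no-interaction) entries never enter the counts.

SATURATED_RANGE <- 65535L
COUNTER_MAX <- 65535L

#' Map an interaction value onto the integer range scale
#'
#' Scores map to themselves; free energies map via `int(-2 * dG)`
#' (truncation toward zero), splitting the dG axis into ranges of width
#' 0.5 kcal/mol.  Results are clamped to \[0, 65535\].
#'
#' @param x Numeric vector of interaction values.
#' @param mode `"score"` or `"dG"`.
#' @return Integer vector of ranges.
#' @examples
#' range_of(-7, "dG")    # 14
#' range_of(-1.25, "dG") # 2
#' @export
range_of <- function(x, mode = c("dG", "score")) {
  mode <- match.arg(mode)
  r <- if (mode == "dG") trunc(-2 * x) else trunc(x)
  as.integer(pmin(pmax(r, 0), SATURATED_RANGE))
}

# Pair-level interaction ranges from a complete interaction table.
# r4[p, q, ] holds the ranges of the four cross-primer interactions
# (pF.qF, pF.qR, pR.qF, pR.qR); saturated (overlap-constrained) entries are
# forced to SATURATED_RANGE.  Unpaired records are ignored here: the
# partitioner moves pairs.
pair_interaction_ranges <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  pi <- table$primers$pair_index
  ids <- sort(unique(pi[!is.na(pi)]))
  np <- length(ids)
  fwd <- match(ids, ifelse(table$primers$role == "forward", pi, NA))
  rev <- match(ids, ifelse(table$primers$role == "reverse", pi, NA))
  rng <- matrix(range_of(table$value, table$mode),
                nrow(table$value), ncol(table$value))
  rng[table$saturated] <- SATURATED_RANGE
  r4 <- array(0L, dim = c(np, np, 4L))
  for (a in seq_len(np)) {
    r4[a, , 1L] <- rng[fwd[a], fwd]
    r4[a, , 2L] <- rng[fwd[a], rev]
    r4[a, , 3L] <- rng[rev[a], fwd]
    r4[a, , 4L] <- rng[rev[a], rev]
  }
  for (a in seq_len(np)) r4[a, a, ] <- 0L   # own F-R is pool-invariant
  list(ids = ids, np = np, r4 = r4,
       r4max = apply(r4, c(1L, 2L), max))
}

# 4-tuple pool score from a vector of interaction ranges
score_tuple <- function(ranges) {
  ranges <- ranges[ranges > 0L]
  if (length(ranges) == 0L) return(c(0L, 0L, 0L, 0L))
  d1 <- max(ranges)
  cnt <- function(r) if (r < 1L) 0L else min(sum(ranges == r), COUNTER_MAX)
  c(d1, cnt(d1), cnt(d1 - 1L), cnt(d1 - 2L))
}

# lexicographic comparison: -1 if a < b, 0 if equal, 1 if a > b
lex_cmp <- function(a, b) {
  d <- which(a != b)
  if (length(d) == 0L) return(0L)
  if (a[d[1L]] < b[d[1L]]) -1L else 1L
}

new_pool_assignment <- function(pool_of, k, size_cap, ids) {
  structure(list(pool_of = stats::setNames(as.integer(pool_of),
                                           as.character(ids)),
                 k = as.integer(k),
                 size_cap = size_cap,
                 pair_ids = ids),
            class = "pool_assignment")
}

#' @export
print.pool_assignment <- function(x, ...) {
  sizes <- tabulate(x$pool_of, nbins = x$k)
  cat(sprintf("Pool assignment: %d pairs in %d pools (sizes %s)\n",
              length(x$pool_of), x$k, paste(sizes, collapse = "/")))
  invisible(x)
}

#' Pool score of one pair in a given pool
#'
#' Aggregates the interaction ranges between the pair's two primers and the
#' primers of every other pair currently assigned to `pool`.
#'
#' @param pair Pair id (as in the assignment).
#' @param pool Pool index to evaluate the pair in (its own or hypothetical).
#' @param assignment A `pool_assignment`.
#' @param table The complete `interaction_table` (with any overlap
#'   constraints already applied).
#' @return Integer 4-tuple `(d1, d2, d3, d4)`.
#' @export
pool_score <- function(pair, pool, assignment, table) {
  ctx <- pair_interaction_ranges(table)
  pool_score_ctx(match(pair, ctx$ids), pool, assignment$pool_of, ctx)
}

pool_score_ctx <- function(p, pool, pool_of, ctx) {
  members <- which(pool_of == pool)
  members <- members[members != p]
  if (length(members) == 0L) return(c(0L, 0L, 0L, 0L))
  score_tuple(as.vector(ctx$r4[p, members, ]))
}

# Whole-assignment score: 4-tuple over all co-pooled cross-pair interactions
# (each unordered pair of pairs counted once).
global_score_ctx <- function(pool_of, ctx) {
  ranges <- integer(0)
  for (k in unique(pool_of)) {
    members <- which(pool_of == k)
    if (length(members) < 2L) next
    comb <- utils::combn(members, 2L)
    for (c0 in seq_len(ncol(comb))) {
      ranges <- c(ranges, ctx$r4[comb[1L, c0], comb[2L, c0], ])
    }
  }
  score_tuple(ranges)
}

#' Overall pool score of an assignment
#'
#' The 4-tuple `(d1, d2, d3, d4)` over every intra-pool cross-pair
#' interaction in the whole assignment; this is the quantity the
#' partitioner's saved-best sequence minimizes.
#'
#' @inheritParams pool_score
#' @return Integer 4-tuple.
#' @export
assignment_score <- function(assignment, table) {
  ctx <- pair_interaction_ranges(table)
  global_score_ctx(assignment$pool_of, ctx)
}

#' Suggest a number of subpools by first-fit threshold packing
#'
#' Pairs are processed in input order; each goes into the first existing
#' pool where its worst cross-interaction stays weaker than dG -7 kcal/mol
#' (range < 14) and no overlap constraint binds; a new pool opens when none
#' fits.
#'
#' @param table A complete `interaction_table` in dG mode with overlap
#'   constraints applied.
#' @return Suggested pool count (integer >= 1).
#' @export
suggest_pool_count <- function(table) {
  ctx <- pair_interaction_ranges(table)
  if (ctx$np == 0L) return(1L)
  pools <- list()
  for (p in seq_len(ctx$np)) {
    placed <- FALSE
    for (k in seq_along(pools)) {
      if (all(ctx$r4max[p, pools[[k]]] < 14L)) {
        pools[[k]] <- c(pools[[k]], p); placed <- TRUE; break
      }
    }
    if (!placed) pools[[length(pools) + 1L]] <- p
  }
  length(pools)
}

# pools with room for one more pair
open_pools <- function(pool_of, k, size_cap) {
  if (is.null(size_cap)) return(seq_len(k))
  sizes <- tabulate(pool_of, nbins = k)
  which(sizes < size_cap)
}

#' Best positive-benefit move of any pair to another pool
#'
#' All pairs are searched for the move that most reduces their own pool
#' score, ranking reductions lexicographically (worst-range reduction first,
#' then the counts).  Ties break to the lowest pair id, then the lowest
#' target pool.  Moves into pools at their size cap are ineligible.
#'
#' @inheritParams pool_score
#' @return A list `(pair, from, to, benefit)` or `NULL` at a local optimum.
#' @export
best_move <- function(assignment, table) {
  ctx <- pair_interaction_ranges(table)
  mv <- best_move_ctx(assignment$pool_of, assignment$k, assignment$size_cap,
                      ctx)
  if (is.null(mv)) return(NULL)
  list(pair = ctx$ids[mv$p], from = mv$from, to = mv$to,
       benefit = mv$benefit)
}

best_move_ctx <- function(pool_of, k, size_cap, ctx) {
  best <- NULL
  open <- open_pools(pool_of, k, size_cap)
  for (p in seq_len(ctx$np)) {
    cur_pool <- pool_of[p]
    cur <- pool_score_ctx(p, cur_pool, pool_of, ctx)
    if (all(cur == 0L)) next   # nothing to gain
    for (t in seq_len(k)) {
      if (t == cur_pool || !(t %in% open)) next
      cand <- pool_score_ctx(p, t, pool_of, ctx)
      if (lex_cmp(cand, cur) >= 0L) next
      benefit <- cur - cand
      if (is.null(best) || lex_cmp(benefit, best$benefit) > 0L) {
        best <- list(p = p, from = cur_pool, to = t, benefit = benefit)
      }
    }
  }
  best
}

climb_ctx <- function(pool_of, k, size_cap, ctx, max_steps = NULL) {
  if (is.null(max_steps)) max_steps <- 50L * ctx$np
  for (s in seq_len(max_steps)) {
    mv <- best_move_ctx(pool_of, k, size_cap, ctx)
    if (is.null(mv)) break
    pool_of[mv$p] <- mv$to
  }
  pool_of
}

random_init_ctx <- function(np, k, size_cap) {
  if (is.null(size_cap)) {
    sample.int(k, np, replace = TRUE)
  } else {
    # randomized round-robin keeps every pool within the cap
    pool_of <- integer(np)
    pool_of[sample.int(np)] <- rep_len(sample.int(k), np)
    pool_of
  }
}

#' Apply random "bad moves" to escape a local optimum
#'
#' Between 1 and `max_bad` uniformly chosen pairs are reassigned to
#' uniformly chosen other pools (respecting the size cap).
#'
#' @inheritParams pool_score
#' @param max_bad Maximum number of bad moves; default
#'   `max(2, n_pairs / 10)`.
#' @return The perturbed `pool_assignment`.
#' @export
perturb_assignment <- function(assignment, table, max_bad = NULL) {
  ctx <- pair_interaction_ranges(table)
  pool_of <- perturb_ctx(assignment$pool_of, assignment$k,
                         assignment$size_cap, ctx$np, max_bad)
  new_pool_assignment(pool_of, assignment$k, assignment$size_cap, ctx$ids)
}

perturb_ctx <- function(pool_of, k, size_cap, np, max_bad = NULL) {
  if (is.null(max_bad)) max_bad <- max(2L, np %/% 10L)
  n_bad <- sample.int(max_bad, 1L)
  for (b in seq_len(n_bad)) {
    p <- sample.int(np, 1L)
    open <- setdiff(open_pools(pool_of, k, size_cap), pool_of[p])
    if (length(open) == 0L) next
    pool_of[p] <- open[sample.int(length(open), 1L)]
  }
  pool_of
}

#' Partition primer pairs into k subpools by hill climbing with restarts
#'
#' Starting from a uniform-random assignment, the partitioner alternates
#' best-move hill climbing, saving the best state seen, random bad-move
#' perturbation, and full re-randomization when a perturbation converges on
#' a worse state.  It stops after `max_stale` consecutive cycles without
#' improving the saved best (or at `time_limit`), returning the best state
#' found.  Runs are reproducible given the seed.
#'
#' @param table Complete `interaction_table` with overlap constraints
#'   applied.
#' @param k Number of pools (1 <= k <= number of pairs).
#' @param size_cap Optional maximum number of pairs per pool.
#' @param seed Integer seed controlling the whole run.
#' @param max_stale Consecutive non-improving perturbation/restart cycles
#'   before stopping.
#' @param time_limit Optional wall-clock limit in seconds.
#' @param verbose Emit a per-epoch summary of pool sizes and the current
#'   best score.
#' @return A `pool_assignment` with attribute `score` (the final 4-tuple)
#'   and `trace` (the monotone saved-best score sequence, one row per
#'   improvement).
#' @export
partition_pools <- function(table, k, size_cap = NULL, seed = 1L,
                            max_stale = 200L, time_limit = NULL,
                            verbose = FALSE) {
  ctx <- pair_interaction_ranges(table)
  np <- ctx$np
  if (np == 0L) stop("no primer pairs to partition", call. = FALSE)
  if (k < 1L || k > np) {
    stop(sprintf("k must be in [1, %d] (number of pairs)", np), call. = FALSE)
  }
  if (!is.null(size_cap) && size_cap * k < np) {
    stop(sprintf("infeasible: size_cap %d x %d pools < %d pairs",
                 size_cap, k, np), call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  t0 <- Sys.time()
  timed_out <- function() {
    !is.null(time_limit) &&
      as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit
  }

  current <- climb_ctx(random_init_ctx(np, k, size_cap), k, size_cap, ctx)
  best <- current
  best_score <- global_score_ctx(current, ctx)
  trace <- matrix(best_score, nrow = 1L,
                  dimnames = list(NULL, c("d1", "d2", "d3", "d4")))
  stale <- 0L
  epoch <- 0L
  while (stale < max_stale && !timed_out() && any(best_score > 0L)) {
    epoch <- epoch + 1L
    saved <- current
    saved_score <- global_score_ctx(saved, ctx)
    current <- climb_ctx(perturb_ctx(current, k, size_cap, np),
                         k, size_cap, ctx)
    if (lex_cmp(global_score_ctx(current, ctx), saved_score) >= 0L) {
      # converged on a worse (or equal) state: re-randomize instead
      current <- climb_ctx(random_init_ctx(np, k, size_cap), k, size_cap, ctx)
    }
    cur_score <- global_score_ctx(current, ctx)
    if (lex_cmp(cur_score, best_score) < 0L) {
      best <- current
      best_score <- cur_score
      trace <- rbind(trace, cur_score)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (verbose) {
      message(sprintf(
        "epoch %d: pool sizes %s; best score (%s)", epoch,
        paste(tabulate(current, nbins = k), collapse = "/"),
        paste(best_score, collapse = ",")))
    }
  }
  out <- new_pool_assignment(best, k, size_cap, ctx$ids)
  attr(out, "score") <- best_score
  rownames(trace) <- NULL
  attr(out, "trace") <- trace
  out
}
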