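test_that("range transform: identity on scores, int(-2 dG) on energies", {
  expect_equal(range_of(-7, "dG"), 14L)
  expect_equal(range_of(-1.25, "dG"), 2L)    # trunc(2.5) = 2
  expect_equal(range_of(-1.5, "dG"), 3L)
  expect_equal(range_of(8, "score"), 8L)
  expect_equal(range_of(0.25, "dG"), 0L)     # never negative
  expect_equal(range_of(-1e6, "dG"), 65535L) # saturates
})

test_that("pool score counts interactions at the worst three ranges", {
  # neighbours contribute ranges {8, 8, 7, 5} -> (8, 2, 1, 0)
  tab <- make_interaction_table(3)
  # pair 1 vs pair 2: F-F 8, F-R 8; pair 1 vs pair 3: F-F 7, F-R 5
  tab$value[1, 3] <- tab$value[3, 1] <- 8
  tab$value[1, 4] <- tab$value[4, 1] <- 8
  tab$value[1, 5] <- tab$value[5, 1] <- 7
  tab$value[1, 6] <- tab$value[6, 1] <- 5
  asn <- structure(list(pool_of = c("1" = 1L, "2" = 1L, "3" = 1L),
                        k = 1L, size_cap = NULL, pair_ids = 1:3),
                   class = "pool_assignment")
  expect_equal(pool_score(1L, 1L, asn, tab), c(8L, 2L, 1L, 0L))
  # alone in a pool: all-zero score
  expect_equal(pool_score(1L, 2L, structure(list(
    pool_of = c("1" = 2L, "2" = 1L, "3" = 1L), k = 2L, size_cap = NULL,
    pair_ids = 1:3), class = "pool_assignment"), tab),
    c(0L, 0L, 0L, 0L))
})

test_that("first-fit dG -7 packing suggests pool counts", {
  # no interaction at or beyond -7: one pool suffices
  quiet <- make_interaction_table(4)
  quiet$mode <- "dG"
  expect_equal(suggest_pool_count(quiet), 1L)

  # pairs 1-2 and 2-3 linked at dG -8; 1-3 clean -> pools {1,3} {2}
  chain <- make_interaction_table(3)
  chain$mode <- "dG"
  chain$value[1, 3] <- chain$value[3, 1] <- -8   # AMP01-F x AMP02-F
  chain$value[3, 5] <- chain$value[5, 3] <- -8   # AMP02-F x AMP03-F
  expect_equal(suggest_pool_count(chain), 2L)

  # three pairwise overlaps force three pools
  tri <- make_interaction_table(3)
  tri$mode <- "dG"
  rep3 <- structure(list(overlaps = data.frame(
    pair_a = c(1L, 1L, 2L), pair_b = c(2L, 3L, 3L), chrom = "chr1",
    shared_start = 1, shared_end = 2, stringsAsFactors = FALSE),
    unmatched_pairs = NULL), class = "overlap_report")
  expect_equal(suggest_pool_count(overlap_constraints(tri, rep3)), 3L)
})

test_that("best_move separates strong interactions and detects optima", {
  tab <- make_interaction_table(2, cliques = list(c(1, 2)), clique_score = 10)
  co <- structure(list(pool_of = c("1" = 1L, "2" = 1L), k = 2L,
                       size_cap = NULL, pair_ids = 1:2),
                  class = "pool_assignment")
  mv <- best_move(co, tab)
  expect_false(is.null(mv))
  expect_equal(mv$to, 2L)
  expect_gt(mv$benefit[1], 0)

  apart <- structure(list(pool_of = c("1" = 1L, "2" = 2L), k = 2L,
                          size_cap = NULL, pair_ids = 1:2),
                     class = "pool_assignment")
  expect_null(best_move(apart, tab))

  # moves into capped pools are ineligible
  capped <- structure(list(pool_of = c("1" = 1L, "2" = 1L, "3" = 2L),
                           k = 2L, size_cap = 1L, pair_ids = 1:3),
                      class = "pool_assignment")
  tab3 <- make_interaction_table(3, cliques = list(c(1, 2)),
                                 clique_score = 10)
  expect_null(best_move(capped, tab3))
})

test_that("perturbation is seeded-deterministic and respects the cap", {
  tab <- make_interaction_table(6, random = TRUE, seed = 2)
  asn <- partition_pools(tab, k = 3, seed = 4, max_stale = 5)
  runs <- lapply(1:2, function(i) {
    set.seed(99)
    perturb_assignment(asn, tab)$pool_of
  })
  expect_identical(runs[[1]], runs[[2]])

  capped <- partition_pools(tab, k = 3, size_cap = 2L, seed = 4,
                            max_stale = 5)
  set.seed(1)
  for (i in 1:20) {
    p <- perturb_assignment(capped, tab)
    expect_true(all(tabulate(p$pool_of, nbins = 3) <= 2L))
  }
})

test_that("separable cliques partition to zero cross-interaction", {
  tab <- make_interaction_table(4, cliques = list(c(1, 2), c(3, 4)),
                                clique_score = 10)
  asn <- partition_pools(tab, k = 2, seed = 5)
  expect_equal(attr(asn, "score"), c(0L, 0L, 0L, 0L))
  expect_true(asn$pool_of[["1"]] != asn$pool_of[["2"]])
  expect_true(asn$pool_of[["3"]] != asn$pool_of[["4"]])

  # k = 1 puts everything together; score equals the whole-set score
  one <- partition_pools(tab, k = 1, seed = 5, max_stale = 2)
  expect_equal(unname(unique(one$pool_of)), 1L)
  expect_equal(attr(one, "score"), assignment_score(one, tab))
  expect_equal(attr(one, "score")[1], 10L)
})

test_that("hill climbing attains the exhaustive optimum on small instances", {
  for (seed in 1:5) {
    np <- c(7L, 8L, 9L, 10L, 8L)[seed]
    k <- c(2L, 3L, 2L, 2L, 3L)[seed]
    tab <- make_interaction_table(np, random = TRUE, max_score = 6,
                                  seed = seed)
    asn <- partition_pools(tab, k = k, seed = seed)
    expect_equal(attr(asn, "score"), exhaustive_best_score(tab, k),
                 info = sprintf("seed %d: %d pairs, %d pools", seed, np, k))
  }
})

test_that("saved-best trace is monotone and runs are reproducible", {
  tab <- make_interaction_table(10, random = TRUE, seed = 6)
  a1 <- partition_pools(tab, k = 3, seed = 11, max_stale = 40)
  a2 <- partition_pools(tab, k = 3, seed = 11, max_stale = 40)
  expect_identical(a1$pool_of, a2$pool_of)
  expect_identical(attr(a1, "score"), attr(a2, "score"))
  tr <- attr(a1, "trace")
  if (nrow(tr) > 1) {
    for (i in 2:nrow(tr)) {
      expect_equal(poolprimers:::lex_cmp(tr[i, ], tr[i - 1, ]), -1L)
    }
  }
  # a different seed is allowed to differ, but scores remain valid 4-tuples
  a3 <- partition_pools(tab, k = 3, seed = 12, max_stale = 40)
  expect_length(attr(a3, "score"), 4L)
})

test_that("infeasible partitions are rejected up front", {
  tab <- make_interaction_table(4)
  expect_error(partition_pools(tab, k = 5, seed = 1), "k must be")
  expect_error(partition_pools(tab, k = 2, size_cap = 1L, seed = 1),
               "infeasible")
})

test_that("saturated overlap entries dominate every returned assignment", {
  tab <- make_interaction_table(4, random = TRUE, seed = 3)
  rep0 <- structure(list(overlaps = data.frame(
    pair_a = 1L, pair_b = 3L, chrom = "chr1", shared_start = 1,
    shared_end = 2, stringsAsFactors = FALSE), unmatched_pairs = NULL),
    class = "overlap_report")
  tab <- overlap_constraints(tab, rep0)
  for (seed in 1:5) {
    asn <- partition_pools(tab, k = 2, seed = seed, max_stale = 20)
    expect_true(asn$pool_of[["1"]] != asn$pool_of[["3"]],
                info = sprintf("seed %d", seed))
  }
})
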