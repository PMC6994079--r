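test_that("match score maximizes bonds minus interior mismatches", {
  expect_equal(match_score("AAAA", "TTTT")$best_score, 4L)
  expect_equal(match_score("AAAA", "AAAA")$best_score, 0L)
  expect_equal(match_score("ACGT", "ACGT")$best_score, 4L)
  # interior mismatch penalized: AACAA vs TTTTT bonds 2+2 around a C.T gap
  expect_equal(match_score("AACAA", "TTTTT")$best_score,
               naive_match_score("AACAA", "TTTTT"))
})

test_that("match score equals the exhaustive per-offset reference", {
  set.seed(202)
  for (i in 1:50) {
    s1 <- random_acgt(sample(4:16, 1))
    s2 <- random_acgt(sample(4:16, 1))
    expect_equal(match_score(s1, s2)$best_score, naive_match_score(s1, s2),
                 info = paste(s1, s2))
  }
})

test_that("interaction scoring is symmetric in its arguments", {
  set.seed(301)
  params <- thermo_params(temperature = 60, sodium = 0.05)
  for (i in 1:15) {
    s1 <- random_acgt(sample(6:14, 1))
    s2 <- random_acgt(sample(6:14, 1))
    expect_equal(match_score(s1, s2)$best_score,
                 match_score(s2, s1)$best_score)
    expect_equal(delta_g(s1, s2, params)$best_dg,
                 delta_g(s2, s1, params)$best_dg, tolerance = 1e-12)
  }
})

test_that("a perfect two-base duplex reproduces its tabulated stack energy", {
  # at 1 M Na+ the salt term vanishes: dG(37) of the AA/TT stack is
  # dH - 310.15 * dS / 1000 = -7.9 + 310.15 * 0.0222
  params <- thermo_params(temperature = 37, sodium = 1)
  expect_equal(delta_g("AA", "TT", params)$best_dg,
               -7.9 - 310.15 * (-22.2) / 1000, tolerance = 1e-9)
  # and the whole-duplex energy of a longer perfect match is the stack sum
  s <- "ACGTCA"
  expected <- sum(vapply(1:5, function(i) {
    x <- substring(s, i, i); y <- substring(s, i + 1, i + 1)
    hs <- poolprimers:::nn_lookup(x, y, chartr("ACGT", "TGCA", x),
                                  chartr("ACGT", "TGCA", y))
    hs[1] - 310.15 * hs[2] / 1000
  }, numeric(1)))
  expect_equal(delta_g(s, reverse_complement(s), params)$best_dg, expected,
               tolerance = 1e-9)
})

test_that("no two consecutive bonds means no stable interaction", {
  # alternating single bonds only: A.A mismatches between A-T bonds would be
  # needed; use sequences whose best alignment isolates every bond
  res <- delta_g("ATAT", "ATAT", thermo_params())
  # palindrome anneals perfectly; use a genuinely stack-free pair instead
  res2 <- delta_g("AAAA", "AAAA", thermo_params())
  expect_equal(res2$best_dg, 0)
  expect_true(res$best_dg < 0)
})

test_that("recomputing at the reported offset reproduces best_dg", {
  set.seed(404)
  params <- thermo_params(temperature = 60, sodium = 0.05)
  for (i in 1:20) {
    s1 <- random_acgt(sample(8:16, 1))
    s2 <- random_acgt(sample(8:16, 1))
    r <- delta_g(s1, s2, params)
    if (r$best_dg < 0) {
      expect_equal(duplex_dg(s1, s2, r$best_offset_dg, params), r$best_dg,
                   tolerance = 1e-12)
    }
  }
})

test_that("extending both primers with a complementary base never destabilizes", {
  set.seed(505)
  params <- thermo_params(temperature = 37, sodium = 0.05)
  for (i in 1:20) {
    s1 <- random_acgt(sample(6:12, 1))
    s2 <- random_acgt(sample(6:12, 1))
    base <- delta_g(s1, s2, params)$best_dg
    # append to s1's 3' end and prepend the complement to s2's 5' end:
    # the old best alignment still exists with one extra possible bond
    b <- sample(c("A", "C", "G", "T"), 1)
    ext <- delta_g(paste0(s1, b),
                   paste0(chartr("ACGT", "TGCA", b), s2), params)$best_dg
    expect_lte(ext, base + 1e-9)
  }
})

test_that("degenerate bonding is the union of its expansions' bonding", {
  # a degenerate position bonds iff some base choice bonds, so at every
  # offset the degenerate bond set contains each expansion's bond set
  set.seed(606)
  for (i in 1:10) {
    s1 <- random_acgt(10)
    pos <- sample(2:9, 1)
    s1deg <- s1
    substring(s1deg, pos, pos) <- "N"
    s2 <- random_acgt(10)
    d1 <- encode_degenerate(s1deg); d2 <- encode_degenerate(s2)
    for (v in expand_degenerate(s1deg)) {
      ev <- upgrade(encode_exact(v))
      for (k in seq.int(-9L, 9L)) {
        deg <- bond_pattern_degenerate(d1, d2, k)$bonds
        con <- bond_pattern_degenerate(ev, d2, k)$bonds
        expect_true(all(deg[con]),
                    info = sprintf("expansion %s offset %d", v, k))
      }
    }
    # and the degenerate evaluation itself completes with a defined result
    r <- delta_g(s1deg, s2, thermo_params())
    expect_true(is.finite(r$best_dg) && r$best_dg <= 0)
  }
})

test_that("all_interactions covers the handshake count, symmetric, both modes", {
  ps <- suppressWarnings(parse_primer_fasta(toy_primer_lines()))
  for (mode in c("score", "dG")) {
    tab <- all_interactions(ps, thermo_params(60, 0.05), mode = mode)
    n <- nrow(tab$primers)
    expect_equal(n, 6L)
    expect_true(isSymmetric(unname(tab$value)))
    h <- summarize_interactions(tab)
    expect_equal(sum(h), n * (n + 1L) / 2L)
  }
  # single primer -> one self interaction
  one <- suppressWarnings(parse_primer_fasta(c(">lone-F", "ACGTACGTACGTACG")))
  tab1 <- all_interactions(one, mode = "score")
  expect_equal(sum(summarize_interactions(tab1)), 1L)
})

test_that("tags take part in hybridization scoring", {
  # untagged primers that cannot interact; tags that anneal strongly
  lines <- c(">tagF", "CCCCCCCCCCCC", ">tagR", "GGGGGGGGGGGG",
             ">A-F", "AAAAAAAAAA", ">A-R", "AAAAAAAAAA")
  ps <- apply_tags(parse_primer_fasta(lines))
  tab <- all_interactions(ps, mode = "score")
  # the C tag on the forward anneals to the G tag on the reverse
  fr <- tab$value["A-F", "A-R"]
  expect_gte(fr, 12L)
  untagged <- parse_primer_fasta(c(">A-F", "AAAAAAAAAA", ">A-R", "AAAAAAAAAA"))
  expect_equal(all_interactions(untagged, mode = "score")$value["A-F", "A-R"],
               0)
})

test_that("dG histogram uses half-kcal ranges via int(-2 dG)", {
  expect_equal(range_of(-7, "dG"), 14L)
  expect_equal(range_of(-1.5, "dG"), 3L)
  expect_equal(range_of(0, "dG"), 0L)
  tab <- all_interactions(suppressWarnings(parse_primer_fasta(
    toy_primer_lines())), thermo_params(60, 0.05), mode = "dG")
  h <- summarize_interactions(tab)
  v <- tab$value[upper.tri(tab$value, diag = TRUE)]
  for (b in names(h)) {
    expect_equal(unname(h[[b]]), sum(trunc(-2 * v) == as.integer(b)))
  }
})

test_that("bonding diagrams render bonds and honor threshold ordering", {
  r <- match_score("AAAA", "TTTT")
  d <- bonding_diagram(r)
  expect_length(d, 4L)                       # header + three render lines
  expect_equal(sum(strsplit(d[3], "")[[1]] == "|"), 4L)
  # no bonds -> suppressed
  expect_length(bonding_diagram(match_score("AAAA", "AAAA")), 0L)

  ps <- suppressWarnings(parse_primer_fasta(toy_primer_lines()))
  tab <- all_interactions(ps, thermo_params(60, 0.05), mode = "dG")
  out <- bonding_diagrams(tab, threshold = 1L)
  heads <- grep("dG .* kcal/mol", out, value = TRUE)
  dgs <- as.numeric(sub(".*dG (-?[0-9.]+) kcal/mol.*", "\\1", heads))
  expect_false(is.unsorted(dgs))             # worst (most negative) first
  # a high threshold filters everything below it
  strong <- bonding_diagrams(tab, threshold = 14L)
  if (length(strong) > 0) {
    dgs14 <- as.numeric(sub(".*dG (-?[0-9.]+) kcal/mol.*", "\\1",
                            grep("kcal/mol", strong, value = TRUE)))
    expect_true(all(dgs14 <= -7))
  }
})
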