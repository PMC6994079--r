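# Independent reference implementations used as oracles.  These deliberately
# avoid the package's bit-plane, sweep and hill-climbing code paths: plain
# per-base loops, all-pairs interval checks and exhaustive enumeration.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"),
  H = c("A", "C", "T"), B = c("C", "G", "T"),
  V = c("A", "C", "G"), D = c("A", "G", "T"),
  N = c("A", "C", "G", "T")
)
COMP <- c(A = "T", C = "G", G = "C", T = "A")

# can the two IUPAC codes bond, i.e. do their base sets contain a
# complementary pair?
codes_may_bond <- function(x, y) {
  any(COMP[IUPAC_SETS[[x]]] %in% IUPAC_SETS[[y]])
}

# per-base loop: bonds between s1 (5'->3') and s2 presented antiparallel,
# at one signed offset (offset 0 aligns s1's 5' end with s2's 3' end)
naive_bond_count <- function(s1, s2, offset) {
  c1 <- strsplit(s1, "")[[1]]
  c2 <- rev(strsplit(s2, "")[[1]])   # 3'->5'
  n <- 0L
  for (i in seq_along(c1)) {
    j <- i - offset
    if (j >= 1L && j <= length(c2) && codes_may_bond(c1[i], c2[j])) {
      n <- n + 1L
    }
  }
  n
}

# match score at one offset: bonds minus non-bonded positions strictly
# between the first and last bond
naive_score_at <- function(s1, s2, offset) {
  c1 <- strsplit(s1, "")[[1]]
  c2 <- rev(strsplit(s2, "")[[1]])
  bonded <- integer(0)
  for (i in seq_along(c1)) {
    j <- i - offset
    if (j >= 1L && j <= length(c2) && codes_may_bond(c1[i], c2[j])) {
      bonded <- c(bonded, i)
    }
  }
  if (length(bonded) == 0L) return(0L)
  span <- max(bonded) - min(bonded) + 1L
  2L * length(bonded) - span
}

naive_match_score <- function(s1, s2) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  best <- 0L
  for (k in seq.int(-(n2 - 1L), n1 - 1L)) {
    best <- max(best, naive_score_at(s1, s2, k))
  }
  best
}

# all-pairs interval intersection between amplicons of different pairs
naive_overlaps <- function(amp) {
  out <- list()
  if (nrow(amp) >= 2L) {
    for (i in seq_len(nrow(amp) - 1L)) {
      for (j in (i + 1L):nrow(amp)) {
        if (amp$chrom[i] == amp$chrom[j] &&
            amp$pair_index[i] != amp$pair_index[j] &&
            amp$start[i] <= amp$end[j] && amp$start[j] <= amp$end[i]) {
          out[[length(out) + 1L]] <- data.frame(
            pair_a = min(amp$pair_index[c(i, j)]),
            pair_b = max(amp$pair_index[c(i, j)]),
            chrom = amp$chrom[i],
            shared_start = max(amp$start[c(i, j)]),
            shared_end = min(amp$end[c(i, j)]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(pair_a = integer(0), pair_b = integer(0),
                      chrom = character(0), shared_start = numeric(0),
                      shared_end = numeric(0), stringsAsFactors = FALSE))
  }
  o <- unique(do.call(rbind, out))
  o <- o[order(o$chrom, o$shared_start, o$pair_a, o$pair_b), , drop = FALSE]
  rownames(o) <- NULL
  o
}

# exact string search on both strands via Biostrings; the independent oracle
# for genome-scan completeness/soundness.  Returns the same columns as
# scan_genome(), sorted the same way.
oracle_scan <- function(genome, set, max_window = 32L) {
  recs <- poolprimers:::primer_records(set, tagged = FALSE)
  rows <- list()
  nm <- names(genome)
  for (i in seq_len(nrow(recs))) {
    s <- recs$sequence[i]
    win <- substring(s, max(1L, nchar(s) - max_window + 1L))
    for (v in expand_degenerate(win)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") v else reverse_complement(v)
        for (ch in seq_along(genome)) {
          m <- Biostrings::matchPattern(pat, genome[[ch]])
          if (length(m) == 0L) next
          st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
          rows[[length(rows) + 1L]] <- data.frame(
            primer = recs$name[i], pair_index = recs$pair_index[i],
            role = recs$role[i], chrom = nm[ch], strand = strand,
            site_start = as.numeric(st), site_end = as.numeric(en),
            pos3 = as.numeric(if (strand == "+") en else st),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  h <- do.call(rbind, rows)
  h <- h[order(h$chrom, h$site_start, h$site_end, h$primer), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# exhaustive search over all k^n assignments (pair 1 pinned to pool 1 --
# pool labels are exchangeable) for the lexicographically best global
# 4-tuple.  Scoring re-derived from the raw table, independent of the
# package's context builder.
exhaustive_best_score <- function(table, k) {
  pi <- table$primers$pair_index
  ids <- sort(unique(pi[!is.na(pi)]))
  np <- length(ids)
  rng <- matrix(poolprimers::range_of(table$value, table$mode),
                nrow(table$value))
  rng[table$saturated] <- 65535L
  rows_of <- lapply(ids, function(p) which(!is.na(pi) & pi == p))
  tuple <- function(assign) {
    ranges <- integer(0)
    for (a in seq_len(np - 1L)) {
      for (b in (a + 1L):np) {
        if (assign[a] == assign[b]) {
          ranges <- c(ranges, as.vector(rng[rows_of[[a]], rows_of[[b]]]))
        }
      }
    }
    ranges <- ranges[ranges > 0L]
    if (length(ranges) == 0L) return(c(0L, 0L, 0L, 0L))
    d1 <- max(ranges)
    c(d1, sum(ranges == d1),
      if (d1 >= 2L) sum(ranges == d1 - 1L) else 0L,
      if (d1 >= 3L) sum(ranges == d1 - 2L) else 0L)
  }
  lex_less <- function(a, b) {
    d <- which(a != b)
    length(d) > 0L && a[d[1L]] < b[d[1L]]
  }
  best <- NULL
  grid <- rep(list(seq_len(k)), np - 1L)
  assign <- integer(np)
  assign[1L] <- 1L
  recurse <- function(pos) {
    if (pos > np) {
      t <- tuple(assign)
      if (is.null(best) || lex_less(t, best)) best <<- t
      return(invisible())
    }
    for (g in seq_len(k)) {
      assign[pos] <<- g
      recurse(pos + 1L)
    }
  }
  recurse(2L)
  best
}

# small deterministic primer FASTA used by several files
toy_primer_lines <- function() {
  c(">tagF", "ACACTGACGACATGGTTCTACA",
    ">tagR", "TACGGTAGCAGAGACTTGGTCT",
    ">ARID1A_ex1-F", "CGCCGTCTTCCACCAACAA",
    ">ARID1A_ex1-R", "GGTAGGCGCTGCGGTT",
    ">CIITA_ex5_1-F", "actcaccttgggctttcatt",
    ">CIITA_ex5_1-R", "agcaggctttggagtcaa",
    ">CCND3_ex2_1-F", "CtY c ag acc cagc agtga",
    ">CCND3_ex2_1-R", "GATG gTCAGGGGCGTGGT")
}

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
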