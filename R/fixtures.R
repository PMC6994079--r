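# Deterministic generators for synthetic primer sets, toy genomes (FASTA and
# 2bit) and interaction tables with known ground truth.  These are first-class
# package functionality: every stage of the pipeline can be exercised, with
# exact expected results, without downloading any reference data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic primer set
#'
#' Primer names follow the pairing convention (`AMP01-F` / `AMP01-R`);
#' optional `tagF`/`tagR` records are emitted first.  Degenerate codes are
#' injected at known positions in the first `n_degenerate` primers.
#' Output is byte-identical under a fixed seed.
#'
#' @param n_pairs Number of primer pairs.
#' @param primer_len Length range (min, max) primer lengths are drawn from.
#' @param n_degenerate Number of primers that receive one degenerate code.
#' @param with_tags Emit common 5' tag records?
#' @param seed Integer seed.
#' @return A list: `fasta` (the FASTA lines), `set` (the parsed
#'   `primer_set`), and `degenerate_primers` (names of records carrying a
#'   degenerate code).
#' @export
make_primer_set <- function(n_pairs = 6L, primer_len = c(18L, 22L),
                            n_degenerate = 0L, with_tags = FALSE, seed = 1L) {
  stopifnot(n_pairs >= 1L, n_degenerate <= 2L * n_pairs)
  with_seed(seed, {
    lens <- sample(seq(primer_len[1L], primer_len[2L]), 2L * n_pairs,
                   replace = TRUE)
    seqs <- vapply(lens, random_bases, character(1))
    names <- as.vector(rbind(sprintf("AMP%02d-F", seq_len(n_pairs)),
                             sprintf("AMP%02d-R", seq_len(n_pairs))))
    seqs <- seqs[order(rep(seq_len(n_pairs), each = 2L))]
    deg_names <- character(0)
    if (n_degenerate > 0L) {
      deg_code <- c(A = "R", C = "Y", G = "S", T = "W")  # code includes base
      for (i in seq_len(n_degenerate)) {
        pos <- sample.int(nchar(seqs[i]) - 2L, 1L) + 1L  # not at the ends
        base <- substring(seqs[i], pos, pos)
        substring(seqs[i], pos, pos) <- deg_code[[base]]
        deg_names <- c(deg_names, names[i])
      }
    }
    fasta <- character(0)
    if (with_tags) {
      fasta <- c(">tagF", random_bases(22L), ">tagR", random_bases(22L))
    }
    fasta <- c(fasta, as.vector(rbind(paste0(">", names), seqs)))
    list(fasta = fasta,
         set = parse_primer_fasta(fasta),
         degenerate_primers = deg_names)
  })
}

#' Generate a toy genome with planted amplicons, in FASTA and 2bit
#'
#' A uniform-random background is generated per chromosome, then each row of
#' `layout` plants one amplicon: the pair's opening primer sequence at the
#' amplicon start and the reverse complement of the closing primer at the
#' end (concrete first expansion for degenerate primers).  Generation
#' verifies that every planted variant occurs exactly as often as planted
#' (no accidental background occurrences) and redraws the background
#' otherwise.  Expected hits, amplicons and overlaps are returned as exact
#' ground truth.
#'
#' @param set A `primer_set` (see [make_primer_set()]).
#' @param layout Data frame with columns `pair_index`, `chrom`, `start`,
#'   `length` and optionally `orientation` (default positive-strand-first).
#' @param genome_len Length of every chromosome.
#' @param chroms Chromosome names.
#' @param n_block Optional `c(start, length)` run of Ns inserted into the
#'   first chromosome (outside planted sites) to exercise invalid windows.
#' @param dir Directory the FASTA and 2bit twins are written to.
#' @param seed Integer seed.
#' @param max_retries Background redraws allowed on placement collision.
#' @return List: `genome` (DNAStringSet), `fasta_path`, `twobit_path`,
#'   `expected_hits`, `expected_amplicons`, `expected_overlaps`.
#' @export
make_genome <- function(set, layout, genome_len = 20000L,
                        chroms = "chr1", n_block = NULL,
                        dir = tempdir(), seed = 1L, max_retries = 20L) {
  stopifnot(inherits(set, "primer_set"),
            all(c("pair_index", "chrom", "start", "length") %in% names(layout)))
  if (is.null(layout$orientation)) layout$orientation <- "positive-strand-first"
  stopifnot(all(layout$chrom %in% chroms),
            all(layout$start + layout$length - 1L <= genome_len))
  pairs <- set$pairs
  concrete <- function(s) expand_degenerate(s)[1L]

  plant_one <- function(chrseq, row) {
    p <- pairs[pairs$index == row$pair_index, , drop = FALSE]
    stopifnot(nrow(p) == 1L)
    fwd <- concrete(p$fwd_seq); rev <- concrete(p$rev_seq)
    if (row$orientation == "positive-strand-first") {
      open_seq <- fwd; close_seq <- reverse_complement(rev)
    } else {
      open_seq <- rev; close_seq <- reverse_complement(fwd)
    }
    lo <- nchar(open_seq); lc <- nchar(close_seq)
    stopifnot(row$length >= lo + lc)
    end <- row$start + row$length - 1L
    substring(chrseq, row$start, row$start + lo - 1L) <- open_seq
    substring(chrseq, end - lc + 1L, end) <- close_seq
    chrseq
  }

  expected_for_layout <- function() {
    hits <- list(); amps <- list()
    for (r in seq_len(nrow(layout))) {
      row <- layout[r, ]
      p <- pairs[pairs$index == row$pair_index, , drop = FALSE]
      fwd <- concrete(p$fwd_seq); rev <- concrete(p$rev_seq)
      lf <- min(nchar(fwd), MAX_SCAN_BASES)
      lr <- min(nchar(rev), MAX_SCAN_BASES)
      end <- row$start + row$length - 1L
      pos_first <- row$orientation == "positive-strand-first"
      # matched windows are the last <=32 (3'-most) bases of each primer;
      # on the minus strand those bases sit at the left end of the planted
      # reverse-complemented sequence
      if (pos_first) {
        hits[[length(hits) + 1L]] <- data.frame(
          primer = c(p$fwd_name, p$rev_name),
          pair_index = row$pair_index,
          role = c("forward", "reverse"),
          chrom = row$chrom, strand = c("+", "-"),
          site_start = c(row$start + nchar(fwd) - lf,
                         end - nchar(rev) + 1L),
          site_end = c(row$start + nchar(fwd) - 1L,
                       end - nchar(rev) + lr),
          stringsAsFactors = FALSE)
        amp_start <- row$start + nchar(fwd) - lf
        amp_end <- end - nchar(rev) + lr
      } else {
        hits[[length(hits) + 1L]] <- data.frame(
          primer = c(p$rev_name, p$fwd_name),
          pair_index = row$pair_index,
          role = c("reverse", "forward"),
          chrom = row$chrom, strand = c("+", "-"),
          site_start = c(row$start + nchar(rev) - lr,
                         end - nchar(fwd) + 1L),
          site_end = c(row$start + nchar(rev) - 1L,
                       end - nchar(fwd) + lf),
          stringsAsFactors = FALSE)
        amp_start <- row$start + nchar(rev) - lr
        amp_end <- end - nchar(fwd) + lf
      }
      amps[[length(amps) + 1L]] <- data.frame(
        pair_index = row$pair_index, chrom = row$chrom,
        start = amp_start, end = amp_end,
        length = amp_end - amp_start + 1L,
        orientation = row$orientation, stringsAsFactors = FALSE)
    }
    h <- do.call(rbind, hits)
    h$pos3 <- ifelse(h$strand == "+", h$site_end, h$site_start)
    h <- h[order(h$chrom, h$site_start, h$site_end, h$primer), , drop = FALSE]
    rownames(h) <- NULL
    a <- do.call(rbind, amps)
    a <- a[order(a$chrom, a$start, a$end, a$pair_index), , drop = FALSE]
    rownames(a) <- NULL
    list(hits = h, amplicons = a)
  }

  expected <- expected_for_layout()
  # brute-force expected overlap list from the planted intervals
  ov <- list()
  a <- expected$amplicons
  if (nrow(a) >= 2L) {
    for (i in seq_len(nrow(a) - 1L)) {
      for (j in (i + 1L):nrow(a)) {
        if (a$chrom[i] == a$chrom[j] && a$pair_index[i] != a$pair_index[j] &&
            a$start[i] <= a$end[j] && a$start[j] <= a$end[i]) {
          ov[[length(ov) + 1L]] <- data.frame(
            pair_a = min(a$pair_index[c(i, j)]),
            pair_b = max(a$pair_index[c(i, j)]),
            chrom = a$chrom[i],
            shared_start = max(a$start[c(i, j)]),
            shared_end = min(a$end[c(i, j)]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  expected_overlaps <- if (length(ov)) {
    o <- unique(do.call(rbind, ov))
    o <- o[order(o$chrom, o$shared_start, o$pair_a, o$pair_b), , drop = FALSE]
    rownames(o) <- NULL
    o
  } else {
    data.frame(pair_a = integer(0), pair_b = integer(0), chrom = character(0),
               shared_start = numeric(0), shared_end = numeric(0),
               stringsAsFactors = FALSE)
  }

  # every distinct matched window, with its expected occurrence count
  win <- expected$hits
  win$window <- NA_character_
  genome <- with_seed(seed, {
    for (try in seq_len(max_retries)) {
      chrseqs <- stats::setNames(
        vapply(chroms, function(x) random_bases(genome_len), character(1)),
        chroms)
      for (r in seq_len(nrow(layout))) {
        row <- layout[r, ]
        chrseqs[[row$chrom]] <- plant_one(chrseqs[[row$chrom]], row)
      }
      if (!is.null(n_block)) {
        ns <- n_block[1L]; ne <- n_block[1L] + n_block[2L] - 1L
        substring(chrseqs[[1L]], ns, ne) <- strrep("N", n_block[2L])
      }
      # collision check: each planted window must occur exactly as planted
      for (r in seq_len(nrow(win))) {
        win$window[r] <- substring(chrseqs[[win$chrom[r]]],
                                   win$site_start[r], win$site_end[r])
      }
      counts_ok <- TRUE
      for (w in unique(win$window)) {
        want <- sum(win$window == w)
        got <- sum(vapply(chrseqs, function(ch) {
          length(gregexpr(w, ch, fixed = TRUE)[[1]]) -
            (gregexpr(w, ch, fixed = TRUE)[[1]][1] == -1L)
        }, numeric(1)))
        if (got != want) { counts_ok <- FALSE; break }
      }
      if (counts_ok) break
      if (try == max_retries) {
        stop("could not place amplicons without background collisions",
             call. = FALSE)
      }
    }
    Biostrings::DNAStringSet(chrseqs)
  })

  fasta_path <- file.path(dir, sprintf("genome_seed%d.fa", seed))
  twobit_path <- file.path(dir, sprintf("genome_seed%d.2bit", seed))
  Biostrings::writeXStringSet(genome, fasta_path)
  rtracklayer::export.2bit(genome, twobit_path)
  list(genome = genome, fasta_path = fasta_path, twobit_path = twobit_path,
       expected_hits = expected$hits[, c("primer", "pair_index", "role",
                                         "chrom", "strand", "site_start",
                                         "site_end", "pos3")],
       expected_amplicons = expected$amplicons,
       expected_overlaps = expected_overlaps)
}

#' Generate a synthetic interaction table with planted structure
#'
#' Either block-structured (cliques of pairs whose cross-primer interactions
#' all carry `clique_score`) or fully random.  The result is a valid
#' `interaction_table` in score mode that feeds the partitioner directly.
#'
#' @param n_pairs Number of primer pairs.
#' @param cliques List of integer vectors of pair ids; within each clique,
#'   every cross-pair forward-forward interaction gets `clique_score`.
#' @param clique_score Score planted inside cliques.
#' @param random If `TRUE`, ignore `cliques` and draw every cross-pair
#'   interaction from \{0, ..., max_score\} (zero-inflated).
#' @param max_score Maximum random score.
#' @param seed Integer seed.
#' @return An `interaction_table` (mode `"score"`).
#' @export
make_interaction_table <- function(n_pairs, cliques = list(),
                                   clique_score = 10L, random = FALSE,
                                   max_score = 8L, seed = 1L) {
  names <- as.vector(rbind(sprintf("AMP%02d-F", seq_len(n_pairs)),
                           sprintf("AMP%02d-R", seq_len(n_pairs))))
  n <- 2L * n_pairs
  primers <- data.frame(
    name = names,
    sequence = strrep("A", 20L),
    pair_index = rep(seq_len(n_pairs), each = 2L),
    role = rep(c("forward", "reverse"), n_pairs),
    stringsAsFactors = FALSE)
  value <- matrix(0, n, n, dimnames = list(names, names))
  fwd_row <- function(p) 2L * p - 1L
  if (random) {
    with_seed(seed, {
      for (p in seq_len(n_pairs - 1L)) {
        for (q in (p + 1L):n_pairs) {
          for (rp in c(2L * p - 1L, 2L * p)) {
            for (rq in c(2L * q - 1L, 2L * q)) {
              v <- sample(c(0L, 0L, 0L, seq_len(max_score)), 1L)
              value[rp, rq] <- v
              value[rq, rp] <- v
            }
          }
        }
      }
    })
  } else {
    for (cl in cliques) {
      for (p in cl) {
        for (q in cl) {
          if (p < q) {
            value[fwd_row(p), fwd_row(q)] <- clique_score
            value[fwd_row(q), fwd_row(p)] <- clique_score
          }
        }
      }
    }
  }
  structure(list(mode = "score", primers = primers, value = value,
                 offset = matrix(0L, n, n),
                 saturated = matrix(FALSE, n, n,
                                    dimnames = list(names, names)),
                 params = NULL),
            class = "interaction_table")
}
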