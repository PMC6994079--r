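# fixed 32-base tail shared by the long-primer tests
random_seq_fixed <- function() "GATTACAGATTACAGATTACAGATTACAGATT"

test_that("FASTA and 2bit genomes read identically; bad input errors", {
  dir <- withr::local_tempdir()
  set.seed(9)
  seqs <- Biostrings::DNAStringSet(c(chrA = random_acgt(500),
                                     chrB = random_acgt(300)))
  fa <- file.path(dir, "g.fa"); tb <- file.path(dir, "g.2bit")
  Biostrings::writeXStringSet(seqs, fa)
  rtracklayer::export.2bit(seqs, tb)
  g1 <- read_genome(fa); g2 <- read_genome(tb)
  expect_equal(names(g1), c("chrA", "chrB"))
  expect_equal(as.character(g1), as.character(g2))
  expect_equal(Biostrings::width(g1), c(500L, 300L))

  empty <- file.path(dir, "empty.fa"); file.create(empty)
  expect_error(read_genome(empty), "empty")
  expect_error(read_genome(file.path(dir, "nope.fa")), "not found")
})

test_that("variant index: key length, strands, degeneracy, long primers", {
  ps <- parse_primer_fasta(c(
    ">A-F", "GATTACAGATTACAGATT",       # 18
    ">A-R", "CCGGAATTCCGGAATTCCGG"))    # 20
  idx <- build_variant_index(ps)
  expect_equal(idx$n_key, 18L)
  # two primers x (1 expansion) x 2 strands
  expect_equal(nrow(idx$variants), 4L)
  expect_setequal(unique(idx$variants$strand), c("+", "-"))
  # reverse complement variants present verbatim
  expect_true(reverse_complement("GATTACAGATTACAGATT") %in% idx$variants$seq)

  deg <- suppressWarnings(parse_primer_fasta(c(
    ">D-F", paste0("N", strrep("A", 17)))))
  idxd <- suppressWarnings(build_variant_index(deg))
  expect_equal(nrow(idxd$variants), 8L)   # 4 expansions x 2 strands

  long <- suppressWarnings(parse_primer_fasta(c(
    ">L-F", paste(rep(c("A", "C", "G", "T"), 10), collapse = ""))))  # 40
  expect_warning(idxl <- build_variant_index(long), "32")
  expect_equal(idxl$long_primers, "L-F")
  expect_true(all(nchar(idxl$variants$seq) == 32L))

  expect_error(build_variant_index(
    suppressWarnings(parse_primer_fasta(c(">X-F", strrep("N", 20)))),
    cap = 1000), "variants")
})

test_that("planted primers are found with exact 3' coordinates, both strands", {
  primer <- "GATTACAGATTACAGATT"   # 18 bases
  ps <- suppressWarnings(parse_primer_fasta(c(">P-F", primer)))
  idx <- build_variant_index(ps)
  set.seed(33)
  bg <- random_acgt(200)
  # plant at 1-based position 101 (0-based offset 100)
  genome <- bg
  substring(genome, 101, 118) <- primer
  substring(genome, 151, 168) <- reverse_complement(primer)
  hits <- scan_chromosome(genome, idx, "chr1")
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$pos3, 118)       # 0-based 117 == 1-based 118
  expect_equal(plus$site_start, 101)
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$site_start, 151)
  expect_equal(minus$pos3, 151)      # 3' end is the leftmost base on minus

  expect_equal(nrow(scan_chromosome(strrep("N", 500), idx)), 0L)
  # windows straddling an N produce no hits
  broken <- genome
  substring(broken, 110, 110) <- "N"
  h2 <- scan_chromosome(broken, idx, "chr1")
  expect_equal(nrow(h2[h2$strand == "+", ]), 0L)
})

test_that("a long primer is matched by its last 32 bases only", {
  long <- paste0(strrep("A", 8), random_seq_fixed())  # 8 + 32 = 40 bases
  ps <- suppressWarnings(parse_primer_fasta(c(">L-F", long)))
  expect_warning(idx <- build_variant_index(ps), "32")
  tail32 <- substring(long, 9)
  genome <- paste0(strrep("C", 50), tail32, strrep("C", 50))
  hits <- scan_chromosome(genome, idx, "chr1")
  expect_equal(nrow(hits[hits$strand == "+", ]), 1L)
  # the first 8 bases alone (without the 3' window) never match
  genome2 <- paste0(strrep("C", 50), strrep("A", 8), strrep("C", 80))
  expect_equal(nrow(scan_chromosome(genome2, idx, "chr1")), 0L)
})

test_that("amplicons form only in convergent orientation within max_len", {
  hits <- data.frame(
    primer = c("P-F", "P-R"), pair_index = 1L,
    role = c("forward", "reverse"), chrom = "chr1",
    strand = c("+", "-"),
    site_start = c(101, 181), site_end = c(120, 200),
    pos3 = c(120, 181), stringsAsFactors = FALSE)
  amp <- find_amplicons(hits, 200)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 101)
  expect_equal(amp$end, 200)
  expect_equal(amp$length, 100)
  expect_equal(amp$orientation, "positive-strand-first")

  # same sites, tighter limit: no amplicon
  expect_equal(nrow(find_amplicons(hits, 80)), 0L)

  # lone forward hit: nothing
  expect_equal(nrow(find_amplicons(hits[1, ], 200)), 0L)

  # divergent arrangement (reverse site upstream) forms nothing
  div <- hits
  div$site_start <- c(181, 101); div$site_end <- c(200, 120)
  div$pos3 <- c(200, 101)
  expect_equal(nrow(find_amplicons(div, 200)), 0L)
})

test_that("negative-strand-first pairs are reconstructed symmetrically", {
  hits <- data.frame(
    primer = c("P-R", "P-F"), pair_index = 1L,
    role = c("reverse", "forward"), chrom = "chr1",
    strand = c("+", "-"),
    site_start = c(301, 421), site_end = c(320, 440),
    pos3 = c(320, 421), stringsAsFactors = FALSE)
  amp <- find_amplicons(hits, 200)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$orientation, "negative-strand-first")
  expect_equal(c(amp$start, amp$end), c(301, 440))
})

test_that("overlap detection matches brute-force interval intersection", {
  a <- data.frame(pair_index = 1:2, chrom = "chr1",
                  start = c(100, 150), end = c(199, 260),
                  length = c(100, 111),
                  orientation = "positive-strand-first",
                  stringsAsFactors = FALSE)
  rep1 <- detect_overlaps(a)
  expect_equal(nrow(rep1$overlaps), 1L)
  expect_equal(c(rep1$overlaps$shared_start, rep1$overlaps$shared_end),
               c(150, 199))

  b <- a; b$start <- c(100, 200); b$end <- c(199, 300)
  expect_equal(nrow(detect_overlaps(b)$overlaps), 0L)

  set.seed(77)
  for (trial in 1:5) {
    n <- 50L
    starts <- sample(1:5000, n, replace = TRUE)
    tile <- data.frame(
      pair_index = seq_len(n),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = starts,
      end = starts + sample(50:400, n, replace = TRUE),
      length = 0, orientation = "positive-strand-first",
      stringsAsFactors = FALSE)
    tile$length <- tile$end - tile$start + 1
    got <- detect_overlaps(tile)$overlaps
    want <- naive_overlaps(tile)
    expect_equal(got, want)
  }
})

test_that("overlap constraints saturate all four cross entries, reversibly", {
  ps <- parse_primer_fasta(c(">P-F", "ACGTACGTAC", ">P-R", "TGCATGCATG",
                             ">Q-F", "AACCGGTTAA", ">Q-R", "GGCCAATTGG"))
  tab <- all_interactions(ps, mode = "score")
  before <- tab$value
  rep0 <- structure(list(overlaps = data.frame(
    pair_a = 1L, pair_b = 2L, chrom = "chr1",
    shared_start = 1, shared_end = 2, stringsAsFactors = FALSE),
    unmatched_pairs = NULL), class = "overlap_report")
  tab2 <- overlap_constraints(tab, rep0)
  p_rows <- which(tab2$primers$pair_index == 1L)
  q_rows <- which(tab2$primers$pair_index == 2L)
  expect_true(all(tab2$saturated[p_rows, q_rows]))
  expect_true(all(tab2$saturated[q_rows, p_rows]))
  expect_false(any(tab2$saturated[p_rows, p_rows]))
  # original values recoverable
  expect_identical(tab2$value, before)
  # ranges reflect saturation
  ctx <- poolprimers:::pair_interaction_ranges(tab2)
  expect_true(all(ctx$r4[1, 2, ] == 65535L))

  # empty report leaves the table untouched
  empty_rep <- structure(list(overlaps = data.frame(
    pair_a = integer(0), pair_b = integer(0), chrom = character(0),
    shared_start = numeric(0), shared_end = numeric(0)),
    unmatched_pairs = NULL), class = "overlap_report")
  expect_identical(overlap_constraints(tab, empty_rep), tab)
})

test_that("pairs without amplicons are warned about, with the mapped side", {
  ps <- parse_primer_fasta(c(">P-F", "ACGTACGTAC", ">P-R", "TGCATGCATG",
                             ">Q-F", "AACCGGTTAA", ">Q-R", "GGCCAATTGG"))
  amp <- data.frame(pair_index = 1L, chrom = "chr1", start = 10, end = 90,
                    length = 81, orientation = "positive-strand-first",
                    stringsAsFactors = FALSE)
  hits <- data.frame(primer = "Q-F", pair_index = 2L, role = "forward",
                     chrom = "chr1", strand = "+", site_start = 500,
                     site_end = 509, pos3 = 509, stringsAsFactors = FALSE)
  expect_warning(rep <- detect_overlaps(amp, set = ps, hits = hits),
                 "no amplicon")
  expect_equal(rep$unmatched_pairs$pair_index, 2L)
  expect_match(rep$unmatched_pairs$mapped, "forward")
})
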