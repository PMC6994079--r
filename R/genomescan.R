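# Index-free mapping of primers onto a genome, amplicon reconstruction and
# overlap detection.
#
# All concrete variants of every untagged primer (degenerate expansion plus
# reverse complements for the negative strand) are truncated to their last
# 32 bases and keyed by their last N bases (N = shortest primer length).
# A single pass over each chromosome slides a 2-bit window and binary-searches
# the fixed-width keys; a key hit triggers full-window verification.  Primer
# hits become "events" from which amplicons are reconstructed, and amplicons
# of different pairs with intersecting intervals are reported as overlaps.
#
# Coordinates are 1-based inclusive throughout (genome-browser convention).

MAX_SCAN_BASES <- 32L

#' Read a reference genome in FASTA or UCSC 2bit format
#'
#' The format is detected from the 2bit magic number (0x1A412743, either
#' byte order); anything else is treated as FASTA.
#'
#' @param path Path to the genome file.
#' @return A [Biostrings::DNAStringSet], one element per chromosome, in file
#'   order.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop(sprintf("genome file not found: %s", path),
                               call. = FALSE)
  if (file.size(path) == 0) stop("genome file is empty", call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  two_bit <- identical(magic, as.raw(c(0x1A, 0x41, 0x27, 0x43))) ||
             identical(magic, as.raw(c(0x43, 0x27, 0x41, 0x1A)))
  genome <- if (two_bit) {
    rtracklayer::import(rtracklayer::TwoBitFile(path))
  } else {
    g <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    stop(sprintf("malformed genome FASTA '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
    g
  }
  if (length(genome) == 0L) stop("genome file contains no sequences",
                                 call. = FALSE)
  genome
}

#' Build the variant lookup index for the genome scan
#'
#' Uses the untagged primer sequences (tags never enter the scan).  Every
#' concrete expansion of every primer and of its reverse complement is
#' added; each variant keeps only its last 32 bases.  Primers longer than
#' 32 bases are recorded in a warning list, since only their last 32 bases
#' are matched.
#'
#' @param set A `primer_set`.
#' @param cap Maximum number of concrete expansions per primer.
#' @return A `variant_index`: data frame of variants (sequence, primer name,
#'   pair index, role, strand), the key length `n_key`, and `long_primers`.
#' @export
build_variant_index <- function(set, cap = 4096L) {
  stopifnot(inherits(set, "primer_set"))
  recs <- primer_records(set, tagged = FALSE)
  if (nrow(recs) == 0L) stop("primer set is empty", call. = FALSE)
  n_key <- min(pmin(nchar(recs$sequence), MAX_SCAN_BASES))
  long_primers <- recs$name[nchar(recs$sequence) > MAX_SCAN_BASES]
  if (length(long_primers) > 0L) {
    warning(sprintf(
      "%d primer(s) longer than %d bases are matched by their last %d bases only: %s",
      length(long_primers), MAX_SCAN_BASES, MAX_SCAN_BASES,
      paste(long_primers, collapse = ", ")), call. = FALSE)
  }
  last_n <- function(s, n) substring(s, pmax(1L, nchar(s) - n + 1L))
  rows <- lapply(seq_len(nrow(recs)), function(i) {
    # truncate to the primer's last (3') 32 bases, then take both strands,
    # so long primers are matched by the same 3' window on either strand
    fwd <- last_n(recs$sequence[i], MAX_SCAN_BASES)
    rev <- reverse_complement(fwd)
    v_fwd <- expand_degenerate(fwd, cap = cap, name = recs$name[i])
    v_rev <- expand_degenerate(rev, cap = cap, name = recs$name[i])
    data.frame(
      seq = c(v_fwd, v_rev),
      primer = recs$name[i],
      pair_index = recs$pair_index[i],
      role = recs$role[i],
      strand = rep(c("+", "-"), c(length(v_fwd), length(v_rev))),
      stringsAsFactors = FALSE)
  })
  structure(list(variants = do.call(rbind, rows),
                 n_key = as.integer(n_key),
                 long_primers = long_primers),
            class = "variant_index")
}

#' @export
print.variant_index <- function(x, ...) {
  cat(sprintf("Variant index: %d variants (both strands), key length %d\n",
              nrow(x$variants), x$n_key))
  if (length(x$long_primers)) {
    cat(sprintf("  %d primer(s) matched by last %d bases only\n",
                length(x$long_primers), MAX_SCAN_BASES))
  }
  invisible(x)
}

#' Scan one chromosome for all primer variants
#'
#' @param bases Chromosome sequence: a string, [Biostrings::DNAString], or
#'   anything `as.character` turns into one.
#' @param index A `variant_index` from [build_variant_index()].
#' @param chromosome Chromosome name recorded on the hits.
#' @return Data frame of hits: `primer`, `pair_index`, `role`, `chrom`,
#'   `strand`, `site_start`, `site_end` (genomic extent of the matched
#'   window) and `pos3` (coordinate of the primer's 3'-most matched base).
#'   1-based inclusive.
#' @export
scan_chromosome <- function(bases, index, chromosome = "chr") {
  stopifnot(inherits(index, "variant_index"))
  seq <- toupper(as.character(bases))
  raw <- cpp_scan_chromosome(seq, index$variants$seq, index$n_key)
  v <- raw$variant
  if (length(v) == 0L) {
    return(data.frame(primer = character(0), pair_index = integer(0),
                      role = character(0), chrom = character(0),
                      strand = character(0), site_start = numeric(0),
                      site_end = numeric(0), pos3 = numeric(0),
                      stringsAsFactors = FALSE))
  }
  len <- nchar(index$variants$seq[v])
  strand <- index$variants$strand[v]
  site_end <- raw$pos3
  site_start <- site_end - len + 1
  hits <- data.frame(
    primer = index$variants$primer[v],
    pair_index = index$variants$pair_index[v],
    role = index$variants$role[v],
    chrom = chromosome,
    strand = strand,
    site_start = site_start,
    site_end = site_end,
    # on the negative strand the primer's 3' end is the leftmost base
    pos3 = ifelse(strand == "+", site_end, site_start),
    stringsAsFactors = FALSE)
  hits[order(hits$site_start, hits$site_end, hits$primer), , drop = FALSE]
}

#' Scan a whole genome for all primer variants
#'
#' @param genome A [Biostrings::DNAStringSet] (see [read_genome()]) or a
#'   named character vector of chromosome sequences.
#' @inheritParams scan_chromosome
#' @return Combined hit data frame over all chromosomes (see
#'   [scan_chromosome()]), sorted by chromosome then position.
#' @export
scan_genome <- function(genome, index) {
  nm <- names(genome)
  if (is.null(nm)) nm <- paste0("chr", seq_along(genome))
  hits <- lapply(seq_along(genome), function(i) {
    scan_chromosome(genome[[i]], index, chromosome = nm[i])
  })
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Reconstruct amplicons from primer-site events
#'
#' An amplicon forms when a pair's two primer sites occur in convergent
#' orientation on one chromosome within the length limit: the forward
#' primer on the plus strand followed by the reverse primer's site on the
#' minus strand (positive-strand-first), or the mirror-image arrangement
#' (negative-strand-first).  The amplicon spans from the first base of the
#' opening site to the last base of the closing site, primers included.
#' A pair may yield several amplicons.
#'
#' @param hits Hit data frame from [scan_genome()].
#' @param max_len Maximum amplicon length in bases (inclusive bound on
#'   `end - start + 1`); pairs whose only candidate products exceed it are
#'   simply not reported.
#' @return Data frame: `pair_index`, `chrom`, `start`, `end`, `length`,
#'   `orientation`.
#' @export
find_amplicons <- function(hits, max_len) {
  stopifnot(is.numeric(max_len), length(max_len) == 1L, max_len >= 1)
  out <- list()
  if (nrow(hits) > 0L) {
    paired <- hits[!is.na(hits$pair_index), , drop = FALSE]
    for (key in unique(paste(paired$pair_index, paired$chrom))) {
      h <- paired[paste(paired$pair_index, paired$chrom) == key, , drop = FALSE]
      combos <- list(
        list(open_role = "forward", close_role = "reverse",
             orientation = "positive-strand-first"),
        list(open_role = "reverse", close_role = "forward",
             orientation = "negative-strand-first"))
      for (cb in combos) {
        open <- h[h$role == cb$open_role & h$strand == "+", , drop = FALSE]
        close <- h[h$role == cb$close_role & h$strand == "-", , drop = FALSE]
        if (nrow(open) == 0L || nrow(close) == 0L) next
        for (a in seq_len(nrow(open))) {
          for (b in seq_len(nrow(close))) {
            # convergent: the closing site lies downstream of the opening one
            if (close$site_start[b] <= open$site_end[a]) next
            len <- close$site_end[b] - open$site_start[a] + 1
            if (len > max_len) next
            out[[length(out) + 1L]] <- data.frame(
              pair_index = open$pair_index[a],
              chrom = open$chrom[a],
              start = open$site_start[a],
              end = close$site_end[b],
              length = len,
              orientation = cb$orientation,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(pair_index = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      length = numeric(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  }
  amp <- do.call(rbind, out)
  amp <- amp[order(amp$chrom, amp$start, amp$end, amp$pair_index), ,
             drop = FALSE]
  rownames(amp) <- NULL
  amp
}

#' Detect overlapping amplicons and unmatched pairs
#'
#' Every pair of amplicons belonging to different primer pairs on the same
#' chromosome whose \[start, end\] intervals intersect is reported once.
#' When the primer set and hits are supplied, pairs with no amplicon are
#' listed in `unmatched_pairs`, annotated with which of their primers
#' mapped at all.
#'
#' @param amplicons Data frame from [find_amplicons()].
#' @param set Optional `primer_set`, enables unmatched-pair reporting.
#' @param hits Optional hit data frame used for the mapped-side annotation.
#' @return An `overlap_report`: `overlaps` (pair_a, pair_b, chrom, shared
#'   interval) and `unmatched_pairs`.
#' @export
detect_overlaps <- function(amplicons, set = NULL, hits = NULL) {
  overlaps <- list()
  for (chr in unique(amplicons$chrom)) {
    a <- amplicons[amplicons$chrom == chr, , drop = FALSE]
    if (nrow(a) < 2L) next
    ir <- IRanges::IRanges(start = a$start, end = a$end)
    ov <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    keep <- a$pair_index[qh] != a$pair_index[sh]
    if (!any(keep)) next
    qh <- qh[keep]; sh <- sh[keep]
    overlaps[[length(overlaps) + 1L]] <- data.frame(
      pair_a = pmin(a$pair_index[qh], a$pair_index[sh]),
      pair_b = pmax(a$pair_index[qh], a$pair_index[sh]),
      chrom = chr,
      shared_start = pmax(a$start[qh], a$start[sh]),
      shared_end = pmin(a$end[qh], a$end[sh]),
      stringsAsFactors = FALSE)
  }
  overlaps <- if (length(overlaps)) {
    o <- do.call(rbind, overlaps)
    o <- unique(o)
    o <- o[order(o$chrom, o$shared_start, o$pair_a, o$pair_b), , drop = FALSE]
    rownames(o) <- NULL
    o
  } else {
    data.frame(pair_a = integer(0), pair_b = integer(0), chrom = character(0),
               shared_start = numeric(0), shared_end = numeric(0),
               stringsAsFactors = FALSE)
  }
  unmatched <- NULL
  if (!is.null(set)) {
    idx <- set$pairs$index
    missing <- idx[!(idx %in% amplicons$pair_index)]
    mapped_roles <- function(p) {
      if (is.null(hits)) return(NA_character_)
      r <- unique(hits$role[hits$pair_index == p])
      if (length(r) == 0L) "neither primer mapped"
      else paste(r, "primer mapped", collapse = "; ")
    }
    unmatched <- data.frame(
      pair_index = missing,
      amplicon = set$pairs$amplicon[match(missing, idx)],
      mapped = vapply(missing, mapped_roles, character(1)),
      stringsAsFactors = FALSE)
    if (nrow(unmatched) > 0L) {
      warning(sprintf(
        "%d pair(s) formed no amplicon and cannot be checked for overlap: %s",
        nrow(unmatched), paste(unmatched$amplicon, collapse = ", ")),
        call. = FALSE)
    }
  }
  structure(list(overlaps = overlaps, unmatched_pairs = unmatched),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Overlap report: %d overlapping amplicon pair(s)\n",
              nrow(x$overlaps)))
  if (nrow(x$overlaps)) {
    for (i in seq_len(nrow(x$overlaps))) {
      cat(sprintf("  pairs %d and %d share %s:%g-%g\n",
                  x$overlaps$pair_a[i], x$overlaps$pair_b[i],
                  x$overlaps$chrom[i], x$overlaps$shared_start[i],
                  x$overlaps$shared_end[i]))
    }
  }
  if (!is.null(x$unmatched_pairs) && nrow(x$unmatched_pairs)) {
    cat(sprintf("  warning: %d unmatched pair(s): %s\n",
                nrow(x$unmatched_pairs),
                paste(x$unmatched_pairs$amplicon, collapse = ", ")))
  }
  invisible(x)
}

#' Saturate the interactions of overlapping amplicon pairs
#'
#' For every overlapping pair of amplicons, all four cross-primer
#' interaction entries are marked saturated (the maximum of the range
#' scale), so the partitioner immediately separates those pairs and keeps
#' them apart.  Original interaction values stay in the table for
#' reporting.
#'
#' @param table An `interaction_table`.
#' @param report An `overlap_report` over the same pair set.
#' @return The table with its saturation mask updated.
#' @export
overlap_constraints <- function(table, report) {
  stopifnot(inherits(table, "interaction_table"),
            inherits(report, "overlap_report"))
  if (nrow(report$overlaps) == 0L) return(table)
  pi <- table$primers$pair_index
  for (i in seq_len(nrow(report$overlaps))) {
    ra <- which(!is.na(pi) & pi == report$overlaps$pair_a[i])
    rb <- which(!is.na(pi) & pi == report$overlaps$pair_b[i])
    table$saturated[ra, rb] <- TRUE
    table$saturated[rb, ra] <- TRUE
  }
  table
}

#' Write amplicons as a BED file
#'
#' @param amplicons Data frame from [find_amplicons()].
#' @param path Output path.
#' @param names Optional amplicon names (defaults to `pair<index>`).
#' @return Invisibly, `path`.
#' @export
amplicons_to_bed <- function(amplicons, path, names = NULL) {
  if (is.null(names)) names <- paste0("pair", amplicons$pair_index)
  # BED is 0-based half-open
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   amplicons$chrom, as.integer(amplicons$start - 1),
                   as.integer(amplicons$end), names,
                   ifelse(amplicons$orientation == "positive-strand-first",
                          "+", "-"))
  writeLines(lines, path)
  invisible(path)
}
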