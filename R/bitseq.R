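# Bit-plane primer encodings and base-level bonding tests.
#
# A base is encoded in two planes: at_plane = base is A or T, gt_plane =
# base is G or T (so A = 10, C = 00, G = 01, T = 11).  Two bases are
# Watson-Crick complementary iff their A|T digits are equal and their G|T
# digits differ, so a whole alignment's bonding pattern is
# XNOR(at) AND XOR(gt) AND both-valid, evaluated over all positions at once.
# Planes are stored one element per base; the capacity contract is 128 bases
# per primer.

MAX_PRIMER_LEN <- 128L

#' Encode a non-degenerate primer into two bit planes
#'
#' @param sequence A string over A, C, G, T (upper case).
#' @return An object of class `encoded_primer` with logical planes
#'   `at_plane`, `gt_plane`, `valid_bits` and the primer `length`.
#' @seealso [encode_degenerate()] for IUPAC-degenerate sequences.
#' @export
encode_exact <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (is_degenerate(sequence)) {
    check_iupac(sequence)
    stop("sequence contains degenerate bases; use encode_degenerate()",
         call. = FALSE)
  }
  if (nchar(sequence) > MAX_PRIMER_LEN) {
    stop(sprintf("primer longer than %d bases", MAX_PRIMER_LEN), call. = FALSE)
  }
  chars <- seq_chars(sequence)
  structure(list(
    at_plane   = chars %in% c("A", "T"),
    gt_plane   = chars %in% c("G", "T"),
    valid_bits = rep(TRUE, length(chars)),
    length     = length(chars),
    sequence   = sequence
  ), class = "encoded_primer")
}

#' Encode an IUPAC (possibly degenerate) primer into four base planes
#'
#' Plane `ra` marks positions that might be A, `rc` might be C, `rg` might
#' be G, `rt` might be T.  A position with all four planes clear is invalid,
#' so no separate validity plane is needed.
#'
#' @param sequence An IUPAC nucleotide string.
#' @return An object of class `encoded_primer_deg` with logical planes
#'   `ra`, `rc`, `rg`, `rt` and `length`.
#' @export
encode_degenerate <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  check_iupac(sequence)
  if (nchar(sequence) > MAX_PRIMER_LEN) {
    stop(sprintf("primer longer than %d bases", MAX_PRIMER_LEN), call. = FALSE)
  }
  chars <- seq_chars(sequence)
  sets <- IUPAC_CODES[chars]
  has <- function(b) vapply(sets, function(s) b %in% s, logical(1),
                            USE.NAMES = FALSE)
  structure(list(
    ra = if (length(chars)) has("A") else logical(0),
    rc = if (length(chars)) has("C") else logical(0),
    rg = if (length(chars)) has("G") else logical(0),
    rt = if (length(chars)) has("T") else logical(0),
    length = length(chars),
    sequence = sequence
  ), class = "encoded_primer_deg")
}

#' Convert a two-plane encoding to the four-plane form
#'
#' Bond results are identical under either representation; the four-plane
#' form is only needed when degenerate primers take part in a comparison.
#'
#' @param e An `encoded_primer`.
#' @return The equivalent `encoded_primer_deg`.
#' @export
upgrade <- function(e) {
  stopifnot(inherits(e, "encoded_primer"))
  at <- e$at_plane; gt <- e$gt_plane; v <- e$valid_bits
  structure(list(
    ra = v & at & !gt,
    rc = v & !at & !gt,
    rg = v & !at & gt,
    rt = v & at & gt,
    length = e$length,
    sequence = e$sequence
  ), class = "encoded_primer_deg")
}

# Overlap window of primer 1 positions for a given offset.
# Primer 2 is presented antiparallel: q = reverse(p2), so q[j] is p2's base
# len2 - j + 1 counted from p2's 5' end.  Offset k slides q rightwards:
# p1 position i aligns with q position i - k.  Offset 0 juxtaposes p1's 5'
# end with p2's 3' end.
bond_window <- function(len1, len2, offset) {
  lo <- max(1L, 1L + offset)
  hi <- min(len1, len2 + offset)
  if (lo > hi) return(integer(0))
  lo:hi
}

#' All alignment offsets at which two primers overlap by at least one base
#' @keywords internal
all_offsets <- function(len1, len2) {
  if (len1 == 0L || len2 == 0L) return(integer(0))
  seq.int(-(len2 - 1L), len1 - 1L)
}

#' Bonding pattern of two exact-encoded primers at one alignment offset
#'
#' Primer 2 is presented antiparallel (3' to 5') against primer 1 (5' to 3').
#' At offset 0 primer 1's 5' end faces primer 2's 3' end; positive offsets
#' slide primer 2 towards primer 1's 3' end.  A position bonds iff the A|T
#' digits are equal and the G|T digits differ and both positions are valid.
#'
#' @param p1,p2 `encoded_primer` objects.
#' @param offset Signed alignment offset.
#' @return A `bond_pattern`: logical `bonds` indexed along primer 1, the
#'   overlap `width`, the `offset`, and `n_bonds` (the population count).
#' @export
bond_pattern <- function(p1, p2, offset) {
  stopifnot(inherits(p1, "encoded_primer"), inherits(p2, "encoded_primer"))
  bonds <- rep(FALSE, p1$length)
  idx <- bond_window(p1$length, p2$length, offset)
  if (length(idx)) {
    # antiparallel presentation: reverse p2's planes
    j <- p2$length - (idx - offset) + 1L
    at2 <- p2$at_plane[j]; gt2 <- p2$gt_plane[j]; v2 <- p2$valid_bits[j]
    bonds[idx] <- (p1$at_plane[idx] == at2) &   # XNOR
                  (p1$gt_plane[idx] != gt2) &   # XOR
                  p1$valid_bits[idx] & v2
  }
  structure(list(bonds = bonds, width = length(idx), offset = offset,
                 n_bonds = sum(bonds)),
            class = "bond_pattern")
}

#' Bonding pattern of two four-plane encoded primers at one offset
#'
#' A position bonds iff some base choice on each side is complementary:
#' `(RA1 & RT2) | (RC1 & RG2) | (RG1 & RC2) | (RT1 & RA2)`.
#' On non-degenerate inputs this agrees with [bond_pattern()] at every
#' offset.
#'
#' @inheritParams bond_pattern
#' @param p1,p2 `encoded_primer_deg` objects.
#' @export
bond_pattern_degenerate <- function(p1, p2, offset) {
  stopifnot(inherits(p1, "encoded_primer_deg"),
            inherits(p2, "encoded_primer_deg"))
  bonds <- rep(FALSE, p1$length)
  idx <- bond_window(p1$length, p2$length, offset)
  if (length(idx)) {
    j <- p2$length - (idx - offset) + 1L
    bonds[idx] <- (p1$ra[idx] & p2$rt[j]) | (p1$rc[idx] & p2$rg[j]) |
                  (p1$rg[idx] & p2$rc[j]) | (p1$rt[idx] & p2$ra[j])
  }
  structure(list(bonds = bonds, width = length(idx), offset = offset,
                 n_bonds = sum(bonds)),
            class = "bond_pattern")
}

#' Encode a primer, choosing the representation the sequence needs
#' @keywords internal
encode_auto <- function(sequence) {
  if (is_degenerate(sequence)) encode_degenerate(sequence)
  else encode_exact(sequence)
}

#' Bond pattern dispatcher: upgrades mixed representations as needed
#' @keywords internal
bond_pattern_auto <- function(p1, p2, offset) {
  d1 <- inherits(p1, "encoded_primer_deg")
  d2 <- inherits(p2, "encoded_primer_deg")
  if (!d1 && !d2) return(bond_pattern(p1, p2, offset))
  if (!d1) p1 <- upgrade(p1)
  if (!d2) p2 <- upgrade(p2)
  bond_pattern_degenerate(p1, p2, offset)
}
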