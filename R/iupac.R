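# IUPAC nucleotide code tables and sequence-level utilities.

#' @keywords internal
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"),
  H = c("A", "C", "T"), B = c("C", "G", "T"),
  V = c("A", "C", "G"), D = c("A", "G", "T"),
  N = c("A", "C", "G", "T")
)

IUPAC_ALPHABET <- names(IUPAC_CODES)

# Complement map over the full degenerate alphabet (R<->Y, K<->M, S/W self,
# B<->V, D<->H, N self).
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", M = "K", K = "M", S = "S", W = "W",
  H = "D", B = "V", V = "B", D = "H", N = "N"
)

#' Split a sequence string into single-character bases
#' @keywords internal
seq_chars <- function(sequence) {
  if (nchar(sequence) == 0L) return(character(0))
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

#' Check a sequence against the IUPAC nucleotide alphabet
#'
#' @param sequence A nucleotide string (already upper-cased).
#' @return `TRUE` invisibly; signals an error naming the offending character
#'   otherwise.
#' @keywords internal
check_iupac <- function(sequence, what = "sequence") {
  bad <- setdiff(unique(seq_chars(sequence)), IUPAC_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-IUPAC character(s): %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse complement of an IUPAC nucleotide sequence
#'
#' Degenerate codes map to their complements (R to Y, K to M, S and W to
#' themselves, B to V, D to H, N to N), then the sequence is reversed.
#'
#' @param sequence An IUPAC nucleotide string, 5' to 3'.
#' @return The reverse complement, 5' to 3'.
#' @examples
#' reverse_complement("AAG")  # "CTT"
#' reverse_complement("RW")   # "WY"
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  check_iupac(sequence)
  if (nchar(sequence) == 0L) return(sequence)
  chars <- seq_chars(sequence)
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Expand a degenerate sequence into all concrete ACGT variants
#'
#' Expansion is the Cartesian product over degenerate positions, in a
#' deterministic order: bases at each position in A < C < G < T order, the
#' leftmost position varying slowest.
#'
#' @param sequence An IUPAC nucleotide string.
#' @param cap Maximum number of variants allowed before erroring; guards
#'   against runaway expansion of highly degenerate primers.
#' @param name Label used in the error message when the cap is exceeded.
#' @return Character vector of ACGT sequences.
#' @examples
#' expand_degenerate("AW")  # "AA", "AT"
#' @export
expand_degenerate <- function(sequence, cap = 4096L, name = sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  check_iupac(sequence)
  if (nchar(sequence) == 0L) return(character(0))
  sets <- IUPAC_CODES[seq_chars(sequence)]
  n_var <- prod(lengths(sets))
  if (n_var > cap) {
    stop(sprintf("degenerate expansion of '%s' yields %g variants (cap %d)",
                 name, n_var, cap), call. = FALSE)
  }
  out <- ""
  for (s in sets) {
    out <- as.vector(t(outer(out, s, paste0)))
  }
  out
}

#' Number of concrete variants of a degenerate sequence
#' @keywords internal
degeneracy <- function(sequence) {
  if (nchar(sequence) == 0L) return(1)
  prod(lengths(IUPAC_CODES[seq_chars(toupper(sequence))]))
}

#' Does a sequence contain degenerate (non-ACGT) codes?
#' @keywords internal
is_degenerate <- function(sequence) {
  grepl("[^ACGT]", toupper(sequence))
}
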