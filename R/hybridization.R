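# Inter-/intra-primer interaction scoring.
#
# Every unordered pair of primers (self-pairs included) is slid over all
# alignment offsets, antiparallel.  Two measures are available:
#   * match score: bonded positions minus non-bonded positions strictly
#     between the first and last bond, maximized over offsets;
#   * delta G: nearest-neighbour free energy of the duplex at the offset,
#     minimized (most stable) over offsets.  Each maximal run of >= 2
#     consecutive bonds contributes its stack sum; a single internal
#     mismatch flanked by bonds contributes its two tabulated mismatch
#     stacks.  Only the extreme over all offsets is kept.

# per-record precomputation shared by the scorers
prep_primer <- function(sequence) {
  sequence <- toupper(sequence)
  chars <- seq_chars(sequence)
  list(enc = encode_auto(sequence),
       chars = chars,
       sets = unname(IUPAC_CODES[chars]),
       length = length(chars),
       sequence = sequence)
}

score_at_offset <- function(bonds) {
  w <- which(bonds)
  if (length(w) == 0L) return(0L)
  span <- w[length(w)] - w[1L] + 1L
  2L * length(w) - span
}

# columns of primer 2 (reversed, i.e. 3'->5') aligned under primer 1
# positions `idx` at offset k
aligned_p2_index <- function(p2_len, idx, offset) {
  p2_len - (idx - offset) + 1L
}

# most stable dG of the stack spanning columns (i, i+1); columns give the
# allowed (base1, base2) choices; NULL when no tabulated combination exists
best_step_dg <- function(choices_i, choices_i1, params) {
  best <- NULL
  for (a in seq_len(nrow(choices_i))) {
    for (b in seq_len(nrow(choices_i1))) {
      hs <- nn_lookup(choices_i[a, 1L], choices_i1[b, 1L],
                      choices_i[a, 2L], choices_i1[b, 2L],
                      params$nn_dg_table)
      if (is.null(hs)) next
      dg <- stack_dg(hs, params)
      if (is.null(best) || dg < best) best <- dg
    }
  }
  best
}

# (base1, base2) choices at one column: complementary pairs when bonded,
# non-complementary pairs otherwise
column_choices <- function(set1, set2, bonded) {
  grid <- expand.grid(b1 = set1, b2 = set2, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  comp <- WC_PAIRS[grid$b1] == grid$b2
  as.matrix(grid[if (bonded) comp else !comp, , drop = FALSE])
}

# duplex free energy at a single alignment offset
dg_at_offset <- function(pp1, pp2, offset, params) {
  bp <- bond_pattern_auto(pp1$enc, pp2$enc, offset)
  bonds <- bp$bonds
  idx <- bond_window(pp1$length, pp2$length, offset)
  if (length(idx) < 2L || bp$n_bonds < 2L) return(0)
  j <- aligned_p2_index(pp2$length, idx, offset)
  # choice sets per overlapped column, indexed along `idx`
  n <- length(idx)
  choices <- vector("list", n)
  get_choices <- function(t, bonded) {
    if (is.null(choices[[t]])) {
      choices[[t]] <<- column_choices(pp1$sets[[idx[t]]], pp2$sets[[j[t]]],
                                      bonded)
    }
    choices[[t]]
  }
  total <- 0
  any_stack <- FALSE
  b <- bonds[idx]
  for (t in seq_len(n - 1L)) {
    if (b[t] && b[t + 1L]) {           # stack inside a bonded run
      dg <- best_step_dg(get_choices(t, TRUE), get_choices(t + 1L, TRUE),
                         params)
      if (is.null(dg)) {
        stop(sprintf("no nearest-neighbour entry for step %s%s/%s%s",
                     pp1$chars[idx[t]], pp1$chars[idx[t + 1L]],
                     pp2$chars[j[t]], pp2$chars[j[t + 1L]]), call. = FALSE)
      }
      total <- total + dg
      any_stack <- TRUE
    }
  }
  if (!any_stack) return(0)
  # single internal mismatches flanked by bonds
  if (n >= 3L) {
    for (t in 2L:(n - 1L)) {
      if (!b[t] && b[t - 1L] && b[t + 1L]) {
        mm <- get_choices(t, FALSE)
        if (nrow(mm) == 0L) next
        left <- best_step_dg(get_choices(t - 1L, TRUE), mm, params)
        right <- best_step_dg(mm, get_choices(t + 1L, TRUE), params)
        if (is.null(left) || is.null(right)) {
          stop(sprintf(
            "no nearest-neighbour entry for mismatch step around column %d (%s.%s)",
            idx[t], pp1$chars[idx[t]], pp2$chars[j[t]]), call. = FALSE)
        }
        total <- total + left + right
      }
    }
  }
  total
}

#' Best match score between two primers over all alignment offsets
#'
#' The score at one offset is the number of bonded positions minus the
#' number of non-bonded positions strictly between the first and last bond.
#' Ties between offsets are broken towards the smallest signed offset.
#'
#' @param seq1,seq2 Primer sequences (IUPAC, 5' to 3'); `seq2` may equal
#'   `seq1` for self-interaction.
#' @param name1,name2 Labels carried into the result.
#' @return An `interaction_result` with `best_score` and
#'   `best_offset_score`.
#' @examples
#' match_score("AAAA", "TTTT")$best_score  # 4
#' @export
match_score <- function(seq1, seq2, name1 = seq1, name2 = seq2) {
  pp1 <- prep_primer(seq1); pp2 <- prep_primer(seq2)
  best <- 0L; best_off <- 0L
  for (k in all_offsets(pp1$length, pp2$length)) {
    s <- score_at_offset(bond_pattern_auto(pp1$enc, pp2$enc, k)$bonds)
    if (s > best) { best <- s; best_off <- k }
  }
  structure(list(primer_a = name1, primer_b = name2,
                 seq_a = pp1$sequence, seq_b = pp2$sequence,
                 mode = "score",
                 best_score = best, best_offset_score = best_off),
            class = "interaction_result")
}

#' Most stable nearest-neighbour duplex free energy over all offsets
#'
#' @inheritParams match_score
#' @param params A [thermo_params()] object (temperature, sodium, table).
#' @return An `interaction_result` with `best_dg` (kcal/mol, <= 0; 0 means
#'   no stable interaction) and `best_offset_dg`.
#' @examples
#' p <- thermo_params(temperature = 37, sodium = 1)
#' delta_g("AA", "TT", p)$best_dg  # the AA/TT stack value at 37 C
#' @export
delta_g <- function(seq1, seq2, params = thermo_params(),
                    name1 = seq1, name2 = seq2) {
  pp1 <- prep_primer(seq1); pp2 <- prep_primer(seq2)
  best <- 0; best_off <- 0L; found <- FALSE
  for (k in all_offsets(pp1$length, pp2$length)) {
    dg <- dg_at_offset(pp1, pp2, k, params)
    if (dg < best) { best <- dg; best_off <- k; found <- TRUE }
  }
  structure(list(primer_a = name1, primer_b = name2,
                 seq_a = pp1$sequence, seq_b = pp2$sequence,
                 mode = "dG",
                 best_dg = if (found) best else 0,
                 best_offset_dg = best_off),
            class = "interaction_result")
}

#' Free energy of a specific alignment offset
#'
#' Useful for verifying that recomputing at a reported best offset
#' reproduces `best_dg`.
#'
#' @inheritParams delta_g
#' @param offset Signed alignment offset (0 puts `seq1`'s 5' end against
#'   `seq2`'s 3' end).
#' @return Free energy in kcal/mol (0 when no stacked bonds exist there).
#' @export
duplex_dg <- function(seq1, seq2, offset, params = thermo_params()) {
  dg_at_offset(prep_primer(seq1), prep_primer(seq2), offset, params)
}

#' Score all inter- and intra-primer interactions of a primer set
#'
#' Every unordered pair of primers, including each primer against itself,
#' is evaluated with the tagged sequences (tags are part of the reaction).
#'
#' @param set A `primer_set`; call [apply_tags()] first if tags are present.
#' @param params [thermo_params()] used when `mode = "dG"`.
#' @param mode `"dG"` (recommended) or `"score"`.
#' @return An `interaction_table`: symmetric matrices of values and offsets
#'   over all primers, plus the primer roster.
#' @export
all_interactions <- function(set, params = thermo_params(), mode = c("dG", "score")) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "primer_set"))
  if ((!is.null(set$tag_forward) || !is.null(set$tag_reverse)) && !set$tagged) {
    set <- apply_tags(set)
  }
  recs <- primer_records(set, tagged = TRUE)
  n <- nrow(recs)
  if (n == 0L) stop("primer set is empty", call. = FALSE)
  preps <- lapply(recs$sequence, prep_primer)
  value <- matrix(0, n, n, dimnames = list(recs$name, recs$name))
  offset <- matrix(0L, n, n, dimnames = list(recs$name, recs$name))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (mode == "score") {
        best <- 0L; boff <- 0L
        for (k in all_offsets(preps[[i]]$length, preps[[j]]$length)) {
          s <- score_at_offset(
            bond_pattern_auto(preps[[i]]$enc, preps[[j]]$enc, k)$bonds)
          if (s > best) { best <- s; boff <- k }
        }
        value[i, j] <- value[j, i] <- best
      } else {
        best <- 0; boff <- 0L
        for (k in all_offsets(preps[[i]]$length, preps[[j]]$length)) {
          dg <- dg_at_offset(preps[[i]], preps[[j]], k, params)
          if (dg < best) { best <- dg; boff <- k }
        }
        value[i, j] <- value[j, i] <- best
      }
      offset[i, j] <- offset[j, i] <- boff
    }
  }
  structure(list(mode = mode,
                 primers = recs,
                 value = value,
                 offset = offset,
                 saturated = matrix(FALSE, n, n,
                                    dimnames = list(recs$name, recs$name)),
                 params = params),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  n <- nrow(x$primers)
  cat(sprintf("Interaction table: %d primers, %d unordered pairs, mode = %s\n",
              n, n * (n + 1L) / 2L, x$mode))
  h <- summarize_interactions(x)
  print(h)
  invisible(x)
}

#' Histogram of interactions per score / delta-G range
#'
#' In score mode, one bin per unit score.  In dG mode, bins of width 0.5
#' kcal/mol via `range = int(-2 * dG)` (so bin 14 collects interactions at
#' or beyond -7 kcal/mol within that half-unit).
#'
#' @param table An `interaction_table`.
#' @return Named integer vector of counts (class `interaction_histogram`);
#'   the counts sum to the number of unordered primer pairs.
#' @export
summarize_interactions <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  v <- table$value[upper.tri(table$value, diag = TRUE)]
  bins <- range_of(v, table$mode)
  counts <- tabulate(bins + 1L, nbins = max(bins) + 1L)
  names(counts) <- as.character(seq_along(counts) - 1L)
  structure(counts, mode = table$mode, class = "interaction_histogram")
}

#' @export
print.interaction_histogram <- function(x, ...) {
  mode <- attr(x, "mode")
  cat(sprintf("Interactions per %s range:\n",
              if (mode == "dG") "delta-G (0.5 kcal/mol)" else "score"))
  nz <- x[x > 0]
  for (b in names(nz)) {
    lab <- if (mode == "dG") {
      sprintf("dG in (-%.1f, -%.1f]", (as.integer(b) + 1L) / 2, as.integer(b) / 2)
    } else sprintf("score %s", b)
    cat(sprintf("  %-22s %d\n", lab, nz[[b]]))
  }
  invisible(x)
}

#' ASCII bonding diagram of one interaction
#'
#' Three lines: primer 1 rendered 5' to 3', bond marks, primer 2 rendered
#' 3' to 5' shifted to the reported offset.
#'
#' @param result An `interaction_result` (or the pieces: sequences, offset).
#' @return Character vector of lines; empty when the interaction has no
#'   bonds.
#' @export
bonding_diagram <- function(result) {
  stopifnot(inherits(result, "interaction_result"))
  off <- if (result$mode == "score") result$best_offset_score else result$best_offset_dg
  s1 <- result$seq_a; s2 <- result$seq_b
  pp1 <- prep_primer(s1); pp2 <- prep_primer(s2)
  bonds <- bond_pattern_auto(pp1$enc, pp2$enc, off)$bonds
  if (!any(bonds)) return(character(0))
  # p1 occupies columns 1..len1 shifted right when offset < 0
  c0 <- min(1L, off + 1L)
  pad1 <- 1L - c0
  pad2 <- off + 1L - c0
  marks <- paste(ifelse(bonds, "|", " "), collapse = "")
  val <- if (result$mode == "score") {
    sprintf("score %d", result$best_score)
  } else sprintf("dG %.2f kcal/mol", result$best_dg)
  c(sprintf("%s vs %s (%s, offset %d)", result$primer_a, result$primer_b,
            val, off),
    paste0("5'-", strrep(" ", pad1), s1, "-3'"),
    paste0("   ", strrep(" ", pad1), marks),
    paste0("3'-", strrep(" ", pad2),
           paste(rev(seq_chars(s2)), collapse = ""), "-5'"))
}

#' Render the worst interactions of a table as bonding diagrams
#'
#' @param table An `interaction_table`.
#' @param threshold Range threshold: only interactions whose
#'   [range_of()] value is at or beyond it are rendered.
#' @return Character vector of diagram lines, worst interaction first.
#' @export
bonding_diagrams <- function(table, threshold) {
  stopifnot(inherits(table, "interaction_table"))
  n <- nrow(table$primers)
  ut <- which(upper.tri(table$value, diag = TRUE), arr.ind = TRUE)
  rng <- range_of(table$value[ut], table$mode)
  keep <- which(rng >= threshold)
  if (length(keep) == 0L) return(character(0))
  ord <- keep[order(if (table$mode == "dG") table$value[ut][keep]
                    else -table$value[ut][keep])]
  out <- character(0)
  for (e in ord) {
    i <- ut[e, 1L]; j <- ut[e, 2L]
    res <- if (table$mode == "score") {
      match_score(table$primers$sequence[i], table$primers$sequence[j],
                  table$primers$name[i], table$primers$name[j])
    } else {
      delta_g(table$primers$sequence[i], table$primers$sequence[j],
              table$params, table$primers$name[i], table$primers$name[j])
    }
    out <- c(out, bonding_diagram(res), "")
  }
  out
}
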