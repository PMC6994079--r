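# Parsing of primer FASTA lists, pairing by trailing F/R, 5' tags, and
# per-pool FASTA output.
#
# Input convention: each record is one primer; a pair shares its full name
# except the last letter (F = forward, R = reverse, case-insensitive on that
# letter only).  Records named tagF / tagR (case-insensitive whole name) are
# common 5' tag sequences, prepended to every forward / reverse primer for
# hybridization analysis but never for the genome scan.  Sequences may be
# mixed case with embedded whitespace and may span several lines.

#' Parse a primer list in FASTA format
#'
#' @param input Path to a FASTA file, or a character vector of FASTA lines,
#'   or a single string containing the whole file.
#' @return A `primer_set`: a list with
#'   \describe{
#'     \item{pairs}{data frame with one row per primer pair: `amplicon`
#'       (record name minus the trailing F/R letter), `index` (ordinal in the
#'       input), `fwd_name`, `fwd_seq`, `rev_name`, `rev_seq`, and the tagged
#'       forms `fwd_tagged`, `rev_tagged` (equal to the untagged sequences
#'       until [apply_tags()] is used).}
#'     \item{tag_forward, tag_reverse}{optional tag records (name, sequence).}
#'     \item{unpaired}{data frame of records that could not be paired.}
#'     \item{tagged}{have tags been applied to the tagged columns yet?}
#'   }
#' @examples
#' txt <- c(">AMP1-F", "ACGTACGTACGTACGTAC", ">AMP1-R", "TTGCATGCATGCATGCAT")
#' ps <- parse_primer_fasta(txt)
#' ps$pairs$amplicon
#' @export
parse_primer_fasta <- function(input) {
  lines <- fasta_lines(input)
  recs <- split_fasta_records(lines)
  if (nrow(recs) == 0L) stop("no FASTA records found in primer input",
                             call. = FALSE)
  if (anyDuplicated(recs$name)) {
    stop(sprintf("duplicate primer record name(s): %s",
                 paste(unique(recs$name[duplicated(recs$name)]),
                       collapse = ", ")), call. = FALSE)
  }
  for (i in seq_len(nrow(recs))) {
    check_iupac(recs$sequence[i], what = sprintf("record '%s'", recs$name[i]))
    if (nchar(recs$sequence[i]) < 1L) {
      stop(sprintf("record '%s' has an empty sequence", recs$name[i]),
           call. = FALSE)
    }
    if (nchar(recs$sequence[i]) > MAX_PRIMER_LEN) {
      stop(sprintf("record '%s' is longer than %d bases",
                   recs$name[i], MAX_PRIMER_LEN), call. = FALSE)
    }
  }

  is_tag_f <- tolower(recs$name) == "tagf"
  is_tag_r <- tolower(recs$name) == "tagr"
  if (sum(is_tag_f) > 1L) stop("more than one tagF record", call. = FALSE)
  if (sum(is_tag_r) > 1L) stop("more than one tagR record", call. = FALSE)
  tag_forward <- if (any(is_tag_f)) {
    list(name = recs$name[is_tag_f], sequence = recs$sequence[is_tag_f])
  }
  tag_reverse <- if (any(is_tag_r)) {
    list(name = recs$name[is_tag_r], sequence = recs$sequence[is_tag_r])
  }
  body <- recs[!(is_tag_f | is_tag_r), , drop = FALSE]

  last <- toupper(substring(body$name, nchar(body$name)))
  stem <- substring(body$name, 1L, nchar(body$name) - 1L)
  role <- ifelse(last == "F", "forward",
                 ifelse(last == "R", "reverse", NA_character_))

  pairs <- data.frame(amplicon = character(0), index = integer(0),
                      fwd_name = character(0), fwd_seq = character(0),
                      rev_name = character(0), rev_seq = character(0),
                      stringsAsFactors = FALSE)
  unpaired_idx <- integer(0)
  used <- rep(FALSE, nrow(body))
  ord <- 0L
  for (i in seq_len(nrow(body))) {
    if (used[i]) next
    if (is.na(role[i])) { unpaired_idx <- c(unpaired_idx, i); next }
    partner_last <- if (role[i] == "forward") "R" else "F"
    j <- which(!used & stem == stem[i] & last == partner_last)
    if (length(j) == 0L) { unpaired_idx <- c(unpaired_idx, i); next }
    j <- j[1L]
    used[i] <- TRUE; used[j] <- TRUE
    fi <- if (role[i] == "forward") i else j
    ri <- if (role[i] == "forward") j else i
    ord <- ord + 1L
    pairs <- rbind(pairs, data.frame(
      amplicon = stem[i], index = ord,
      fwd_name = body$name[fi], fwd_seq = body$sequence[fi],
      rev_name = body$name[ri], rev_seq = body$sequence[ri],
      stringsAsFactors = FALSE))
  }
  unpaired <- body[unpaired_idx, c("name", "sequence"), drop = FALSE]
  rownames(unpaired) <- NULL
  if (nrow(unpaired) > 0L) {
    warning(sprintf("%d record(s) could not be paired: %s",
                    nrow(unpaired), paste(unpaired$name, collapse = ", ")),
            call. = FALSE)
  }
  pairs$fwd_tagged <- pairs$fwd_seq
  pairs$rev_tagged <- pairs$rev_seq

  structure(list(pairs = pairs,
                 tag_forward = tag_forward, tag_reverse = tag_reverse,
                 unpaired = unpaired, tagged = FALSE),
            class = "primer_set")
}

# Accepts a path, a single string with newlines, or a vector of lines.
fasta_lines <- function(input) {
  stopifnot(is.character(input))
  if (length(input) == 1L && !startsWith(trimws(input), ">") &&
      file.exists(input)) {
    return(readLines(input, warn = FALSE))
  }
  unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
}

# Header line then >=1 sequence lines; sequence normalized to upper case with
# all whitespace removed.  Lines starting with ';' or '#' are comments.
split_fasta_records <- function(lines) {
  lines <- lines[!grepl("^\\s*[;#]", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(name = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  is_header <- startsWith(trimws(lines), ">")
  if (!is_header[1L]) stop("primer input does not start with a FASTA header",
                           call. = FALSE)
  grp <- cumsum(is_header)
  names <- trimws(sub("^\\s*>", "", lines[is_header]))
  seqs <- vapply(split(lines[!is_header], grp[!is_header]), function(ss) {
    toupper(gsub("\\s+", "", paste(ss, collapse = "")))
  }, character(1))
  # records with a header but no sequence lines
  seq_full <- character(length(names))
  seq_full[as.integer(names(seqs))] <- seqs
  data.frame(name = names, sequence = seq_full, stringsAsFactors = FALSE)
}

#' Prepend the 5' tag sequences to every forward and reverse primer
#'
#' The tagged forms (`fwd_tagged`, `rev_tagged`) feed the hybridization
#' analysis; the original untagged sequences are retained for the genome
#' scan, which never sees tags.
#'
#' @param set A `primer_set` from [parse_primer_fasta()].
#' @return The set with tagged sequence columns filled in. A set without
#'   tags is returned unchanged.
#' @export
apply_tags <- function(set) {
  stopifnot(inherits(set, "primer_set"))
  if (is.null(set$tag_forward) && is.null(set$tag_reverse)) return(set)
  tf <- if (!is.null(set$tag_forward)) set$tag_forward$sequence else ""
  tr <- if (!is.null(set$tag_reverse)) set$tag_reverse$sequence else ""
  fwd <- paste0(tf, set$pairs$fwd_seq)
  rev <- paste0(tr, set$pairs$rev_seq)
  too_long <- c(set$pairs$fwd_name[nchar(fwd) > MAX_PRIMER_LEN],
                set$pairs$rev_name[nchar(rev) > MAX_PRIMER_LEN])
  if (length(too_long) > 0L) {
    stop(sprintf("tagged primer(s) exceed %d bases: %s", MAX_PRIMER_LEN,
                 paste(too_long, collapse = ", ")), call. = FALSE)
  }
  set$pairs$fwd_tagged <- fwd
  set$pairs$rev_tagged <- rev
  set$tagged <- TRUE
  set
}

#' Summary statistics of a primer set
#'
#' @param object A `primer_set`.
#' @param ... Unused.
#' @return A list: primer count, min/max primer length, max tag length, and
#'   max tagged length.
#' @export
summary.primer_set <- function(object, ...) {
  seqs <- c(object$pairs$fwd_seq, object$pairs$rev_seq, object$unpaired$sequence)
  tf <- if (!is.null(object$tag_forward)) nchar(object$tag_forward$sequence) else 0L
  tr <- if (!is.null(object$tag_reverse)) nchar(object$tag_reverse$sequence) else 0L
  # expected tagged length: each role gets its own tag prepended
  tagged <- c(tf + nchar(object$pairs$fwd_seq), tr + nchar(object$pairs$rev_seq))
  list(n_primers = length(seqs),
       n_pairs = nrow(object$pairs),
       n_unpaired = nrow(object$unpaired),
       min_length = if (length(seqs)) min(nchar(seqs)) else 0L,
       max_length = if (length(seqs)) max(nchar(seqs)) else 0L,
       max_tag_length = max(tf, tr),
       max_tagged_length = if (length(tagged)) max(tagged) else 0L)
}

#' @export
print.primer_set <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Primer set: %d primers (%d pairs, %d unpaired)\n",
              s$n_primers, s$n_pairs, s$n_unpaired))
  cat(sprintf("  primer length %d-%d; max tag length %d; max tagged length %d\n",
              s$min_length, s$max_length, s$max_tag_length,
              s$max_tagged_length))
  if (!is.null(x$tag_forward) || !is.null(x$tag_reverse)) {
    cat(sprintf("  tags: %s%s\n",
                if (!is.null(x$tag_forward)) x$tag_forward$name else "-",
                if (!is.null(x$tag_reverse)) paste0(", ", x$tag_reverse$name) else ""))
  }
  invisible(x)
}

# All primer records that enter hybridization analysis, one row per primer.
# pair_index is NA for unpaired records; sequence column is tagged or
# untagged per `tagged`.
primer_records <- function(set, tagged = TRUE) {
  stopifnot(inherits(set, "primer_set"))
  p <- set$pairs
  recs <- data.frame(
    name = c(p$fwd_name, p$rev_name, set$unpaired$name),
    sequence = if (tagged) {
      c(p$fwd_tagged, p$rev_tagged, set$unpaired$sequence)
    } else {
      c(p$fwd_seq, p$rev_seq, set$unpaired$sequence)
    },
    pair_index = c(p$index, p$index,
                   rep(NA_integer_, nrow(set$unpaired))),
    role = c(rep("forward", nrow(p)), rep("reverse", nrow(p)),
             rep("unpaired", nrow(set$unpaired))),
    stringsAsFactors = FALSE)
  recs[order(c(p$index * 2L - 1L, p$index * 2L,
               nrow(p) * 2L + seq_len(nrow(set$unpaired)))), , drop = FALSE]
}

#' Write pool assignments as FASTA files
#'
#' Untagged primer records are emitted grouped by pool, names preserved.
#'
#' @param assignment A `pool_assignment` from [partition_pools()] covering
#'   every pair in `set`.
#' @param set The `primer_set` the assignment refers to.
#' @param path Output directory (multi-file mode) or file path (single-file
#'   mode).
#' @param single_file If `TRUE`, one FASTA with `# Pool <i>` comment lines
#'   marking pool boundaries; otherwise one `pool<i>.fasta` per pool under
#'   `path`.
#' @return Invisibly, the paths written.
#' @export
write_pool_fastas <- function(assignment, set, path, single_file = FALSE) {
  stopifnot(inherits(assignment, "pool_assignment"),
            inherits(set, "primer_set"))
  pool_of <- assignment$pool_of
  idx <- set$pairs$index
  if (!all(as.character(idx) %in% names(pool_of))) {
    missing <- setdiff(as.character(idx), names(pool_of))
    stop(sprintf("assignment is missing pair(s): %s",
                 paste(set$pairs$amplicon[match(missing, as.character(idx))],
                       collapse = ", ")), call. = FALSE)
  }
  fasta_for_pool <- function(k) {
    rows <- set$pairs[pool_of[as.character(idx)] == k, , drop = FALSE]
    unlist(lapply(seq_len(nrow(rows)), function(i) {
      c(paste0(">", rows$fwd_name[i]), rows$fwd_seq[i],
        paste0(">", rows$rev_name[i]), rows$rev_seq[i])
    }), use.names = FALSE)
  }
  pools <- seq_len(assignment$k)
  if (single_file) {
    lines <- unlist(lapply(pools, function(k) {
      c(sprintf("# Pool %d", k), fasta_for_pool(k))
    }), use.names = FALSE)
    writeLines(lines, path)
    invisible(path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    files <- file.path(path, sprintf("pool%d.fasta", pools))
    for (k in pools) writeLines(fasta_for_pool(k), files[k])
    invisible(files)
  }
}
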