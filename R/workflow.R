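# End-to-end orchestration: parse -> tag -> interactions -> reports ->
# [genome scan -> overlaps -> constraints] -> pool suggestion -> partition ->
# per-pool FASTA output.

#' Run the full primer pooling workflow
#'
#' Executes the three stages in order: (1) hybridization analysis of all
#' inter-/intra-primer interactions (tags included), with a histogram and
#' worst-first bonding diagrams; (2) optionally, an index-free genome scan
#' reconstructing amplicons and saturating the interactions of overlapping
#' pairs; (3) partitioning into `pools` subpools by seeded hill climbing,
#' writing one FASTA per pool.
#'
#' @param primers Path to the primer FASTA list (or its lines).
#' @param genome Optional path to a FASTA or 2bit reference genome.
#' @param max_amplicon_len Maximum amplicon length in bases; required
#'   whenever `genome` is given (tags are never part of the scan).
#' @param mode `"dG"` (recommended) or `"score"`.
#' @param temperature,sodium Reaction conditions for `mode = "dG"`.
#' @param threshold Range threshold for rendering bonding diagrams
#'   (default 14 in dG mode, i.e. -7 kcal/mol; 7 in score mode).
#' @param pools Number of subpools; defaults to the first-fit suggestion.
#' @param size_cap Optional maximum number of pairs per pool.
#' @param seed Integer seed for the partitioner.
#' @param max_stale,time_limit Stopping controls for [partition_pools()].
#' @param out_dir Directory for all reports and pool FASTAs.
#' @param single_file Write one pools FASTA instead of one file per pool.
#' @param diagrams Render bonding diagrams into the interaction report?
#' @param verbose Emit per-stage progress messages.
#' @return Invisibly, a list with the parsed `set`, the `table`, the
#'   overlap `report` (or NULL), the pool-count `suggestion`, the final
#'   `assignment`, and the paths written.
#' @export
run_pool_workflow <- function(primers, genome = NULL, max_amplicon_len = NULL,
                              mode = c("dG", "score"), temperature = 37,
                              sodium = 0.05, threshold = NULL, pools = NULL,
                              size_cap = NULL, seed = 1L, max_stale = 200L,
                              time_limit = NULL, out_dir = tempdir(),
                              single_file = FALSE, diagrams = TRUE,
                              verbose = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(genome) && is.null(max_amplicon_len)) {
    stop("max_amplicon_len is required when a genome is supplied",
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(threshold)) threshold <- if (mode == "dG") 14L else 7L

  say("stage 1: parsing primers and scoring interactions")
  set <- apply_tags(parse_primer_fasta(primers))
  params <- thermo_params(temperature = temperature, sodium = sodium)
  table <- all_interactions(set, params = params, mode = mode)

  report_path <- file.path(out_dir, "interactions.txt")
  lines <- c(utils::capture.output(print(summarize_interactions(table))),
             if (diagrams) c("", bonding_diagrams(table, threshold)))
  writeLines(lines, report_path)

  report <- NULL
  overlap_path <- NULL
  if (!is.null(genome)) {
    say("stage 2: scanning genome %s", genome)
    g <- read_genome(genome)
    index <- build_variant_index(set)
    hits <- scan_genome(g, index)
    amplicons <- find_amplicons(hits, max_amplicon_len)
    report <- detect_overlaps(amplicons, set = set, hits = hits)
    table <- overlap_constraints(table, report)
    overlap_path <- file.path(out_dir, "overlaps.txt")
    writeLines(utils::capture.output(print(report)), overlap_path)
    amplicons_to_bed(amplicons, file.path(out_dir, "amplicons.bed"))
  }

  suggestion <- suggest_pool_count(table)
  k <- if (is.null(pools)) suggestion else as.integer(pools)
  say("stage 3: partitioning into %d pools (suggested %d), seed %d",
      k, suggestion, seed)
  assignment <- partition_pools(table, k = k, size_cap = size_cap,
                                seed = seed, max_stale = max_stale,
                                time_limit = time_limit, verbose = verbose)
  pool_paths <- if (single_file) {
    write_pool_fastas(assignment, set, file.path(out_dir, "pools.fasta"),
                      single_file = TRUE)
  } else {
    write_pool_fastas(assignment, set, out_dir)
  }

  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    sprintf("poolprimers %s", as.character(utils::packageVersion("poolprimers"))),
    sprintf("seed: %d", seed),
    sprintf("mode: %s; temperature: %g C; sodium: %g M", mode, temperature,
            sodium),
    sprintf("pairs: %d; pools: %d (suggested %d)", nrow(set$pairs), k,
            suggestion),
    sprintf("final pool score: (%s)",
            paste(attr(assignment, "score"), collapse = ", ")),
    sprintf("pool sizes: %s",
            paste(tabulate(assignment$pool_of, nbins = k), collapse = "/"))),
    log_path)

  invisible(list(set = set, table = table, report = report,
                 suggestion = suggestion, assignment = assignment,
                 files = c(interactions = report_path,
                           overlaps = overlap_path,
                           pools = unname(pool_paths)[1],
                           log = log_path)))
}
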