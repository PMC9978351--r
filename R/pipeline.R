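#' Run the full mate-pair structural analysis end to end
#'
#' Orchestrates simulate -> trim -> (subsample) -> map -> fusion detection
#' and depth estimation as one seeded, logged run: the miniature equivalent
#' of sequencing a strain and asking whether an anchor plasmid has
#' integrated elsewhere and how replicon copy numbers compare. Reads are
#' simulated from `genome` (e.g. a mutant carrying a cointegrate) and
#' mapped back to `reference` (e.g. the wild-type replicon set). Stage
#' seeds are derived from the master seed by fixed offsets (simulation:
#' `seed + 101`, subsampling: `seed + 202`), so the whole run, and its
#' summary, is reproducible from `seed` alone.
#'
#' Pair-level analyses use only pairs with both mates surviving trimming;
#' depth estimation uses every surviving read.
#'
#' @param genome `mp_genome` to simulate reads from.
#' @param library A [matepair_library()]; its `seed` is overridden by the
#'   run seed.
#' @param reference `mp_genome` (or named sequences) to map against;
#'   default: `genome` itself.
#' @param trim A [trim_policy()]; default uses the library's junction
#'   adapter.
#' @param mapping A [mapper_params()].
#' @param anchor Anchor replicon name for fusion detection, or `NULL` to
#'   skip fusion detection.
#' @param targets Target replicons (default: all but the anchor).
#' @param min_support,require_unique Fusion-calling parameters (see
#'   [call_fusions()] and [select_anchor_pairs()]).
#' @param seed Master seed.
#' @param output_dir If non-`NULL`, stage outputs (reference FASTA, paired
#'   FASTQ, truth/scatter/call/depth TSVs and a `summary.json`) are written
#'   there.
#' @return A list of class `mp_run`: `reads`, `pairing`, `cset`, `calls`,
#'   `depth`, and `summary` (named list with counts and set sizes).
#' @export
run_matepair_pipeline <- function(genome, library, reference = genome,
                                  trim = trim_policy(adapter = library$adapter),
                                  mapping = mapper_params(), anchor = NULL,
                                  targets = NULL, min_support = 5L,
                                  require_unique = TRUE, seed = 1L,
                                  output_dir = NULL) {
  stopifnot(inherits(genome, "mp_genome"),
            inherits(library, "matepair_library"))
  library$seed <- as.integer(seed + 101L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  reads <- stage("simulate", simulate_matepairs(genome, library))
  trimmed <- stage("trim", trim_reads(reads, trim))
  kept <- trimmed[trimmed$kept, ]
  if (!is.null(trim$subsample_n))
    kept <- stage("subsample",
                  subsample_reads(kept, trim$subsample_n,
                                  seed = seed + 202L))

  index <- stage("index", build_index(reference, k = mapping$k))
  ref_replicons <- if (inherits(reference, "mp_genome")) reference$replicons
                   else NULL
  # pairing uses pairs with both mates kept; depth uses every kept read
  cnt <- dplyr::count(kept, .data$pair_id)
  both <- cnt$pair_id[cnt$n == 2L]
  pair_reads <- kept[kept$pair_id %in% both, ]
  pairing <- stage("map", map_pairs(pair_reads, index, mapping))
  singles <- kept[!kept$pair_id %in% both, ]
  single_pl <- if (nrow(singles) > 0)
    stage("map_singles", map_reads(singles, index, mapping))
  else NULL
  all_pl <- bind_rows(
    pairing$placements[, c("read_id", "replicon", "start", "strand",
                           "score", "aligned_length", "identity", "n_best")],
    single_pl)

  depth <- NULL
  if (!is.null(ref_replicons))
    depth <- stage("depth", replicon_depths(all_pl, ref_replicons))

  cset <- NULL; calls <- NULL; sizes <- c(A = 0L, B = 0L, B_rev = 0L, C = 0L)
  if (!is.null(anchor)) {
    cset <- stage("fusion", reciprocal_intersect(pairing, anchor, targets,
                                                 require_unique))
    sizes <- attr(cset, "set_sizes")
    repeats <- if (inherits(reference, "mp_genome")) reference$repeats
               else NULL
    calls <- stage("call", call_fusions(
      cset, anchor, insert_max = library$insert_max,
      min_support = min_support, read_length = library$read_length,
      repeats = repeats))
  }

  summary <- list(
    seed = seed,
    n_pairs_simulated = library$n_pairs,
    n_reads_kept = nrow(kept),
    n_pairs_mapped = nrow(pairing$pairs),
    set_sizes = as.list(sizes),
    n_fusion_calls = if (is.null(calls)) NA_integer_ else nrow(calls),
    fusion_calls = if (is.null(calls)) list()
                   else lapply(seq_len(nrow(calls)),
                               function(i) as.list(calls[i, ])),
    depth_ratios = if (is.null(depth)) list()
                   else as.list(setNames(depth$ratio_to_chromosome,
                                         depth$replicon))
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    if (inherits(reference, "mp_genome"))
      write_genome_fasta(reference, file.path(output_dir, "reference.fasta"))
    write_fastq(reads, file.path(output_dir, "reads"))
    readr::write_tsv(reads[, c("read_id", "replicon", "start", "strand",
                               "has_adapter")],
                     file.path(output_dir, "truth.tsv"))
    if (!is.null(cset))
      readr::write_tsv(scatter_table(cset),
                       file.path(output_dir, "scatter.tsv"))
    if (!is.null(calls))
      readr::write_tsv(as_tibble(calls),
                       file.path(output_dir, "fusion_calls.tsv"))
    if (!is.null(depth))
      readr::write_tsv(depth, file.path(output_dir, "depth.tsv"))
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(
    list(reads = trimmed, pairing = pairing, cset = cset, calls = calls,
         depth = depth, summary = summary),
    class = "mp_run"
  )
}

#' @export
print.mp_run <- function(x, ...) {
  s <- x$summary
  cat("<mp_run> seed ", s$seed, ": ", s$n_pairs_simulated, " pairs simulated, ",
      s$n_reads_kept, " reads kept\n", sep = "")
  cat("Anchored-pair set sizes: |A|=", s$set_sizes$A, " |B|=", s$set_sizes$B,
      " |B'|=", s$set_sizes$B_rev, " |C|=", s$set_sizes$C, "\n", sep = "")
  if (!is.null(x$calls)) {
    cat(nrow(x$calls), " fusion call(s)\n", sep = "")
    if (nrow(x$calls) > 0) print(as_tibble(x$calls))
  }
  if (!is.null(x$depth)) print(x$depth)
  invisible(x)
}
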