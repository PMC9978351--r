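#' Mapper parameters
#'
#' Seed-and-extend alignment parameters. A placement is accepted when the
#' aligned fraction of the read is at least `length_fraction` and the
#' alignment identity (matches / aligned columns, gaps counting as columns)
#' is at least `similarity_fraction` — the acceptance semantics of the
#' classic workbench thresholds "length fraction 0.8, similarity
#' fraction 0.9". All tied-best placements are reported, so downstream logic
#' can require uniqueness explicitly.
#'
#' @param k Exact seed length (default 15).
#' @param length_fraction Minimum aligned read fraction (0, 1].
#' @param similarity_fraction Minimum alignment identity (0, 1].
#' @param match,mismatch,gap Alignment scores (defaults +1/-2/-3; the gap
#'   penalty is linear per gap base).
#' @param band Half-width of the alignment band around the seeded diagonal.
#' @param seed_step Query offset step between successive seeds (smaller is
#'   more sensitive, larger is faster).
#' @param max_hits Cap on reported tied-best placements per read.
#' @return A list of class `mapper_params`.
#' @export
mapper_params <- function(k = 15L, length_fraction = 0.8,
                          similarity_fraction = 0.9, match = 1L,
                          mismatch = -2L, gap = -3L, band = 8L,
                          seed_step = 2L, max_hits = 50L) {
  stopifnot(length_fraction > 0, length_fraction <= 1,
            similarity_fraction > 0, similarity_fraction <= 1,
            k >= 4, band >= 1, seed_step >= 1, max_hits >= 1)
  structure(
    list(k = as.integer(k), length_fraction = length_fraction,
         similarity_fraction = similarity_fraction,
         match = as.integer(match), mismatch = as.integer(mismatch),
         gap = as.integer(gap), band = as.integer(band),
         seed_step = as.integer(seed_step), max_hits = as.integer(max_hits)),
    class = "mapper_params"
  )
}

#' Build a k-mer index over a multi-replicon reference
#'
#' Records exact k-mer start positions over the forward strand of every
#' replicon (reverse-strand placements are found by aligning the reverse
#' complement of each read). Circular replicons are indexed across the
#' origin, so a 100-nt circular sequence has 100 forward k-mer start
#' positions while a linear one has `100 - k + 1`.
#'
#' @param reference An `mp_genome`, or a named character vector of sequences.
#' @param circular Logical, recycled over replicons; ignored when `reference`
#'   is an `mp_genome` (its own `circular` column is used).
#' @param k Seed length.
#' @return A list of class `mp_index` with elements `names`, `seq`,
#'   `length`, `circular`, `k` and `n_kmer_positions`.
#' @export
build_index <- function(reference, circular = TRUE, k = 15L) {
  if (inherits(reference, "mp_genome")) {
    seqs <- reference$seq
    circular <- reference$replicons$circular
  } else {
    seqs <- reference
    circular <- rep_len(circular, length(seqs))
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    abort("Reference sequences must carry unique names.")
  if (any(nchar(seqs) == 0)) abort("Reference sequences must be non-empty.")
  k <- as.integer(k)
  len <- nchar(seqs)
  npos <- ifelse(circular, len, pmax(0L, len - k + 1L))
  short <- len < k
  if (any(short)) {
    warn(paste0("k exceeds the length of replicon(s): ",
                paste(names(seqs)[short], collapse = ", "),
                "; their index is empty."))
    npos[short] <- 0L
  }
  structure(
    list(names = names(seqs), seq = unname(toupper(seqs)),
         length = unname(len), circular = unname(circular),
         k = as.integer(k), n_kmer_positions = setNames(npos, names(seqs))),
    class = "mp_index"
  )
}

#' @export
print.mp_index <- function(x, ...) {
  cat("<mp_index> k=", x$k, ", ", length(x$names), " replicon(s): ",
      paste0(x$names, " (", format(x$length, big.mark = ","), " nt)",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Map reads against an indexed reference
#'
#' Seed-and-extend with banded gapped extension. For every read, all
#' placements with the maximal alignment score that satisfy both the length
#' and similarity fractions are returned; a read with no qualifying
#' placement is simply absent from the result. Coordinates are 1-based;
#' `start` is the leftmost aligned reference position (circular placements
#' are reported modulo the replicon length).
#'
#' @param reads Read tibble (columns `read_id`, `seq`) or a character vector
#'   of sequences.
#' @param index An [build_index()] object.
#' @param params A [mapper_params()].
#' @return Tibble of placements: `read_id`, `replicon`, `start`, `strand`,
#'   `score`, `aligned_length`, `identity`, `n_best` (number of tied-best
#'   placements of that read).
#' @export
map_reads <- function(reads, index, params = mapper_params()) {
  stopifnot(inherits(index, "mp_index"), inherits(params, "mapper_params"))
  if (is.character(reads))
    reads <- tibble(read_id = if (is.null(names(reads)))
      paste0("r", seq_along(reads)) else names(reads), seq = unname(reads))
  df <- cpp_map_reads(index$seq, index$circular, reads$seq,
                      index$k, params$seed_step,
                      params$length_fraction, params$similarity_fraction,
                      params$match, params$mismatch, params$gap,
                      params$band, params$max_hits)
  pl <- as_tibble(df)
  if (nrow(pl) == 0) {
    return(tibble(read_id = character(), replicon = character(),
                  start = numeric(), strand = character(), score = integer(),
                  aligned_length = integer(), identity = numeric(),
                  n_best = integer()))
  }
  pl %>%
    mutate(read_id = reads$read_id[.data$read],
           replicon = index$names[.data$ref],
           strand = ifelse(.data$strand > 0, "+", "-"),
           aligned_length = .data$aligned_read_bases,
           identity = .data$matches / .data$aligned_columns) %>%
    group_by(.data$read) %>%
    mutate(n_best = dplyr::n()) %>%
    ungroup() %>%
    select("read_id", "replicon", "start", "strand", "score",
           "aligned_length", "identity", "n_best")
}

#' Map both mates of every pair and join their placements
#'
#' Mates are matched on `pair_id`; orphan mates (only one mate present)
#' trigger a warning and are excluded from the pairing table. The result
#' carries, per pair and mate, the number of tied-best placements, a
#' uniqueness flag, and the unique placement (replicon/position/strand,
#' `NA` when not unique or unmapped).
#'
#' @param reads Read tibble with `read_id`, `pair_id`, `mate` (1/2), `seq`.
#' @param index An [build_index()] object.
#' @param params A [mapper_params()].
#' @return A list of class `mp_pairing`: `pairs` (one row per pair) and
#'   `placements` (all tied-best placements, with `pair_id` and `mate`).
#' @export
map_pairs <- function(reads, index, params = mapper_params()) {
  stopifnot(all(c("pair_id", "mate", "seq") %in% names(reads)))
  cnt <- dplyr::count(reads, .data$pair_id)
  orphans <- cnt$pair_id[cnt$n != 2L]
  if (length(orphans) > 0) {
    warn(sprintf("%d orphan pair id(s) excluded from pairing.",
                 length(orphans)))
    reads <- reads[!reads$pair_id %in% orphans, ]
  }
  pl <- map_reads(reads, index, params) %>%
    left_join(reads[, c("read_id", "pair_id", "mate")], by = "read_id")
  side <- function(m) {
    sub <- pl[pl$mate == m, ]
    n_by <- dplyr::count(sub, .data$pair_id, name = "n")
    uni <- sub %>%
      semi_join(n_by[n_by$n == 1L, ], by = "pair_id") %>%
      select("pair_id", replicon = "replicon", pos = "start",
             strand = "strand")
    left_join(n_by, uni, by = "pair_id")
  }
  s1 <- side(1L); s2 <- side(2L)
  pairs <- tibble(pair_id = unique(reads$pair_id)) %>%
    left_join(s1, by = "pair_id") %>%
    rename(n1 = "n", rep1 = "replicon", pos1 = "pos", strand1 = "strand") %>%
    left_join(s2, by = "pair_id") %>%
    rename(n2 = "n", rep2 = "replicon", pos2 = "pos", strand2 = "strand") %>%
    mutate(n1 = tidyr::replace_na(.data$n1, 0L),
           n2 = tidyr::replace_na(.data$n2, 0L),
           unique1 = .data$n1 == 1L, unique2 = .data$n2 == 1L)
  structure(list(pairs = pairs, placements = pl), class = "mp_pairing")
}

#' @export
print.mp_pairing <- function(x, ...) {
  cat("<mp_pairing> ", nrow(x$pairs), " pairs; ",
      sum(x$pairs$unique1 & x$pairs$unique2),
      " with both mates uniquely placed\n", sep = "")
  invisible(x)
}

#' Write placements as a minimal SAM file
#'
#' Emits an `@HD`/`@SQ` header and one alignment line per placement with the
#' mandatory fields and an `NM` tag. The CIGAR reports aligned read bases as
#' matches/mismatches (`M`); soft-clipped bases are summarised as `S`
#' operations flanking the match when the aligned length is below the read
#' length. This is a deliberate SAM subset for interoperability, not a full
#' SAM writer.
#'
#' @param placements Placement tibble from [map_reads()].
#' @param reads The read tibble that was mapped (for lengths).
#' @param index The reference index.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(placements, reads, index, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", index$names, index$length))
  rl <- setNames(nchar(reads$seq), reads$read_id)
  n <- nrow(placements)
  lines <- character(n)
  if (n > 0) {
    len <- rl[placements$read_id]
    clip <- pmax(0L, len - placements$aligned_length)
    cigar <- ifelse(clip > 0,
                    sprintf("%dM%dS", placements$aligned_length, clip),
                    sprintf("%dM", placements$aligned_length))
    flag <- ifelse(placements$strand == "-", 16L, 0L) +
      ifelse(placements$n_best > 1L, 256L, 0L)
    nm <- round((1 - placements$identity) * placements$aligned_length)
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tNM:i:%d",
                     placements$read_id, flag, placements$replicon,
                     as.integer(placements$start),
                     ifelse(placements$n_best > 1L, 0L, 60L), cigar, nm)
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
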