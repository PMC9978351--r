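#' Describe a replicon
#'
#' Builds a one-row tibble describing a circular (or linear) replicon of a
#' multi-replicon genome: its name, length, expected copy number per
#' chromosome copy, and whether it is the chromosome. Rows are combined with
#' [dplyr::bind_rows()] into the replicon table consumed by
#' [generate_genome()].
#'
#' @param name Replicon name (unique within a genome).
#' @param length Replicon length in nucleotides.
#' @param copy_number Expected copies per chromosome copy (positive real).
#' @param is_chromosome Is this the chromosome? Exactly one replicon per
#'   genome must have `is_chromosome = TRUE`.
#' @param circular Is the replicon circular? Bacterial chromosomes and
#'   plasmids generally are; linear replicons are supported for completeness.
#' @return A one-row tibble with columns `name`, `length`, `copy_number`,
#'   `is_chromosome`, `circular`.
#' @examples
#' dplyr::bind_rows(
#'   replicon_spec("chr", 200000, 1, is_chromosome = TRUE),
#'   replicon_spec("pA", 20000, 4)
#' )
#' @export
replicon_spec <- function(name, length, copy_number = 1,
                          is_chromosome = FALSE, circular = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length < 1) abort("`length` must be positive.")
  if (copy_number <= 0) abort("`copy_number` must be > 0.")
  tibble(
    name = name, length = as.integer(length),
    copy_number = as.numeric(copy_number),
    is_chromosome = isTRUE(is_chromosome), circular = isTRUE(circular)
  )
}

#' Describe a placement of a repeat-family copy
#'
#' One row per planted copy of a repeat family (e.g. a transposase or
#' integrase gene shared between replicons). All placements of a family carry
#' an identical sequence, so they must have identical lengths. Coordinates
#' are 1-based inclusive.
#'
#' @param family Repeat family identifier.
#' @param replicon Replicon the copy sits on.
#' @param start,end 1-based inclusive coordinates on the replicon.
#' @param strand `"+"` or `"-"`; a `"-"` copy is the reverse complement of
#'   the family sequence.
#' @return A one-row tibble with columns `family`, `replicon`, `start`,
#'   `end`, `strand`.
#' @export
repeat_placement <- function(family, replicon, start, end, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  if (end < start) abort("`end` must be >= `start`.")
  tibble(
    family = family, replicon = replicon,
    start = as.integer(start), end = as.integer(end), strand = strand
  )
}

validate_replicons <- function(replicons) {
  req <- c("name", "length", "copy_number", "is_chromosome", "circular")
  missing <- setdiff(req, names(replicons))
  if (length(missing) > 0)
    abort(paste0("Replicon table lacks columns: ",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(replicons$name))
    abort("Replicon names must be unique.")
  if (sum(replicons$is_chromosome) != 1L)
    abort("Exactly one replicon must have `is_chromosome = TRUE`.")
  if (any(replicons$copy_number <= 0))
    abort("All copy numbers must be > 0.")
  invisible(replicons)
}

validate_repeats <- function(repeats, replicons) {
  if (is.null(repeats) || nrow(repeats) == 0) return(invisible(repeats))
  bad <- setdiff(repeats$replicon, replicons$name)
  if (length(bad) > 0)
    abort(paste0("Repeat placements on unknown replicons: ",
                 paste(unique(bad), collapse = ", ")))
  lens <- merge(repeats, replicons[, c("name", "length")],
                by.x = "replicon", by.y = "name")
  out <- lens$start < 1 | lens$end > lens$length
  if (any(out)) {
    r <- lens[which(out)[1], ]
    abort(sprintf(
      "Repeat placement %s:%d-%d extends past the end of replicon '%s' (%d nt).",
      r$family, r$start, r$end, r$replicon, r$length))
  }
  # identical length within a family
  w <- repeats$end - repeats$start + 1L
  for (f in unique(repeats$family)) {
    if (length(unique(w[repeats$family == f])) > 1L)
      abort(sprintf("All placements of family '%s' must have equal length.", f))
  }
  # no overlaps on the same replicon
  for (rn in unique(repeats$replicon)) {
    sub <- repeats[repeats$replicon == rn, ]
    if (nrow(sub) < 2) next
    ord <- order(sub$start)
    sub <- sub[ord, ]
    for (i in seq_len(nrow(sub) - 1)) {
      if (sub$start[i + 1] <= sub$end[i])
        abort(sprintf(
          "Overlapping repeat placements on '%s': %s:%d-%d and %s:%d-%d.",
          rn, sub$family[i], sub$start[i], sub$end[i],
          sub$family[i + 1], sub$start[i + 1], sub$end[i + 1]))
    }
  }
  invisible(repeats)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a multi-replicon genome with planted repeat families
#'
#' Draws uniform-composition random sequences for each replicon and plants
#' identical copies of each repeat family at the stated placements (reverse
#' complemented for `"-"` placements). Deterministic for a fixed seed.
#'
#' @param replicons Tibble of replicon descriptions (see [replicon_spec()]).
#' @param repeats Optional tibble of repeat placements
#'   (see [repeat_placement()]).
#' @param seed Integer seed.
#' @return An object of class `mp_genome`: a list with elements `seq` (named
#'   character vector of uppercase sequences), `replicons`, `repeats`, and
#'   `fusions` (truth records of applied fusions, empty for a fresh genome).
#' @seealso [apply_fusion()], [simulate_matepairs()], [write_genome_fasta()]
#' @export
generate_genome <- function(replicons, repeats = NULL, seed = 1L) {
  validate_replicons(replicons)
  if (is.null(repeats))
    repeats <- tibble(family = character(), replicon = character(),
                      start = integer(), end = integer(), strand = character())
  validate_repeats(repeats, replicons)
  seqs <- local({
    set.seed(seed)
    s <- vapply(replicons$length, random_dna, character(1))
    names(s) <- replicons$name
    # one sequence per family, planted at every placement
    for (f in unique(repeats$family)) {
      sub <- repeats[repeats$family == f, ]
      flen <- sub$end[1] - sub$start[1] + 1L
      fseq <- random_dna(flen)
      for (i in seq_len(nrow(sub))) {
        ins <- if (sub$strand[i] == "+") fseq else revcomp_chr(fseq)
        substr(s[[sub$replicon[i]]], sub$start[i], sub$end[i]) <- ins
      }
    }
    s
  })
  structure(
    list(seq = seqs, replicons = replicons, repeats = as_tibble(repeats),
         fusions = tibble()),
    class = "mp_genome"
  )
}

#' @export
print.mp_genome <- function(x, ...) {
  cat("<mp_genome> ", nrow(x$replicons), " replicon(s), total ",
      format(sum(nchar(x$seq)), big.mark = ","), " nt\n", sep = "")
  print(x$replicons)
  if (nrow(x$repeats) > 0) {
    cat("Repeat placements:\n")
    print(x$repeats)
  }
  if (nrow(x$fusions) > 0) {
    cat("Applied fusions:\n")
    print(x$fusions)
  }
  invisible(x)
}

#' Fuse a donor replicon into an acceptor through a shared repeat
#'
#' Models a single crossover between one repeat copy on the donor and one on
#' the acceptor (cointegrate formation): the acceptor is opened inside its
#' repeat copy at `crossover_offset`, the entire donor is inserted (rotated so
#' that its repeat copy aligns), and the donor disappears as a free replicon.
#' Total sequence content is conserved and one complete repeat copy flanks
#' each junction. The coordinates of both junctions (and of the two repeat
#' copies in the fused replicon) are recorded in the genome's `fusions`
#' truth table.
#'
#' @param genome An `mp_genome`.
#' @param donor,acceptor Replicon names; must differ and must each carry a
#'   placement of `family` on the same strand.
#' @param family Repeat family shared by donor and acceptor.
#' @param crossover_offset 0-based crossover position within the repeat
#'   (0 .. repeat length); default: the repeat midpoint.
#' @param donor_copy,acceptor_copy Which placement of the family to use when
#'   a replicon carries several (index in placement order, default first).
#' @return The modified `mp_genome`.
#' @export
apply_fusion <- function(genome, donor, acceptor, family,
                         crossover_offset = NULL,
                         donor_copy = 1L, acceptor_copy = 1L) {
  stopifnot(inherits(genome, "mp_genome"))
  if (donor == acceptor) abort("`donor` and `acceptor` must differ.")
  for (nm in c(donor, acceptor)) {
    if (!nm %in% genome$replicons$name)
      abort(paste0("Unknown replicon: ", nm))
  }
  dr <- genome$repeats[genome$repeats$family == family &
                         genome$repeats$replicon == donor, ]
  ar <- genome$repeats[genome$repeats$family == family &
                         genome$repeats$replicon == acceptor, ]
  if (nrow(dr) == 0 || nrow(ar) == 0)
    abort(sprintf(
      "Family '%s' must have a placement on both '%s' and '%s'.",
      family, donor, acceptor))
  dr <- dr[donor_copy, ]
  ar <- ar[acceptor_copy, ]
  if (dr$strand != ar$strand)
    abort("Crossover requires both repeat copies on the same strand.")
  rep_len <- dr$end - dr$start + 1L
  if (is.null(crossover_offset)) crossover_offset <- rep_len %/% 2L
  if (crossover_offset < 0 || crossover_offset > rep_len)
    abort("`crossover_offset` must lie within the repeat (0 .. repeat length).")

  A <- genome$seq[[acceptor]]
  D <- genome$seq[[donor]]
  La <- nchar(A); Ld <- nchar(D)
  a1 <- ar$start; d1 <- dr$start
  co <- as.integer(crossover_offset)
  rot <- paste0(substr(D, d1 + co, Ld), substr(D, 1, d1 + co - 1L))
  fused <- paste0(substr(A, 1, a1 + co - 1L), rot, substr(A, a1 + co, La))
  stopifnot(nchar(fused) == La + Ld)
  fused_name <- paste0(acceptor, "+", donor)

  # replicon table: acceptor row becomes the cointegrate, donor row removed
  repl <- genome$replicons
  ai <- which(repl$name == acceptor)
  repl$name[ai] <- fused_name
  repl$length[ai] <- La + Ld
  repl <- repl[repl$name != donor, ]

  # re-map repeat annotations onto the fused replicon
  rep_tab <- genome$repeats
  keep <- !(rep_tab$replicon == acceptor &
              rep_tab$family == family & rep_tab$start == ar$start) &
    !(rep_tab$replicon == donor &
        rep_tab$family == family & rep_tab$start == dr$start)
  rep_tab <- rep_tab[keep, ]
  out_rep <- list()
  for (i in seq_len(nrow(rep_tab))) {
    r <- rep_tab[i, ]
    if (r$replicon == acceptor) {
      shift <- ifelse(r$start >= a1 + co, Ld, 0L)
      r$start <- r$start + shift; r$end <- r$end + shift
      r$replicon <- fused_name
    } else if (r$replicon == donor) {
      map_pos <- function(x) a1 + co + ((x - (d1 + co)) %% Ld)
      ns <- map_pos(r$start); ne <- map_pos(r$end)
      if (ne < ns) {
        warn(sprintf(
          "Repeat %s:%d-%d on donor spans the rotation point; dropped from the fused annotation.",
          r$family, r$start, r$end))
        next
      }
      r$start <- as.integer(ns); r$end <- as.integer(ne)
      r$replicon <- fused_name
    }
    out_rep[[length(out_rep) + 1]] <- r
  }
  # the two full repeat copies flanking the junctions
  copy1 <- tibble(family = family, replicon = fused_name,
                  start = a1, end = a1 + rep_len - 1L, strand = ar$strand)
  copy2 <- tibble(family = family, replicon = fused_name,
                  start = a1 + Ld, end = a1 + Ld + rep_len - 1L,
                  strand = ar$strand)
  rep_tab <- bind_rows(c(out_rep, list(copy1, copy2))) %>%
    arrange(.data$replicon, .data$start)

  seqs <- genome$seq[setdiff(names(genome$seq), c(acceptor, donor))]
  seqs <- c(seqs, setNames(fused, fused_name))
  seqs <- seqs[repl$name]

  truth <- tibble(
    donor = donor, acceptor = acceptor, fused_name = fused_name,
    family = family, crossover_offset = co,
    junction1 = a1 + co,       # first donor-derived base in fused coords
    junction2 = a1 + Ld + co,  # first acceptor-derived base after the donor
    repeat1_start = copy1$start, repeat1_end = copy1$end,
    repeat2_start = copy2$start, repeat2_end = copy2$end,
    donor_repeat_start = dr$start, donor_repeat_end = dr$end,
    acceptor_repeat_start = ar$start, acceptor_repeat_end = ar$end
  )

  structure(
    list(seq = seqs, replicons = repl, repeats = rep_tab,
         fusions = bind_rows(genome$fusions, truth)),
    class = "mp_genome"
  )
}

#' Write a genome as multi-FASTA (plus annotation TSVs)
#'
#' @param genome An `mp_genome`.
#' @param path Output FASTA path. When `annotations = TRUE`, replicon and
#'   repeat tables are written next to it as `<path>.replicons.tsv` and
#'   `<path>.repeats.tsv`.
#' @param annotations Also write the annotation TSVs?
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, annotations = TRUE) {
  stopifnot(inherits(genome, "mp_genome"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path)
  if (annotations) {
    readr::write_tsv(genome$replicons, paste0(path, ".replicons.tsv"))
    readr::write_tsv(genome$repeats, paste0(path, ".repeats.tsv"))
  }
  invisible(path)
}

#' Read a multi-FASTA reference into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  s <- toupper(as.character(x))
  names(s) <- sub("\\s.*$", "", names(x))
  s
}
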