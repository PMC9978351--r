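#' Define a transcript substrate by genomic coordinates
#'
#' A strand-aware transcript span with optional non-templated 5' additions
#' (e.g. the extra G residues left by transcription from a T7 promoter).
#' For a reverse-strand transcript the 5'-most templated coordinate is the
#' larger one.
#'
#' @param five_prime_pos Genome coordinate of the 5'-most templated
#'   nucleotide.
#' @param three_prime_pos Genome coordinate of the 3'-most templated
#'   nucleotide.
#' @param strand `"+"` or `"-"`.
#' @param extra5 Count of non-templated 5' residues (default 0).
#' @param phospho_state `"triphosphate"` (primary 5' end) or
#'   `"monophosphate"` (processed or dephosphorylated 5' end).
#' @return A list of class `transcript_substrate`.
#' @examples
#' # in vitro antisense-RNA substrate: reverse strand 32,483 -> 32,329
#' # with three extra 5' Gs
#' s <- transcript_substrate(32483, 32329, "-", extra5 = 3)
#' substrate_length(s) # 158
#' @export
transcript_substrate <- function(five_prime_pos, three_prime_pos, strand,
                                 extra5 = 0L,
                                 phospho_state = c("triphosphate",
                                                   "monophosphate")) {
  strand <- match.arg(strand, c("+", "-"))
  phospho_state <- match.arg(phospho_state)
  if (extra5 < 0) abort("`extra5` must be >= 0.")
  if (strand == "-" && five_prime_pos < three_prime_pos)
    abort("On the reverse strand `five_prime_pos` must be >= `three_prime_pos`.")
  if (strand == "+" && five_prime_pos > three_prime_pos)
    abort("On the forward strand `five_prime_pos` must be <= `three_prime_pos`.")
  structure(
    list(five_prime_pos = five_prime_pos, three_prime_pos = three_prime_pos,
         strand = strand, extra5 = as.integer(extra5),
         phospho_state = phospho_state),
    class = "transcript_substrate"
  )
}

#' @export
print.transcript_substrate <- function(x, ...) {
  cat(sprintf(
    "<transcript_substrate> strand %s, %s -> %s (%d nt templated, +%d non-templated 5'), 5'-%s\n",
    x$strand, format(x$five_prime_pos, big.mark = ","),
    format(x$three_prime_pos, big.mark = ","),
    abs(x$five_prime_pos - x$three_prime_pos) + 1L, x$extra5,
    x$phospho_state))
  invisible(x)
}

#' Total substrate length in nucleotides
#'
#' Templated span plus non-templated 5' additions.
#'
#' @param s A [transcript_substrate()].
#' @return Length in nt.
#' @export
substrate_length <- function(s) {
  stopifnot(inherits(s, "transcript_substrate"))
  as.integer(abs(s$five_prime_pos - s$three_prime_pos) + 1L + s$extra5)
}

# 1-based position of a genome coordinate along the templated transcript
transcript_index <- function(s, pos) {
  if (s$strand == "-") s$five_prime_pos - pos + 1 else pos - s$five_prime_pos + 1
}

#' Predict cleavage-fragment sizes for a set of cut sites
#'
#' Cleavage sites follow the 5'-monophosphate convention used by
#' transcriptome-wide 5'-end mapping: the site coordinate is the 5'-terminal
#' nucleotide of the downstream cleavage product. The substrate is
#' partitioned at every cut; non-templated 5' residues count toward the
#' 5'-most fragment, and fragment lengths always sum to
#' [substrate_length()].
#'
#' @param s A [transcript_substrate()].
#' @param cuts Numeric vector of genome coordinates, or a tibble with
#'   columns `position` and (optionally) `strand`, which must then match the
#'   substrate strand.
#' @return Integer vector of fragment lengths ordered 5' to 3'.
#' @examples
#' s <- transcript_substrate(32483, 32329, "-", extra5 = 3)
#' fragment_sizes(s, 32426)          # 60, 98
#' fragment_sizes(s, 32418)          # 68, 90
#' fragment_sizes(s, c(32426, 32418)) # 60, 8, 90
#' @export
fragment_sizes <- function(s, cuts) {
  stopifnot(inherits(s, "transcript_substrate"))
  if (is.data.frame(cuts)) {
    if ("strand" %in% names(cuts) && any(cuts$strand != s$strand))
      abort("Cut strand differs from the substrate strand.")
    cuts <- cuts$position
  }
  span <- abs(s$five_prime_pos - s$three_prime_pos) + 1L
  idx <- vapply(cuts, function(p) transcript_index(s, p), numeric(1))
  bad <- which(idx < 1 | idx > span)
  if (length(bad) > 0)
    abort(sprintf("Cut at %s lies outside the templated span %s-%s.",
                  format(cuts[bad[1]], big.mark = ","),
                  format(s$five_prime_pos, big.mark = ","),
                  format(s$three_prime_pos, big.mark = ",")))
  idx <- sort(unique(as.integer(idx)))
  if (any(idx == 1L) && s$extra5 == 0L)
    abort("A cut at the 5' terminus would yield an empty fragment.")
  first <- s$extra5 + idx[1] - 1L
  if (length(idx) == 1L) {
    lens <- c(first, span - idx[1] + 1L)
  } else {
    lens <- c(first, diff(idx), span - idx[length(idx)] + 1L)
  }
  as.integer(lens)
}

#' Amino acids encoded by an ORF span (excluding the stop codon)
#'
#' @param start,end 1-based genome coordinates of the reading frame,
#'   inclusive of the stop codon.
#' @param strand `"+"` or `"-"` (the count does not depend on it).
#' @return Amino-acid count.
#' @examples
#' orf_aa_count(32289, 32483) # 64
#' @export
orf_aa_count <- function(start, end, strand = "+") {
  len <- end - start + 1
  if (len %% 3 != 0)
    abort(sprintf("ORF span %d-%d is %d nt, not a multiple of 3.",
                  start, end, len))
  as.integer(len / 3 - 1)
}

#' Distance between two transcriptional start sites
#'
#' @param pos_a,pos_b Genome coordinates.
#' @return `abs(pos_a - pos_b)` in nt.
#' @examples
#' tss_distance(32177, 32481) # 304
#' @export
tss_distance <- function(pos_a, pos_b) {
  abs(pos_a - pos_b)
}

#' Classify processing sites from differential 5'-end counts
#'
#' Classifies 5'-monophosphate processing sites (PSS) from a table of
#' per-site fold changes and adjusted p values between RNase E strains.
#' In the `"wt_vs_ts"` comparison (active vs heat-inactivated
#' temperature-sensitive enzyme), a significantly positive fold change
#' (higher counts with active RNase E) marks a *bona fide* RNase E cleavage
#' site; a significantly negative one marks a site whose product is
#' stabilized when RNase E declines, i.e. cleavage by another RNase whose
#' product RNase E normally turns over. In the `"wt_vs_5p"` comparison
#' (native vs 5'-sensing-deficient enzyme), a significantly positive fold
#' change again marks a native-enzyme cleavage site, while a significantly
#' negative one marks a site whose further processing depends on
#' 5'-sensing. Missing adjusted p values leave a site unclassified.
#'
#' @param pss Tibble of PSS records (see [read_pss_sites()] for the packaged
#'   example): columns `fc_wt_ts`, `padj_wt_ts`, `fc_wt_5p`, `padj_wt_5p`.
#' @param comparison `"wt_vs_ts"` or `"wt_vs_5p"`.
#' @param alpha Significance threshold on the adjusted p value
#'   (default 0.05); comparisons use `padj <= alpha`.
#' @return `pss` with an added factor column `category` with levels
#'   `rnase_e_site`, `stabilized_in_ts`, `five_prime_sensing_dependent`,
#'   `unclassified`.
#' @export
classify_pss <- function(pss, comparison = c("wt_vs_ts", "wt_vs_5p"),
                         alpha = 0.05) {
  comparison <- match.arg(comparison)
  fc <- if (comparison == "wt_vs_ts") pss$fc_wt_ts else pss$fc_wt_5p
  padj <- if (comparison == "wt_vs_ts") pss$padj_wt_ts else pss$padj_wt_5p
  neg_label <- if (comparison == "wt_vs_ts") "stabilized_in_ts"
               else "five_prime_sensing_dependent"
  cat_ <- dplyr::case_when(
    is.na(padj) | is.na(fc) ~ "unclassified",
    padj <= alpha & fc > 0 ~ "rnase_e_site",
    padj <= alpha & fc < 0 ~ neg_label,
    TRUE ~ "unclassified"
  )
  pss$category <- factor(cat_, levels = c(
    "rnase_e_site", "stabilized_in_ts", "five_prime_sensing_dependent",
    "unclassified"))
  pss
}

#' Packaged processing-site table for the plasmid mRNA/antisense locus
#'
#' The 14 mapped processing sites across the three transcriptional units of
#' the *ssr7036*/asRNA1 locus, with per-site fold change and
#' Benjamini-Hochberg adjusted p value for the two strain comparisons
#' (active vs temperature-sensitive enzyme; native vs 5'-sensing-deficient
#' enzyme). Adjusted p values are stored at their two-decimal reported
#' precision (so "0.00" is stored as 0); classification uses `padj <= alpha`.
#'
#' @return Tibble with columns `position`, `strand`, `tu`, `comment`,
#'   `fc_wt_ts`, `padj_wt_ts`, `fc_wt_5p`, `padj_wt_5p`.
#' @export
read_pss_sites <- function() {
  path <- system.file("extdata", "pss_sites.tsv", package = "replikit",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    position = readr::col_integer(),
                    strand = readr::col_character(),
                    tu = readr::col_character(),
                    comment = readr::col_character(),
                    .default = readr::col_double()))
}

#' Packaged coordinate constants of the plasmid mRNA/antisense locus
#'
#' Named genome coordinates on the ~103-kb plasmid: the two transcriptional
#' start sites, the short ORF span, the antisense RNA 3' end, the in vitro
#' substrate 5' end and the two mapped cleavage positions.
#'
#' @return Tibble with columns `name`, `value`, `strand`, `note`.
#' @export
locus_coordinates <- function() {
  path <- system.file("extdata", "locus_coords.tsv", package = "replikit",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = "cicc")
}

#' Packaged oligonucleotide table
#'
#' Primer identifiers, sequences and labels, including the probe-template
#' primer pairs whose amplicons locate the plasmid and chromosome probes
#' (T7-tagged reverse primers carry the leader
#' `TAATACGACTCACTATAGGG`).
#'
#' @return Tibble with columns `id`, `sequence`, `label`.
#' @export
read_primer_table <- function() {
  path <- system.file("extdata", "primers.tsv", package = "replikit",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, col_types = "ccc")
}

#' In silico restriction digest
#'
#' Cuts a sequence at every exact occurrence of the recognition site (cut
#' position taken at the site start; fragment sizes depend only on site
#' spacing). Circular sequences yield one fragment per site, including the
#' fragment spanning the origin; a sequence without any site yields a
#' single fragment. Fragment lengths always sum to the sequence length.
#'
#' @param sequence Character scalar (or `DNAString`).
#' @param recognition_site Recognition sequence (default `"AAGCTT"`,
#'   HindIII).
#' @param circular Treat the sequence as circular?
#' @return Tibble with columns `start`, `end`, `length`; for a circular
#'   wrap-around fragment `end` exceeds the sequence length and is to be
#'   read modulo it.
#' @export
digest_sequence <- function(sequence, recognition_site = "AAGCTT",
                            circular = FALSE) {
  seq <- toupper(as.character(sequence))
  len <- nchar(seq)
  if (len == 0) abort("`sequence` must be non-empty.")
  slen <- nchar(recognition_site)
  subject <- if (circular) paste0(seq, substr(seq, 1L, slen - 1L)) else seq
  m <- Biostrings::matchPattern(Biostrings::DNAString(recognition_site),
                                Biostrings::DNAString(subject))
  sites <- Biostrings::start(m)
  sites <- sites[sites <= len]
  if (length(sites) == 0)
    return(tibble(start = 1L, end = len, length = len))
  sites <- sort(sites)
  if (circular) {
    starts <- sites
    lens <- diff(c(sites, sites[1] + len))
    tibble(start = starts, end = starts + lens - 1L, length = lens)
  } else {
    starts <- unique(c(1L, sites))
    ends <- c(starts[-1] - 1L, len)
    tibble(start = starts, end = ends, length = ends - starts + 1L)
  }
}

#' Which digest fragment contains a position?
#'
#' @param fragments Digest table from [digest_sequence()].
#' @param position 1-based position on the digested sequence.
#' @param seq_length Sequence length (needed to resolve circular
#'   wrap-around fragments).
#' @return The matching fragment row.
#' @export
fragment_containing <- function(fragments, position, seq_length) {
  pos2 <- position + seq_length # image in the unwrapped coordinate
  hit <- which((fragments$start <= position & fragments$end >= position) |
                 (fragments$start <= pos2 & fragments$end >= pos2))
  if (length(hit) == 0)
    abort(sprintf("Position %d not contained in any fragment.", position))
  fragments[hit[1], ]
}

#' Locate a PCR amplicon by exact primer matching
#'
#' Finds the genomic span amplified by a primer pair: the forward primer is
#' matched exactly on the given sequence and the reverse primer as its
#' reverse complement. A T7 promoter leader on either primer is stripped
#' before matching. Zero or multiple hits for either primer are an error.
#'
#' @param sequence Character scalar (or `DNAString`).
#' @param fwd_primer,rev_primer Primer sequences (>= 15 nt after leader
#'   stripping).
#' @param t7_leader Leader stripped from primer 5' ends when present.
#' @return Tibble with columns `start`, `end`, `length`.
#' @export
locate_amplicon <- function(sequence, fwd_primer, rev_primer,
                            t7_leader = "TAATACGACTCACTATAGGG") {
  strip <- function(p) {
    p <- toupper(p)
    if (startsWith(p, t7_leader)) substr(p, nchar(t7_leader) + 1L, nchar(p))
    else p
  }
  fwd <- strip(fwd_primer)
  rev <- strip(rev_primer)
  if (nchar(fwd) < 15 || nchar(rev) < 15)
    abort("Primers must be at least 15 nt after leader stripping.")
  subj <- Biostrings::DNAString(toupper(as.character(sequence)))
  fhit <- Biostrings::matchPattern(Biostrings::DNAString(fwd), subj)
  rcrev <- Biostrings::reverseComplement(Biostrings::DNAString(rev))
  rhit <- Biostrings::matchPattern(rcrev, subj)
  if (length(fhit) != 1L)
    abort(sprintf("Forward primer has %d exact hits (need exactly 1).",
                  length(fhit)))
  if (length(rhit) != 1L)
    abort(sprintf("Reverse primer has %d exact hits (need exactly 1).",
                  length(rhit)))
  s <- Biostrings::start(fhit)[1]
  e <- Biostrings::end(rhit)[1]
  if (e < s) abort("Reverse-primer hit lies upstream of the forward primer.")
  tibble(start = s, end = e, length = e - s + 1L)
}
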