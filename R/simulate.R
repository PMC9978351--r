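#' Describe a mate-pair sequencing library
#'
#' Parameters of a simulated long-insert mate-pair library: fragments are
#' drawn with probability proportional to replicon copy number times length,
#' insert sizes are uniform on `[insert_min, insert_max]`, and both fragment
#' ends are read at `read_length` nt. A configurable fraction of reads run
#' through the circularization junction and therefore contain the junction
#' adapter followed by sequence from the opposite fragment end. Base-call
#' errors are uniform substitutions; qualities follow a two-state
#' high/low-tail profile.
#'
#' @param n_pairs Number of read pairs.
#' @param insert_min,insert_max Insert (fragment) size range in nt; the
#'   default 2,000-10,000 nt matches long-insert mate-pair protocols.
#' @param read_length Read length in nt (default 150).
#' @param adapter Junction adapter sequence (default: a fixed 19-mer).
#' @param adapter_fraction Fraction of reads containing the junction adapter.
#' @param error_rate Per-base substitution probability (0 <= rate < 0.1).
#' @param quality_high,quality_low Phred scores of the two quality states.
#' @param low_tail_fraction Fraction of reads whose 3' tail (5-30 nt) is
#'   assigned the low quality state.
#' @param seed Integer seed.
#' @return A list of class `matepair_library`.
#' @export
matepair_library <- function(n_pairs, insert_min = 2000L, insert_max = 10000L,
                             read_length = 150L,
                             adapter = "CTGTCTCTTATACACATCT",
                             adapter_fraction = 0.2, error_rate = 0.005,
                             quality_high = 37L, quality_low = 11L,
                             low_tail_fraction = 0.3, seed = 1L) {
  if (n_pairs <= 0) abort("`n_pairs` must be positive.")
  if (insert_min <= 2L * read_length)
    abort("`insert_min` must exceed twice the read length.")
  if (insert_max < insert_min) abort("`insert_max` must be >= `insert_min`.")
  if (error_rate < 0 || error_rate >= 0.1)
    abort("`error_rate` must be in [0, 0.1).")
  if (adapter_fraction > 0 && read_length < nchar(adapter) + 40L)
    abort("`read_length` too short for the junction-adapter read model.")
  structure(
    list(n_pairs = as.integer(n_pairs), insert_min = as.integer(insert_min),
         insert_max = as.integer(insert_max),
         read_length = as.integer(read_length), adapter = adapter,
         adapter_fraction = adapter_fraction, error_rate = error_rate,
         quality_high = as.integer(quality_high),
         quality_low = as.integer(quality_low),
         low_tail_fraction = low_tail_fraction, seed = as.integer(seed)),
    class = "matepair_library"
  )
}

#' Simulate a mate-pair library from a multi-replicon genome
#'
#' Fragments are sampled across replicons with probability proportional to
#' `copy_number * length`. For circular replicons fragments may span the
#' origin; coordinates are reported modulo the replicon length, 1-based.
#' Each pair consists of the two fragment-end reads (mate 1 at the fragment
#' 5' end on the fragment strand, mate 2 the reverse complement of the other
#' end). Ground truth (source replicon, 1-based leftmost position and strand
#' of each mate) is carried in the returned tibble, so downstream stages can
#' be scored without external files. Deterministic for a fixed library seed.
#'
#' @param genome An `mp_genome`.
#' @param lib A [matepair_library()].
#' @return A tibble with one row per read: `pair_id`, `mate`, `read_id`,
#'   `seq`, `qual`, and truth columns `replicon`, `start` (1-based leftmost
#'   reference position), `strand`, `has_adapter`.
#' @export
simulate_matepairs <- function(genome, lib) {
  stopifnot(inherits(genome, "mp_genome"), inherits(lib, "matepair_library"))
  if (length(genome$seq) == 0) abort("Genome is empty.")
  repl <- genome$replicons
  rl <- lib$read_length
  n <- lib$n_pairs
  set.seed(lib$seed)

  w <- repl$copy_number * repl$length
  ridx <- sample.int(nrow(repl), n, replace = TRUE, prob = w)
  L <- sample(seq(lib$insert_min, lib$insert_max), n, replace = TRUE)
  L <- pmin(L, repl$length[ridx])
  circ <- repl$circular[ridx]
  len <- repl$length[ridx]
  fstart <- ifelse(circ,
                   1L + floor(runif(n) * len),
                   1L + floor(runif(n) * pmax(1L, len - L + 1L)))
  frag_strand <- sample(c("+", "-"), n, replace = TRUE)

  left_start <- fstart
  right_start <- fstart + L - rl
  left_seq <- character(n)
  right_seq <- character(n)
  ext <- lib$insert_max
  for (i in seq_len(nrow(repl))) {
    sel <- which(ridx == i)
    if (length(sel) == 0) next
    s <- genome$seq[[i]]
    if (repl$circular[i]) s <- paste0(s, substr(s, 1L, ext))
    left_seq[sel] <- substring(s, left_start[sel], left_start[sel] + rl - 1L)
    right_seq[sel] <- substring(s, right_start[sel], right_start[sel] + rl - 1L)
  }
  right_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(right_seq)))
  left_mod <- ((left_start - 1L) %% len) + 1L
  right_mod <- ((right_start - 1L) %% len) + 1L

  plus <- frag_strand == "+"
  mate1_seq <- ifelse(plus, left_seq, right_rc)
  mate2_seq <- ifelse(plus, right_rc, left_seq)
  mate1_start <- ifelse(plus, left_mod, right_mod)
  mate2_start <- ifelse(plus, right_mod, left_mod)
  mate1_strand <- ifelse(plus, "+", "-")
  mate2_strand <- ifelse(plus, "-", "+")

  pair_id <- sprintf("p%07d", seq_len(n))
  reads <- tibble(
    pair_id = rep(pair_id, 2L),
    mate = rep(c(1L, 2L), each = n),
    seq = c(mate1_seq, mate2_seq),
    replicon = rep(repl$name[ridx], 2L),
    start = c(mate1_start, mate2_start),
    strand = c(mate1_strand, mate2_strand),
    has_adapter = FALSE
  )
  reads$read_id <- paste0(reads$pair_id, "/", reads$mate)

  # junction-adapter reads: own prefix + adapter + opposite-end sequence
  if (lib$adapter_fraction > 0) {
    nr <- nrow(reads)
    alen <- nchar(lib$adapter)
    is_junction <- runif(nr) < lib$adapter_fraction
    jj <- which(is_junction)
    if (length(jj) > 0) {
      p <- sample(seq(20L, rl - alen - 20L), length(jj), replace = TRUE)
      partner <- ifelse(jj > n, jj - n, jj + n) # the other mate's row
      reads$seq[jj] <- paste0(
        substr(reads$seq[jj], 1L, p), lib$adapter,
        substr(reads$seq[partner], 1L, rl - p - alen))
      reads$has_adapter[jj] <- TRUE
    }
  }

  if (lib$error_rate > 0)
    reads$seq <- as.character(cpp_inject_errors(reads$seq, lib$error_rate))

  hi <- rawToChar(as.raw(lib$quality_high + 33L))
  lo <- rawToChar(as.raw(lib$quality_low + 33L))
  nr <- nrow(reads)
  qual <- rep(strrep(hi, rl), nr)
  low_tail <- which(runif(nr) < lib$low_tail_fraction)
  if (length(low_tail) > 0) {
    tl <- sample(5:30, length(low_tail), replace = TRUE)
    qual[low_tail] <- paste0(strrep(hi, rl - tl), strrep(lo, tl))
  }
  reads$qual <- qual

  reads[, c("read_id", "pair_id", "mate", "seq", "qual",
            "replicon", "start", "strand", "has_adapter")]
}

#' Write reads to paired FASTQ files (Phred+33)
#'
#' @param reads Read tibble (columns `read_id`, `mate`, `seq`, `qual`).
#' @param prefix Output prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written. Reads with other `mate` values go to
#'   `<prefix>_0.fastq`.
#' @return The written paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  paths <- character(0)
  for (m in sort(unique(reads$mate))) {
    sub <- reads[reads$mate == m, ]
    path <- sprintf("%s_%d.fastq", prefix, m)
    x <- Biostrings::DNAStringSet(sub$seq)
    names(x) <- sub$read_id
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(sub$qual))
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a FASTQ file into a read tibble
#'
#' Pair and mate identifiers are recovered from read names of the form
#' `<pair>/<mate>`; other names yield `pair_id = read_id` and `mate = NA`.
#'
#' @param path FASTQ file (Phred+33).
#' @return Tibble with columns `read_id`, `pair_id`, `mate`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  ids <- sub("\\s.*$", "", names(x))
  has_mate <- grepl("/[0-9]+$", ids)
  tibble(
    read_id = ids,
    pair_id = ifelse(has_mate, sub("/[0-9]+$", "", ids), ids),
    mate = ifelse(has_mate, as.integer(sub("^.*/", "", ids)), NA_integer_),
    seq = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}
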