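#' Read-trimming policy
#'
#' Trimming follows, in order: junction-adapter removal (keeping the longer
#' adapter-free segment), Mott error-probability quality trimming at the
#' stated Phred cutoff, removal of a fixed number of terminal nucleotides
#' from both ends (applied exactly once per read), and a minimum-length
#' filter. "Phred quality score > cutoff" is interpreted as Mott trimming
#' with error-probability limit `10^(-cutoff/10)`, not hard truncation at the
#' first low-quality base.
#'
#' @param phred_cutoff Phred cutoff (default 30, i.e. error-probability
#'   limit 0.001).
#' @param terminal_trim Nucleotides clipped from each end after quality
#'   trimming (default 5).
#' @param min_length Reads shorter than this after trimming are flagged as
#'   discarded (default 20).
#' @param adapter Junction adapter sequence to remove, or `NULL`.
#' @param subsample_n If set, [run_matepair_pipeline()] subsamples this many
#'   trimmed reads before mapping (the classic workflow used 4,000,000;
#'   scale to the experiment).
#' @return A list of class `trim_policy`.
#' @export
trim_policy <- function(phred_cutoff = 30L, terminal_trim = 5L,
                        min_length = 20L, adapter = NULL,
                        subsample_n = NULL) {
  stopifnot(phred_cutoff >= 0, terminal_trim >= 0, min_length >= 1)
  structure(
    list(phred_cutoff = as.integer(phred_cutoff),
         terminal_trim = as.integer(terminal_trim),
         min_length = as.integer(min_length), adapter = adapter,
         subsample_n = if (is.null(subsample_n)) NULL else as.integer(subsample_n)),
    class = "trim_policy"
  )
}

# split at every exact adapter occurrence, keep the longest segment
# (leftmost on ties); returns start/end of the retained segment per read
adapter_bounds <- function(seq, adapter) {
  n <- length(seq)
  out <- cbind(start = rep(1L, n), end = nchar(seq))
  hit <- which(stringr::str_detect(seq, stringr::fixed(adapter)))
  if (length(hit) == 0) return(out)
  alen <- nchar(adapter)
  locs <- stringr::str_locate_all(seq[hit], stringr::fixed(adapter))
  for (i in seq_along(hit)) {
    r <- hit[i]
    st <- locs[[i]][, 1]
    seg_start <- c(1L, st + alen)
    seg_end <- c(st - 1L, nchar(seq[r]))
    lens <- seg_end - seg_start + 1L
    best <- which.max(lens)
    out[r, ] <- c(seg_start[best], seg_end[best])
  }
  out
}

#' Trim reads: adapter removal, Mott quality trim, terminal clip, length filter
#'
#' Discarded reads are flagged (`kept = FALSE`), not silently dropped, so
#' that paired bookkeeping stays possible downstream. The terminal clip is
#' applied exactly once per read: reads already carrying
#' `terminal_clipped = TRUE` are not clipped again, which makes trimming
#' idempotent under a fixed policy.
#'
#' @param reads Read tibble with columns `seq` and `qual` (Phred+33);
#'   other columns are preserved.
#' @param policy A [trim_policy()].
#' @return The input tibble with `seq`/`qual` trimmed and columns `kept`
#'   and `terminal_clipped` added. Per-filter counts are attached as
#'   attribute `"trim_stats"`.
#' @export
trim_reads <- function(reads, policy = trim_policy()) {
  stopifnot(inherits(policy, "trim_policy"))
  if (!all(c("seq", "qual") %in% names(reads)))
    abort("`reads` must have columns `seq` and `qual`.")
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad) > 0)
    abort(sprintf(
      "Malformed read record %d: sequence and quality lengths differ.",
      bad[1]))
  out <- reads
  n <- nrow(out)
  seq <- out$seq
  qual <- out$qual

  # 1. adapter removal
  n_adapter <- 0L
  if (!is.null(policy$adapter) && nchar(policy$adapter) > 0) {
    ab <- adapter_bounds(seq, policy$adapter)
    changed <- ab[, "start"] != 1L | ab[, "end"] != nchar(seq)
    n_adapter <- sum(changed)
    seq <- substr(seq, ab[, "start"], ab[, "end"])
    qual <- substr(qual, ab[, "start"], ab[, "end"])
  }

  # 2. Mott quality trimming
  limit <- 10^(-policy$phred_cutoff / 10)
  mb <- cpp_mott_bounds(qual, limit, 33L)
  seq <- substr(seq, mb[, 1], mb[, 2])
  qual <- substr(qual, mb[, 1], mb[, 2])

  # 3. terminal clip, once per read
  already <- if ("terminal_clipped" %in% names(out)) out$terminal_clipped
             else rep(FALSE, n)
  tt <- policy$terminal_trim
  if (tt > 0) {
    clip <- !already
    seq[clip] <- substr(seq[clip], tt + 1L, nchar(seq[clip]) - tt)
    qual[clip] <- substr(qual[clip], tt + 1L, nchar(qual[clip]) - tt)
  }

  # 4. length filter
  kept <- nchar(seq) >= policy$min_length
  out$seq <- seq
  out$qual <- qual
  out$kept <- kept
  out$terminal_clipped <- TRUE
  attr(out, "trim_stats") <- c(
    n_in = n, n_adapter_trimmed = n_adapter,
    n_discarded_short = sum(!kept), n_kept = sum(kept))
  out
}

#' Uniform random subsample of reads without replacement
#'
#' If `n` is at least the number of available reads, all reads are returned.
#' Deterministic for a fixed seed.
#'
#' @param reads Read tibble.
#' @param n Number of units to keep (`n >= 0`).
#' @param seed Integer seed.
#' @param unit `"read"` (default) samples rows; `"pair"` samples whole pairs
#'   by `pair_id`.
#' @return The sampled tibble, in original row order.
#' @export
subsample_reads <- function(reads, n, seed = 1L, unit = c("read", "pair")) {
  unit <- match.arg(unit)
  if (n < 0) abort("`n` must be >= 0.")
  set.seed(seed)
  if (unit == "read") {
    if (n >= nrow(reads)) return(reads)
    idx <- sort(sample.int(nrow(reads), n))
    reads[idx, ]
  } else {
    ids <- unique(reads$pair_id)
    if (n >= length(ids)) return(reads)
    keep <- sample(ids, n)
    reads[reads$pair_id %in% keep, ]
  }
}
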