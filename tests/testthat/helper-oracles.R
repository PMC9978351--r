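# Independent oracles used by the tests. These deliberately share no code
# with the package internals: the aligner oracle is an exhaustive
# Smith-Waterman over the full dynamic-programming matrix (linear gap), and
# the quality-trim oracle searches every interval.

# best local alignment score of query vs subject, exhaustive DP
oracle_local_score <- function(query, subject, match = 1, mismatch = -2,
                               gap = -3) {
  q <- utf8ToInt(query)
  s <- utf8ToInt(subject)
  m <- length(q)
  n <- length(s)
  gp <- -gap
  pen <- gp * seq_len(n)
  h_prev <- numeric(n + 1)
  best <- 0
  for (i in seq_len(m)) {
    sc <- ifelse(s == q[i], match, mismatch)
    w <- pmax(0, h_prev[1:n] + sc, h_prev[2:(n + 1)] + gap)
    h <- cummax(w + pen) - pen
    best <- max(best, h)
    h_prev <- c(0, h)
  }
  best
}

# best score over both strands of the query against a set of references
oracle_best_score <- function(query, refs) {
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(query)))
  max(vapply(refs, function(r) {
    max(oracle_local_score(query, r), oracle_local_score(rc, r))
  }, numeric(1)))
}

# maximum over all intervals of sum(limit - perr), brute force
oracle_mott_score <- function(qual, cutoff = 30, offset = 33) {
  p <- 10^(-(utf8ToInt(qual) - offset) / 10)
  s <- 10^(-cutoff / 10) - p
  n <- length(s)
  cs <- c(0, cumsum(s))
  best <- 0
  for (i in seq_len(n)) best <- max(best, cs[(i + 1):(n + 1)] - cs[i])
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# two-replicon genome with one shared 1.5-kb repeat family (the study
# conditions for the fusion simulations, scaled to a 200-kb chromosome)
study_genome <- function(seed, chr_len = 200000L, anchor_len = 30000L,
                         repeat_len = 1500L, anchor_copy = 2) {
  repl <- dplyr::bind_rows(
    replicon_spec("chr", chr_len, 1, is_chromosome = TRUE),
    replicon_spec("pAnchor", anchor_len, anchor_copy))
  reps <- dplyr::bind_rows(
    repeat_placement("tnp1", "chr", 120001L, 120000L + repeat_len),
    repeat_placement("tnp1", "pAnchor", 10001L, 10000L + repeat_len))
  generate_genome(repl, reps, seed = seed)
}

# small genome for fast unit tests
tiny_genome <- function(seed = 1, with_repeat = TRUE) {
  repl <- dplyr::bind_rows(
    replicon_spec("chr", 30000L, 1, is_chromosome = TRUE),
    replicon_spec("pA", 8000L, 4))
  reps <- if (with_repeat) {
    dplyr::bind_rows(
      repeat_placement("rep1", "chr", 15001L, 16500L),
      repeat_placement("rep1", "pA", 3001L, 4500L))
  } else NULL
  generate_genome(repl, reps, seed = seed)
}
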