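test_that("index position counts respect circularity and short replicons warn", {
  set.seed(12)
  s <- c(lin = random_seq(100), circ = random_seq(100))
  idx <- build_index(s, circular = c(FALSE, TRUE), k = 15)
  expect_identical(unname(idx$n_kmer_positions["lin"]), 86L)
  expect_identical(unname(idx$n_kmer_positions["circ"]), 100L)
  expect_warning(
    idx2 <- build_index(c(a = random_seq(10)), circular = FALSE, k = 15),
    "exceeds")
  expect_identical(unname(idx2$n_kmer_positions["a"]), 0L)
  expect_error(build_index(setNames(c("ACGT", "ACGT"), c("x", "x"))),
               "unique")
})

test_that("error-free reads place uniquely at their true position; repeats tie", {
  g <- tiny_genome(seed = 14)
  idx <- build_index(g)
  # unique region read
  r_unique <- substr(g$seq[["chr"]], 501, 650)
  pl <- map_reads(r_unique, idx)
  expect_identical(nrow(pl), 1L)
  expect_identical(pl$replicon, "chr")
  expect_identical(pl$start, 501)
  expect_identical(pl$strand, "+")
  expect_equal(pl$identity, 1.0)
  expect_identical(pl$aligned_length, 150L)

  # read wholly inside the two-copy repeat: exactly two tied placements
  r_rep <- substr(g$seq[["chr"]], 15201, 15350)
  pl2 <- map_reads(r_rep, idx)
  expect_identical(nrow(pl2), 2L)
  expect_setequal(pl2$replicon, c("chr", "pA"))
  expect_identical(unique(pl2$n_best), 2L)
  expect_identical(length(unique(pl2$score)), 1L)

  # read across the circular origin maps back to its wrapped start
  r_circ <- paste0(substr(g$seq[["pA"]], 7951, 8000),
                   substr(g$seq[["pA"]], 1, 100))
  pl3 <- map_reads(r_circ, idx)
  expect_identical(nrow(pl3), 1L)
  expect_identical(pl3$start, 7951)
})

test_that("a read with evenly spread mismatches below 90% identity is unmapped", {
  set.seed(33)
  ref <- c(chr = random_seq(600))
  idx <- build_index(ref, circular = FALSE)
  read <- substr(ref[["chr"]], 201, 350)
  # plant 20 substitutions every 7th position: any >=120-nt window keeps
  # at least 16 of them, so no qualifying alignment exists
  pos <- seq(5, 145, by = 7)[1:20]
  chars <- strsplit(read, "")[[1]]
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  chars[pos] <- flip[chars[pos]]
  mut <- paste(chars, collapse = "")
  expect_identical(nrow(map_reads(mut, idx)), 0L)
  # brute-force window scan: every candidate aligned stretch of >=120 read
  # bases (the length-fraction floor) carries more than 12 mismatches, so no
  # placement can reach 90% identity (gaps only add aligned columns)
  err <- rep(FALSE, 150)
  err[pos] <- TRUE
  min_err <- min(vapply(1:(150 - 120 + 1), function(s)
    sum(err[s:(s + 119)]), numeric(1)))
  expect_gt(min_err, 12)
})

test_that("mapper best score equals the exhaustive local-alignment oracle", {
  set.seed(91)
  n_inst <- 60
  miss <- 0L
  checked <- 0L
  for (i in seq_len(n_inst)) {
    ref <- c(r1 = random_seq(sample(300:500, 1)))
    start <- sample(50, 1)
    len <- sample(60:100, 1)
    read <- substr(ref[["r1"]], start, start + len - 1L)
    nerr <- rbinom(1, len, 0.01)
    if (nerr > 0) {
      chars <- strsplit(read, "")[[1]]
      pos <- sample(len, nerr)
      flip <- c(A = "C", C = "G", G = "T", T = "A")
      chars[pos] <- flip[chars[pos]]
      read <- paste(chars, collapse = "")
    }
    idx <- build_index(ref, circular = FALSE)
    pl <- map_reads(read, idx)
    if (nrow(pl) == 0) {
      miss <- miss + 1L
    } else {
      checked <- checked + 1L
      expect_identical(max(pl$score), as.integer(oracle_best_score(read, ref)))
    }
  }
  expect_gt(checked, 0.9 * n_inst)
  expect_lt(miss / n_inst, 0.01 + 1e-9)
})

test_that("threshold monotonicity and strand symmetry hold", {
  g <- tiny_genome(seed = 18)
  idx <- build_index(g)
  lib <- matepair_library(n_pairs = 150, error_rate = 0.02,
                          adapter_fraction = 0, seed = 44)
  reads <- simulate_matepairs(g, lib)
  strict <- map_reads(reads, idx, mapper_params(similarity_fraction = 0.97))
  loose <- map_reads(reads, idx, mapper_params(similarity_fraction = 0.9))
  # raising similarity_fraction never adds placements
  key <- function(x) paste(x$read_id, x$replicon, x$start, x$strand)
  expect_true(all(key(strict) %in% key(loose)))

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads$seq[1:50])))
  fwd <- map_reads(reads$seq[1:50], idx)
  rev <- map_reads(rc, idx)
  flip <- function(s) ifelse(s == "+", "-", "+")
  expect_identical(
    sort(paste(fwd$read_id, fwd$replicon, fwd$start, fwd$strand)),
    sort(paste(rev$read_id, rev$replicon, rev$start, flip(rev$strand))))
})

test_that("pair mapping recovers simulated positions and handles orphans", {
  g <- tiny_genome(seed = 25, with_repeat = FALSE)
  lib <- matepair_library(n_pairs = 2000, error_rate = 0,
                          adapter_fraction = 0, seed = 10)
  reads <- simulate_matepairs(g, lib)
  idx <- build_index(g)
  pairing <- map_pairs(reads, idx)
  expect_identical(nrow(pairing$pairs), 2000L)
  joined <- dplyr::inner_join(
    pairing$placements, reads,
    by = c("read_id", "pair_id", "mate"), suffix = c("", ".truth"))
  exact <- joined$replicon == joined$replicon.truth &
    joined$start == joined$start.truth
  # near-perfect recovery of error-free unique-region pairs
  expect_gte(mean(exact), 0.999)

  # orphan mate excluded with a warning; one-sided mapping keeps the pair
  orphaned <- reads[-1, ]
  expect_warning(p2 <- map_pairs(orphaned, idx), "orphan")
  expect_identical(nrow(p2$pairs), 1999L)

  # SAM subset round-trips through a parser-independent check
  tmp <- withr::local_tempfile(fileext = ".sam")
  write_sam(pairing$placements, reads, idx, tmp)
  lines <- readLines(tmp)
  expect_identical(sum(startsWith(lines, "@SQ")), 2L)
  body <- lines[!startsWith(lines, "@")]
  expect_identical(length(body), nrow(pairing$placements))
  expect_true(all(grepl("NM:i:", body)))
})
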