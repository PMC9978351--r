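# a small mutant/reference setup shared by the fusion tests
fusion_fixture <- function(seed, n_pairs = 3000, wt = FALSE) {
  g <- tiny_genome(seed = seed)
  sim_from <- if (wt) g else
    apply_fusion(g, donor = "pA", acceptor = "chr", family = "rep1")
  lib <- matepair_library(n_pairs = n_pairs, insert_min = 2000,
                          insert_max = 4000, error_rate = 0,
                          adapter_fraction = 0, seed = seed + 1)
  reads <- simulate_matepairs(sim_from, lib)
  pairing <- map_pairs(reads, build_index(g))
  list(reference = g, pairing = pairing, lib = lib)
}

test_that("anchored-pair selection follows the ambiguity policy", {
  fx <- fusion_fixture(seed = 51)
  pairing <- fx$pairing
  a <- select_anchor_pairs(pairing, "pA")
  # every selected pair has a unique placement on the anchor
  expect_true(all(a$anchor_mate %in% c(1L, 2L)))
  on_anchor <- ifelse(a$anchor_mate == 1L, a$rep1, a$rep2)
  expect_true(all(on_anchor == "pA"))
  # pairs with both mates on the chromosome only are excluded
  chr_only <- pairing$pairs$pair_id[
    pairing$pairs$rep1 %in% "chr" & pairing$pairs$rep2 %in% "chr"]
  expect_length(intersect(a$pair_id, chr_only), 0L)
  expect_error(select_anchor_pairs(pairing, "nope"), "Unknown anchor")

  # permissive mode admits repeat multireads, strict mode does not: every
  # strict selection is justified by a unique anchor placement of that mate
  a_perm <- select_anchor_pairs(pairing, "pA", require_unique = FALSE)
  expect_gte(nrow(a_perm), nrow(a))
  uniq_n <- ifelse(a$anchor_mate == 1L, a$n1, a$n2)
  expect_true(all(uniq_n == 1L))
})

test_that("reciprocal intersection equals the brute-force set intersection", {
  for (seed in c(52, 53)) {
    fx <- fusion_fixture(seed = seed, n_pairs = 1500)
    pairing <- fx$pairing
    cset <- reciprocal_intersect(pairing, "pA")
    # brute force from raw placements: pair ids with one mate uniquely on the
    # anchor and the other uniquely on a target, computed both ways
    pl <- pairing$placements
    uniq <- pairing$pairs
    u1 <- setNames(uniq$rep1, uniq$pair_id)[uniq$unique1]
    u2 <- setNames(uniq$rep2, uniq$pair_id)[uniq$unique2]
    both <- intersect(names(u1), names(u2))
    cross <- both[(u1[both] == "pA" & u2[both] == "chr") |
                    (u1[both] == "chr" & u2[both] == "pA")]
    expect_setequal(cset$pair_id, cross)
    sizes <- attr(cset, "set_sizes")
    expect_identical(unname(sizes["C"]), nrow(cset))
    # scatter table carries one row per supporting pair, inside bounds
    sc <- scatter_table(cset)
    expect_identical(nrow(sc), nrow(cset))
    if (nrow(sc) > 0) {
      expect_true(all(sc$anchor_pos >= 1 & sc$anchor_pos <= 8000))
      expect_true(all(sc$target_pos >= 1 & sc$target_pos <= 30000))
    }
  }
})

test_that("a planted cointegrate yields one call at the shared repeat; WT yields none", {
  fx <- fusion_fixture(seed = 54, n_pairs = 4000)
  cset <- reciprocal_intersect(fx$pairing, "pA")
  calls <- call_fusions(cset, "pA", insert_max = fx$lib$insert_max,
                        min_support = 5, repeats = fx$reference$repeats)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$target_replicon, "chr")
  # intervals overlap the repeat copies the crossover went through
  expect_true(calls$anchor_start <= 4500 && calls$anchor_end >= 3001)
  expect_true(calls$target_start <= 16500 && calls$target_end >= 15001)
  expect_true(calls$within_repeat)
  expect_identical(calls$anchor_repeat_family, "rep1")

  # min_support above the cluster size silences the call
  none <- call_fusions(cset, "pA", insert_max = fx$lib$insert_max,
                       min_support = nrow(cset) + 1L)
  expect_identical(nrow(none), 0L)

  # matched WT simulation: no cross-replicon evidence survives
  wt <- fusion_fixture(seed = 54, n_pairs = 4000, wt = TRUE)
  cset_wt <- reciprocal_intersect(wt$pairing, "pA")
  calls_wt <- call_fusions(cset_wt, "pA", insert_max = wt$lib$insert_max,
                           min_support = 5, repeats = wt$reference$repeats)
  expect_identical(nrow(calls_wt), 0L)

  # empty input stays empty
  expect_identical(nrow(call_fusions(cset[0, ], "pA")), 0L)
})

test_that("tied placements on a third repeat copy do not fabricate calls", {
  # three copies of one family: two on the chromosome, one on the plasmid;
  # reads from inside any copy are ambiguous and must be excluded by the
  # strict policy
  repl <- dplyr::bind_rows(
    replicon_spec("chr", 30000L, 1, is_chromosome = TRUE),
    replicon_spec("pA", 8000L, 3))
  reps <- dplyr::bind_rows(
    repeat_placement("fam", "chr", 5001L, 6200L),
    repeat_placement("fam", "chr", 20001L, 21200L),
    repeat_placement("fam", "pA", 3001L, 4200L))
  g <- generate_genome(repl, reps, seed = 60)
  lib <- matepair_library(n_pairs = 3000, insert_min = 2000,
                          insert_max = 4000, error_rate = 0,
                          adapter_fraction = 0, seed = 61)
  reads <- simulate_matepairs(g, lib)
  pairing <- map_pairs(reads, build_index(g))
  strict <- reciprocal_intersect(pairing, "pA", require_unique = TRUE)
  calls <- call_fusions(strict, "pA", insert_max = 4000, min_support = 5,
                        repeats = g$repeats)
  expect_identical(nrow(calls), 0L)
  # the permissive policy admits repeat-mediated pairs (visible ambiguity)
  perm <- reciprocal_intersect(pairing, "pA", require_unique = FALSE)
  expect_gte(nrow(perm), nrow(strict))
})
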