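test_that("depth arithmetic, multiread weighting and strain comparison are exact", {
  repl <- tibble::tibble(
    name = c("chr", "pA"), length = c(1000000L, 10000L),
    is_chromosome = c(TRUE, FALSE))
  pl <- tibble::tibble(
    read_id = c(paste0("c", 1:10000), paste0("p", 1:1000)),
    replicon = c(rep("chr", 10000), rep("pA", 1000)),
    n_best = 1L)
  d <- replicon_depths(pl, repl)
  expect_equal(d$average_depth[d$replicon == "chr"], 0.01)
  expect_equal(d$average_depth[d$replicon == "pA"], 0.1)
  expect_equal(d$ratio_to_chromosome[d$replicon == "pA"], 10)
  expect_equal(d$ratio_to_chromosome[d$replicon == "chr"], 1)

  # a read tied between two replicons contributes half weight to each
  pl2 <- tibble::tibble(
    read_id = rep(c("m1", "m2"), each = 2),
    replicon = rep(c("chr", "pA"), times = 2),
    n_best = 2L)
  d2 <- replicon_depths(pl2, repl)
  expect_equal(d2$mapped_read_weight, c(1, 1))
  # unique weighting drops them entirely, leaving no chromosome signal
  expect_error(replicon_depths(pl2, repl, weighting = "unique"), "zero")

  # identical strains: all folds 1; chromosome fold is always 1
  expect_equal(compare_strains(d, d)$fold, c(1, 1))
  d3 <- d
  d3$ratio_to_chromosome[d3$replicon == "pA"] <- 20
  cmp <- compare_strains(d, d3)
  expect_equal(cmp$fold[cmp$replicon == "pA"], 2)
  expect_equal(cmp$fold[cmp$replicon == "chr"], 1)
  expect_error(compare_strains(d, d[d$replicon == "chr", ]), "same replicons")
})

test_that("depth ratios recover planted copy numbers and survive subsampling", {
  repl <- dplyr::bind_rows(
    replicon_spec("chr", 40000L, 1, is_chromosome = TRUE),
    replicon_spec("pB", 8000L, 5))
  g <- generate_genome(repl, seed = 71)
  lib <- matepair_library(n_pairs = 20000, error_rate = 0,
                          adapter_fraction = 0, seed = 72)
  reads <- simulate_matepairs(g, lib)
  idx <- build_index(g)
  pl <- map_reads(reads, idx)
  d <- replicon_depths(pl, g$replicons)
  ratio <- d$ratio_to_chromosome[d$replicon == "pB"]
  expect_lt(abs(ratio - 5) / 5, 0.15)

  # ratio is stable (within sampling error) under 50% read subsampling
  half <- subsample_reads(reads, nrow(reads) %/% 2, seed = 73)
  dh <- replicon_depths(map_reads(half, idx), g$replicons)
  rh <- dh$ratio_to_chromosome[dh$replicon == "pB"]
  expect_lt(abs(rh - ratio) / ratio, 0.1)
})

test_that("signal-ratio quantification matches the t-test definition", {
  # identical groups: fold 1, p = 1 (degenerate zero-variance case)
  d_id <- tibble::tibble(
    grp = rep(c("WT", "OE"), each = 3),
    a = rep(2, 6), b = rep(1, 6))
  expect_warning(fit <- signal_ratio_test(d_id, grp, a, b, ref_group = "WT"),
                 "zero variance")
  td <- tidy(fit)
  expect_equal(td$fold, 1)
  expect_equal(td$p_value, 1)

  # constant triplets 1 vs 3: fold 3, p ~ 0 with a zero-variance warning
  d3 <- tibble::tibble(
    grp = rep(c("WT", "OE"), each = 3),
    a = c(1, 1, 1, 3, 3, 3), b = rep(1, 6))
  expect_warning(fit3 <- signal_ratio_test(d3, grp, a, b, ref_group = "WT"),
                 "zero variance")
  expect_equal(tidy(fit3)$fold, 3)
  expect_lt(tidy(fit3)$p_value, 0.001)

  # agreement with stats::t.test on non-degenerate data
  set.seed(80)
  dn <- tibble::tibble(
    grp = rep(c("WT", "OE"), each = 4),
    a = c(rnorm(4, 1, 0.1), rnorm(4, 3, 0.2)), b = 1)
  fitn <- signal_ratio_test(dn, grp, a, b, ref_group = "WT")
  ref <- t.test(dn$a[dn$grp == "OE"], dn$a[dn$grp == "WT"], var.equal = TRUE)
  expect_equal(tidy(fitn)$p_value, ref$p.value)
  expect_equal(tidy(fitn)$t_statistic, unname(ref$statistic))
  expect_identical(glance(fitn)$n_groups, 2L)

  # single replicate: ratio reported, test refused
  d1 <- tibble::tibble(grp = c("WT", "WT", "OE"), a = c(1, 1.2, 2), b = 1)
  expect_warning(f1 <- signal_ratio_test(d1, grp, a, b, ref_group = "WT"),
                 "fewer than 2")
  expect_true(is.na(tidy(f1)$p_value))
  expect_false(is.na(tidy(f1)$fold))
})

test_that("the t-test p value is uniform under label permutation", {
  set.seed(81)
  ps <- replicate(200, {
    lab <- sample(rep(c("g1", "g2"), each = 4))
    d <- tibble::tibble(grp = lab, a = rnorm(8, mean = 5, sd = 0.7), b = 1)
    suppressWarnings(tidy(signal_ratio_test(d, grp, a, b,
                                            ref_group = "g1"))$p_value)
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
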