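asrna1_substrate <- function() {
  transcript_substrate(32483, 32329, "-", extra5 = 3)
}

test_that("substrate lengths match the locus coordinates", {
  expect_identical(substrate_length(asrna1_substrate()), 158L)
  # native antisense transcript, no non-templated additions
  expect_identical(
    substrate_length(transcript_substrate(32481, 32329, "-")), 153L)
  # single-nucleotide span
  expect_identical(
    substrate_length(transcript_substrate(100, 100, "+")), 1L)
  expect_error(transcript_substrate(32329, 32483, "-"), "reverse strand")
  expect_error(transcript_substrate(10, 5, "+"), "forward strand")
})

test_that("cleavage-fragment sizes follow the downstream-5'-end convention", {
  s <- asrna1_substrate()
  expect_identical(fragment_sizes(s, 32426), c(60L, 98L))
  expect_identical(fragment_sizes(s, 32418), c(68L, 90L))
  expect_identical(fragment_sizes(s, c(32426, 32418)), c(60L, 8L, 90L))
  # cut order in the input does not matter
  expect_identical(fragment_sizes(s, c(32418, 32426)), c(60L, 8L, 90L))
  # cuts accepted as a site table with matching strand
  tab <- tibble::tibble(position = c(32426, 32418), strand = "-")
  expect_identical(fragment_sizes(s, tab), c(60L, 8L, 90L))
  expect_error(fragment_sizes(s, tibble::tibble(position = 32426,
                                                strand = "+")),
               "strand")
  expect_error(fragment_sizes(s, 32500), "outside")
  expect_error(fragment_sizes(s, 32300), "outside")
})

test_that("fragment lengths always sum to the substrate length (random cut sets)", {
  set.seed(101)
  for (i in 1:50) {
    strand <- sample(c("+", "-"), 1)
    a <- sample(1000:2000, 1)
    span <- sample(50:400, 1)
    extra <- sample(0:5, 1)
    s <- if (strand == "-")
      transcript_substrate(a + span - 1, a, "-", extra5 = extra)
    else transcript_substrate(a, a + span - 1, "+", extra5 = extra)
    interior <- if (strand == "-") (a):(a + span - 2) else (a + 1):(a + span - 1)
    cuts <- sample(interior, sample(1:5, 1))
    lens <- fragment_sizes(s, cuts)
    expect_identical(sum(lens), substrate_length(s))
    expect_true(all(lens > 0))

    # strand symmetry: the mirrored forward-strand problem gives the same
    # fragment series
    if (strand == "-") {
      mirror <- transcript_substrate(
        -s$five_prime_pos, -s$three_prime_pos, "+", extra5 = s$extra5)
      expect_identical(fragment_sizes(mirror, -cuts), lens)
    }
  }
})

test_that("ORF and TSS arithmetic reproduce the locus constants", {
  expect_identical(orf_aa_count(32289, 32483), 64L)
  expect_identical(orf_aa_count(1, 6), 1L)
  expect_error(orf_aa_count(1, 4), "multiple of 3")
  expect_identical(tss_distance(32177, 32481), 304)
  expect_identical(tss_distance(32481, 32177), 304)
  expect_identical(tss_distance(5, 5), 0)
})

test_that("processing-site classification reproduces the packaged table", {
  pss <- read_pss_sites()
  expect_identical(nrow(pss), 14L)
  expect_identical(sum(pss$tu %in% c("TU7029", "TU7030")), 10L)
  expect_identical(sum(pss$tu == "TU7031"), 4L)

  cl <- classify_pss(pss, "wt_vs_ts")
  # the two antisense-RNA sites with significantly higher counts under
  # active RNase E are called cleavage sites
  tu31 <- cl[cl$tu == "TU7031", ]
  expect_identical(sum(tu31$category == "rnase_e_site"), 2L)
  expect_setequal(tu31$position[tu31$category == "rnase_e_site"],
                  c(32426L, 32418L))
  expect_identical(
    as.character(cl$category[cl$position == 32418]), "rnase_e_site")
  expect_identical(
    as.character(cl$category[cl$position == 32463]), "stabilized_in_ts")
  expect_identical(
    as.character(cl$category[cl$position == 32469]), "unclassified")

  # second comparison: sites accumulating in the 5'-sensing-deficient strain
  cl5 <- classify_pss(pss, "wt_vs_5p")
  dep <- cl5$position[cl5$category == "five_prime_sensing_dependent"]
  expect_true(all(c(32251, 32260) %in% dep))
  # missing adjusted p leaves a site unclassified
  expect_identical(
    as.character(cl5$category[cl5$position == 32426]), "unclassified")

  # alpha is a real threshold: alpha = 0.01 drops the padj = 0.02 site
  cl_strict <- classify_pss(pss, "wt_vs_ts", alpha = 0.01)
  expect_identical(
    as.character(cl_strict$category[cl_strict$position == 32426]),
    "unclassified")
})

test_that("in silico digestion and primer location work on constructed circles", {
  set.seed(110)
  site <- "AAGCTT"
  # 10-kb circle with sites planted at 1,000 and 3,550
  backbone <- gsub("AAGCTT", "AAGCAT", random_seq(10000), fixed = TRUE)
  plasmid <- backbone
  substr(plasmid, 1000, 1005) <- site
  substr(plasmid, 3550, 3555) <- site
  frags <- digest_sequence(plasmid, site, circular = TRUE)
  expect_identical(nrow(frags), 2L)
  expect_setequal(frags$length, c(2550L, 7450L))
  expect_identical(sum(frags$length), 10000L)

  # linear digestion of the same molecule gives three fragments
  lin <- digest_sequence(plasmid, site, circular = FALSE)
  expect_identical(nrow(lin), 3L)
  expect_identical(sum(lin$length), 10000L)

  # no site: one fragment, whole molecule
  none <- digest_sequence(backbone, site, circular = FALSE)
  expect_identical(none$length, 10000L)

  # primer pair with a T7-tagged reverse primer locates its amplicon
  fwd <- substr(plasmid, 1500, 1519)
  rev_rc <- substr(plasmid, 2281, 2300)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rev_rc)))
  amp <- locate_amplicon(plasmid, fwd, rev)
  expect_identical(amp$start, 1500L)
  expect_identical(amp$end, 2300L)
  expect_identical(amp$length, 801L)
  t7 <- paste0("TAATACGACTCACTATAGGG", rev)
  expect_identical(locate_amplicon(plasmid, fwd, t7), amp)
  expect_error(locate_amplicon(plasmid, "ACGTACGTACGTACGTACGT", rev),
               "0 exact hits")
  # the fragment containing the amplicon is the 2,550-nt one
  frag <- fragment_containing(frags, amp$start, 10000L)
  expect_identical(frag$length, 2550L)
})
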