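Package: replikit
Title: Plasmid Cointegrate Detection from Mate-Pair Reads, Replicon Copy
    Number, and RNase E Processing-Site Arithmetic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the genomic structure of multi-replicon
    bacterial genomes such as Synechocystis sp. PCC 6803 from long-insert
    mate-pair sequencing. Simulates multi-replicon genomes with shared
    homologous repeat elements, single-crossover plasmid cointegrates and
    mate-pair FASTQ libraries with truth tables; trims reads (Mott quality
    trimming, junction-adapter removal, terminal clipping); maps reads with a
    seed-and-extend aligner that reports all tied-best placements; detects
    whole-plasmid integration events by reciprocal anchored-pair selection and
    clusters the supporting pairs into fusion calls; estimates relative
    replicon copy numbers from read-depth ratios; and performs strand-aware
    transcript coordinate arithmetic for RNase E cleavage-fragment prediction,
    processing-site classification, in silico restriction digestion and primer
    placement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
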