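# replikit

Detecting whole-plasmid integration from mate-pair sequencing, estimating
replicon copy numbers from read depth, and doing the strand-aware coordinate
arithmetic of an RNase-E-regulated plasmid copy-number control locus.

## The problem

Cyanobacteria such as *Synechocystis* sp. PCC 6803 carry a large chromosome
plus several plasmids. When a plasmid loses its replication initiator (Rep)
protein it can survive by recombining — in its entirety — into the
chromosome or another plasmid through a single crossover between homologous
repeats (transposase or integrase genes shared between replicons). Because
such genomes are riddled with duplicated sequences over 1 kb, short-insert
libraries cannot see these events; long-insert (2–10 kb) mate-pair
libraries can: after mapping, a cointegrate announces itself as read pairs
whose two mates land on *different* replicons, clustering around the
junction.

`replikit` implements that analysis as a tested, seeded R pipeline:

* **Reciprocal anchored-pair selection.** Select pairs with one side on the
  anchor plasmid (set A), narrow to pairs whose other side maps to a
  chromosomal or plasmid locus (set B), repeat with the references switched
  (set B′), and keep the pairs common to both subsets (set C). First
  positions of the supporting pairs form the diagnostic scatter; single-
  linkage clustering at the maximum insert size turns them into fusion
  calls. Because crossover happens *inside* an identical repeat, the
  breakpoint is only identifiable up to that repeat; calls therefore report
  junction intervals, flagged `within_repeat`.
* **Copy number from depth ratios.** Average read depth = mapped reads on a
  replicon / replicon length; a plasmid's depth divided by the chromosomal
  depth estimates its copy number per chromosome copy. Multireads are
  weighted fractionally across tied-best placements so shared repeats do
  not inflate plasmid depth. A two-probe blot quantification
  (`signal_ratio_test()`, plasmid probe over chromosome probe, unpaired
  two-tailed Student's t-test) covers the orthogonal wet-lab readout.
* **Read processing and mapping.** Mott quality trimming at Phred > 30
  (error-probability limit 10⁻³), junction-adapter removal, clipping of 5
  terminal nt from both ends, discarding reads < 20 nt, seeded random
  subsampling; then a k-mer seed-and-extend aligner (Rcpp) that accepts a
  placement when aligned-length fraction ≥ 0.8 and identity ≥ 0.9 and
  reports **all** tied-best placements, so downstream logic can require
  uniqueness explicitly.
* **Synthetic data as a first-class module.** `generate_genome()`,
  `apply_fusion()` and `simulate_matepairs()` build multi-replicon genomes
  with planted repeat families, single-crossover cointegrates, and
  mate-pair FASTQ with junction adapters, base-call errors and in-band
  ground truth — every downstream stage is testable without downloads.
* **Locus arithmetic.** The plasmid copy-number control locus encodes an
  mRNA (*ssr7036*) and an abundant antisense RNA overlapping it, both cut
  by RNase E — a ColE1 RNAI/RNAII-like arrangement.
  `transcript_substrate()`, `fragment_sizes()` (cleavage-site coordinate =
  5′-terminal nucleotide of the downstream product), `orf_aa_count()`,
  `tss_distance()`, `classify_pss()` over the packaged TIER-seq site table,
  plus in silico restriction digestion and primer/amplicon location.

## Worked example

Simulate a mutant in which a 30-kb anchor plasmid has integrated into a
200-kb chromosome through a shared 1.5-kb transposase repeat, then detect
the event by mapping the mutant's mate pairs back to the wild-type
reference:

```r
library(replikit)
library(dplyr)

replicons <- bind_rows(
  replicon_spec("chr", 200000, copy_number = 1, is_chromosome = TRUE),
  replicon_spec("pSYSA_like", 30000, copy_number = 2))
repeats <- bind_rows(
  repeat_placement("transposase", "chr", 120001, 121500),
  repeat_placement("transposase", "pSYSA_like", 10001, 11500))
wt <- generate_genome(replicons, repeats, seed = 1)
mutant <- apply_fusion(wt, donor = "pSYSA_like", acceptor = "chr",
                       family = "transposase")

run <- run_matepair_pipeline(
  mutant, matepair_library(n_pairs = 50000), reference = wt,
  anchor = "pSYSA_like", seed = 1)
run
#> <mp_run> seed 1: 50000 pairs simulated, 100000 reads kept
#> Anchored-pair set sizes: |A|=7228 |B|=1598 |B'|=1598 |C|=1598
#> 1 fusion call(s)
#>   anchor_replicon anchor_start anchor_end target_replicon target_start
#> 1 pSYSA_like             10000      11519 chr                   119991
```

The single call brackets the planted repeat on both replicons (true copies
at 10,001–11,500 and 120,001–121,500) and is flagged `within_repeat`. The
depth table of the same run shows the integrated plasmid at a depth ratio
of ≈ 1 — it now replicates with the chromosome:

```r
run$depth
#>   replicon   length average_depth ratio_to_chromosome
#> 1 chr        200000         0.427               1
#> 2 pSYSA_like  30000         0.425               0.994
```

The locus arithmetic reproduces the in vitro cleavage expectations: a
reverse-strand substrate from 32,483 down to 32,329 with three extra
5′ G residues is 158 nt, and cuts at 32,426 and 32,418 partition it into
60 + 8 + 90 nt:

```r
s <- transcript_substrate(32483, 32329, "-", extra5 = 3)
substrate_length(s)                    #> 158
fragment_sizes(s, c(32426, 32418))     #> 60  8 90
classify_pss(read_pss_sites(), "wt_vs_ts") |> count(tu, category)
#>   TU7030 rnase_e_site 3 ... TU7031 rnase_e_site 2 ...
```

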