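---
title: "Methods: mate-pair cointegrate detection, depth ratios and locus arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mate-pair cointegrate detection, depth ratios and locus arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind `replikit`, the
assumptions they make, the parameters that matter, and the numerical and
design choices taken where more than one defensible option existed.

## 1. The biological model

A bacterial genome here is a set of circular replicons: one chromosome and
one or more plasmids, each present at some copy number per chromosome copy.
Replicons share *repeat families* — transposase or integrase genes of 1 kb
and more whose copies are identical in sequence. A plasmid that cannot
replicate autonomously (for instance after loss of its Rep protein) can
persist as a **cointegrate**: a single crossover between one repeat copy on
the plasmid (donor) and a homologous copy on the chromosome or another
plasmid (acceptor) inserts the *entire* donor into the acceptor. After the
event, one complete repeat copy flanks each junction, and the donor
disappears as a free replicon. `apply_fusion()` implements exactly this
operation and records both junction coordinates as ground truth.

We deliberately model only the single-crossover cointegrate, because that
is the configuration in which the whole donor sequence is retained and the
junctions fall at homologous genes; double-crossover replacement (which
loses sequence) is out of scope.

Two consequences drive the detector's design:

1. Junction-spanning DNA fragments have one end in donor-derived and one
   end in acceptor-derived sequence. Mapped back to the *unfused*
   reference, such a fragment produces a read pair split across two
   replicons.
2. The crossover lies *inside* an identical repeat, so its position is
   fundamentally unidentifiable within the repeat. Any honest caller must
   report an interval, not a base-pair breakpoint.

## 2. The mate-pair library model

`matepair_library()` describes a long-insert library: fragments of
2,000–10,000 nt (uniform), read at 150 nt from each end, sampled across
replicons with probability proportional to copy number × length, with
origins allowed to span the circular origin. These defaults are the
protocol values of long-insert mate-pair sequencing; insert sizes well
above the repeat length are what lets mates bridge a 1.5-kb repeat.

Mate-pair library construction circularizes fragments, so a fraction of
reads run through the circularization junction: they contain a junction
adapter followed by sequence from the opposite fragment end. We model this
with a configurable `adapter_fraction` (default 0.2) and a fixed 19-mer
adapter (configurable; we do not claim chemistry-accurate fidelity for any
particular kit). Base-call errors are uniform substitutions
(`error_rate`, default 0.005); indel errors, GC bias and PCR duplicates
are *not* modelled, so passing tests say nothing about robustness to
those. Qualities follow a two-state profile — Phred 37 bases with an
optional low-quality (Phred 11) 3′ tail on 30% of reads — which is
deliberately minimal: it is exactly enough to exercise a Phred-30
quality trimmer, not a full error model.

The simulator writes ground truth (source replicon, leftmost 1-based
position, strand, adapter status per read) as ordinary tibble columns, so
any downstream stage can be scored in code. Since the mate orientation
convention after adapter processing varies between workflows, the truth
records strand explicitly and no stage uses orientation as evidence.

## 3. Read processing

`trim_reads()` applies, in order:

1. **Junction-adapter removal** — split at every exact adapter occurrence
   and keep the longest adapter-free segment. This runs first because
   adapter chimeras must be removed before any coordinate-based clipping.
2. **Quality trimming** — "Phred quality score > 30" is interpreted as
   Mott trimming: keep the contiguous segment maximising
   Σ (0.001 − p_err(base)), not hard truncation at the first base under
   Q30. Hard truncation throws away everything after one bad base; the
   Mott interval is the standard interpretation of workbench-style quality
   trimming. Ties on the score are resolved to the longer, then leftmost
   segment.
3. **Terminal clipping** — 5 nt off both ends, applied exactly once per
   read (a `terminal_clipped` flag makes re-trimming idempotent).
4. **Length filter** — reads under 20 nt are *flagged* discarded, never
   silently dropped, so pair bookkeeping survives.

If one mate of a pair is discarded, the pair leaves the pairing analysis
but the surviving mate still counts for depth estimation (depth uses
reads; pairing uses pairs). Subsampling (`subsample_reads()`) is uniform
without replacement and counts reads by default (pairs optionally); the
classic workflow's 4,000,000-read subsample is a scalable parameter, not a
constant.

## 4. The mapper

`map_reads()` is a k-mer seed-and-extend aligner (compiled via Rcpp, as
aligners in this field are): exact 15-mer seeds over the forward strand of
every replicon (circular replicons indexed across the origin), diagonal
voting, then banded Smith–Waterman extension with scores +1/−2/−3
(match/mismatch/per-gap-base) in a band of ±8 around the seeded diagonal.
A placement qualifies when

* aligned read bases / read length ≥ `length_fraction` (0.8), and
* matches / aligned columns ≥ `similarity_fraction` (0.9), gaps counting
  as columns.

These are our renditions of the workbench "length fraction" and
"similarity fraction"; the original tool does not publish its exact
semantics, so ours are documented approximations, validated against an
exhaustive Smith–Waterman oracle in the tests (scores agree whenever the
mapper places a read; seed misses at 1% error stay under 1%).

**All tied-best placements are reported.** A popular alternative is to
place multireads randomly; we refuse, because fusion junctions sit inside
repeats and invisible ambiguity would fabricate cross-replicon pairs in
unfused genomes. Reporting ties lets the fusion logic require uniqueness
explicitly. Coordinates are 1-based; `start` is the leftmost aligned
reference position (SAM convention) with strand carried separately — for
a reverse-strand read the biological "first base" is the rightmost
coordinate, but clustering and scatter plots are insensitive to this
choice.

## 5. Fusion detection

Given pair-level placements and an anchor replicon:

* `select_anchor_pairs()` — set A: pairs with one side on the anchor.
* `cross_replicon_pairs()` — set B: the subset whose other side maps to a
  target replicon.
* `reciprocal_intersect()` — set B′ with references switched, and
  C = B ∩ B′ by pair identity. The intersection is keyed on pair ids (the
  literal reading of "pairs common to both subsets"); on every test
  instance it equals the brute-force set intersection.
* `call_fusions()` — single-linkage clustering of C with linkage distance
  `insert_max` on both the anchor and the target axis; clusters under
  `min_support` (default 5) are dropped. Mate-pair inserts give dense
  junction coverage, so genuine junctions attract tens to hundreds of
  pairs; singleton chimeras are library artifacts, hence the support
  floor.

**Ambiguity policy.** By default a mate "maps to" a replicon only when its
*unique* best placement is there (`require_unique = TRUE`). This is the
load-bearing choice: reads wholly inside a shared repeat are tied between
copies and must not count as cross-replicon evidence, otherwise every
unfused genome with a shared repeat would light up. The permissive mode
(any tied placement) is retained for comparison.

**Interval reporting.** Within a cluster, supporting positions sit on both
sides of the junction while the repeat itself is a mapping dead zone (only
ambiguous placements originate there). If the largest internal gap in the
sorted positions clearly dominates — exceeding both twice the read length
and twice the second-largest gap — the call brackets that gap (innermost
flanking positions, padded by one read length); otherwise, with sparse
support, the junction is only localized to the cluster span and we report
that honestly. If a repeat annotation is supplied and the interval
overlaps a repeat copy, the interval is widened to the full repeat and
flagged `within_repeat` — stating, not hiding, the identifiability limit.

## 6. Copy number

`replicon_depths()` computes average depth = Σ read weights / length and
the ratio to the chromosome. The default **fractional weighting** splits
each read's unit weight equally across its tied-best placements; under
unique weighting, repeats shared between replicons would deterministically
siphon depth between replicons in proportion to their copy-number
difference. Read counts (not pair counts) are used. `compare_strains()` is
the ratio of ratios, so the chromosome's fold is 1 by construction.

`signal_ratio_test()` quantifies a two-probe blot: per-replicate
plasmid/chromosome signal ratio, group mean ratios, and an unpaired
two-tailed Student's t-test (pooled variance, because that is what a
"Student's t-test" is; Welch behind `var_equal = FALSE`) on the
per-replicate ratios against a reference group. The test is computed on
ratios rather than per-lane-normalized raw signals — the ratio *is* the
per-lane normalization. Degenerate inputs are defined, not undefined
behavior: one replicate → ratio only, test refused; zero variance in both
groups → p = 1 for equal means, p = 0 otherwise, each with a warning.

## 7. Locus arithmetic

`transcript_substrate()` describes a transcript as a strand-aware genomic
span plus `extra5` non-templated 5′ residues (e.g. the three G left by T7
initiation) and a 5′ phosphorylation state. The **cleavage-site
convention** is fixed: a site coordinate is the 5′-terminal nucleotide of
the downstream product. This is the only convention consistent both with
5′-monophosphate end sequencing (the mapped end *is* the downstream
product's first base) and with all three fragment sizes printed for the
antisense-RNA substrate (60/98 for the upstream cut, 90 for the
downstream, 8 between the two). `fragment_sizes()` partitions the
substrate accordingly; `extra5` counts toward the 5′-most fragment, and
conservation (fragments sum to substrate length) holds for any cut set. A
cut coinciding with the templated 5′ terminus of a substrate without
non-templated residues would create an empty fragment and is rejected.

`classify_pss()` consumes a table of per-site fold changes and adjusted p
values (these come from the upstream differential analysis; we never
recompute them). Classification uses only the sign of the fold change and
`padj <= alpha`, so the log base of the fold change is immaterial.
Adjusted p values printed as "0.00" are stored exactly as printed; with a
`<=` comparison the rounded zero classifies identically to any true value
below 0.005. The default `alpha = 0.05` matches which table rows the
accompanying analysis treats as significant. In the strain comparison
with the temperature-sensitive enzyme, significantly *positive* fold
change (more 5′ ends with active enzyme) marks an RNase E site and
significantly negative marks a site stabilized when the enzyme declines
(cleavage by another RNase); in the comparison involving the
5′-sensing-deficient enzyme, significantly negative marks processing that
depends on 5′ sensing.

`digest_sequence()` cuts at every exact recognition-site occurrence (cut
coordinate at the site start — fragment *sizes* depend only on site
spacing, which is what blot band sizes measure), handles circular
molecules including the origin-spanning fragment, and always conserves
total length. `locate_amplicon()` finds a primer pair's product by exact
matching after stripping a T7 promoter leader, and errors on zero or
multiple hits rather than guessing.

## 8. Pipeline, seeding and problem sizes

`run_matepair_pipeline()` chains simulate → trim → (subsample) → map →
fusion detection + depth estimation. Stage seeds derive from the master
seed by fixed offsets (simulation +101, subsampling +202), so a run is
byte-reproducible from one integer, and every stochastic stage is seeded.
Any stage failure aborts with the stage name.

The simulation scale used throughout the tests is our own choice of a
desk-scale study condition: a 200-kb chromosome standing in for a
multi-megabase one, a 30-kb anchor plasmid, one shared 1.5-kb repeat,
50,000 pairs at 0.5% substitution error for detection runs, and 100,000
pairs for copy-number recovery at planted ratios {1, 5, 10}. At these
sizes junction coverage and depth estimates are well within the regimes
the claims address, while a full run stays in the tens of seconds.

## 9. Known limitations

* Split-read (within-read breakpoint) evidence, inversions/deletions and
  junction assembly are out of scope; the detector sees only
  replicon-identity of mate placements.
* The aligner is a deliberate approximation of the original workbench
  mapper: tie-breaking, trimmed-vs-raw length semantics and multiread
  placement of that tool are not public, so exact read-level agreement
  with it is not claimed — only oracle-validated alignment optimality
  under our stated scoring.
* The simulator omits indels, GC bias, chimeras beyond the junction-read
  model, and real adapter chemistry; conclusions from synthetic runs
  transfer to real libraries only to the extent those effects are
  second-order for replicon-level evidence.
* Depth-based copy number has no GC/mappability correction and no
  windowed segmentation; it estimates whole-replicon averages only.
* The processing-site classifier consumes externally computed
  differential statistics; it adds no multiple-testing machinery of its
  own.
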