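---
title: "Methods: integrative ChIP-seq co-occupancy, motif and conservation analysis"
author: "peakCobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative ChIP-seq co-occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakCobind)
```

# Scope and model

peakCobind implements the integrative analysis that links genome-wide
binding maps of two transcription factors (replicate ChIP-seq peak sets)
to gene regulation: TSS-proximal peak-to-gene assignment, two-factor
co-occupancy classification, position-weight-matrix motif scanning,
ortholog-projected cross-species conservation of bound gene sets, and
contingency-table association between binding classes and
expression-responsive gene sets. Peak calling, read alignment,
differential-expression calling and de novo motif discovery are upstream
of this package and out of scope; their outputs (BED/TSV peak tables,
GTF annotation, JASPAR matrices, DE tables) are its inputs.

# Coordinates and containers

Internally all intervals live in `GenomicRanges::GRanges`, the
Bioconductor convention (1-based, closed). All file formats keep their
native conventions and are converted at the I/O boundary: BED and the
MACS-style TSV dialect are 0-based half-open, GTF is 1-based closed. The
derived quantities are defined so that half-open arithmetic holds
exactly:

* midpoint of a peak occupying `[s, e)` (half-open) is `floor((s + e)/2)`;
* the TSS of a plus-strand gene spanning `[s, e)` is `s`, of a
  minus-strand gene `e − 1`;
* two peaks overlap when their intersection contains at least
  `minOverlap` bases — abutting half-open intervals do not overlap;
* a peak is proximal to a gene when the peak interval intersects the
  *closed* window `[tss − w, tss + w]` (default `w` = 10 kb) by at least
  one base.

Windows are tested against the whole peak interval by default (the
inclusive reading of "binding within 10 kb"); `mode = "midpoint"` in
`assignProximal()` restricts the test to peak midpoints for sensitivity
analysis. One consequence of the interval mode is that a wide peak can
intersect the window while its midpoint lies slightly outside ±w; the
stored signed distance is always the true strand-oriented TSS→midpoint
distance, so it is not clamped to the window.

# Replicate consensus and peak sharing

Only binding events supported by both independent ChIP-seq replicates are
analysed. `replicateConsensus()` groups the combined peaks into maximal
chains of transitively overlapping intervals (overlap ≥ `minOverlap`) and
keeps a chain only when both replicates contribute; the emitted consensus
interval is the union span of the chain, its height the maximum member
height. The union policy (rather than intersection) is recorded in the
output metadata; the minimum overlap defaults to 1 bp and is
configurable, since published peak tables rarely state either convention.
Internally the transitive closure is obtained by trimming `minOverlap − 1`
bases from every interval end and reducing: two intervals overlap by ≥ k
bases exactly when their trimmed versions still overlap, so a single
`reduce()` yields the connected components.

`sharePeaks()` applies the same overlap predicate between the consensus
sets of two factors; a factor-A peak is *shared* when it overlaps at
least one factor-B peak. "Binding at the same coordinates" is thus read
as ≥ 1 bp peak overlap by default. At the gene level
(`geneBindingClasses()`), *common* means at least one of the gene's
proximal A-peaks overlaps one of its proximal B-peaks; a gene with any
such pair is common even if it also has non-overlapping pairs (common
beats uncommon, the two labels being exclusive); *uncommon* requires
proximal peaks of both factors with no overlapping pair. The five labels
(A-only, common, uncommon, B-only, none) partition the gene universe.

# Motif scanning

`PFMotif` stores a JASPAR position frequency matrix with a background
model *q* (default uniform) and pseudocount *s* (default 0.8, distributed
by background frequency, the TFBS-suite convention). The log-odds score
of base *b* at column *j* is

$$M_{bj} = \log_2 \frac{(n_{bj} + s\,q_b) / (N_j + s)}{q_b},$$

and a window's relative score rescales its summed log-odds between the
matrix's minimum and maximum attainable scores, so the consensus string —
the per-column count maximiser — always scores exactly 1. Both strands
are scanned (the minus strand by scoring with the reverse-complemented
matrix), offsets are reported on the forward strand, windows containing
`N` are skipped, and ties for a peak's best hit go to the smallest offset
and then the plus strand. The default reporting threshold of 0.80
relative score is a convention, not a published value; fractions of peaks
with a hit are therefore meaningful mainly in comparisons across peak
sets at the same threshold. Between-set enrichment
(`motifSetEnrichment()`) uses the Pearson chi-square on the 2×2
with/without-hit table and reports the hit-rate ratio as fold.
Positional centrality (`motifCentrality()`) compares the mean absolute
offset of best hits from peak midpoints with the same statistic under
uniform re-randomisation of hit positions within each peak (default 100
draws); centrally enriched motifs fall well below the uniform
expectation of roughly a quarter of the peak width.

# Cross-species conservation

Foreign-species proximal-bound gene sets are projected onto reference
identifiers through a 3-column ortholog map. All three homology types
(one2one, one2many, many2many) contribute by default — the inclusive
"orthologues and possible orthologues" reading — and projection takes the
union of targets, deduplicated (sets, not multisets); inputs without a
usable record are counted and reported rather than silently dropped.
`vennPartition()` computes all `2^k − 1` disjoint membership patterns for
2–4 sets, and `conservationClasses()` assigns each reference gene the
number of other species in which it is bound.

# Association statistics

`chiSquare2x2()` is the plain Pearson statistic without Yates continuity
correction — the counts this analysis meets are large, and the
uncorrected test is what "chi-square test" denotes in the source
literature — with the upper-tail P from the χ²₁ distribution. Zero
marginals leave the test undefined and raise an error; the pipeline
records such associations as undefined instead of failing the run. Fold
enrichment is observed/expected for the focal cell; the sample odds ratio
is also reported. Term-set enrichment (`termFoldEnrichment()`) uses the
plain fold ratio and a two-sided Fisher exact P, appropriate for small
term sets; no multiple-testing correction is applied by default because
the headline analyses report raw P values. qPCR helpers implement the
percent-of-input transform `100·E^{(Ct_input − log_E dilution) − Ct_target}`
(amplification efficiency E = 2 by default, configurable) and fold over
the IgG control.

# The synthetic-data generator

Because the original genome-scale inputs require external downloads, the
package ships a generator whose outputs carry recorded ground truth, so
every pipeline stage is testable offline:

* `simulateGenomeAnnotation()` — uniform-random DNA; genes packed without
  overlap by distributing the free space randomly; strands random.
* `simulatePeaks()` — each peak is TSS-proximal with the planted
  probability; proximal peaks centre at TSS + N(0, 3 kb) (under 0.1% of
  that Gaussian lies beyond the 10 kb window), background peaks are
  placed uniformly in space kept ≥ 10 kb away from every TSS, widths
  uniform 200–800 bp, heights log-normal to mimic RPM values.
* `simulateCofactorPeaks()` — a Bernoulli(p) subset of base peaks (p
  defaults to 0.4, the co-occupancy level observed for Smad2/Eomesa)
  receives an overlapping partner whose centre is jittered by N(0, 100 bp)
  but clamped to guarantee ≥ 1 bp overlap; extra independent peaks avoid
  all base peaks. The truth labels equal `sharePeaks()` output exactly
  when base peaks are mutually non-overlapping and spaced beyond the
  jitter range (`tilePeaks()` provides such sets); with clustered base
  peaks a partner can also graze a neighbour, inflating the realised
  sharing slightly above the planted fraction.
* `plantMotifs()` — writes consensus instances (maximal detectability;
  PFM-sampled mode available for power studies) into a Bernoulli(rate)
  subset of peaks at N(0, 50 bp) from the midpoint, random strand.
* `simulateOrthologyAndForeignSets()` — per-species conservation flags
  (defaults 0.30/0.30/0.20 for a human/mouse/xenopus-like trio, chosen to
  emulate the observed cross-species overlap levels, e.g. ≥ 1-mammal
  conservation near 50%); foreign bound sets are constructed so that
  projecting them back recovers the planted flags exactly, including
  under one2many fan-out (fan-out targets are drawn among conserved
  genes).
* `simulateDETable()` — per-gene responsiveness with class-dependent
  odds (log-odds of the base rate shifted by log OR); responsive genes
  draw |log2FC| ~ |N(2, 0.5)| with 78% upregulated (matching the
  observed up/down split of Nodal-responsive genes) and P uniform below
  the threshold; non-responsive genes draw P uniform above it.

Every generator takes a seed and reproduces its outputs byte-identically;
`childSeed(seed, stream)` fans a root seed out deterministically so
stages can be regenerated independently. What the generator does *not*
emulate: read-level noise, fragment-size effects, mappability biases,
non-uniform base composition, clustered regulatory architecture, and
correlated P values — so green tests demonstrate correctness of the
analytical machinery on planted structure, not robustness to every
artefact of real ChIP-seq data.

# Numerical and design choices

* Height classes (`classifyPeakHeight()`) attach interval endpoints to
  the lower class (h ≤ 1.5 RPM is low for Smad2), since the published
  boundaries ("1.5 to 3") do not state endpoint ownership; the
  boundaries are configurable.
* Bins in distance histograms are right-open with the final edge closed;
  nearest-TSS ties break by lexicographic gene id (this affects profiles
  only, never assignment).
* DE membership uses P ≤ threshold inclusively; zero fold change belongs
  to neither direction.
* Chromosome name order is normalised alphabetically on construction so
  sorted outputs are stable across input orderings.
* The chi-square test's finite-sample calibration is verified empirically
  in the test suite: over 1000 simulated independent 2×2 tables the
  type-I error at P < 0.05 stays at the nominal level.

# Problem sizes used in tests

The test suite and acceptance script run at desk scale, sizes chosen so
each statistical property is comfortably identifiable: oracle-equivalence
checks use 20 random instances of 50–200 intervals; parameter-recovery
checks use 1000 peaks (sharing), 2000 genes (odds ratio) and 100–400
peaks (motifs) across 100 seeds; the full suite completes in a few
minutes on one CPU.

# Known limitations

Exact reproduction of published genome-scale counts additionally requires
the original supplementary peak tables, the Ensembl release used for
annotation, and the unstated overlap/window conventions of the original
scripts; the package exposes those conventions as parameters
(`minOverlap`, `window`, interval-vs-midpoint mode) precisely so such
sensitivity can be explored when those inputs are available. Motif hit
fractions depend on the relative-score threshold; only their ordering
across peak sets is threshold-stable. Transcript-level isoform structure,
alternative promoters and liftover between genome builds are out of
scope.
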