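# peakCobind

Integrative analysis of transcription-factor ChIP-seq co-occupancy,
binding-site motifs, cross-species target conservation, and association
with gene-expression responses.

## The scientific problem

Nodal signalling patterns mesoderm and endoderm in vertebrate embryos
through the transcription factor Smad2, which acts at *cis*-regulatory
elements together with partner factors such as the T-box factor
Eomesodermin (Eomesa) and Foxh1. Given genome-wide binding maps (ChIP-seq
peak sets) for two factors, a gene annotation, and differential-expression
tables from pathway perturbations, the recurring analytical questions are:

1. **Which genes does each factor bind?** A peak is assigned to a gene
   when it lies within ±10 kb of the gene's transcription start site
   (TSS) — *proximal binding*.
2. **Where do the two factors co-occur?** Peaks of factor A overlapping
   peaks of factor B (≥ *k* bp, default 1) are *shared*; at the gene level
   a gene is *common* when one of its proximal A-peaks overlaps one of its
   proximal B-peaks, *uncommon* when both factors bind the ±10 kb region
   at non-overlapping positions, and otherwise *A-only* / *B-only* /
   unbound.
3. **Do bound regions carry a partner factor's sequence motif?** Peak
   sequences are scanned on both strands with a JASPAR position frequency
   matrix (e.g. MA0479.1 for Foxh1) converted to a log-odds matrix

   `M[b,j] = log2( (n[b,j] + s·q[b]) / (N[j] + s) / q[b] )`

   with pseudocount *s* (default 0.8) and background *q* (default
   uniform); a window is a hit when its *relative score*
   `(raw − min) / (max − min)` reaches a threshold (default 0.80).
   Hit fractions are compared between peak sets by a Pearson chi-square
   test, and hit positions are tested for centrality within peaks against
   uniform re-randomisation.
4. **Is the regulatory network conserved?** Foreign-species bound gene
   sets are projected onto reference gene identifiers through Ensembl-style
   ortholog tables (one2one/one2many/many2many), then multi-way Venn
   partitions and per-gene conservation classes (number of other species
   with proximal binding) are computed.
5. **Is binding functional?** Responsive gene sets (P ≤ threshold, signed
   log2 fold change) are tested for association with binding classes by
   the Pearson chi-square on the 2×2 table (in/out class × in/out
   responsive), without continuity correction, reporting the statistic,
   P, focal-cell fold enrichment and odds ratio.

The package implements every step behind S4 classes (`PeakSet`,
`ProximalAssignment`, `PeakSharing`, `BindingClassMap`, `PFMotif`,
`ContingencyResult`, `ConservationTable`), plus a synthetic-data module
that generates coupled genome/annotation/peak/motif/ortholog/expression
fixtures with recorded ground truth, and a YAML-driven end-to-end
pipeline (`runPipeline()`, with a thin CLI in
`inst/scripts/peakcobind.R`).

## Worked example

Simulate a study — a genome with 100 genes, a Smad2-like peak set (60%
TSS-proximal), an Eomesa-like co-factor sharing 40% of those peaks, and an
expression table in which responsiveness is associated with common
binding at odds ratio 4 — then run the analysis:

```r
library(peakCobind)

sim    <- simulateGenomeAnnotation(nChroms = 2, chromLength = 3e6,
                                   nGenes = 100, seed = 7)
cl     <- c(chr1 = 3e6, chr2 = 3e6)
smad2  <- simulatePeaks(sim$genes, cl, nPeaks = 150, proximalFraction = 0.6,
                        factorName = "Smad2", seed = childSeed(7, "smad2"))
eomesa <- simulateCofactorPeaks(smad2$peaks, cl, sharedFraction = 0.4,
                                nExtra = 150, factorName = "Eomesa",
                                seed = childSeed(7, "eomesa"))

sharing <- sharePeaks(smad2$peaks, eomesa$peaks)
sharing
#> PeakSharing: Smad2 vs Eomesa (min overlap 1 bp)
#>  factor n_total n_shared n_only
#>   Smad2     150       69     81
#>  Eomesa     214       64    150

aA <- assignProximal(smad2$peaks,  sim$genes, window = 10000)
aB <- assignProximal(eomesa$peaks, sim$genes, window = 10000)
classes <- geneBindingClasses(aA, aB, sharing, names(sim$genes))
classes
#> BindingClassMap (A = Smad2, B = Eomesa)
#>
#>   A_only   common uncommon   B_only     none
#>       13       40       11       16       20

de <- simulateDETable(classes, baseRate = 0.15, oddsRatios = c(common = 4),
                      seed = childSeed(7, "expression"))
responsive <- union(responsiveSets(de$table, 0.05, "up"),
                    responsiveSets(de$table, 0.05, "down"))
bindingResponseAssociation(classes, responsive, names(sim$genes), "common")
#> ContingencyResult (binding-class association (focal = common))
#>            responsive not_responsive
#> common             13             27
#> not_common          6             54
#>   chi2 = 7.895 on 1 df, P = 0.00496
#>   fold enrichment = 1.71, odds ratio = 4.33
```

Reading the output: 69/150 (46%) of the Smad2-like peaks overlap an
Eomesa-like peak, close to the planted 40% (partner peaks can also graze a
neighbouring peak); 40 genes carry overlapping proximal peaks of both
factors (*common*); and responsive genes are significantly associated
with the common class, with the sample odds ratio 4.33 recovering the
planted odds ratio of 4.

The same analysis runs end to end from a YAML config over files on disk:

```r
runPipeline("config.yaml", "results/")      # writes TSVs + report.json
```

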