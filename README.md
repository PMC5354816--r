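# bivalency

Calling high-confidence bivalent chromatin regions from multi-cell-line
ChIP-seq peak sets and integrating them with DNA methylation and expression
data.

## The problem

In human embryonic stem cells (hESCs), many CpG-island (CGI) promoters carry
both the active H3K4me3 and the repressive H3K27me3 histone marks — the
*bivalent* signature that holds developmental genes poised. Bivalent CGIs are
the CpGs most prone to aberrant DNA hypermethylation in tumors, so a reliable,
genome-wide, coordinate-level list of bivalent / H3K4me3-only / H3K27me3-only
regions is a practical tool for cancer-epigenetics analyses built on Infinium
methylation arrays (HM450K / EPIC).

`bivalency` implements the full analysis as a tested, reusable R package for
epigenomics researchers:

- **Region calling.** Per cell line, a bivalent domain is a maximal interval
  where an H3K4me3 peak and an H3K27me3 peak overlap by ≥ 1 kb. Domains are
  union-merged across lines with per-line support counting; regions present in
  **all** lines form the high-confidence (HC) bivalent list. H3K4me3-only and
  H3K27me3-only lists are the cross-line per-base intersection of one mark's
  peaks (≥ 1 kb), with any region touching a bivalent domain of any line
  discarded. Sex chromosomes are excluded.
- **Annotation.** CGI / promoter (TSS ± 1 kb) / gene-body / intergenic
  classification, enhancer overlap, per-gene promoter chromatin signatures
  (genes with discordant multi-promoter signatures are flagged `mixed` and
  excluded downstream) and retroelement frequency profiles around the TSS
  (± 4 kb).
- **Occupancy clustering.** Each HC bivalent region (± 1 kb) is summarized by
  its EZH2, PolII, TAF1 and TCF12 signal (RPM); K-means (k = 3) on
  log-transformed, z-scored features partitions the regions into cluster 1
  (PolII/TAF1-high), cluster 2 (EZH2-high, PRC2-defined) and cluster 3
  (intermediate), with deterministic semantic labeling.
- **Expression integration.** log2 RPKM normalized per tissue to the median of
  H3K4me3-only genes; per-class and per-cluster medians and per-gene IQRs
  across tissues.
- **Methylation integration.** Probe → region mapping, β-value bands
  (0.1 / 0.3 / 0.7), moderated two-group t-statistics with empirical-Bayes
  variance shrinkage (s²ₘ = (d₀s₀² + d s²)/(d₀ + d)), Benjamini–Hochberg FDR,
  differential calls at |Δβ| > 0.25 and FDR < 0.05, CIMP-stratified analyses,
  hyper/hypo category distributions and ≥ 5-of-8-type pan-cancer recurrence.
- **Synthetic data.** A seeded generator with planted truth emulating every
  input (5-line peak sets with jitter and dropout, factor signal tracks with
  the 3-cluster structure, β matrices with hypermethylation planted
  preferentially at cluster-2 bivalent CGIs, tissue expression with poised
  switching) so the whole pipeline is testable offline.

## Worked example

```r
library(bivalency)

study <- simulateStudy(genomeSpec(seed = 1), jitterSd = 0, dropout = 0)
states <- callChromatinStates(study$peaks$k4, study$peaks$k27)
states
#> ChromatinStates consensus over 5 cell line(s): LINE1, LINE2, LINE3, LINE4, LINE5
#>   high-confidence regions: 547
#>     bivalent: 188
#>     K4only: 201
#>     K27only: 158
#>   merged bivalent regions (all support levels): 188

biv <- regions(states, "bivalent")
clusters <- clusterBivalentRegions(biv, study$tracks)
table(clusters$cluster)
#>   1   2   3
#>  33  43 112

arms <- stratifyCimp(study$methylomes$beta, study$methylomes$samples, "T01")
pm <- mapProbes(study$methylomes$manifest, states, clusters)
cd <- categoryDistribution(arms$positive, pm)
round(cd$hyper, 3)
#>     none bivalent   K4only  K27only
#>    0.411    0.589    0.000    0.000
round(cd$hyper_clusters, 3)
#> cluster1 cluster2 cluster3
#>    0.083    0.500    0.417
```

With zero jitter and dropout, the three HC lists equal the planted truth
base-for-base; the cluster table recovers the planted 17/22/61 proportions;
and hypermethylated probes in the first tumor type concentrate in bivalent
regions (59%), predominantly cluster 2 — the direction the method is designed
to quantify.

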