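---
title: "Calling bivalent chromatin regions and quantifying their tumor hypermethylation"
author: "bivalency authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling bivalent chromatin regions and quantifying their tumor hypermethylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalency)
```

# The model

Bivalent chromatin — the co-occurrence of the active H3K4me3 and repressive
H3K27me3 marks at a promoter/CGI — is called here from peak sets, not reads.
The package treats peak calling (MACS on aligned ChIP-seq) as upstream input
and implements everything from peak lists onward.

## Region calling

For one cell line with H3K4me3 peak set $P_4$ and H3K27me3 peak set $P_{27}$,
a *bivalent domain* is a maximal interval of $P_4 \cap P_{27}$ of width
$\ge$ 1000 bp. The domain is the overlap itself, not the union of the two
parent peaks: this guarantees that both marks cover every reported base. The
1 kb floor is inclusive — an overlap of exactly 1000 bp qualifies.

Across $L$ cell lines, per-line domains are union-merged into maximal
connected regions; each merged region records every line contributing at
least one overlapping base. Regions supported by all $L$ lines are the
*high-confidence* (HC) bivalent list. This merge-then-count scheme is the
only one consistent with reporting a single merged list together with
per-line membership; union coordinates are the most inclusive deterministic
choice. The alternative (an all-lines base-wise intersection) is available by
treating the consensus as an exclusive-region call.

Single-mark lists (H3K4me3-only, H3K27me3-only) are the per-base intersection
of one mark's peaks over **all** lines, width-filtered at $\ge$ 1 kb, after
which any candidate overlapping a bivalent domain of *any* line — by even a
single base — is discarded entirely (not trimmed). Because the wording of the
size rule alternates between "at least" and "more than" 1 kb in the source
material for this type of analysis, both the overlap rule and the size rule
are implemented as $\ge$ 1000 bp for consistency; both are parameters
(`minOverlap`, `minWidth`). Sex chromosomes are excluded because hESC lines
derive from embryos of both sexes.

Coordinates: the internal container is `GRanges` (1-based closed, the
Bioconductor convention). All BED-family files, and the `bedRanges()` /
`asBed()` helpers, use 0-based half-open coordinates and convert at the
boundary; array-manifest positions are 1-based on disk and converted on read.
Strand is ignored in all region algebra (peaks are unstranded); book-ended
intervals merge during normalization.

## Annotation

Promoters are TSS ± 1 kb (`promoterFlank`), one per transcript, clipped at
the chromosome start. Annotation flags use any-overlap ($\ge$ 1 bp;
`minBp` exposes a stricter alternative). The mutually exclusive feature class
uses the precedence CGI/promoter > promoter > gene body > intergenic, chosen
so the per-category breakdown is a partition; the tie-break is not dictated
by the biology and is therefore documented rather than configurable.
Enhancer overlap is recorded independently because it is only read on the
non-promoter subset. A region overlapping promoters of several genes is
attached to all of them; a gene whose marked promoters disagree in category
is classed `mixed` and excluded from expression summaries and exported gene
lists. Retroelement profiles count, per 100-bp bin within TSS ± 4 kb, the
fraction of TSS whose bin overlaps a repeat of a class (LINE/SINE/LTR by
default); minus-strand bins are the point reflection around the TSS, so
flipping every strand reverses the profile exactly.

## Occupancy clusters

Each HC bivalent region, extended by 1 kb on each side, is summarized by the
total RPM signal of EZH2, PolII, TAF1 and TCF12 (sum by default; mean is an
option). K-means with $k = 3$ runs on $\log_2(\text{RPM}+1)$, per-factor
z-scored features: raw RPM would let the strongest factor dominate the
Euclidean metric, and the transform is configurable for sensitivity
analyses. Lloyd iterations, 50 random starts, fixed seed 1729 by default.
Cluster labels are then made semantic and stable: the cluster with the
highest mean PolII + TAF1 is **1**, the highest mean EZH2 among the remaining
two is **2**, the rest is **3**; ties break by cluster size, descending.

## Expression

Summaries are on $\log_2(\text{RPKM} + 0.1)$. The 0.1 pseudocount keeps
silent genes near $-3.3$ on the log scale, matching the dynamic range a
$-6..+6$ display implies; zero handling is otherwise unspecified upstream, so
the pseudocount is a package choice and a parameter. Normalization subtracts,
per tissue, the median of the H3K4me3-only-class genes — a reference chosen
because that class is expressed stably across tissues — making the per-tissue
K4only median exactly 0 by construction. IQRs use type-7 (linear
interpolation) quantiles; the rule is declared because IQR values depend
on it.

## Differential methylation

Analyses run on β values directly (not M-values) because every threshold in
this analysis — the 0.1/0.3/0.7 bands and the Δβ > 0.25 effect filter — is
on the β scale. The test is an unpaired two-group comparison of tumor versus
matched-normal columns; pairing information is carried in the sample sheet
and the unpaired design is the default because the upstream description
specifies only a limma-style moderated test. Per probe,

$$ t_g = \frac{\bar\beta_{g,T} - \bar\beta_{g,N}}
           {\sqrt{s^2_{g,\mathrm{mod}} (1/n_T + 1/n_N)}},\qquad
   s^2_{g,\mathrm{mod}} = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, $$

with $(d_0, s_0^2)$ estimated by method of moments on the log sample
variances (digamma/trigamma inversion by Newton iteration, tolerance
$10^{-8}$, at most 100 steps) and $p$ from a $t$ distribution on $d_0 + d$
degrees of freedom. Two degenerate branches matter:

- when all sample variances are exactly equal, $d_0 = \infty$ and $s_0^2$ is
  their common value, so the moderated t *equals* the ordinary t — the
  natural fixed point of shrinkage;
- when the spread of log variances does not exceed what equal true variances
  imply, $d_0 = \infty$ with the bias-corrected location estimate
  $s_0^2 = \exp(\bar e)$; an uncorrected geometric mean would deflate
  $s_0^2$ by $\exp(\psi(d/2) - \log(d/2))$ and visibly skew null p-values at
  array scale.

Setting $d_0 = 0$ recovers the ordinary t exactly; estimation failure falls
back to it with a warning. The test suite checks the estimator against
`limma::eBayes` as an independent reference.

Calls: hyper iff $\Delta\beta > 0.25$ and BH-FDR $< 0.05$; hypo iff
$\Delta\beta < -0.25$ at the same FDR. The printed hypomethylation rule in
the source material ("delta β < 0.25") is read as a sign typo for
$< -0.25$; the threshold is configurable. Probes need at least two
non-missing values per group to be tested. CIMP stratification runs the
positive and negative tumor arms independently, each against its own matched
normals; tumors with unknown CIMP status are excluded from arms. β bands use
closed mid-interval boundaries: exactly 0.3 or 0.7 is intermediate, so the
four bands partition the non-missing probes.

Recurrence: probes hyper in $\ge$ 5 of the 8 per-type analyses (per arm) are
pan-cancer recurrent; the promoter regions containing them identify the
recurrently affected genes.

# The synthetic study

The generator plants truth and emulates the statistical structure the
analysis assumes, at a scale that runs in seconds on one CPU (the methods
vignette and tests use 5 autosomes × 10 Mb plus a 5-Mb chrX, ~600 planted
regions over ~800 genes, ~20 000 probes, 8 tumor types × 20 pairs, 34
tissues):

- **Peak sets** (5 lines): each planted bivalent region emits an H3K4me3 peak
  overhanging its start side and an H3K27me3 peak overhanging its end side,
  so the per-line overlap is exactly the planted region at zero jitter;
  boundary jitter is Gaussian (default SD 50 bp, a realistic peak-boundary
  uncertainty) and dropout (default 5%) removes a region's peak pair from a
  line, creating line-specific regions.
- **Tracks**: Gaussian bumps per factor with cluster-dependent amplitudes
  (cluster 1 PolII/TAF1-high, cluster 2 EZH2-high with moderate TCF12,
  cluster 3 intermediate), per-region lognormal amplitude variation and
  Poisson background; cluster proportions default to 17/22/61%.
- **Methylomes**: CGI/promoter probes unmethylated in normals (β ≈ 0.05),
  H3K27me3-only and gene-body/background probes methylated; per-type hyper
  sets (Δβ = 0.4) drawn with weights favoring cluster-2 bivalent CGI probes
  relative to pool size, a shared set planted in every tumor of a type plus
  disjoint CIMP-positive (large) and CIMP-negative (small) extras, a designed
  pan-cancer core recurring in 6 types, and a small hypo set in methylated
  none-probes. β noise is truncated normal (clamped to [0, 1]) for
  simplicity. Because candidate pools are finite and re-used across types,
  the realized recurrent sets (per arm, ≥ 5 types) are recorded alongside the
  designed core, and tests compare against the realized sets.
- **Expression**: lognormal RPKM; K4only genes high everywhere, K27only
  silent, bivalent genes switching on/off per tissue with activity
  probability 0.8/0.15/0.5 for clusters 1/2/3.

What the generator does **not** emulate: genomic sequence content, read-level
noise, peak-caller artifacts, copy-number or purity effects in tumors,
correlated probes within a CGI, or batch structure. Passing tests therefore
demonstrate the correctness of the algorithms under their stated assumptions,
not robustness to every artifact of real data.

# Validation design

Every interval operation is checked bit-for-bit against base-wise boolean
array oracles (AND/OR/AND-NOT plus run extraction) on random instances;
domain recovery is exact on noise-free synthetic data and follows the
binomial law $({1-p_\text{drop}})^5$ under dropout; clustering must reach
ARI ≥ 0.95 with correct semantic labels at the planted separation; the
moderated test must be uniform under a global null, reach sensitivity ≥ 0.95
at empirical FDR ≤ 0.10 on planted effects, and agree with `limma`; BH
q-values match the literal step-up definition; and the whole pipeline is
byte-reproducible under a fixed config and seed.

# Known limitations

- The consensus is deterministic but convention-dependent: HC bivalent
  coordinates are unions of supporting per-line domains; a different
  convention (intersection, or one reference line) shifts boundaries by the
  jitter scale.
- K-means determinism under input permutation holds when the best-of-starts
  optimum is stable (well-separated data); near-degenerate configurations
  can relabel.
- The unpaired design ignores pairing information; with strong
  patient effects a paired design would gain power.
- Probe → region mapping uses the probe's single CpG position; probes on
  region boundaries are assigned by the half-open convention.

# Session

```{r}
sessionInfo()
```
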