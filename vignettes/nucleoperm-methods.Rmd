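---
title: "Permutation co-location analysis of retained sperm nucleosomes"
author: "nucleoperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation co-location analysis of retained sperm nucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(nucleoperm)
  library(GenomicRanges)
})
```

# Background

During spermiogenesis most histones are replaced by protamines; the small
fraction of nucleosomes that escape the exchange remains at specific
genomic positions, and whether those positions are random or programmatic
is a central question in sperm chromatin biology. MNase-seq of sperm
produces two protected-fragment populations: a mono-nucleosomal (MN)
fraction around 147 bp, the DNA wrapped around an intact histone octamer,
and a sub-nucleosomal (SN) fraction below ~110 bp, thought to represent
partially unwrapped or sub-octamer particles. `nucleoperm` implements the
statistical scaffolding of such a study downstream of peak calling:
fragment-length separation of the two fractions, annotation of peaks
against gene features, and the permutation machinery that decides whether
peaks co-locate with a feature set more (or less) often than random
placement would produce.

# The permutation co-location model

For a query region set $Q$ (peaks) and a subject set $S$ (a feature
class), the observed statistic is the number of query intervals sharing at
least one base with any subject interval,
$T = \#\{q \in Q : \exists s \in S,\ q \cap s \neq \emptyset\}$.
The null distribution is generated by $B$ width-preserving
randomisations: every interval keeps its width and is replaced uniformly
at random within a chromosome, the chromosome being drawn with probability
proportional to its length among those the interval fits on. Writing
$T_1, \dots, T_B$ for the randomised statistics and
$\bar{T}$ for their mean,

* the empirical two-sided p-value is
  $p = \frac{1}{B}\#\{b : |T_b - \bar T| \ge |T - \bar T|\}$,
* the fold change is $\mathrm{FC} = T / \bar T$, and
* a comparison is called *enriched* when $p < 0.001$ and
  $\mathrm{FC} \ge 1.5$, *depleted* when $p < 0.001$ and
  $\mathrm{FC} \le 0.66$, and *none* otherwise.

Counting deviations with $\ge$ (ties included) is the conservative
convention; a p-value of 0 only means the observed count fell beyond every
randomisation and is reported as `<1/B`. The summary table also carries
the minimum, maximum, mean and an "SE" column for the permutation counts;
the SE column is the standard deviation of the counts, which matches the
magnitude such tables conventionally print, and `permSummary(x, sd =
FALSE)` switches to the standard error of the mean.

Two numerical choices deserve a note:

* **Overlap counting unit.** Each query interval counts at most once, no
  matter how many subject intervals it touches. This keeps counts bounded
  by $|Q|$ and makes fold changes insensitive to fragmented subject
  annotations; `countOverlapping(..., mode = "pairs")` provides the
  per-pair alternative.
* **Calibration versus reporting.** Because overlap counts are discrete,
  the tie-inclusive estimator is stochastically *larger* than uniform
  under the null — deliberately conservative. Uniformity checks therefore
  use the tie-symmetric mid-p counterpart
  (`computeEmpiricalP(..., estimator = "mid")`), which counts ties with
  weight 1/2 and is the estimator's unbiased version; reported p-values
  stay with the plain conservative rule.

Reproducibility is handled with one root seed from which every
permutation derives an independent sub-seed, so results do not depend on
execution order, and `withSeed()` guarantees the caller's RNG state is
never clobbered.

# Fragment partitioning

Paired-end template length separates the fractions: fragments up to
110 bp are SN, fragments of 111–1000 bp are MN, and everything else is
discarded. The bounds are exposed because they are protocol conventions,
not constants of nature. Replicate agreement is assessed as the Pearson
correlation of binned coverage tracks, with options to drop bins that are
zero in both replicates and to remove extreme pile-up bins via a robust
median + k·MAD rule (default k = 200, so only gross artefacts are
touched); the outlier rule is our choice, since plotting-tool references
in the literature leave it unspecified.

# Feature annotation

A gene-feature catalog derives, per gene: a 1-bp TSS site (optionally
expanded), a strand-aware promoter of 2,000 bp immediately upstream of
(and excluding) the TSS base, the 5′/3′ UTR and CDS blocks, and introns as
span minus exons; everything else is intergenic. The 2-kb promoter is the
common convention and is configurable because absolute feature counts
depend on it. When a peak overlaps several features it takes the
highest-priority class, `TSS > PROMOTER > UTR5 > UTR3 > CDS > INTRON`,
chosen so that rare, specific features are not absorbed by the broad ones;
the order is configurable. The co-location tests, by contrast, test each
feature class as its own subject set, so one peak may legitimately
contribute to several rows of the summary table.

The TSS-centred signal matrix counts fragments in fixed-width bins across
`[tss - flank, tss + flank)`; on the minus strand the window is
`[tss - flank + 1, tss + flank]` and columns are reversed, which makes the
TSS base land in the same column on both strands (the strand-symmetry
property the tests assert).

# RNA integration and gene-set overlap

Gene-level FPKM values are binned into absent `[0,1)`, low `[1,10)`,
intermediate `[10,100)` and high `[100,∞)` classes. A gene co-locates
with a fraction when its span lies strictly less than 5 kb from the
nearest peak (distance from the whole gene span, not the TSS, matching the
closest-gene convention; "below 5 kb" is read as a strict inequality).
Each expressed class is compared against the absent class with the
two-tailed Fisher exact test on the near/far 2×2 table, and abundance
distributions are compared with the Kruskal–Wallis test on
`log2(FPKM + 1)` — the pseudo-count matters only for display summaries,
as the rank-based test is invariant to any common monotone transform.

Cross-species gene-set overlap uses the upper-tail hypergeometric
distribution. The gene universe $N$ is a required argument: overlap
p-values are meaningless without stating the universe, so the package
never defaults it silently.

# The synthetic-data generator

Every statistical claim the package makes is checked against data with
known ground truth, generated at desk scale:

* **Genome and genes** — 10 Mbp over four chromosomes, 500
  non-overlapping genes with log-normal spans, 1 + Poisson exons, CDS
  flanked by UTRs, balanced strands.
* **Peaks** — widths log-normal with means ~270 bp (MN) and ~141 bp (SN),
  matching the width scale of sperm MNase-seq peak sets; 2,000 MN and 300
  SN peaks by default.
* **Planted enrichment** — `plantPeaks()` rejection-samples uniform
  proposals so that the rate of peaks classifying into class $c$ is
  exactly $\rho(c)$ times the uniform rate, with the background class
  absorbing the complement. Rejection sampling (rather than mixture
  placement) was chosen precisely so that the planted $\rho$ is the
  quantity a permutation fold change estimates. Uniform class rates are
  estimated once from 20,000 calibration placements. Infeasible targets
  (class rates summing past 1) are rejected with an error.
* **Abundance** — log-normal FPKM (normal on the log2 scale, mean −0.5,
  SD 4, which populates the four classes at roughly 55/26/16/3%, the
  proportions a sperm transcriptome shows); genes within 5 kb of a peak
  get a +β log2 shift (default 1), so β = 0 is the null of the Fisher
  tests.
* **Fragments** — template lengths from a two-component normal mixture,
  147 ± 10 bp (MN) and 95 ± 10 bp (SN) with 90% MN weight (the
  read-count ratio such libraries show); each fragment's true component
  is recorded, so partition agreement is scored exactly. At this
  separation the expected misclassification across the 110/111 boundary
  is below 1%.

In recovery experiments the planted class is tested as its own subject
through a single-class catalog, so the planted ρ and the estimated FC
coincide by construction; in the multi-class end-to-end scenario the
repeat-like features are placed in intergenic space (as interspersed
repeats largely are), because a depleted class spatially entangled with a
strongly enriched one would have its signal diluted by cross-overlap —
a property of the genome geometry, not of the test.

What the generator does *not* emulate: sequence content (no GC or
mappability structure), peak-calling noise, overdispersed coverage, or
correlated placement of features. Passing tests therefore demonstrate
the correctness and calibration of the statistical machinery, not the
biological conclusions one would draw from any particular dataset.

# Problem sizes and test design

The suite runs the calibration and recovery experiments at deliberately
modest sizes — 200 null trials at 200 permutations, 20 recovery runs per
planted ρ at 4,000 peaks, exhaustive small-table oracles (every 2×2
symmetry orbit with total ≤ 60, every hypergeometric configuration with
N ≤ 60) — sizes chosen so the whole suite completes in minutes on one
CPU while keeping Monte-Carlo error well inside the asserted bounds.
Published-scale quantities that require raw sequencing data (the 25,293
MN / 4,239 SN peak counts, genome coverage fractions, the replicate
correlation of 0.87) are out of scope by design; what the package
reproduces from the published tables is their *arithmetic* — fold
changes from observed counts and permutation means, and Fisher exact
p-values from the printed 2×2 counts.

# Known limitations

* The shuffle null is uniform: no GC-, gap- or mappability-aware
  randomisation, no exclusion of assembly gaps unless an explicit
  `exclude` set is supplied.
* Gene annotation input is deliberately simple (one record per gene, no
  isoform resolution); transcript-level catalogs must be collapsed
  upstream.
* Chromosome name matching is exact; no "chr" prefix normalisation is
  attempted.
* One of the published Fisher p-values (the SN intermediate-abundance
  row) is not reproducible from its own printed 2×2 counts by an exact
  two-sided test (two independent implementations agree to machine
  precision on a different value), so agreement with that printed number
  cannot be achieved by a correct implementation.

# A worked example

```{r example, eval = FALSE}
library(nucleoperm)

sc <- simulateScenario(simulationConfig(rho = c(PROMOTER = 3)), seed = 1)
res <- runFullAnalysis(sc$genome, sc$genes, sc$mnPeaks, sc$snPeaks,
                       abundance = sc$abundance,
                       fragments = sc$fragments,
                       outdir = tempfile("run"), nPerms = 200, seed = 1)
subset(res$enrichment, Feature == "PROMOTER")
```

The promoter rows of `res$enrichment` show the observed overlap count,
the permutation summary, the empirical p (0, i.e. below 1/200) and a fold
change near the planted 3, labelled `enriched`.
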