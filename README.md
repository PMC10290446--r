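# nucleoperm

Permutation co-location analysis of retained nucleosomes in sperm
MNase-seq data.

Mature spermatozoa replace most histones with protamines; the nucleosomes
that escape this exchange are retained at particular genomic positions,
and whether those positions track functional elements — promoters, TSSs,
UTRs, sperm-expressed RNAs, repeat families, trait-associated regions —
is the question this package quantifies. It implements the analysis layer
of a sperm MNase-seq study downstream of alignment and peak calling, for
researchers in reproductive genomics and chromatin biology.

## What it computes

**Fragment partitioning.** Paired-end template length separates the
sub-nucleosomal fraction (SN, ≤ 110 bp, partially unwrapped particles)
from the mono-nucleosomal fraction (MN, 111–1000 bp, the ~147 bp octamer
footprint), with binned-coverage Pearson correlation for replicate QC.

**Peak annotation.** Each peak gets exactly one gene-feature class by
priority (TSS > promoter > 5′UTR > 3′UTR > CDS > intron > intergenic),
with a strand-aware 2-kb promoter window.

**Permutation co-location (the core).** For query peaks *Q* and a feature
set *S*, the observed statistic is the number of peaks overlapping *S* by
≥ 1 bp. The null is built from *B* width-preserving randomisations
(chromosome drawn ∝ length, placement uniform). With permutation counts
*T₁…T_B* and mean *T̄*:

    p  = #{b : |T_b − T̄| ≥ |T − T̄|} / B        (empirical, two-sided)
    FC = T / T̄
    enriched:  p < 0.001 and FC ≥ 1.5
    depleted:  p < 0.001 and FC ≤ 0.66

**RNA integration.** FPKM classes (absent < 1 ≤ low < 10 ≤ intermediate
< 100 ≤ high), a strict < 5 kb gene-to-peak proximity rule, two-tailed
Fisher exact tests of each expressed class against the absent class, and
Kruskal–Wallis on log2(FPKM + 1).

**Gene-set overlap.** Upper-tail hypergeometric test of ortholog-mapped,
peak-adjacent gene sets against a reference list, with an explicit,
never-defaulted gene universe.

**Synthetic data.** A generator for genomes, gene models, peak sets with
*planted* per-class enrichment multipliers ρ (rejection-sampled so ρ is
exactly what the permutation FC estimates), abundance tables with a
tunable abundance–proximity coupling, and two-component fragment-length
mixtures with recorded ground truth.

## Worked example

```r
library(nucleoperm)

sc  <- simulateScenario(simulationConfig(rho = c(PROMOTER = 3)), seed = 1)
r   <- permutationTest(sc$mnPeaks,
                       featureRegions(sc$catalog)$PROMOTER,
                       sc$genome, nPerms = 200, seed = 1,
                       queryLabel = "MN", subjectLabel = "PROMOTER")
r
#> EnrichmentResult: MN vs PROMOTER
#>   observed 591 | perm min 178 max 251 mean 218.24 SE 14.63 (n=200)
#>   P <0.005  FC 2.71  -> enriched
```

591 of 2,000 peaks hit a promoter against a permutation mean of 218.24,
an FC of 2.71 with an empirical p below the 1/200 resolution, called
`enriched`. (The recovered FC sits slightly below the planted 3× because
peaks classified as TSS also overlap promoters; the methods vignette
discusses this geometry effect.)
`runFullAnalysis()` runs every stage and writes the co-location report
(one row per fraction × feature with Real/Min/Max/Mean/SE/P/FC/Label),
class proportions, the RNA co-location table, an abundance summary and a
TSS-centred signal matrix, all seeded and byte-reproducible.

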