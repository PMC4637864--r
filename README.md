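# ccqtl

QTL mapping and cross-trait pleiotropy analysis for multiparental
recombinant inbred (RI) mouse panels such as the Collaborative Cross (CC).

## The scientific problem

In a panel of RI strains, every strain's genome is a fixed, fully
homozygous mosaic of the eight founder haplotypes. Phenotyping replicate
animals of each strain lets modest panels dissect complex traits: every
biallelic marker partitions the strains into two allele groups, and a
quantitative trait locus (QTL) shows up as a difference between those
groups. When two traits — here body weight (g) and rotarod speed at fall
(rpm), a motor-coordination phenotype — are measured on the same animals,
overlap between their QTL and the relative sign of the allele effects asks
whether the traits share genetic control, and in which direction.

`ccqtl` implements that full chain, with a first-class simulator so every
stage is testable without any external data:

1. **Simulation** — founder mosaics (Poisson breakpoints, uniform
   no-self-transition founder Markov chain), a marker map with founder
   strain-distribution patterns (SDPs) that persist spatially the way
   array SNPs tag shared variants, genotype projection, and a two-trait
   phenotype model with planted loci, a shared set of opposite-sign
   pleiotropic loci, sex effects, strain and animal noise, and rotarod
   trial averaging.
2. **Association scan** — per marker, least squares of the trait on the
   allele code with sex as an additive covariate (a
   logistic-on-dichotomized-trait mode is also provided):
   `y = b0 + b1*allele + b2*sex + e`, two-sided test of `b1`;
   Benjamini–Hochberg FDR across markers; classification as significant
   (`-log10 p > 20` and `-log10 q > 18` by default) or suggestive
   (`10 <= -log10 p` and `8 <= -log10 q`).
3. **QTL calling** — a locus is a maximal cluster of >= 3 significant
   markers (up to 2 interior non-significant markers allowed), bounded by
   the nearest flanking non-significant markers; suggestive loci for one
   trait are called only inside the other trait's significant regions.
4. **Cross-trait analysis** — strain/sex summaries, cross-sex Pearson and
   between-trait Spearman correlations, interval overlap of the two
   traits' loci with both a binned hypergeometric and an
   interval-permutation null, and effect-direction concordance at each
   shared peak.
5. **Enrichment** — genes assigned to loci by partial interval overlap
   (BED/GFF3 input), hypergeometric overlap with an external gene list
   (e.g. human GWAS hits), case-insensitive with optional ortholog
   mapping.

## Worked example

```r
library(ccqtl)
res <- run_pipeline(demo_config(), out_dir = "demo_out")
res$summary
#> <strain_summary> 60 strains
#> cross-sex Pearson (strain means): weight_g = 0.913, rotarod_rpm = 0.907
#> between-trait Spearman (animals): F = -0.586, M = -0.659
res$overlap
#> <overlap_result> 1 of 1 A loci intersect 1 B loci
#> hypergeometric p = 0.002 (universe N = 499 bins of 5e+06 bp)
#> permutation p = 0.048 (n_perm = 1000)
#> directions: weight_g_significant_01~rotarod_rpm_significant_01:discordant
```

The demo simulates 60 RI strains (4 mice per strain per sex) under the
default architecture: two pleiotropic loci whose alleles raise body weight
while lowering rotarod speed, plus weaker trait-specific loci. The printed
output shows what the method is built to detect: strain means of the two
traits are strongly rank-anticorrelated within each sex, the two traits'
significant loci overlap (here one overlapping pair on chr1, peak
`-log10 p` 71.2 for weight and 53.7 for rotarod), and the shared peak is
*discordant* — the allele that adds ~4.1 g of body weight costs ~6.7 rpm of
rotarod performance. `demo_out/` holds every artifact as plain text
(genotype CSV, marker-map/phenotype/scan/locus TSVs, BED intervals,
overlap and enrichment reports, a run manifest), each re-readable by the
package's own readers.

A note on scale: with replicate animals carrying identical strain
genotypes, an animal-level regression overstates evidence (`-log10 p` in
the tens) and, on small panels, produces strain-background ghost peaks.
This mirrors how such scans are usually run on CC cohorts; a conservative
`unit = "strain_mean"` mode is available, and the vignette quantifies the
trade-off.

A thin command-line front end with `run`, `simulate`, `scan`, `call`,
`overlap` and `enrich` subcommands is installed at
`inst/scripts/ccqtl`.

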