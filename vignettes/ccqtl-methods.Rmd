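---
title: "Methods: simulation and QTL analysis for recombinant inbred panels"
author: "ccqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and QTL analysis for recombinant inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccqtl)
```

`ccqtl` analyses two quantitative traits measured on a multiparental
recombinant inbred (RI) panel — the motivating system is the Collaborative
Cross (CC), where each strain is a fixed homozygous mosaic of eight founder
haplotypes — and ships a simulator that generates every input it consumes.
This vignette explains the generative model, the statistical procedures,
the tunable parameters and their defaults, the numerical choices, and what
the package's tests do and do not establish about real data.

## 1. The genome and genotype simulator

**Founder mosaics.** Each strain × chromosome is partitioned into segments
labelled by founder of origin (0–7). Breakpoint counts are Poisson with
rate `recomb_rate` per Mb (default 0.05/Mb, i.e. roughly 130 breakpoints
per 2.5 Gb genome, the order observed in finished CC strains); breakpoint
positions are uniform; founder labels follow a uniform Markov chain
constrained to change at every breakpoint. This is deliberately *not* a
pedigree simulation of the CC funnel: downstream stages need realistic
linkage-block structure and eight-way allele patterns, not pedigree
fidelity, and the simple point-process model has two parameters instead of
a breeding design.

**Markers.** Markers are placed uniformly at `marker_density` per Mb
(default 2/Mb ≈ 5,100 markers on the default mouse-sized 19-autosome
layout). Each marker carries a strain-distribution pattern (SDP): the
subset of founders carrying allele 1. SDPs persist along the chromosome —
each marker inherits its left neighbour's SDP with probability `sdp_share`
(default 0.9), with each founder bit flipped at rate `sdp_mut` (default
0.05), otherwise a fresh SDP is drawn uniformly among non-trivial subsets.
Persistence is essential, not cosmetic: on genotyping arrays many probes
tag the same ancestral variant, which is precisely why "several adjacent
significant SNPs" is a meaningful locus criterion. With fully independent
SDPs a causal variant would light up exactly one marker and no
multi-marker locus rule could ever fire.

**Genotypes.** `allele(strain, marker) = 1` iff the founder of the segment
containing the marker lies in the marker's SDP. Strains are fully
homozygous; a residual-heterozygosity rate exists (`het_rate`) but
defaults to 0 and emits missing codes when drawn. `filter_informative()`
drops markers whose minor allele is carried by fewer than a configurable
number of strains.

## 2. The two-trait phenotype model

For trait $t$ and animal $a$ of strain $s$:

$$y_{a} = \mu_t + s_t\,\mathrm{I}(\text{male}) + \sum_k \beta_{tk}\,
  g_{s k} + u_{st} + \varepsilon_{at},$$

with $u_{st} \sim N(0, \sigma_{u,t}^2)$ drawn once per strain per trait,
$\varepsilon \sim N(0, \sigma_{e,t}^2)$ per animal, and — for the trait
named in `averaged_trait` (rotarod) — the reported value is the mean of
$k$ trial draws, $k$ uniform on `trials_range` (default 3–5, mean ≈ 3.3,
matching common accelerating-rotarod protocols), each trial adding
$N(0, \sigma_{\text{trial}}^2)$ noise. Shared pleiotropic loci carry an
enforced opposite-sign constraint $(\beta_1 \beta_2 < 0)$. Planted
positions given in bp snap to the nearest marker (ties to the left). One
seed drives a run; sub-draws consume the stream in a documented order
(strain effects per trait, then animal noise per trait, then trials).

The default architecture plants two strong shared loci (heavier allele,
slower fall: +3.5 g / −5.5 rpm and +3.0 g / −5.0 rpm), two weak
weight-only and two weak rotarod-only loci, a +5 g male weight shift,
$\sigma_u = (0.5, 0.8)$ and $\sigma_e = (1.5, 2.5)$ for (weight, rotarod),
and trial SD 3 rpm. These values were chosen once so that (i) strain-mean
ranges (≈ ±5 g around 20 g; ≈ ±8 rpm around 18 rpm) and between-trait
Spearman correlations (≈ −0.4 to −0.65) sit in the range reported for real
CC cohorts, and (ii) the shared loci dominate the genetic variance (see
§5 on ghost peaks). The simulator supports only the shared-locus
(pleiotropy) mechanism for the weight–rotarod relationship; causal
mediation of one trait by the other is not modelled, and nothing in the
analysis chain could distinguish the two.

## 3. Association scan

The default model regresses trait values on the allele code with sex as an
additive covariate, at the level of individual animals; the allele
coefficient's two-sided t-test gives the p-value. The scan engine is exact
least squares, vectorised across markers via the Frisch–Waugh
decomposition (covariates are projected out of the trait and of every
allele column; per-marker slopes, residual sums of squares and t-statistics
follow from column sums); markers with missing calls are refit exactly on
complete cases. Tests cross-check the engine against per-marker `lm()`.
Monomorphic markers and zero-variance traits yield `p = 1` with a flag
rather than an error so scans stream. Underflowing p-values are floored at
the smallest positive double (~4.9e-324) before logs; the floor is recorded
in the result attributes. Benjamini–Hochberg q-values (`stats::p.adjust`)
are computed across all tested markers of a trait.

Classification uses two simultaneous conditions — significant when
$-\log_{10} p > 20$ and $-\log_{10} q > 18$; suggestive when not
significant but $-\log_{10} p \ge 10$ and $-\log_{10} q \ge 8$. Those
default thresholds reproduce the convention used in animal-level CC scans;
they are only meaningful *because* of within-strain replication
(pseudo-replication), which multiplies nominal evidence roughly by the
per-strain replicate count. Three design alternatives are configurable:
`sex_handling` (`covariate` default, `pooled`, `per_sex`), `unit`
(`animal` default, `strain_mean` for the conservative one-point-per-strain
analysis), and `model` (`linear` default, plus `logistic_dichotomized`,
which dichotomizes the trait at its median and tests the allele in a
logistic model — provided because regressing continuous values by logistic
regression is sometimes reported in this literature even though it has no
defined likelihood for continuous traits; the linear model is the only
internally consistent reading and is the default).

## 4. QTL calling, overlap, and enrichment

**Calling.** A locus is a maximal cluster of significant markers allowing
at most `gap_tolerance` (default 2) consecutive non-significant markers
inside, with at least `min_run` (default 3) significant markers.
"Adjacent or closely clustered" is not a precise rule in the field; the
gap-tolerance family is the smallest one that distinguishes the two words,
and `gap_tolerance = 0` reduces to plain adjacency (tests prove
equivalence to a maximal-run scanner). Boundaries extend to the nearest
flanking non-significant marker, exclusive — by cluster maximality the
adjacent outside marker is always non-significant — truncated at
chromosome ends. Intervals are 0-based half-open internally; BED output
keeps that convention, report TSVs are 1-based closed. Peaks take the
maximum $-\log_{10} p$ with deterministic leftmost tie-breaking.
Suggestive loci for trait A are called, under the same run rule, only
among suggestive markers lying inside trait B's significant intervals.
Overlapping significant and suggestive loci of the same trait are kept as
separate class-labelled records rather than merged; no confidence
intervals are attached to boundaries (no LOD-drop rule is defined for this
scan).

**Cross-trait overlap.** Overlap counts the number of A loci intersecting
at least one B locus (loci, not pairs). Two null models are reported side
by side: a hypergeometric tail on a binned universe — $N$ = number of
disjoint bins of `bin_width` (default 5 Mb) tiling the genome, always
reported with the p-value, because any such test is meaningless without
its universe — and an interval-permutation null that re-places the A
intervals uniformly within their chromosomes (lengths preserved, no
self-overlap, rejection sampling) and uses the add-one estimator
$(1 + \#\{\text{perm} \ge \text{obs}\})/(n_{\text{perm}} + 1)$. The two
agree exactly in the limiting case of unit-width loci on an integer-length
chromosome (a test enforces this) and differ in general because real loci
have widths. Direction concordance evaluates the sign product of the two
traits' allele effects at the shared peak — the marker maximising
$\min(-\log_{10} p_1, -\log_{10} p_2)$ inside the intersection.

**Enrichment.** Genes are assigned to loci by interval intersection
(partial overlap suffices; GFF3 input is converted from 1-based closed to
the internal convention). The gene-list overlap test is an upper-tail
hypergeometric on unique case-folded symbols, with an optional explicit
ortholog map (no homology database is consulted). The universe defaults to
all genes in the supplied annotation and is always reported — overlap
p-values are not comparable across unstated universes.

## 5. Small panels, pseudo-replication, and ghost peaks

Two facts dominate the statistics of animal-level RI scans, and both are
reproduced (deliberately) by this package:

* **Inflation.** With $m$ replicate animals per strain, strain-level
  signals gain roughly a factor $m$ in $\chi^2$, which is how
  $-\log_{10} p$ values in the tens arise from a few hundred mice. The
  `strain_mean` unit removes the inflation and, at these panel sizes,
  cannot reach the conventional thresholds at all.
* **Ghost peaks.** Any strain-level variance component — the random
  strain effect $u$ *and the planted loci themselves* — chance-correlates
  with some of the genome's markers. With $n_s$ strains the maximal
  absolute correlation over thousands of effectively independent markers
  is roughly $0.4$–$0.6$ for $n_s \le 60$, so markers unlinked to any
  causal locus can reach $-\log_{10} p$ of 20–35 whenever the strain-level
  genetic variance is an appreciable fraction of the total. At 16 strains
  this regime produces dozens of callable loci; that is the honest
  statistical face of published CC scans reporting ~45 loci from 16
  strains, and the vignette's demo uses 60 strains precisely to keep the
  planted loci separable from this background.

These considerations fixed the bundled study designs, all chosen from the
power analysis before the corresponding checks were run:

* **Demo cohort** (`demo_config()`): 60 strains × 4 mice/sex, default
  architecture. Strong shared loci (≈1.3–1.8× the trait SD per allele)
  clear the 20/18 thresholds; the deliberately weak trait-specific loci
  do not compete, keeping the strain-level genetic fraction low enough
  that ghost peaks stay below threshold.
* **Recovery study** (acceptance script and tests): 5 planted loci with
  effects 3× the animal-level noise SD, split 3/2 across the two traits,
  60 strains × 10 mice, ~5,000 markers. Splitting matters: each planted
  locus sits in the residual of the others, so concentrating five 3σ loci
  on one trait would push the ghost background above any threshold that
  the planted loci can clear. Loci are planted at *tagged* markers
  (`tagged_markers()`): allele frequency in [0.35, 0.65], at least one
  well-correlated flanking marker on each side, and pairwise allele
  correlation ≤ 0.2 between planted loci. A power study conditions on
  detectable variants — an untagged or near-private variant measures
  array coverage, not the caller — and chance inter-locus correlation at
  60 strains otherwise biases effect estimates by up to ~25%. The scan
  thresholds for this study are design-calibrated to 25/22 (the
  replicated-animal null maximum sits near $-\log_{10} p \approx 30$ at
  this size; the default 20/18 convention belongs to the demo-scale
  design and is retained there).
* **Null calibration**: 30 strains × 8 mice, 2,000 independent-SDP
  markers, no strain-level variance ($\sigma_u = 0$, no loci). With any
  strain-level component the animal-level null p-values are *not*
  uniform (pseudo-replication), so calibration is only a property of the
  exchangeable-animal null; SDP persistence is likewise disabled because
  duplicated marker columns add dependence without information.

One calibration property deserves a caveat: within a single cohort the
per-marker null p-values are marginally uniform (the t-test is exact) but
*mutually dependent*, because every marker is tested against the same 30
realised strain means. The pooled one-sample Kolmogorov–Smirnov statistic
therefore exceeds its iid critical value far more often than its nominal
level even for a correct implementation (and the excess shrinks only
slowly with panel size). The package's uniformity checks that isolate the
regression engine — alleles drawn independently per animal — pass KS at
the 1% level essentially always; the cohort-level KS check is reported as
measured. Zero significant calls at the 20/18 thresholds under the null
is robust either way.

## 6. Numerical and interface choices

* Coordinates: 1-based bp in all tabular files and marker maps; 0-based
  half-open internally for intervals; BED stays 0-based, report TSVs are
  1-based; GFF3 is converted on input.
* Doubles are serialized with 17 significant digits, so every
  writer/reader pair round-trips bit-identically (property-tested on
  fuzzed instances).
* Determinism: every simulation entry point takes an explicit seed; the
  pipeline derives stage seeds as fixed offsets from the master seed and
  records them in the manifest, so identical configs give identical
  artifacts byte for byte.
* Degenerate inputs (monomorphic markers, constant traits, empty locus
  lists, single-sex strains) return flagged results or are excluded with
  a report, never silent errors, so genome-wide streams do not abort.
* Problem sizes in the test-suite and acceptance studies (60 × 10 cohort,
  25 seeds; 100 null cohorts; 10⁵ permutation draws) are the sizes at
  which the measured quantities stabilise relative to their Monte Carlo
  error.

## 7. What the tests show — and what they cannot

The simulator emulates linkage blocks, eight-way SDP structure, sex
effects, replicate noise and trial averaging, but not: the CC funnel
pedigree and its X-chromosome rules, real megaMUGA probe content,
genotyping error, non-normal trait distributions, or kinship beyond strain
identity (no mixed-model correction is implemented — by design, matching
the single-marker biallelic scan it studies). Passing tests therefore
establish that the pipeline recovers what its own generative model plants,
at realistic sizes, with calibrated error rates — not that any specific
biological finding in real cohorts is correct. The package also cannot
distinguish pleiotropy from tight linkage of distinct causal variants;
"discordant overlap" is an operational statement about peak effect signs,
not a mechanism.
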