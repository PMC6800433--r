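---
title: "Methods: ROH segmentation, tract dating, ancestry classification and the pedigree simulator"
author: "autozyg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH segmentation, tract dating, ancestry classification and the pedigree simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

This vignette documents the models behind `autozyg`, the parameters
that matter and their defaults, the numerical choices, what the
simulator does and does not emulate, and the package's known
limitations. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## Input representation

The unit of analysis is a per-individual diploid consensus genome:
named scaffolds over the 11-letter alphabet `ACGT` + `RYSWKM` (the six
two-base IUPAC codes, marking heterozygous sites) + `N` (masked or
failed sites). Only biallelic heterozygotes are representable by
design, so the three- and four-base codes (`V,H,D,B`) are rejected at
load time; soft-masked lowercase is uppercased, never masked — masking
is expressed exclusively through `N`. Intervals are held as `GRanges`
(1-based, closed) internally; the 0-based half-open convention of BED
and the 1-based positions of genotype tables are converted exactly
once, at the file boundary, because coordinate-dialect mixing is the
classic off-by-one source in this kind of pipeline.

## Windowed heterozygosity

`windowHet()` tiles each scaffold with non-overlapping windows
(default `windowSize = 100 kb`; the last window of a scaffold may be
short) and records per window the heterozygote count k and the
callable (non-N) count n. Non-overlapping windows keep the HMM's
observations conditionally independent; 100 kb puts roughly 100
windows on a 10 Mb tract, ample resolution for Mb-scale segmentation
while keeping per-window counts large enough (~100 het sites at
heterozygosity 1e-3) to separate the states sharply. Windows with
n/width < 0.2 (default `minCallableFrac`) are flagged `missing`:
masked deserts carry almost no information and would otherwise mimic
homozygosity. `genomeHet()` is the exact callable-weighted mean of the
window rates and is therefore invariant to the window size.

## The ROH HMM

Two hidden states per window — inbred (ROH) and outbred — with
emissions

k_t | state s ~ Poisson(lambda_s * n_t),

i.e. a het rate per *callable* bp scaled by the window's exposure n_t,
which makes variable masking harmless. Missing-flagged windows
contribute likelihood 1 in both states. The Poisson family is the
natural count model here; overdispersion from mutation-rate or mapping
heterogeneity is absorbed, imperfectly, by the transition prior (see
Limitations).

Fitting is plain Baum–Welch: forward–backward in log space, an
exposure-weighted M-step `lambda_s = sum(gamma_s k) / sum(gamma_s n)`,
transitions from the expected-count ratio, and a stop when the
relative log-likelihood improvement falls below `tol = 1e-6` or at
`maxIter = 100`. The log-likelihood trajectory is recorded on the
returned object and is non-decreasing (an EM property the tests
check). Initialisation: `lambdaOut` = the overall het rate, `lambdaIn`
= one tenth of it, transition matrix with diagonal 0.999 — tracts are
Mb-scale and windows 100 kb, so staying probabilities must be close
to 1. EM label switching is resolved by ordering states
`lambdaIn < lambdaOut` after convergence. If the data contain no
heterozygote at all the fit is degenerate (both rates 0) and flagged,
with a warning.

Decoding provides both the Viterbi path and forward–backward
posteriors. Viterbi ties are broken toward the outbred state, so ROH
calls are conservative — the cost of a missed window is preferred over
an inflated inbreeding estimate. `extractTracts()` merges consecutive
inbred windows (missing windows inside a run are bridged naturally,
because the Viterbi path assigns them the flanking state: their
emissions are flat and the transition prior dominates) and applies a
minimum length, default 2 Mb: tracts above this floor are callable
with high confidence, and the 2 Mb floor also matches the shortest
length class used in the dating summary.

## Dating tracts in generations

An autozygous tract is a stretch of an ancestral haplotype that
survived, unrecombined, the 2g meioses connecting the two copies
inherited by the focal individual (g up each of the two lineage
paths). Crossovers arrive along the loop at 2g · r/100 per Mb, so the
tract length is approximately exponential with mean L = 100/(2rg) Mb;
inverted, g = 100/(2rL). The default r = 1.1 cM/Mb is a felid
genome-wide average; change it per species with the `r` argument. The
summary histogram's default bin edges {2, 5.7, 9.1, 15.2, Inf} Mb are
the lengths implied by ancestors 8, 5 and 3 generations back at that
rate, above the 2 Mb call floor, so the histogram reads directly as an
inbreeding-age profile. Unrounded generation values are reported
alongside the bins.

## IBD-ROH sharing

`ibdFraction(a, b)` is the summed length of the interval intersection
of two individuals' ROH, divided by the analysed genome length (the
total length of the scaffolds included in the analysis, not a full
assembly). Overlap alone can pair two *different* ancestral
haplotypes, so when consensus genomes are supplied each overlap must
also agree at ≥ 95% (`identityThreshold`) of sites where both
individuals are homozygous for an unambiguous base. Overlaps shorter
than 1 Mb (`minOverlap`) are discarded as tract-end jitter: called
boundaries are only window-accurate. The matrix version puts each
individual's F_ROH on the diagonal, and every off-diagonal entry is
bounded by the smaller of the two diagonals by construction.

## Local ancestry of admixed genomes

Diagnostic sites are positions where every panel-A genome is
homozygous for one base and every panel-B genome homozygous for a
different base (any N or heterozygote disqualifies the site). The
three diploid ancestry states A/A, A/B ("MIXED") and B/B emit the
observed genotype class (hom-A / het / hom-B) with probability
1 − ε for the expected class and ε/2 for each other class; genotypes
matching none of the classes are treated as missing. ε defaults
to 0.01 — a genotyping/assignment error well above per-base sequencing
error because it also absorbs imperfectly fixed "diagnostic" sites
selected from finite panels.

Between adjacent sites separated by d bp, the chance of switching to a
specific other state is (1 − exp(−τ d))/3. τ is the per-bp ancestry
switch rate; with an admixture event G generations back, ancestry
junctions accumulate at ~G · r/100 per Mb per haplotype, so the
default τ = 8.8e-8 corresponds to G ≈ 8 at r = 1.1 — the scale of a
handful of generations since admixture. Parameters are fixed rather
than EM-fitted by default: three-state EM on sparse, noisy sites is
fragile, and the decoding is insensitive to τ within an order of
magnitude because the emission evidence per segment is strong.
Decoding is Viterbi; segment boundaries are placed at the midpoint
between adjacent sites decoded to different states, the first and last
segments extend to the scaffold ends, and scaffolds with no diagnostic
site are excluded from the analysed universe.

Each called ROH is labelled by the ancestry state covering the
majority of its length (exact ties → MIXED). Because autozygosity
means both haplotypes descend from one ancestral haplotype, a genuine
ROH carries a single ancestry; finding no MIXED-labelled ROH in an
admixed genome is the expected signature, and admixture actively
prevents the formation of ROH spanning ancestry boundaries.

## Mitochondrial clock

`pairwiseDivergence()` counts differing sites among positions where
both aligned sequences carry an unambiguous base; gaps, N and
ambiguity codes are excluded from numerator and denominator. Node ages
average `divergence / rate` over all cross-clade pairs, with the
spread reported as the across-pair standard deviation — the only
dispersion statistic the procedure supports. The default rate 0.0115
(1.15% per Myr) is treated as a *pairwise* divergence rate; if a
per-lineage calibration is intended, `perLineage = TRUE` halves the
ages. The ambiguity is real in published composite rates, so both
interpretations are exposed and the choice is explicit in the call.

## The pedigree simulator

Founder panels: a random uniform-base reference per scaffold;
within-population polymorphic sites placed as a Poisson process at
density 2θ per bp, each founder haplotype drawing an allele at
frequency 0.5 — so an outbred individual's expected heterozygosity is
exactly θ per bp (the tests verify the recovery); fixed
inter-population differences at density d_AB, population A carrying
the reference allele. Defaults θ = 1e-3 (a mammalian outbred-genome
scale) and d_AB = 1e-4 (one diagnostic site per 10 kb, dense enough
that ancestry tracts of a few Mb contain hundreds of sites). Both are
arguments, not constants.

Haplotypes are mosaics of founder haplotype copies. Meiosis draws
crossover breakpoints as a Poisson process at r/100 per Mb (no
interference — the same idealisation as the dating formula), the
gamete starting on a uniformly chosen parental haplotype. No new
mutations arise during propagation: at the tract scale and over tens
of generations, founder-derived variation dominates, and this
guarantees the invariant that focal heterozygous sites never fall
inside truth autozygous tracts. Ground truth needs no sequence at all:
autozygous tracts are the intervals where the two mosaics carry the
same founder copy, ancestry tracts map copies to founder populations,
and rendering bases is a separate, optional step — which is why
tract-length studies can run on multi-Gb scaffolds cheaply.

The `isolated_inbred` scenario uses a *funnel* pedigree: every
ancestral path from the focal individual to the top generation has
length exactly g, so every inbreeding loop spans 2g meioses and the
100/(2rg) law applies to all tracts. The top generation is a pool of
K founders shared between the maternal and paternal sides
(`poolSize`, default `min(2^(g-1), 8)`), giving an expected autozygous
genome fraction of 1/(2K) *independent of g* — this is what makes
deep-loop scenarios (g = 8) testable on desk-scale genomes, where a
single loop's 2^(1-2g) would be hopeless. When K equals the 2^(g-1)
ancestor slots per side no founder repeats within a side, all
intermediate individuals are outbred, and tract lengths are unbiased
exponential; with smaller pools (deep g) founder reuse makes some
intermediates autozygous, and crossovers inside their autozygous
regions can silently extend tracts — a mild upward length bias of
order 1/(2K) accepted in exchange for tract density. The
`admixed_inbred` scenario is the same funnel with one pool founder
from population B: the admixture event coincides with the loop depth
(default g = 7, the scale of an admixture event 6–9 generations back
followed by close inbreeding), and autozygous tracts can then be of
either pure ancestry but never mixed.

Two further design points. Tracts cut by a scaffold end are flagged
`truncated`; the exponential-mean law assumes unbounded chromosomes,
and *excluding* truncated tracts under-samples long tracts with a
downward bias of about E[L²]/T per scaffold of length T — the
acceptance computation therefore uses 2 Gb scaffolds (the limit of
32-bit interval coordinates), where the residual bias (~0.2 Mb
against a 15.15 Mb mean) is well inside sampling noise for 500
tracts. And reproducibility: each scenario runs under one explicitly
seeded RNG stream in a fixed execution order, so equal seeds give
byte-identical outputs; per-meiosis sub-streams are unnecessary in
this single-threaded implementation.

### What the simulator does not emulate

Coalescent depth (no deep demography, so no background relatedness:
unrelated simulated individuals share *no* IBD, which real
conspecifics always do), new mutations inside ROH, crossover
interference, gene conversion, sex chromosomes, variable recombination
maps, genotyping error, and reference/mapping artefacts in the N-mask.
Passing tests on these simulations therefore demonstrates correctness
of the segmentation, dating, sharing and classification machinery
under the stated generative model — not robustness to every real-data
pathology; the `minCallableFrac` masking guard and the ε emission
error are the knobs that absorb the latter in practice.

## Problem sizes used in the tests

Unit tests run on strings of a few hundred bp to a few Mb and HMM
tracks of ≤ 5,000 windows. The acceptance-level checks use: 500+
ground-truth tracts on 2 × 2 Gb scaffolds (truth only, no sequence);
ROH-calling quality on three replicates each of 8 × 25 Mb rendered
genomes for g = 3 and g = 8; ancestry decoding on two replicates of
6 × 25 Mb admixed genomes with 4-genome panels per population. These
sizes give stable bp-level statistics while keeping a full suite run
in a few minutes on one CPU.

## Numerical choices and degenerate inputs

All HMM arithmetic is in log space; per-scaffold chains restart from
the initial distribution. Transition and initial probabilities are
floored at 1e-12 during EM to avoid log(0) lock-in. `dpois` handles
rate-zero emissions exactly (likelihood 1 for k = 0, 0 otherwise).
Zero-callable windows have undefined rates and are flagged missing
rather than imputed. A genome with no heterozygotes yields a flagged
degenerate fit instead of an arbitrary segmentation; under a
degenerate (indistinguishable-state) model the conservative tie-break
decodes everything outbred. Empty call sets propagate as empty
`GRanges` through summaries (F_ROH 0) and sharing (fraction 0).

## Known limitations

* Poisson emissions understate real overdispersion; a
  negative-binomial emission would be the first upgrade for noisy
  resequencing data.
* Tract boundaries are window-quantised (±half a window per edge).
* The ancestry HMM assumes exactly two source populations and
  unphased input; it reports diploid ancestry state, not per-haplotype
  assignment.
* The IBD measure is interval overlap plus a homozygote-identity
  filter, not a phased IBD segment model; it cannot separate one
  shared haplotype from two.
* The dating formula gives the *expected* age for a tract length;
  individual tracts are exponentially dispersed, so per-tract dates
  should be read as order-of-magnitude, and summaries should pool many
  tracts.
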