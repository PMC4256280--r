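---
title: "Methods: population genomics of copy-number variation with cnvpop"
author: "cnvpop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics of copy-number variation with cnvpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpop)
```

# Overview

`cnvpop` analyses copy-number variation (CNV) across structured natural
populations: cohorts sampled along a geographic hierarchy of continents,
countries and populations, such as replicated parapatric lake–river ecotype
pairs of a fish species. The pipeline takes per-individual CNV calls from
several complementary callers plus a loci × samples read-depth matrix, and
produces a filtered consensus call set, cross-individual CNV regions,
integer copy-number genotypes, allele-frequency spectra, population
differentiation scans, geographic sharing classes, gene-loss calls, a
selection-coefficient estimate, and gene-category enrichment tests. A
synthetic-cohort simulator generates every input with recorded truth so the
entire pipeline is testable without any sequencing data.

All internal coordinates are 0-based half-open, as in BED; conversions to
the 1-based conventions of GFF3 and VCF happen only at I/O boundaries.
Overlap arithmetic is delegated to `GenomicRanges`/`IRanges`.

# Multi-caller consensus

CNV callers built on read depth, discordant read pairs and split reads have
complementary error profiles, so per-individual calls are integrated before
any population-level analysis:

1. **Within-caller merging.** Calls from the same individual, caller and SV
   type merge when their overlap exceeds 50% of the *shorter* call, applied
   to transitive closure with union spans. The shorter-call denominator is
   the most permissive reading of an overlap-fraction rule and makes the
   result idempotent and order-invariant.
2. **Cross-caller support.** Read-depth calls are retained only when a call
   of the same individual and type from another approach overlaps more
   than 50% of the *read-depth call's* length — the conservative choice of
   denominator for a filtering step.
3. **Filters**, in a fixed, logged order: minimum length (500 bp; shorter
   events are unreliable for depth genotyping), sex-chromosome removal
   (male hemizygosity mimics deletion), repeat-mask overlap (> 50% of the
   call inside the mask), and removal of call clusters present in *all*
   individuals (these reflect reference-genome alleles rather than
   polymorphism). Clusters are formed by reciprocal 50% overlap; every
   overlap comparison in the package is strict (`>`).
4. **Region delineation.** CNV regions are contiguous stretches encompassed
   by CNVs: unions of calls from all samples and both SV types sharing at
   least one base. Book-ended intervals stay separate
   (`reduce(min.gapwidth = 0)`), and each region records its carrier set
   and the SV types observed.

Individual-level sharing (used for the pairwise sharing matrix) requires
*reciprocal* 50% overlap of both calls, with greedy one-to-one matching by
decreasing overlap, ties to the leftmost pair.

# Read-depth genotyping

Mean read depth per locus is divided by the per-locus median across
individuals and multiplied by two, so the typical individual sits at the
diploid value 2; rounding half-away-from-zero gives integer copy-numbers.
The tie rule is documented rather than derived: 2.5 rounds to 3.

This normalization cancels locus-specific mappability and GC effects but
carries one structural assumption: **the median individual must be diploid
at the locus**. When the carrier fraction exceeds one half (allele
frequency above ≈ 0.29 under Hardy–Weinberg), the median shifts to a
carrier and every copy-number at that locus is mis-centered. This is an
inherent property of median normalization, not of this implementation; the
simulator (below) therefore keeps its frequency law inside the valid
regime, and results on real data should be interpreted with this caveat
for high-frequency loci.

A locus is **bi-allelic** when its copy-numbers are explainable by a
reference allele plus a single deletion allele (values ⊆ {0,1,2}, at least
one below 2) or a single duplication allele (⊆ {2,3,4}, at least one above
2). Genotype codes equal copy-numbers: 0 hom-deletion, 1 het-deletion, 2
wild type, 3 het-duplication, 4 hom-duplication. Copy-numbers above 4, or
deletion and duplication alleles at one locus, make the locus multi-allelic:
excluded from the frequency spectrum but retained for V~ST~, which uses
continuous normalized depth and handles multi-allelic variation naturally.

The unfolded site-frequency spectrum counts segregating bi-allelic loci by
non-reference allele count *i* = 1 … n−1 among n = 2N chromosomes,
polarized against the reference genome.

**Gene loss** is called for gene g in individual s when normalized gene
depth is below 0.25 (8-fold below diploid) *and* at least one individual
exceeds 2 at that gene — the guard prevents loss calls at genes whose
depth is regionally depressed in everyone by mapping bias.

# Population differentiation: V~ST~

For two populations with n~1~ and n~2~ individuals and per-individual
copy-number values (normalized depth by default; integer copy-number by
choice):

$$V_{ST} = \frac{V_T - \frac{n_1 V_1 + n_2 V_2}{n_1+n_2}}{V_T}$$

where V~T~ is the variance of the pooled values and V~k~ the
within-population variances. All variances use divisor *n* (population
variance); with size weighting this makes the total = within + between
decomposition exact, so V~ST~ coincides with 1 − SSW/SST of a one-way
ANOVA — the identity the test suite exploits as an independent oracle. The
statistic is reported *signed* by the direction of the mean difference,
with the river population listed first, so positive values mean higher
copy-number in the river. V~T~ = 0 (no variation at all) is defined as 0.
Scan thresholds use the empirical type-7 (linear interpolation) quantile of
|V~ST~|, by default the 99.9th percentile.

# Geographic sharing

A variant's carrier set maps to one of four mutually exclusive levels by
walking the manifest hierarchy: **Population** (one population),
**Country** (several populations, one country), **Continent** (several
countries, one continent), **Ancestral** (several continents). The
marine population has no parapatric partner and participates only through
this hierarchy, not in lake–river contrasts. Pairwise sharing between two
individuals is the Jaccard-style ratio matched/(|A| + |B| − matched) over
reciprocal-overlap matches, averaged within four relation groups (within
populations, between populations, between countries, between continents).
The two German sites are one country in the default design, so sharing
between them is classed `Country`.

# Selection on the frequency spectrum

Under the Poisson Random Field model for a stationary population with a
single shared scaled selection coefficient γ ("single point mass"), the
expected density of derived-allele frequency q is

$$g(q;\gamma) = \frac{1 - e^{-2\gamma(1-q)}}{(1 - e^{-2\gamma})\, q(1-q)},
\qquad g(q;0) = 1/q,$$

up to a constant absorbed by the mutation intensity θ. The expected
spectrum is p~i~ ∝ ∫ g(q;γ) C(n,i) q^i (1−q)^{n−i} dq, which reduces to
p~i~ ∝ 1/i at neutrality. **Convention:** γ here is the coefficient of the
2γ form above; under the alternative 4Ns convention fitted values differ by
a factor of two, which matters when comparing against other software.

Numerics: the integral is evaluated by Gauss–Legendre quadrature with node
doubling until the spectrum is stable to a relative 1e−8 componentwise
(`expm1` keeps the density stable through γ = 0, where it is continuous).
θ is profiled out by conditioning on the number of segregating sites, so
the fit maximizes a multinomial log-likelihood over a γ grid (default
[−20, 10] in steps of 0.1), refines the maximum by golden-section search
within the bracketing cell, and takes the 95% CI from the likelihood-ratio
bound 2Δℓ ≤ 3.84 with linear interpolation between grid points. A maximum
or CI end at the grid edge sets the `boundary` flag. Grid spectra are
cached per (n, grid), so repeated fits at the same sample size are cheap.

# Permutation enrichment

Observed statistic: the number of genes per orthology category covered
> 95% by the union of CNV regions (the same 5% breakpoint leeway used for
CNV-gene calls). Each permutation redraws, per chromosome and SV type, the
same number of intervals with exactly the same lengths at uniform starts;
placements may overlap each other and ignore the repeat mask by default
(the literal reading of count-and-length matching; a masked-placement
option exists). P-values use the add-one correction
p = (1 + #{permuted ≥ observed})/(n+1), so they are never zero. Because the
count statistic is discrete, these p-values are conservative
(super-uniform) rather than exactly uniform under the null — the acceptance
suite tests validity, not exact uniformity.

# The synthetic cohort

`simulate_cohort()` emulates the downstream products of a 66-genome
resequencing design — not reads or alignments. Defaults, chosen once as the
study conditions:

* **Design**: 11 populations (five lake–river pairs: G1, G2, No, Us, Ca,
  plus the marine Dk) × 6 individuals; Germany's two sites are one country;
  continents are Atlantic and Pacific.
* **Loci**: 400 CNV loci, 82% deletions (the deletion:duplication ratio of
  multi-caller call sets), non-overlapping on a 25 kb slot grid over four
  10 Mb autosomes plus a sex chromosome, lengths log-normal around 6 kb.
* **Frequency law**: 70% of loci uniform below 0.05 (the low-frequency skew
  of CNV spectra), the rest uniform on (0.05, 0.20). Population frequencies
  derive from the overall frequency through a three-level beta cascade
  (continent → country → population, concentration 12 per level), giving
  geographically correlated drift, and are bounded at 0.2 so every locus
  stays inside the median-normalization regime discussed above. Five
  divergent loci get frequencies 0.9 vs 0.1 between the G1 pair.
* **Depth**: genotypes are Hardy–Weinberg draws; depth is Normal with mean
  μ·cn/2 (μ = 26, the study-scale coverage) and sd σ·√(cn/2) — the
  mean–variance scaling of count data — truncated at zero, with copy-number
  0 at a residual ε = 0.02 of diploid signal (mismapping). σ defaults to
  0.8, ≈ 3% of diploid: Poisson sampling alone over a multi-kb locus at 26×
  gives sd < 0.1, and a few-fold inflation allows for mappability and GC
  overdispersion.
* **Callers**: cnvnator (sensitivity 0.95, ±50 bp jitter), breakdancer and
  delly (0.80, ±100 bp), pindel (0.70, ±50 bp), each with Poisson false
  calls per individual (3–5) at lengths resampled from true calls.
* **Genes**: 300 genes in five orthology categories (non-LSG singletons
  52%, non-LSG paralogs 28%, non-LSG LSD 10%, LSG LSD 4%, LSG singletons
  6%); lineage-specific categories are placed inside CNV loci at 3× the
  base rate, reproducing the young-gene/CNV association. Five genes carry
  engineered homozygous losses in 1–2 individuals.

What the simulator does **not** emulate: read-level artifacts (GC waves,
mappability tracks), breakpoint microhomology, multi-allelic loci beyond
copy-number 4, gene conversion, linkage between loci, and realistic
demography (frequencies come from the beta cascade, not a coalescent).
Passing recovery tests therefore demonstrates the pipeline's correctness on
data satisfying its model assumptions, not robustness to every artifact of
real sequencing. One visible consequence: with moderate drift and
consensus-filtered false positives, region sharing in the default cohort is
less skewed toward population-private variants than in real cohorts.

# Problem sizes and determinism

Everything is a pure function of inputs + thresholds + seed; reruns of
`run_pipeline()` with the same configuration are byte-identical. The suite
exercises the default 66-sample, 400-locus cohort end to end; oracle tests
use 1000 random V~ST~ draws, fine-grid quadrature spectra at n = 10, a
200-seed null calibration of the permutation test, and 30 PRF fits at
n = 132 chromosomes and 1500 sites — sizes at which each component's
behaviour is measurable in seconds on one core.

# Known limitations

* Median normalization mis-centers loci with carrier fraction above one
  half; such loci can masquerade as the opposite SV type.
* The PRF fit assumes a stationary population and one shared γ;
  demographic change and selection heterogeneity bias γ̂, and the γ
  convention must be checked before comparing with other tools.
* The all-individuals filter uses reciprocal-overlap clustering; whether a
  region-membership criterion was preferable is undecidable from first
  principles and this choice is the documented one.
* Fig-3A-style context classes count regions, not calls; both denominators
  are defensible and `classify_genomic_context()` operates on regions.
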