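---
title: "Simulating island founder events and measuring genome erosion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating island founder events and measuring genome erosion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`foundersim` studies what happens to the genome of a large mammal population
when a handful of individuals colonise an island, stay small and isolated for
millennia, and later pass through a short harvest bottleneck: how much
heterozygosity is lost, how inbreeding (runs of homozygosity, F~ROH~)
accumulates, and whether the inbreeding purges highly deleterious recessive
variation while leaving weakly deleterious variation untouched. The package
has two halves that meet in the middle: a forward, individual-based genetic
simulator that produces populations with known history, and an
empirical-statistics toolkit (heterozygosity, ROH detection, genetic-load
and R~xy~ accounting) that can be pointed either at simulator output or at
annotated VCF-style variant tables.

## The demographic model

The simulator is a non-Wright-Fisher (nonWF) model: one cycle is one
calendar year, generations overlap, and population size N is an emergent
property regulated by a carrying capacity K rather than being imposed.
Each year,

1. **Reproduction.** Every female aged between `first_repro_age` (1) and
   `max_repro_age` (13) produces a litter; litter sizes 1–8 follow a
   monotonically declining distribution (default p(k) ∝ 2^−(k−1), mean
   ≈ 1.97; the supplementary litter table of the source study is not public,
   so a geometric decline was chosen and can be overridden). The sire is
   drawn uniformly from the year's breeding males: each male in the
   reproductive age window is allowed to breed that year independently with
   probability `male_breeding_fraction` (0.5), re-drawn annually — a
   harem-like system. A per-male Bernoulli draw rather than a fixed-size
   half keeps a lone male fertile in expectation, which matters in rescaled
   populations of a dozen animals.
2. **Survival.** Individual i survives with probability
   `min(1, W_i × (1 − m(age_i)) × min(K/N, 1))`, where W is multiplicative
   genetic fitness, m the age-specific mortality (calves 0.2; ages 1–14
   0.05; age 15 0.74; age 16 1.0), and `min(K/N, 1)` the density rescaling
   with N censused after reproduction. The three factors are combined
   multiplicatively; the survival draw is what expresses both viability
   selection and density regulation. No individual outlives 16 years.
3. **Events.** Scheduled demographic events fire after survival: a founding
   copies k individuals sampled uniformly without replacement from the
   mainland into a new island population (the mainland persists); capacity
   changes are instantaneous.

Summaries are recorded every 10 years (every scaled year in rescaled runs)
from a uniform sample of 30 individuals per population, or the whole
population when it is smaller.

## Genomes, mutation, selection

The genome is gene-structured: by default 6 chromosomes × 500 genes ×
1,750 bp (5.25 Mb of coding sequence). There is no recombination within a
gene, a crossover probability of 10^−3^ at each gene boundary, and free
recombination between chromosomes. Mutations enter at each meiosis at
1.76 × 10^−9^ per site (a per-generation rate of 1.06 × 10^−8^ over a
six-year generation time), are deleterious (non-synonymous) with probability
2.31/3.31 and neutral otherwise. Deleterious selection coefficients are
−X with X ~ Gamma(shape 0.186, mean 0.01314833); dominance is inversely
tied to effect size (h = 0 below s = −0.1, then 0.01, 0.1, and 0.4 for
s ≥ −0.001), so strong-effect mutations are (nearly) recessive. The same
bins name the reporting categories: weak, moderate, strong, very strong.
Fitness is multiplicative over sites with no epistasis; fixed deleterious
mutations stay in the fitness product (they are realized load), although
internally they are compacted out of the haplotypes into a per-population
fixed list.

## Scenarios

A scenario is a mainland source population (K = 50,000, 500,000-year
burn-in at full scale) plus timed events in years before present: founding
of the island at 7,000 BP (founder sizes 25–500, or 20,000 for the null
scenario), recovery to 1,000–5,000 at 6,900 BP, growth to 20,000 at
1,200 BP, an overharvest bottleneck to 1,800 at 200 BP, and recovery to
20,000 at 100 BP. The shipped library (`scenario_library()`,
`inst/extdata/scenarios/*.yaml`) holds all founder × recovery combinations
and the null scenario; `load_scenario()`/`write_scenario()` round-trip the
YAML form and reject unknown keys.

## Population rescaling

Full-scale scenarios are not desk-runnable, so `apply_scaling()` implements
standard population rescaling by λ ∈ (0, 1]: capacities ×λ, per-site
mutation rate and inter-gene recombination ×1/λ, selection coefficients
×1/λ (clamped at −1), and — crucially — event times and burn-in ×λ. Time
compression is not optional: with λK individuals, drift per generation is
1/λ times stronger, so a window must contain λ times fewer generations for
the total drift, and hence the heterozygosity and load trajectories, to be
preserved. Three distortions remain and are deliberate, documented choices:

* **Age structure is not rescaled** (a 6-year generation cannot be made a
  0.3-year generation), so generational processes span relatively more of
  the compressed timeline. Quantities defined by a number of generations —
  notably the post-founding purging window of masked load, ≈33 generations
  — must be read off at the corresponding number of *generations*
  (200 scaled years), not at the naively compressed calendar offset.
* **Tiny capacities break demography, not just genetics.** founder size 25
  at λ = 1/20 rescales to 1–2 animals, which under density-dependent
  survival and stochastic sex ratios goes extinct almost surely — an
  artifact the full-scale population does not have. `scaling_policy()`
  therefore has a `min_capacity` floor; scaled runs of the severe founder
  scenarios use 10, about the smallest deme that reliably persists under
  this life history (a few breeding females plus males).
* **Clamping creates a lethal class.** s/λ is clamped at −1, so at
  λ = 1/20 every raw effect below −0.05 becomes a recessive lethal.
  Dominance and category are always assigned from the *unscaled* effect,
  otherwise the whole DFE would slide across the dominance bins. Masked
  load in scaled runs is therefore dominated by carrier status for a
  modest number of recessive lethals and is noisier than at full scale.

ROH length thresholds are genetic lengths: rescaling multiplies the per-bp
recombination rate by 1/λ, so the 0.1 Mb threshold of F~ROH~ corresponds
to `1e5 × λ` bp on the rescaled physical map.

## Burn-in and equilibrium seeding

Neutral variation is seeded analytically at mutation–drift equilibrium:
the expected number of neutral sites at derived count i among 2N genomes
is θL/i, with θ = 4N~e~μ. Under this life history the effective size is
well below census — trial trajectories decay with a timescale implying
N~e~/N ≈ 0.25 (harem mating, litter-size variance, overlapping
generations) — so seeding uses that ratio (`ne_ratio`). Deleterious
variation is never seeded; it accumulates to mutation–selection balance
during a relaxation burn-in. In the rescaled acceptance configuration the
realized and masked load plateau within roughly 800–2,000 scaled years, and
2,000 scaled years is used. One burnt-in mainland per seed is shared
(cloned) across scenarios.

## Summary statistics on simulated samples

* **Heterozygosity**: mean heterozygous sites per individual per 1,000 bp of
  simulated sequence.
* **F~ROH~** is defined against the sites segregating within the
  30-individual sample — monomorphic stretches carry no information, which
  mirrors what SNP-based empirical F~ROH~ can see. For one individual a run
  is a maximal stretch of the physical map free of heterozygous segregating
  sites, bounded by the flanking heterozygous sites (exclusive) or the
  chromosome ends; tracts of at least 0.1 Mb (rescaled map units in scaled
  runs) are summed and divided by the genome length.
* **Realized load** = 1 − mean individual fitness, fixed deleterious
  mutations included.
* **Masked load** = 1 − mean over individuals of
  ∏~het~ (1+s)/(1+hs): the additional fitness that would be lost if every
  heterozygous deleterious site became homozygous. Both loads average
  arithmetically over individuals.
* **Category counts**: derived alleles per individual per category
  (hom = 2, het = 1, fixed = 2).

## The ROH toolkit

`detect_roh()` is a PLINK-parameterised sliding-window detector: windows of
`window_snp` SNPs (profiles `w100h1`, `w1000h1`, and h3 variants) are
homozygous if they contain at most `window_het_max` heterozygous calls;
each SNP's hit fraction is the proportion of windows containing it that are
homozygous, with the reduced denominator at chromosome edges so that edge
SNPs are not blind spots; SNPs at or above `window_threshold` (5%) form
candidate runs, split at inter-SNP gaps above 1 Mb, and a run is emitted if
it has ≥ 25 SNPs, spans ≥ 100 kb, has at least one SNP per 50 kb, and
contains at most 750 heterozygous calls (so sequencing errors do not cut
long ROH). Missing genotypes neither count as heterozygous nor break runs,
and no missingness threshold is imposed. Coordinates are 1-based inclusive
(VCF convention; segment length = end − start + 1); BED export converts to
0-based half-open. Segments are never merged across chromosomes.

`inbreeding_clock()` dates inbreeding from ROH length by g = 100/(2rL)
with r = 1.04 cM/Mb and a 6-year generation time. Displayed generations are
rounded to one decimal below 10 and truncated to integers above, matching
the conventional presentation; note that one published table prints 2.4
generations for the ≥2 Mb class where the formula (and the matching years
column, 144) give 24 — the function follows the formula.

## The load toolkit

`count_load()` reports per-individual homozygous/heterozygous/total variant
counts and derived allele counts per impact category (HIGH, MODERATE,
SYNONYMOUS, INTERGENIC; ALT is the derived allele, polarised upstream),
optionally excluding sites fixed across all populations. Both the
total-variant and the allele count are exposed because published
per-individual counts can be either. `load_ratio()` normalises HIGH or
MODERATE counts by the synonymous count, absorbing mapping and
reference-distance batch effects. `rxy()` implements
L~x∉y~(S) = Σ f^x^(1−f^y^) and the double ratio
(L~x∉y~(C)/L~x∉y~(N)) / (L~y∉x~(C)/L~y∉x~(N)), with N a seeded random draw
of intergenic sites matching |C| (the same seed makes the self-comparison
exactly 1 and swap-reciprocity exact), and a delete-one block jackknife
over 50 contiguous equal-site-count genomic blocks applied jointly to C and
N — contiguous blocks respect linkage, which the resampling unit must.
`filter_variants()` applies the hard-call rules: genotype depth within
[mean/3, 2×mean], site base quality ≥ 30, heterozygote reference-allele
balance within [0.2, 0.8], and removal of indels and SNPs within 5 bp of an
indel.

## Synthetic data

`generate_table()` builds annotated multi-population genotype tables with
known truth: per-category site counts, per-population Beta-distributed
derived-allele frequencies (with an optional multiplicative deficit in one
population to emulate purged categories), Hardy–Weinberg genotypes, planted
homozygous tracts, negative-binomial depths and Beta-distributed heterozygote
allele balances. `write_fixture()` emits VCF v4.2 (GT:DP:AD) plus annotation
and population-map TSVs and a truth JSON that round-trip through
`read_variant_table()`. The generator is deliberately simpler than real
data: genotypes are Hardy–Weinberg within populations and sites are
unlinked, so there is no background LD beyond the planted tracts, no allele
frequency spectrum shaped by selection, and no within-population structure.
Passing tests on these fixtures demonstrate the statistics' arithmetic and
their response to planted signal, not robustness to the correlation
structure of real resequencing data.

## Problem sizes and numerical choices

The test and acceptance configuration runs λ = 1/20 with 2 chromosomes
(1.75 Mb), mainland K = 2,500, 2,000-year seeded burn-in, 10 replicates
with one shared burn-in per seed, and per-year sampling of 30 individuals —
about 30 s per burn-in and 10 s per scenario continuation. Ties and
degenerate cases: capacity rounding uses `round()` with the viability
floor; event-time collisions after rescaling are an error rather than a
silent merge; empty samples are errors; a chromosome with fewer SNPs than
one window yields no ROH rather than an error; jackknife replicates with a
zero L term are dropped with a warning; an optional extra lethal point mass
in the DFE exists as a switch (`p_lethal`) and defaults to off, since the
gamma plus clamping already covers the published classes.

## Limitations

Beyond the rescaling distortions above: no migration after founding, no
environmental stochasticity, autosomes only, no epistasis, infinite-sites
stacking within the bp map, and no tree-sequence recording. The inbreeding
clock inherits the usual caveats of converting tract lengths to times
(uncertain recombination rate and generation time). Full-scale (λ = 1)
replication of the published 30-replicate simulation panels is outside
desk scale by design; the rescaled runs are the supported configuration.
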