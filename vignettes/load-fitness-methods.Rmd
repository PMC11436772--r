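---
title: "Methods: mutational load, heterozygosity and fitness at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutational load, heterozygosity and fitness at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loadfit)
```

## Overview

`loadfit` analyses impact-annotated re-sequencing data from a small, admixed
population: it computes per-individual mutational-load profiles, per-class
site-frequency spectra and genome-wide heterozygosity, relates them to
lifetime fitness records, and screens for candidate deleterious variants by
zygosity pattern. Because the real study system (an endangered fox population
of a few dozen breeding adults, monitored over decades) cannot be re-run, the
package also ships a forward-in-time simulator whose generative model has
exactly the causal structure the analysis assumes. Every inferential route in
the package is validated against that known truth.

## The generative model

`simulate_population()` runs a year-by-year forward simulation of a diploid,
monogamous, den-structured population on a single pseudo-autosomal chromosome
(uniform recombination, one crossover per meiosis, infinite-sites mutation).

**Standing variation.** Founders carry `founder_sites` segregating variants
per impact class (LoF, missense, synonymous, plus neutral non-coding sites).
Derived-allele counts are drawn from the Wright stationary spectrum for a
deleterious additive-equivalent effect $\gamma = 2 N_e s h$ in the
(unsimulated) source population:

$$f(q) \propto \frac{e^{-2\gamma q}\,\bigl(1 - e^{-2\gamma(1-q)}\bigr)}
{q(1-q)\,\bigl(1 - e^{-2\gamma}\bigr)},$$

written in overflow-safe form (all exponents negative) and reducing to the
neutral $1/q$ spectrum as $\gamma \to 0$. This gives LoF alleles the rare-
shifted founder spectrum that purifying selection predicts, without
simulating the source population.

**Selection.** Each newborn survives an (unrecorded) viability filter with
probability $w = \prod_c (1 - s_c h_c)^{n^{het}_c} (1 - s_c)^{n^{hom}_c}$.
Defaults are $s = (0.15, 0.02, 0)$ and $h = (0.05, 0.1, 0.5)$ for
(LoF, missense, synonymous): strongly deleterious and nearly recessive LoF
alleles, mildly deleterious partially recessive missense alleles, neutral
synonymous alleles. These are conventional magnitudes, deliberately softened
from lethal so that homozygous LoF genotypes still segregate in a population
this small — with $s_{lof} = 0.5$ the class is purged so completely that the
load–fitness association the analysis targets cannot exist in the recorded
data.

**Fitness traits.** Conditional on surviving the neonatal filter:

- first-year survival $\sim \mathrm{Bernoulli}\bigl(\mathrm{logit}^{-1}(a_0 +
  \beta_{het}\,\mathrm{het/kb} + \beta_{mis}\,e_{mis})\bigr)$ with defaults
  $a_0 = -3$, $\beta_{het} = 7$, $\beta_{mis} = -150$, chosen so each
  predictor moves the logit by roughly half a unit per standard deviation at
  the default site density;
- adult longevity is geometric (constant annual survival 0.6) multiplied by
  $\exp(\beta_{LoF}\, e_{lof})$ with $\beta_{LoF} = -300$ — expressed-load
  proportions are of order $10^{-3}$, so coefficients of order $10^2$
  correspond to modest effects;
- litter size $\sim \mathrm{Poisson}$ with a rodent-phase mean (7 in the
  increase phase, 5.5 in the decrease phase), a log-normal den random
  intercept (the variance component the litter LMM estimates), the sire/dam
  expressed-LoF penalty, and a heterosis boost $\beta_{F1} = 0.6$ on the log
  scale for native × immigrant pairs.

**Admixture.** At `immigration_generation` (default year 6 of 12), three
outbred males arrive. They draw alleles at the native standing sites from the
shared source frequencies and carry novel source-private variants (their
count scaled by `immigrant_source_diversity`), at least one of which is LoF —
so the admixed gene pool always contains LoF sites absent from natives, the
signature the gene-pool comparison quantifies.

**Output.** `write_outputs()` emits a VCF v4.2 with SnpEff-style
`ANN=Allele|Annotation|Impact|Gene_Name|Gene_ID` INFO strings, plus pedigree,
fitness, litter and ground-truth TSVs. All writers use binary connections and
fixed column orders, so a fixed seed yields byte-identical files.

## Load metrics

`read_annotated_vcf()` (built on `vcfR`) splits multiallelic records into one
biallelic row per ALT allele and maps SnpEff impacts HIGH → LoF, MODERATE →
missense, LOW → synonymous, anything else → OTHER. `apply_site_filters()`
retains sites called in every individual and segregating.

For each individual, `compute_load_profile()` reports allele-level
proportions $p_c$ (derived alleles of class $c$ over all derived alleles
carried), expressed load $e_c$ (homozygous-derived genotypes over the scored
sites) and masked load $m_c$ (heterozygous genotypes over the same
denominator). OTHER-class sites enter genome-wide heterozygosity
(`heterozygosity_per_kb()`) but never the load denominators. The
`carrier_sites` denominator option restricts the denominator to sites where
the individual carries at least one derived allele.

## Fitness models

Trait transforms are frozen to the study's choices — $\sqrt{\text{LRS}}$,
$\log(\text{longevity})$, identity for litter size — and `boxcox_advise()`
is advisory only: it maximises the Box–Cox profile likelihood on a grid
(validated against `MASS::boxcox`) and maps $\hat\lambda$ to a conventional
transform. Survival uses binomial GLMs with Wald tests; ancestry contrasts
use REML random-intercept (natal den) LMMs via `lme4`, with residual-df Wald
t tests; group comparisons use exact-where-possible Mann–Whitney tests; and
`group_mean_contrast()` reproduces printed-table arithmetic at the precision
of the printed inputs. P values are not adjusted across the battery.

## Candidate screens

`longevity_screen()` and `litter_size_screen()` implement the zygosity
rules (homozygous in all — or at least a configurable fraction of — affected
individuals, never homozygous in unaffected ones); `hybrid_private_lofs()`
finds LoF alleles absent from natives but common among immigrant
descendants. `overrepresentation_test()` is a one-sided hypergeometric
(Fisher) test with Bonferroni adjustment, validated in the test suite against
direct `choose()`-based enumeration for every margin up to 30.

## Validation design

The package is validated on three levels:

1. **Exact oracles** — load profiles against an independent brute-force
   tally; OLS/GLM/correlation routes against closed forms; Fisher p against
   enumeration; worked-example contrasts against the published group means.
2. **Parameter recovery** — replicate simulations at a size (carrying
   capacity 150, 10 generations, ~500 usable records) where the correctly
   specified models — $\log(\text{longevity}) \sim e_{lof}$ and
   survival $\sim$ het/kb with $\beta_{mis} = 0$ — must recover the
   generative coefficients' signs and cover them with nominal 95% CIs. Site
   counts, genome length and mutation rates are scaled together so that
   het/kb keeps the scale the survival calibration assumes.
3. **Null calibration** — type-I error of the Mann–Whitney and survival-GLM
   routes within Monte-Carlo bands of the nominal 5%.

## What is deliberately not emulated

Realistic arctic-fox demography, recombination maps, sex chromosomes,
age-structured fertility, genotyping error and annotation error are out of
scope. The simulator is a validation instrument: it makes the assumed causal
structure true by construction so the estimators can be tested, not a model
of the real population's history.

## Numerical notes

- The Wright spectrum is evaluated with negative exponents only; $\gamma$ up
  to $2 N_e s h \approx 10^3$ is safe.
- Haplotypes are stored as one integer vector per haplotype rather than a
  sites × haplotypes matrix; this keeps gamete writes O(sites) instead of
  forcing copy-on-write of the full matrix and makes the default simulation
  run in seconds.
- All randomness flows from one master seed (`with_seed()`), and the
  pipeline's `report.json` is identical across reruns except its timestamp.

```{r example}
sim <- simulate_population(sim_config(n_generations = 6, seed = 1))
sim
vt <- apply_site_filters(sim$variants)
head(compute_load_profiles(vt, sim$config$genome_length), 3)
```
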