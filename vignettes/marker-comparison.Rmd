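---
title: "Comparing microsatellite and SNP panels for population genetic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing microsatellite and SNP panels for population genetic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markercmp)
```

## The scientific question

Conservation genetics of small, structured populations — a handful of river
populations of a salmonid, say — asks two kinds of questions. Population-level
questions (how differentiated are the populations, how diverse is each, what
is the effective population size) and individual-level questions (who is
related to whom, which individuals form full-sib families, how heterozygous is
each fish). Two marker technologies compete for these jobs: a panel of a dozen
or two multiallelic microsatellites, and thousands of biallelic SNPs from
reduced-representation sequencing. A recurring empirical finding is that the
two marker classes agree closely on population-level structure (F_ST) while
SNP panels are decisively better for individual-level inference (sibship,
relatedness, multilocus heterozygosity).

`markercmp` turns that comparison into a reproducible parameter-recovery
experiment: it simulates structured populations with known pedigrees under
both marker classes, runs the full analysis battery on each, and checks which
conclusions each marker class supports.

## The simulator

`simulate_dataset()` draws, per locus, ancestral allele frequencies (a
symmetric Dirichlet over k alleles for microsatellites; uniform above a minor
allele frequency floor for SNPs), then per-population frequencies from the
Balding–Nichols model: a Dirichlet centred on the ancestral frequencies with
concentration `(1 - G)/G`, which for a biallelic locus is the familiar beta
with parameters `p(1-G)/G` and `(1-p)(1-G)/G`. Founders are drawn at
Hardy–Weinberg proportions, family offspring by Mendelian segregation from
designated parents, and finally per-allele genotyping error and missing calls
are overlaid.

**Calibration of the divergence knob.** Pairwise Nei F_ST measures divergence
relative to the pooled pair of populations, not relative to the (unobserved)
common ancestor, which halves the drift signal: drawing frequencies directly
at a drift parameter F yields realized pairwise F_ST of `(F/2)/(1 - F/2)`.
The simulator therefore maps the configured `divergence_F` through
`G = 2F/(1 + F)` before the beta draw, so that `divergence_F` *is* the
expected pairwise F_ST between two equally diverged populations. With that
calibration, two-deme simulations at F between 0.06 and 0.21 (30 + 30
individuals, 2,000 SNPs) recover the configured value to within about 0.01 on
average.

The defaults describe the study conditions the package targets: four
populations of 30, sixteen microsatellites with 3–18 alleles (repeat unit 2,
allele sizes from 100, so they serialize naturally as three-digit Genepop
codes), 2,000 SNPs with an ancestral MAF floor of 0.05, per-allele genotyping
error 0.05 for SNPs and 0.0001 for microsatellites, about 4% missing calls,
and a haploid chromosome number of 40 for reporting. Family structure is set
by `family_plan`; there is no background relatedness beyond what the plan
specifies, because a defensible background level is population-specific — the
user sets it explicitly. Half-sib families share the sire by convention, with
dams drawn independently; family parents are *unsampled* founders, so the
relationship classes that occur among sampled individuals are unrelated,
half-sib and full-sib, as in a field sample of juveniles.

What the simulator does **not** emulate: linkage (all loci are unlinked,
except in the Wright–Fisher generator below), mutation (no stepwise
microsatellite mutation model), selection, migration, null alleles, and
allelic dropout. Tests passing on these simulations therefore validate the
estimators under drift, family structure, genotyping error and missingness —
not under every pathology of real data.

`simulate_wright_fisher()` is a separate generator for the effective
population size experiments: a constant-size, discrete-generation,
random-mating diploid population (two distinct parents per offspring) with
free recombination. Mixture LD accumulates by drift; for unlinked loci the
composite disequilibrium approaches its drift equilibrium within roughly ten
generations, so the default of 30 generations is comfortable. Initial allele
frequencies are uniform on (0.1, 0.9) to limit fixation over that horizon;
loci that fix anyway are returned monomorphic and removed by the MAF screen
downstream.

## The estimators

### Diversity and Hardy–Weinberg tests

Expected heterozygosity is plain gene diversity `1 - sum(p^2)` (maximum 0.5
for a biallelic locus, 1 for a multiallelic one); the unbiased `n/(n-1)`
variant is opt-in. Allelic richness uses hypergeometric rarefaction,
`Ar = sum_a [1 - C(N - N_a, g)/C(N, g)]`, with the rarefaction depth `g`
defaulting per locus to the minimum typed gene-copy count across populations —
the standard missing-aware convention. Hardy–Weinberg deviation is tested
either by a chi-square goodness of fit over all genotype categories or by a
Monte-Carlo exact test that re-pairs the observed gene copies into random
diploid genotypes (1,000 permutations and a logged seed by default, so filter
chains using it are reproducible); the permutation p-value is floored at
`1/(1 + n_permutations)`.

### The filter chain

`apply_filter_chain()` reproduces the usual RADseq marker/individual filter
battery with explicit, parameterized thresholds: locus presence across
populations and individuals, individual missingness (strict `> 0.20`), marker
missingness (strict `> 0.30`), a marker heterozygosity cap (0.5, against
assembly artefacts), a two-level MAF screen, and Hardy–Weinberg retention
(p > 0.05 in at least two populations; a population where the locus is
monomorphic cannot reject and counts as consistent). Two decisions deserve
note. First, the local/global MAF combination is not uniquely pinned down by
common usage; we retain a marker iff its global MAF clears the global
threshold *and* its MAF clears the local threshold in at least one population
— discard what is rare everywhere, keep what is common somewhere. Second, a
single sequential pass of interdependent threshold filters is not idempotent
(dropping markers changes individual missing fractions and vice versa), so
the chain iterates to a fixpoint — usually one or two passes — making
re-application a no-op by construction. Multiallelic MAF is defined as one
minus the major-allele frequency.

### Nei F_ST and permutation tests

Per locus, `H_S` is the unweighted mean across populations of within-
population gene diversity and `H_T = 1 - sum(pbar^2)` with `pbar` the
unweighted mean frequency; multi-locus F_ST is the ratio of sums
`(sum H_T - sum H_S)/sum H_T`. Unweighted means are deliberate: sample sizes
per population range from 9 to 30 in the motivating design, and hierarchical
estimators of this family ignore them. Ratio-of-sums aggregation is stable
when some loci are near-monomorphic; loci monomorphic across the selected
populations are excluded, and negative estimates are reported as computed.
The permutation test shuffles individuals (both alleles travel together)
between the two populations, preserving sample sizes, with
`p = (1 + #[F_perm >= F_obs])/(1 + n_permutations)` and 999 permutations by
convention.

### LD-based effective population size

`burrows_r2()` computes, for every locus pair, the Burrows composite
disequilibrium from unphased genotype counts — the sample covariance of
per-individual allele-copy counts, halved — and divides its square by the
product of per-locus variance terms `p(1-p) + (P_hom - p^2)`, the binomial
variance adjusted for homozygote excess. The squared correlation is capped at
its theoretical maximum of 1 (the `n/(n-1)` covariance convention can push a
perfectly associated pair fractionally above it). Multiallelic loci are
decomposed into per-allele indicators and averaged; biallelic loci contribute
their minor allele only, because the two indicators give the identical r².
Loci below the MAF cutoff (0.02 by convention) are excluded before pairing.

`ne_from_r2()` subtracts the finite-sample expectation — `1/S + 3.19/S²` for
samples of 30 or more, `0.0018 + 0.907/S + 4.44/S²` below — and inverts the
drift relationship, `Ne = (1/3 + sqrt(1/9 - 2.76 r²'))/(2 r²')`, with the
small-sample coefficient variant below S = 30. A drift r² at or below zero
(or a negative discriminant) is reported as infinite, which is the honest
answer when sampling noise swamps the drift signal; reports print the string
"infinite". The `1/S + 3.19/S²` term matters: with the bare `1/S` the
estimator is biased low by a third at S = 30, and the Wright–Fisher
calibration (true Ne 50, 1,000 loci, 20 seeds) fails its coverage target.
With it, the jackknife interval covers the true value in ~85–95% of runs and
every point estimate lands within a factor of two.

Confidence intervals jackknife over individuals (not locus pairs): the mean
r² is recomputed leaving each individual out, the jackknife variance is
formed on the drift-r² scale, and the normal-theory endpoints are transformed
through the Ne closed form — the upper r² bound becomes the lower Ne bound.
The chromosome-number bias correction divides the estimate by
`0.098 + 0.219 ln(chromosomes)`; at the default haploid number of 40 the
divisor is 0.906, and the correction inflates estimates whenever the
chromosome number is below about 61. All locus pairs are used regardless of
chromosome tag, since simulated loci are unlinked; tags are reporting-only.

### Allele-sharing relatedness and subset precision

Bxy scores each locus by half the multiset intersection of the two allele
pairs (1 for identical genotypes, 0.5 for one shared allele copy, 0 for
none) and averages over loci typed in both individuals; pairs sharing fewer
than five typed loci are reported NA rather than noisily. The subset-precision
curve redraws random locus subsets (without replacement within a replicate —
a subset, with the bootstrap spread coming from replicate-level resampling;
with-replacement sampling is available as an option) and records the mean
absolute difference from the full-panel Bxy. Note that the curve is measured
against the *same panel's* full set, so a 16-locus microsatellite panel's
value at subset size 16 is zero by construction; the informative comparison
between marker classes is the curve as a whole and the largest proper subset
sizes, where the SNP panel's error at 100 loci sits well below the
microsatellite error at 8.

### Pairwise sibship classification

The full-pedigree MCMC reconstruction used by dedicated sibship software is
out of scope; in its place is a fully specified pairwise maximum-likelihood
classifier, and outputs are labelled "pairwise method" to avoid conflation.
Each pair is scored under the IBD-coefficient mixture — unrelated (1, 0, 0),
half sib (1/2, 1/2, 0), full sib (1/4, 1/2, 1/4), parent–offspring (0, 1, 0)
— with per-locus genotype-pair probabilities from the standard one-allele-
shared decomposition. Genotyping error enters as a one-parameter genotype
replacement model (observed genotype correct with probability `1-e`, else a
fresh Hardy–Weinberg draw), which folds into the likelihood in closed form:
`L_obs = (1-e)² L_true + (1-(1-e)²) HW(G1)HW(G2)`. When the data carry
*per-allele* error `e` (as the simulator applies), the matching genotype-scale
rate is `1-(1-e)²` — `allele_to_genotype_error()` — and the recovery
experiments use that conversion. Classes are assigned by maximum likelihood
with equal priors; the reported probability is the normalized likelihood, and
ties break toward the less related class. Full-sib families are connected
components of the graph of full-sib-assigned pairs above a probability
threshold (0.95 by default). Allele frequencies are estimated from the full
population sample including the focal pair, which is simple and nearly
unbiased at the target sample sizes.

**A documented limitation**: with plug-in frequencies estimated from 30 or
fewer individuals, the full-sib/half-sib likelihood margin is fragile at
*rare* alleles — frequency noise systematically erodes the full-sib term, and
misclassification toward half-sib results. With known frequencies, or with
common variants (MAF above ~0.2), family recovery is essentially perfect;
with a MAF-0.05 panel and 30 samples it degrades visibly. This mirrors the
practical advice to screen loci by MAF before relatedness work, and it is why
the worked family-recovery example uses a common-variant panel. Exclusion
probabilities in the sense of full-pedigree software have no pairwise
analogue; the equal-prior class probability reported here is named
differently on purpose, and cross-software comparisons are directional only.

### Standardized multilocus heterozygosity and HHC

`smlh()` divides an individual's count of heterozygous typed loci by the sum,
over those same loci, of the population mean observed heterozygosity — so
with no missing data the group mean is exactly 1. Standardisation can run
across the whole dataset or within populations (both modes are exposed; the
pooled mode also picks up between-population diversity differences, which is
the dominant signal in multi-population datasets). The heterozygosity–
heterozygosity correlation draws two *disjoint* equal-sized random subsets of
loci per replicate (leftover loci unused that replicate), computes sMLH
within each subset — self-contained, rather than reusing full-panel locus
means — and records the Pearson correlation across individuals; replicates
with zero variance are NA and counted. Under identity disequilibrium (or
pooled population structure) the mean HHC rises with subset size; in a single
panmictic population without family structure it sits at zero on average over
datasets, though any one dataset keeps a chance offset of order `1/sqrt(n)`.
`cross_marker_correlation()` compares sMLH between marker classes on shared
individuals with the usual `t = r sqrt(df/(1-r²))` test.

## The pipeline

`run_pipeline()` chains everything: simulate (or load Genepop/VCF inputs) →
carry a configurable subset of individuals through "sequencing" → filter the
SNPs → run diversity, Ne, F_ST, sibship, relatedness-precision, and
sMLH/HHC on the three datasets (microsatellites on everyone; SNPs and
microsatellites on the sequenced subset) → write delimited reports and a
manifest with stage seeds, timings and output checksums. Stage seeds derive
deterministically from the master seed and the stage name, so reruns are
byte-identical and stages can be reproduced standalone. Each subcommand of
the analysis corresponds to an exported function; the pipeline is plain R,
and plotting is left to the user (the curve files are long-format tables
ready for ggplot2).

## Numerical choices and problem sizes

Monte-Carlo settings default to the conventional values (999 F_ST
permutations, 1,000 HWE permutations, 1,000 subset/HHC replicates). The test
suite and the acceptance script scale some experiments to keep a full run in
a few minutes on one CPU: 10 seeds for the F_ST recovery levels, 20
Wright–Fisher seeds for Ne coverage, 10 seeds with 100 replicates for the
subset-precision and HHC contrasts, 50 pairs per class and seed for sibship
accuracy. These sizes were chosen so that the Monte-Carlo standard error of
each checked quantity is several times smaller than the margin being
asserted. Tolerances in tests come from the sampling theory of each
statistic, not from tuning: e.g. F_ST recovery within 0.03 at 2,000 loci,
HWE type-I error within three binomial standard errors of 0.05.

## Known limitations

* The sibship classifier is pairwise; it does not enforce pedigree
  consistency across pairs, and a triangle of pairwise full-sib calls is the
  only notion of "family" available. Counts of half-sib dyads are therefore
  directly comparable between marker classes but not to full-pedigree
  software.
* LD-based Ne assumes discrete generations and random mating; overlapping
  generations, admixture and physical linkage (beyond the chromosome-count
  correction) all bias it.
* The simulator's missingness is completely at random; informative
  missingness (e.g. by sequencing depth) would stress the filters
  differently.
* Identity disequilibrium in simulated data comes from family structure and
  pooled population structure only; there is no inbreeding model, so
  within-population HHC signals are modest by design.
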