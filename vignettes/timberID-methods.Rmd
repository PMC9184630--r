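---
title: "Statistical methods behind timberID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind timberID}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timberID)
```

`timberID` builds and validates the two DNA databases used in forensic
timber identification — a regional SSR allele-frequency database for random
match probabilities, and a chloroplast haplotype database for regional
origin inference. This vignette documents the statistical models, the
package's numerical conventions, the design choices that were genuinely
open, and what the bundled simulator does and does not emulate.

## Data model

A `GenotypeTable` stores diploid multilocus SSR genotypes as an
`n × L × 2` integer array of fragment sizes (bp). Allele labels are
integers throughout — SSR alleles are sized fragments, and treating them as
floats invites binning artefacts. A missing call is a pair of `NA`s; a
half-missing pair is rejected at parse time. Population labels partition
samples, and region labels, when present, partition populations. Region
membership is an input (a `population → region` map), not something the
package re-derives: regional clusters come from upstream model-based
clustering, which is out of scope here. Chloroplast alignments are
`Biostrings::DNAStringSet` objects over `{A, C, G, T, N, -}`, required to be
pre-aligned and equal-width.

## Allele-frequency databases and the 5/(2N) floor

`buildAlleleDb()` computes allele frequencies per group as allele count over
twice the number of individuals genotyped at that locus in that group;
missing calls shrink only that locus's denominator (pairwise deletion).
`applyFloor()` implements the forensic minimum-allele-frequency convention:
any frequency below 5/(2N) is raised to 5/(2N), where N is the group's
sample size. The floor is rounded half-up to four decimals (for N = 381
and N = 1029 this gives 0.0066 and 0.0024 — the thresholds of the reference
regional databases this package models). Two conventions deserve emphasis:

* **floored frequencies are not renormalised** — the genotype-frequency sum
  then slightly exceeds 1, which errs on the side of the defendant
  (conservative); and
* floored frequencies feed only the forensic calculations (profile
  frequencies, extreme profiles, conservativeness); descriptive statistics
  (He, PIC, distances) use raw frequencies.

## Per-locus forensic parameters

For each locus and group, `locusSummary()` reports the allele count A,
observed heterozygosity Ho, unbiased expected heterozygosity
He = (2n/(2n−1))(1 − Σp²), polymorphic information content
PIC = 1 − Σp² − Σ~i<j~ 2p_i²p_j², matching probability MP (the sum of
squared *observed* genotype proportions, the PowerStats convention — not
HWE-expected proportions) and power of discrimination PD = 1 − MP. By
construction PD + MP = 1 and PIC ≤ He.

Hardy–Weinberg conformity is tested with a Guo–Thompson-style Monte-Carlo
exact test: the 2n observed alleles are repeatedly re-paired into n random
genotypes, arrays are ranked by their conditional probability given the
allele counts (computed up to the shared constant as
h·log 2 − Σ log n_g!, h = heterozygote count), and
p = (#{as or more extreme} + 1)/(n_perm + 1). The default n_perm is 10,000;
the two-allele case is checked in the tests against full enumeration of the
heterozygote-count distribution. Linkage disequilibrium between locus pairs
is a permutation test that shuffles one locus's single-locus genotypes among
individuals and uses the G statistic of the two-locus genotype contingency
table. Both tests are deterministic under a fixed seed; monomorphic loci
report p = 1 with a flag rather than an error. Bonferroni correction flags
p < α/k (with 10 loci at α = 0.05, the threshold is 0.0050).

## Weir–Cockerham θ and f

`weirCockerham()` implements the 1984 variance-component estimator with
components a (among populations), b (among individuals within populations)
and c (within individuals), computed per allele with per-locus sample-size
bookkeeping and summed over alleles and loci before taking ratios:
θ = Σa/Σ(a+b+c), f = 1 − Σc/Σ(b+c), F = 1 − Σc/Σ(a+b+c). Summing before
dividing (ratio of sums) follows the original recommendation and the
population-genetics packages this mirrors; averaging per-locus ratios is
biased with unbalanced data. The tests pin the implementation to values
computed with an independent transcription of the estimator, and to its
closed-form limits (θ = 1 under fixation for alternative alleles, θ ≈ 0 for
an arbitrary split of one panmictic population).

Confidence intervals come from `fstatBootstrap()`, which resamples **loci**
(not individuals) with replacement — the convention of the lineage of
programs this replaces — and reports percentile 2.5/97.5 bounds; an estimate
is flagged significantly positive when its interval excludes zero. With the
default 10-locus panels the intervals are wide and their coverage slightly
anti-conservative, which is why the recovery tests demand ≥ 90% empirical
coverage of a nominal 95% interval rather than exact coverage.

## Profile frequencies and the two θ-correction modes

`genotypeFrequency()` exposes both standard readings of a θ/f-corrected
genotype probability, because forensic practice uses each in a different
role:

* `unconditional-frequency` (default): the expected genotype frequency in a
  subpopulation — homozygote `f·p + (1−f)·p·[θ + (1−θ)p]`, heterozygote
  `(1−f)·2·p_i·p_j·(1−θ)`. It is a proper distribution: it sums to one over
  the genotype space for every (θ, f), which the tests verify by exhaustive
  enumeration on a five-allele locus over a θ × f grid.
* `conditional-match`: the NRC-II recommendation 4.10 / Balding–Nichols
  match probabilities — the chance a random subpopulation member carries the
  profile given it has been observed once. No combined θ-and-f version of
  this formula is established, so f is deliberately not folded in here
  (inventing coefficients would be worse than documenting the limitation).

One property often asserted of the conditional formulas is *not* true in
general and the package documents rather than assumes it: heterozygote
match probabilities are non-decreasing in θ only while
p_i·p_j ≤ (p_i + p_j)/5 (the derivative at θ = 0 is
2p_i + 2p_j − 10·p_i·p_j). Homozygote match probabilities are always
non-decreasing. In whole profiles the increasing terms dominate in
practice, but the calibration code never relies on exact monotonicity.

`extremeProfiles()` builds the canonical most-common and rarest profiles —
fully heterozygous, carrying the two most (least) frequent floored alleles
at every locus — with frequency ties broken deterministically towards the
smaller fragment size. `randomMatchProbability()` formats the reciprocal at
three significant figures with short-scale unit words.

## Conservativeness and θ calibration

For each individual, `d = log10(P_origin/P_combined)` compares the profile
frequency under its cognate (own-population) database with the pooled
regional database; d < 0 means the regional database overstates the profile
frequency, i.e. it is conservative for that individual. Two open choices had
to be fixed and are exposed as arguments:

* **P_origin uses θ = 0** — the cognate population is itself the
  subpopulation — while keeping the regional f estimate. The alternative
  (a population-level θ inside P_origin) can be requested via
  `dStatistic()`'s parameters.
* **Calibration runs in conditional-match mode by default**, where raising θ
  inflates P_combined near-monotonically, so the non-conservative set
  shrinks and the grid walk terminates. Unconditional mode is allowed but
  guarded: an all-heterozygous profile gets *rarer* with θ there, so the
  walk detects a growing non-conservative set and reports non-convergence
  instead of looping.

`adjustTheta()` walks the grid θ_init + k·0.005 (reported at four decimals)
and returns the smallest grid value at which every individual is
conservative; the tests verify grid-minimality by re-evaluating one step
below. Individuals with any missing locus are excluded from calibration and
counted in the report.

## Self-assignment

`selfAssignment()` scores every individual against every population with the
Rannala–Mountain Bayesian criterion (the default of the assignment software
this mirrors): a Pólya-urn posterior-predictive genotype probability under a
uniform Dirichlet prior of total mass 1, i.e. pseudo-count 1/K per allele
with K the number of alleles seen at the locus across the whole reference.
The prior mass keeps unseen alleles from zeroing a likelihood. Scoring is
strictly leave-one-out — the individual's two alleles are subtracted from
its own population's counts before scoring — and ties are broken by input
order with a warning. Population accuracy and region accuracy (the region of
the *assigned population*) are reported per group and as means.

## Distances and trees

Nei's D_A between populations is 1 − (1/L)·Σ_loci Σ_alleles √(x_a·y_a) on
raw frequencies. UPGMA uses average-linkage `hclust` converted to an
ultrametric `ape` tree; labels are sorted first so merge-order ties resolve
lexicographically and output is deterministic. Node support bootstraps
loci (the same unit as the F-statistic bootstrap), rebuilding distance
matrix and tree per replicate and counting recovered bipartitions.

## Chloroplast haplotypes

`findVariableSites()` classifies alignment columns: a substitution site has
at least two distinct non-gap, non-N states; a deletion event is a maximal
run of columns whose gap-carrier set is identical — one event regardless of
run length, with overlapping-but-unequal runs splitting where the carrier
set changes. N is missing data, never variation. Coordinates are 1-based in
all reports. `callHaplotypes()` collapses samples by their state tuple at
the variable sites, names haplotypes H1..Hk by descending count (ties by
first observation) and assigns N-bearing samples only when their non-missing
states match exactly one observed haplotype. `inferRegion()` then reports a
query haplotype as diagnostic (one region), shared (several) or unknown
(absent from the database) — an unknown result is expected for rare
haplotypes missing from any finite reference collection.

## The simulator: what it emulates, what it does not

`simulateHierarchicalSSR()` draws ancestral allele frequencies from a
symmetric Dirichlet, then regional and population frequencies through
nested Balding–Nichols steps (Dirichlet with concentration (1−θ)/θ times
the parent frequencies — the standard F-model, matching the Weir–Cockerham
θ in expectation; θ = 0 copies the parent exactly). Individuals are
autozygous with probability f (one allele drawn and duplicated), otherwise
two independent draws. Defaults emulate the reference design's measured
structure: two regions, θ within region ≈ 0.05, f ≈ 0.08, ten unlinked
multi-allelic loci with fragment-size labels 100 + 2k. It does **not**
simulate mutation models, allele-size homoplasy, null alleles, genotyping
error, or physical linkage — observed LD in simulated data arises only from
structure and inbreeding. Passing tests therefore demonstrate estimator and
pipeline correctness under the stated model, not robustness to those
real-data artefacts.

`simulateCpDNA()` builds one dominant haplotype per region plus rare
region-endemic variants over a configurable number of substitution events
and deletion runs (defaults: four markers of 573/487/500/593 bp, 21
substitutions, 7 deletions), with a carrier matrix constrained so every
event is polymorphic and every haplotype pair differs — making the truth
exactly recoverable, which the tests exploit (partition identity, i.e.
adjusted Rand index 1).

## Numerical conventions and degenerate inputs

* Floors: half-up rounding at the fourth decimal for the floor value only;
  all other computation at double precision.
* Monomorphic loci: HWE p = 1 with a flag; F-statistics error only when
  *all* loci are monomorphic; `extremeProfiles()` requires ≥ 2 alleles per
  locus.
* Single-replicate bootstraps collapse intervals to a point; single-locus
  tables refuse to bootstrap.
* All stochastic stages take an explicit integer seed and restore the
  caller's RNG state afterwards; fixed seeds give byte-identical outputs.

## Problem sizes used by the test suite

The suite favours many small, sharply targeted cases. The heavier
statistical checks use: 50 replicate simulations of 30 populations × 30
individuals at 10 loci × 12 alleles for θ/f recovery and bootstrap coverage;
200 replicates for the HWE size check; and two-region sets of 4–8
populations for calibration, assignment and tree support. These sizes give
the property checks enough resolution while keeping a full run fast on a
single CPU.

## Known limitations

* The conditional-match mode has no established combined θ+f formula, so f
  is ignored there (documented above).
* Published per-individual quantities of the reference databases (the exact
  adjusted θ values, assignment percentages, haplotype counts) depend on
  raw genotypes that were never deposited; the package reproduces the
  *procedures* and validates them on synthetic truth instead.
* No mixture likelihood ratios, kinship indices, null-allele estimation, or
  de novo alignment — inputs must be clean genotypes and pre-aligned
  sequences.
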