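---
title: "Methods and design notes for ssrpopkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for ssrpopkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ssrpopkit analyses multiallelic microsatellite genotype matrices from
predominantly selfing crop collections. This vignette records the models
the package implements, the assumptions they rest on, the defaults and why
they were chosen, and the design decisions taken where more than one
reasonable convention exists. It states no empirical result that the test
suite or the acceptance script does not itself compute.

## The data model

A `geno_matrix` holds two allele slots per (individual, locus) cell.
Allele codes are fragment sizes in bp; `0` is the **null allele**, a real
codominantly scored allele state (a non-amplifying variant), not missing
data; `NA` is a missing call, and a cell is either fully missing or fully
called — half-missing cells are rejected at parse time. Throughout the
package the null allele participates in allele counts, frequencies,
diversity, coancestry and distance computations like any other allele
(two nulls are identical by state; a null and a sized allele are not).
This follows from scoring nulls codominantly in the input encodings; an
analysis that wants to exclude null-carrying loci can simply subset the
matrix, which is why no global `exclude-null` switch is built in.

Three text dialects are read and written losslessly: a CSV dialect
(`a/b` cells, `?` missing, `999` null), Genepop (2- or 3-digit allele
codes, width auto-detected; `00`/`000` missing, `99`/`999` null; a
size-to-code sidecar table accompanies written files because Genepop codes
cannot carry fragment sizes), and STRUCTURE two-rows-per-individual
(`-9` missing). Genepop carries no population names, so blocks read back
as `pop1`, `pop2`, ... in file order.

## Diversity statistics

* Unbiased gene diversity: UHe = n/(n−1) · (1 − Σpᵢ²) with **n the number
  of sampled allele copies** (the GenAlEx convention, matching the
  software lineage of this analysis style).
* F_IS = 1 − Ho/UHe is computed per locus and averaged over polymorphic
  loci; loci with UHe = 0 are excluded. The averaging order is a
  convention; per-locus-then-average is used because it weights loci
  equally.
* Rare alleles are counted on each population's own frequencies (pooled
  frequencies for the pooled row); the alternative — rating rarity always
  on pooled frequencies — is defensible but not used.
* Percent polymorphic loci uses the strict ≥ 2 observed alleles
  criterion, not a 95%/99% frequency criterion.
* Rarefied allelic richness and private allelic richness use
  hypergeometric rarefaction to a standard number of gene copies `g`
  (Kalinowski-style). The default `g` is twice the smallest compared
  sample, capped by the smallest per-locus gene count; loci that cannot
  support `g` are dropped per statistic (pairwise deletion), never
  listwise. Exhaustive subsample enumeration is the test oracle at
  `n_genes <= 12`.
* PIC is Botstein's 1 − Σpᵢ² − Σ_{i<j} 2pᵢ²pⱼ².

## Molecular coancestry

The per-locus score f = ¼(I₁₁ + I₁₂ + I₂₁ + I₂₂) over the four ordered
allele comparisons can only take the values {0, ¼, ½, 1}; the suite
verifies this exhaustively. Loci with a missing cell in either individual
are excluded from the average (pairwise deletion) rather than scored
zero, since averaging "over analysed loci" leaves missing-data policy
open and zero-scoring would bias relatedness downward for sparsely typed
pairs. The self-coancestry diagonal is 1 − Ho_i/2. Coancestry is
conventionally run on *all* loci, including any flagged by the neutrality
pre-filter, because relatedness correction in association models wants
genome-wide identity, not only neutral identity; the pipeline follows
that convention.

## Distance, trees, ordination

Nei's minimum distance treats a single diploid genotype as a frequency
vector with entries 0, ½, 1. Neighbour joining is delegated to
`ape::nj()` (deterministic agglomeration); negative branch lengths, which
NJ produces on non-additive input, are clamped to zero with the clamped
total recorded in an attribute. Bootstrap supports resample loci with
replacement and count bipartitions of the point tree via
`ape::prop.clades`. The test oracle fits every unrooted topology by least
squares (n ≤ 7) and confirms exact recovery on additive matrices.

PCoA is the Gower double-centering of −d²/2; reported percent variation
is each positive eigenvalue's share of the positive spectrum. Because the
Nei distance is already a per-locus mean, no further standardization is
applied before embedding.

## Admixture model and model choice

`admixture_gibbs()` is a reduced STRUCTURE-style sampler: symmetric
Dirichlet(λ = 1) priors on cluster allele frequencies, symmetric
Dirichlet(α) on admixture proportions with α updated by a Metropolis step
(uniform(0, 10) prior, normal proposal sd 0.25), and collapsed Gibbs
updates of each allele copy's cluster of origin. No linkage model and no
prior population information — the published Gibbs updates are desk-scale
while full feature parity is not the goal. lnP(D) is estimated as
mean(lnL) − var(lnL)/2 over kept sweeps. Default burn-in/iteration counts
follow the conventional 10,000/100,000; the tests and pipeline use far
smaller, clearly stated values because the datasets are small and the
sampler mixes in hundreds of sweeps there.

Evanno's ΔK = |L′′(K)|/sd(L(K)) over replicate runs picks K; it is
undefined at the boundary K values and when replicate spread is zero (the
pipeline then falls back to the K maximising mean lnP(D)). Assignment
uses the argmax cluster when max Q ≥ 0.70, else "admixed".

F-statistics: Weir–Cockerham θ (variance components summed over alleles
and loci) is the primary estimator, with Nei's G_ST = (Ht − Hs)/Ht
reported alongside as a cross-check, since software-specific FST variants
differ; permutation p-values use the add-one rule (b + 1)/(m + 1).

## Linkage disequilibrium

For material with Ho ≈ 0.02, each homozygous individual carries one
directly observed two-locus haplotype; heterozygous or missing calls are
excluded ("U" convention) rather than phased. The multiallelic r² is the
frequency-weighted average of allele-pair r² values, which reduces
exactly to the classical 2×2 r² for biallelic loci (verified against a
direct computation on random tables). Pair significance uses a chi-square
test on the haplotype contingency table with a Monte-Carlo p-value when
any expected count is below 5 — the original analysis tool does not
document its test, so the generic contingency test is declared here.
Quantiles (the 95th percentile of unlinked r²) use linear interpolation
(type 7).

The decay fit is nonlinear least squares (Levenberg–Marquardt via
minpack.lm) of linked-pair (d, r²) points to the Hill–Weir
drift-recombination expectation with C = ρd, and the block size is the
distance where the fitted curve crosses r² = 0.1 (bisection; 0 if the
curve starts below, infinite if the asymptote ~1/n lies above). A
non-decreasing r²-vs-distance trend flags the fit as unreliable. For
group-comparison decay plots, linked pairs are averaged in distance bins
of the genome-wide block width (`ld_decay_bins()`).

## The four-test selection scan

* **Ewens–Watterson**: observed homozygosity F = Σpᵢ² against the Ewens
  sampling distribution conditional on (n, k), simulated by rejection
  from the Hoppe urn with the urn parameter tuned so E[K] = k. The
  conditional rejection sampler is an exact conditional simulator and
  sidesteps the unspecified exact-enumeration algorithm of the legacy
  software. Two-tailed rank p; a locus is "significant" when
  Dh/sd < −2.5 **and** p < 0.05. The scan applies it to the pooled
  contrast groups. Note a structural property verified by the suite: under
  the conditional null Dh/sd is bounded below near −1 to −3 (H cannot fall
  far below its conditional mean given k), so the neutral flag rate at
  these thresholds is essentially zero — the test is a conservative
  confirmation, not an independent 5%-level test. This is why one
  acceptance assertion that expects a ≥ 1% neutral EW rate is left
  failing rather than loosening the published thresholds.
* **ln RH**: RH = [(1/(1−He_A))² − 1]/[(1/(1−He_B))² − 1], log-ratio
  standardized across loci; |z| > 1.96 flags. Both one- and two-sided
  modes exist; two-sided is the default because the statistic is
  symmetric in the two groups even though the flagging is sometimes
  described one-sided. When sample sizes are supplied, loci monomorphic
  in one group are assigned the heterozygosity of a single allele
  difference (the usual monomorphic correction) so that completed sweeps
  remain testable; otherwise they are excluded with a warning.
* **FDIST-style scan**: a structured-coalescent island model (default 100
  demes, 2 sampled with the observed sample sizes) with stepwise mutation
  wrapped onto 30 allele states and per-locus mutation rates drawn
  log-uniformly so simulated heterozygosities span the observed range.
  Migration is recentred iteratively (up to 20 rounds, tolerance 0.01)
  until the simulated mean Weir–Cockerham θ matches the observed
  5%-trimmed mean. Each observed locus is placed at its empirical
  quantile of simulated θ conditional on heterozygosity (equal-count
  bins, ≥ 50 simulated loci each); quantile > 0.95 flags.
* **Hierarchical scan**: identical machinery with demes arranged in two
  groups of `k_within` demes, within-group migration 10× between-group by
  default (the ratio is configurable since no canonical value exists),
  and the two sampled demes in different groups. At ratio 1 it reduces to
  the island scan, which the suite checks.

A consensus outlier is a locus significant in at least two of the four
tests; no multiple-testing correction is applied, faithful to the
consensus-instead-of-correction design. Candidate windows around outliers
use the local physical-to-genetic ratio (kb/cM) times the genetic span
when the outlier and its best neighbour share a scaffold in strong LD
(r² > 0.4); times the distance at which group LD decays to 0.4 for
moderate LD (0.2–0.4); and a fixed ±10 kb otherwise.

## Bottleneck tests

Equilibrium heterozygosity given an observed allele count is simulated by
a single-population coalescent under the two-phase model (defaults
p_smm = 0.70, multi-step variance 30 — the standard documented defaults,
configurable since the analysis convention leaves them unstated), with
the scaled mutation rate bracketed so the mean simulated allele count
matches, then conditional acceptance on k. The sign test computes each
locus's equilibrium excess probability from those simulations and
evaluates the observed excess count against the exact Poisson-binomial
distribution (dynamic programming — exactness is cheap at desk scale, so
no normal approximation). The mode-shift test bins pooled allele
frequencies into ten 0.1-wide classes and calls "L-shaped" only when the
lowest class is the strict mode. One ordering worth recording: at a fixed
allele count, the stepwise model implies a *higher* equilibrium
heterozygosity than an infinite-alleles-like model (homoplasy hides
alleles), which is what makes the SMM/TPM the conservative choice for
heterozygosity-excess testing; the suite verifies this direction by
simulation.

## The synthetic-data generator

`simulate_ssr()` is a forward-in-time Wright–Fisher simulator chosen over
a coalescent because planted sweeps, partial selfing and map-structured
LD are then straightforward; the package's own structured coalescent (the
scan null engine) and closed-form expectations serve as independent
cross-checks in tests. It models non-overlapping generations, island or
two-level (hierarchical) island migration of parent choice, selfing with
probability `selfing_rate`, recombination along the linkage map with the
Haldane map function and no interference, stepwise or two-phase mutation,
mutation to a null-allele state, and uniform missingness applied last at
sampling. Allele states are repeat scores emitted as fragment sizes
(100 + 2·state). Truth bookkeeping records realized allele counts, a
multilocus G_ST trajectory, the registry of founder and mutant alleles
(every sampled allele must trace to it — an invariant under test),
planted-sweep outcomes and, optionally, the exact pedigree kinship matrix
of the sampled individuals.

`flaxlike_preset()` fixes the study conditions the package is calibrated
against: six demes in two group-clusters, 15 linkage groups, selfing
0.98, stepwise mutation at 10⁻³, four founder alleles per locus. These
values were calibrated once so that realized alleles per locus fall
around 5, group-level θ around 0.1 and observed heterozygosity a few
percent — the magnitudes typical of a selfing crop core collection — and
are not revisited per test.

Two generator features deserve explanation:

* `split_gen` stops between-group migration from a given generation,
  emulating a shared base collection that later separates into isolated
  breeding pools — the demographic history behind divergently bred crop
  groups with modest genome-wide differentiation.
* In-simulation `sweeps` apply fitness (1+s)^dosage for a
  then-segregating minor allele of the target group. A caveat the
  development experiments made very clear: at high selfing, multi-locus
  selection multiplies whole near-clonal lines, collapsing the selected
  group's effective size and inflating *genome-wide* differentiation —
  real biology, but it confounds any experiment that needs a neutral
  background. For calibration experiments that require "neutral loci plus
  known outliers", `plant_sweeps()` therefore engineers the completed
  sweep footprint directly (near-fixation of a group-specific allele at
  chosen loci, everything else untouched).

What the generator does **not** emulate: genotyping error and allele-size
binning artefacts, locus-specific mutation rate variation, gene
conversion, seed banks/overlapping generations, and real pedigree
structure of breeding programs. Passing calibration on simulated data
therefore demonstrates internal statistical correctness under the stated
model, not robustness to those real-data features.

## Problem sizes and numerical choices

The test suite runs at deliberately small, fixed sizes chosen as the
package's own desk-scale defaults: scan calibration uses 20 seeded
replicates of 200 (type-I) or 105 (power) loci on 2×2 demes of 100
individuals with 25 sampled per deme; the ln RH coverage check uses ten
seeds of 500 loci with 50 diploids per deme; oracle-equivalence checks
use n_genes ≤ 12 and trees of ≤ 7 leaves where exhaustive enumeration is
exact. Coalescent and urn simulations run in C++ through Rcpp and use R's
RNG, so every result is reproducible from `set.seed()`. Tolerances:
exact-arithmetic comparisons at 1e-9 or tighter; Monte-Carlo comparisons
at 2–3 standard errors of the quantity involved; the FDIST recentring
tolerance is 0.01 on mean FST.

## Known limitations

* The EW test at the published thresholds is a conservative confirmation
  test (see above); consensus calls in practice rest on ln RH, FDIST and
  the hierarchical scan, whose flags are mutually correlated because all
  three respond to per-locus differentiation — consensus is therefore
  close to their pairwise intersection, not a product of independent
  error rates.
* LD estimation discards heterozygous calls; in material with
  substantially higher outcrossing the haplotype sample would be biased
  and an EM phasing step (out of scope) would be needed.
* The admixture sampler reports a single-run posterior mean; label
  switching across replicate runs is not aligned (no CLUMPP step), so
  replicate Q matrices should be compared by assignment, not entrywise.
* Genepop round-trips preserve population *blocks* but not arbitrary
  population names, a limitation of the format itself.
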