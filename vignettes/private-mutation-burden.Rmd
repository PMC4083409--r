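---
title: "The burden of private mutations: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The burden of private mutations: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privburden)
```

## The quantity

When a population has already contributed `n` sequenced diploid genomes, the
burden of private mutations `α` of the next genome is the proportion of its
heterozygous sites that are absent from those `n` genomes. A site private to
the new individual is heterozygous in it (a homozygous-minor private site
would need two copies) and is a singleton of the combined `2n + 2`-chromosome
sample; so `α` is a per-individual functional of the sample's folded site
frequency spectrum, heavily weighted towards its singleton class.

Two results anchor the package. Under constant population size,

$$E[\alpha] = \frac{E[s]}{E[h]} = \frac{2}{2n+1},$$

since one individual's expected heterozygosity is `E[h] = θ` and its expected
share of the folded singletons `E[η₁] = θ(1 + 1/(2n+1))` is `E[s] =
E[η₁]/(n+1) = 2θ/(2n+1)` by exchangeability (each singleton is equally likely
to sit in any of the `n + 1` individuals — we adopt this exchangeability
reading literally; under panmixia it is exact). `θ` cancels, making `α`
scale-free. For an arbitrary history,

$$E[\alpha] = \frac{1}{n+1}\,
  \frac{E[T_{2n+2,1}] + E[T_{2n+2,2n+1}]}{E[T_{2,1}]},$$

where `T_{p,q}` is the total branch length subtending `q` of `p` tips:
folded singletons arise on branches with 1 or `2n + 1` descendants, and the
denominator is the two-tip tree length, computed from the model rather than
fixed at 2 because non-constant histories rescale it.

## Exact branch-length expectations

`expected_branch_lengths()` computes `E[T_{p,q}]` without simulation. Writing
the cumulative coalescent intensity `Λ(t) = ∫₀ᵗ ds/(2N(s))`, the engine first
evaluates the pair non-coalescence transforms

$$e_j = \int_0^\infty \exp\{-\tbinom{j}{2}\,\Lambda(t)\}\,dt
  \quad (j = 2,\dots,p),$$

in units of `2N₀` generations, then combines them as `E[T_{p,q}] = Σ_j
W_{q,j} e_j` where the weights obey a three-term recurrence in `j` (start
values `W_{q,2} = 6/(p+1)`, `W_{q,3} = 30(p-2q)/((p+1)(p+2))`). The
alternating hypergeometric representation of the same quantity cancels
catastrophically already for `p` in the hundreds; the recurrence does not,
and the test suite verifies the constant-size law `E[T_{p,q}] = 2/q` to
better than `1e-8` at `p = 200` (in fact ~`1e-14`) and finite positive values
at `p = 20,002`, the scale needed for extrapolating the burden to
`n = 10,000`. Should an exotic model ever drive an intermediate negative or
non-finite, the engine raises an explicit numerical-failure error rather than
returning silent garbage.

Per-epoch contributions to `e_j` are closed-form for constant-size epochs.
For exponential epochs the integral has no elementary form; we use adaptive
quadrature (`stats::integrate`, relative tolerance `1e-10`) on an interval
truncated where the integrand has decayed to `exp(-45)`, so the quadrature
never wastes points past machine-negligible mass and never misses a decay
scale much shorter than the epoch. The Monte-Carlo simulator
(`simulate_coalescent_trees()`), which draws standard exponential coalescence
times and maps them through `Λ⁻¹`, is kept as an independent oracle: the
tests require exact values within 3 standard errors of 200,000-tree averages
for three non-constant histories.

Time runs backwards from the present; epochs are listed present → past, sizes
are given at each epoch's recent end, and a positive growth rate means growth
towards the present (`N(s) = N·exp(-g·s)` backwards). Only the most ancient
epoch may be infinite. All scale-free outputs are invariant to jointly
rescaling sizes and durations (tested).

## Folded spectra and their conventions

`expected_folded_sfs()` folds by minor allele count: mass at `x` proportional
to `E[T_{m,x}] + E[T_{m,m-x}]` for `x < m/2`, with the self-complementary
class `x = m/2` counted once. Normalization conditions on segregating sites
*after* folding: the `x = 0` class is zeroed and `x ≥ 1` sums to one. The
`x = 0` class exists so projections can account for variants that become
monomorphic in a subsample; displayed spectra exclude it.

## Projection (probabilistic subsampling)

To compare data sets of different sizes — including within-data-set
variation caused by missing genotype calls — folded counts are projected to a
common `m` chromosomes. A SNV with `j` minor alleles among `n` called
chromosomes lands on subsample minor count `x` with probability

$$P(x) = \frac{1}{1+\delta(x, m-x)}\,
  \frac{\binom{j}{x}\binom{n-j}{m-x} + \binom{j}{m-x}\binom{n-j}{x}}
       {\binom{n}{m}},$$

the two terms folding the hypergeometric draw of the designated minor allele
(`x` or `m − x` copies) onto the subsample's minor class. Two conventions
deserve note. First, the leading factor must be `1/(1+δ)` — halving only the
`x = m/2` class — for the vector to sum to one; the tests verify this against
exhaustive enumeration of all `C(n, m)` subsamples for every `(j, n, m)` with
`n ≤ 12`, in exact integer arithmetic. Second, no additional halving is
applied when `j = n − j`: in that case the two terms are the two labelings of
the same event and their sum is already correct (the enumeration oracle
confirms; halving there would break normalization). Binomials are evaluated
as exact small integers for `n ≤ 50` and via log-gamma above.

`project_dataset()` drops SNVs with fewer than `max(m, min_called)` calls
(the conventional quality filter when reducing heterogeneous call counts to
one sample size), projects the survivors independently — sites are treated
as unlinked, which is what the estimator assumes anyway — and reports the
projected-out (`x = 0`) mass separately.

## The synthetic panel generator

`simulate_panel()` emulates the structure the empirical estimator assumes:
each SNV draws a minor count from a folded SFS conditioned on segregating,
places the copies uniformly without replacement among the `2n` chromosomes
(a chromosome carries at most one copy — biallelic semantics), and pairs
chromosomes into individuals. Uniform placement makes the pairing
exchangeable, so consecutive pairing equals random pairing. Missingness is
applied per (individual, site) *genotype*: both chromosomes drop together,
as genotype-calling failures do; the rate can be one number for the panel or
a per-SNV vector, so empirical per-site call-count profiles can be matched. The defaults for the reference panel-scale
experiment are 493 individuals and 1,746 segregating SNVs — the scale of a
neutral-regions genotype panel with a ≥900-successful-calls filter — with
minor counts from the constant-model SFS at 986 chromosomes. Because `α` is
scale-free given the number of segregating sites, the generator fixes the
SNV count directly instead of a mutation rate.

What the generator does *not* emulate: linkage between sites, sequencing and
genotyping error, population structure or inbreeding, and any explicit model
of selection — functional-category spectra are emulated only through
`skew_sfs()`, which resets the singleton proportion and rescales the other
classes. Passing tests therefore show the estimator and the theory agree
with each other under the model's own assumptions; they do not validate
those assumptions for any real cohort.

## The empirical estimator

`panel_alpha()` computes, per individual, the proportion of its heterozygous
sites whose minor count *among called chromosomes at that site* is exactly 1.
Missing genotypes are discarded site-by-site. Individuals with zero usable
heterozygous sites have an undefined burden and are excluded from the mean
and SD (with the exclusion count reported) rather than set to 0, which would
bias small panels downward; the SD uses the `n − 1` denominator.
`downsample_alpha()` re-evaluates singleton status inside a random subset of
`m` individuals — estimating the burden at `n = m − 1` — and averages over
10 subsets by default (1 recovers a single-draw estimate).
`bootstrap_se()` resamples SNVs with replacement (1,000 times by
convention), recomputing the across-individual mean each time; the SD of
these bootstrap means estimates the standard error due to the finite site
count, and is exactly 0 for degenerate identical-column panels.
`category_ratio()` compares two categories' mean burdens with a delta-method
SE from their bootstrap SEs.

One subtlety the tests pin down: removing an individual never changes another
individual's heterozygous-site denominator, only the singleton status of
shared variants — which is why the burden *rises* as the panel shrinks.

## Preset histories and tunable parameters

`preset_models()` returns a constant-size model, a two-bottleneck toy
history, and the same history with a terminal exponential epoch (default
3.5%/generation for 120 generations, inside the 2–5% per-generation range
estimated for recent European growth). The bottleneck and growth settings
are deliberately labelled *toy*: published fitted histories should be loaded
via `read_model_config()` when quantitative predictions for a real
population are wanted. With these toys, recent growth raises the expected
burden above the constant model for `n ≳ 100` and the gap widens with `n`
(at `n = 492`: 0.505% vs 0.203%); the two-bottleneck toy *without* growth
sits slightly below the constant model, a reminder that bottleneck-only
histories can push this statistic in either direction depending on their
depth and timing.

## Problem sizes and determinism

The test suite runs the enumeration oracle to `n = 12`, the constant-size
law to `p = 200`, Monte-Carlo cross-checks at `p = 6` with 200,000 trees,
estimator calibration over 50 panels at each of `n ∈ {10, 100, 492}`
(1,746 SNVs each), and the stability probe at `p = 20,002`. These sizes make
the whole suite run in about a minute while keeping Monte-Carlo standard
errors small enough for 3-SE assertions to be sharp. Every stochastic
routine takes an explicit integer seed and restores the caller's RNG state,
so panels and bootstrap draws are bit-reproducible.

## Known limitations

- No migration, admixture or population structure in the demographic models;
  structure in real cohorts inflates rare-variant proportions and hence the
  burden, and is not modelled here.
- Selection enters only through empirical/emulated spectrum skew, not
  through a selection coefficient.
- Unfolded (ancestrally polarized) spectra are internal only; all user-facing
  spectra are folded.
- The variance of `α` under the coalescent is not computed; only simulated
  SDs and bootstrap SEs are reported.
- Sex chromosomes are out of scope; all formulas assume autosomal diploidy.
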