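---
title: "Methods: the family-based adaptive combination of P-values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the family-based adaptive combination of P-values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Region-based rare-variant tests pool association signal across the variant
sites of a gene or window because single rare variants carry too little
information to be tested on their own. Pooling, however, inevitably mixes
causal sites with neutral ones, and neutral sites dilute power. The test
implemented here addresses both issues for *pedigree* data: it combines
per-site evidence adaptively — discarding sites whose P-values look null —
and it obtains significance by a permutation scheme that respects the
relatedness structure, by re-randomising transmissions *within* families
rather than shuffling phenotypes across them (which would be invalid under
relatedness).

The design targets family sequencing studies: phased genotypes for every
pedigree member over `L` biallelic sites, a dichotomous or continuous
trait, optional covariates, and complete pedigree structure including
genotyped founders.

## Per-site statistic

Let `Y` be the trait vector and `r = Y - X(X'X)^{-1}X'Y` its ordinary
least-squares residuals on an intercept plus covariates (mean-centring when
there are no covariates). The same linear adjustment is used for 0/1 and
continuous traits: the statistic only needs residuals orthogonal to the
intercept, not a correctly specified mean model, and the permutation layer
supplies finite-sample validity. Let `g_l` be the vector of minor-allele
counts at site `l`, `p_l` the allele frequency computed from *founder*
haplotypes, and `Phi` the genetic-correlation matrix — block-diagonal over
families, with entries twice the kinship coefficient, assembled by the
standard founders-first recursion (`kinship_matrix()`). The per-site score
statistic is

    T_l = (r' g_l)^2 / ( 2 p_l (1 - p_l) * r' Phi r )

with P-value the upper tail of the chi-squared distribution with one degree
of freedom. This is the retrospective (genotypes random, trait fixed)
quasi-likelihood score form for related individuals; treating genotypes as
the random element is what lets ascertained pedigrees be analysed without
modelling the ascertainment. Three numerical remarks:

* The factor `r' Phi r` does not involve genotypes, so it is computed once
  and reused across all sites and all permutations.
* Centring `g_l` by `2 p_l` would be the textbook presentation, but it is a
  no-op here because `r` sums to zero under an intercept model; a unit test
  asserts the equivalent invariances (allele flip, trait shift, trait
  scaling).
* Sites monomorphic in founders have a vanishing denominator and no
  transmission randomness; they are flagged invalid, assigned `P = 1`, and
  excluded from the combined score. They stay invalid in every permutation
  because founder genotypes are fixed, so this choice cannot leak
  information.

The chi-squared calibration is asymptotic. For very rare variants the
statistic is a sum of a handful of discrete contributions and its null
distribution has visible atoms; the package therefore validates the
uniform-P-value property on sites with founder MAF at least 0.05 (and under
founders drawn at Hardy–Weinberg, since haplotypes from one shared
coalescent genealogy are mutually correlated and in complete linkage
disequilibrium, which distorts any finite-sample check built from a single
pool). None of this affects the region-level test, whose significance comes
from permutation, not from the asymptotic approximation — that robustness is
precisely why the adaptive combination needs the permutation layer.

## Adaptive combination and MinP correction

Given per-site P-values `P_1..P_L` and a grid of truncation thresholds
`theta_1 < ... < theta_J` (default `0.05, 0.10, ..., 0.50`), the
significance score at threshold `j` is

    S_j = sum_l ( -ln P_l ) * 1[ P_l < theta_j ]

summed over valid sites (strict inequality; `-log10` is available as an
option, which only rescales scores and changes nothing downstream). Small
thresholds discard likely-neutral sites aggressively; large ones keep more
sites. Because no single threshold is best for all genetic architectures,
the procedure evaluates all of them and pays the multiplicity price through
a MinP construction on the permutation null:

1. For each permutation `b = 1..B` (default `B = 1000`), recompute the
   per-site P-values from permuted genotypes and form `S_j^(b)`.
2. `p(S_j) = #{b: S_j^(b) >= S_j} / B`, and each permuted score is ranked
   against all `B` replicates including itself, keeping all replicate ranks
   on one common scale.
3. `MinP = min_j p(S_j)` and likewise `MinP^(b)` per permutation.
4. The adjusted region P-value is `(1 + #{b: MinP^(b) <= MinP}) / (B + 1)`,
   the add-one estimator that cannot return zero.

Ties are handled exactly by the `>=`/`<=` comparisons — no jitter. With a
single threshold the construction collapses to an ordinary truncated
combination permutation test, which a unit test asserts. An optional
sequential Monte-Carlo mode stops generating permutations once the MinP
exceedance count reaches a user cap (the estimator then uses the
permutations actually generated); it is off by default because fixed-`B`
results are exactly reproducible run to run.

## The permutation null: gene dropping conditional on founders

Under the null hypothesis, transmission of haplotypes from parents to
offspring is completely random conditional on parental genotypes. A
permutation replicate therefore keeps founder haplotypes fixed and redraws,
generation by generation, one full-length haplotype from each parent's
current pair for every non-founder — no within-region recombination, since
regions are single genes or short windows. Traits are never permuted.

For a child of two founders this law is equivalent to the classical
observed/complement swap (keep the observed genotype with probability 1/2,
otherwise replace the score `G_c` by `G_f + G_m - G_c`) whenever at most
one parent is heterozygous at the site; with two heterozygous parents the
swap law conditions on more than the parental genotypes and the two
conditional laws differ, although their marginals over observed data
coincide. The engine always uses the full Mendelian redraw, which is the
stated null. An exact enumerator (`enumerate_transmissions()`) expands all
`4^K` meiosis patterns of a small pedigree and is used both as a test
oracle for the sampler and to drive `ada_test_exact()`, the
enumeration-exact version of the region test; the 12-member template with
fully heterozygous, distinctly labelled founders yields well over 256
distinct configurations, which is what makes within-family permutation
informative at realistic sample sizes.

Founder allele frequencies, validity flags, residuals and `r' Phi r` are
all invariant under the null and are not recomputed per permutation (a test
asserts founder-MAF invariance rather than assuming it). The inner loop —
gene drop plus score accumulation — is compiled (Rcpp); an R reference path
exists and the two are tested for exact equality on shared uniform
deviates. All randomness flows through R's own RNG (`set.seed()` up front
reproduces everything, including the compiled path, because the deviates
are pre-drawn in R); we chose this over per-meiosis counter-based streams
because it is the convention of every R simulation package and makes the
whole pipeline reproducible with one seed.

## The simulator and what it emulates

`coalescent_pool()` builds a haplotype pool from a single random coalescent
genealogy (no recombination): exponential waiting times with rate
`k(k-1)/2`, then exactly `L` mutations placed on branches with probability
proportional to branch length (fixed-S, infinite sites). This reproduces
the neutral site-frequency spectrum (`E(sites at derived count i)
proportional to 1/i`) and hence a realistic excess of rare variants. The
default pool holds 1000 haplotypes — comfortably above the 400 founder
haplotypes drawn per replicate at the default design, so draws are without
replacement — and a fresh pool is generated per replicate so that
between-replicate variation includes the genealogy. What the pool does
*not* emulate: recombination, mutation-rate heterogeneity, demography, or
between-site independence — all sites share one tree and are in strong
linkage disequilibrium, as is true of short regions in real data.

`simulate_families()` instantiates `N` copies of the three-generation
12-member template (founders at positions 1, 2, 5, 6; eight non-founders)
with founder haplotypes drawn from the pool and descendants generated by
gene dropping.

Dichotomous traits follow a multiplicative penetrance model: a subject
carrying `c_j` copies of the causal (minor) allele at causal site `j` is
affected with probability `min(1, f0 * prod_j GRR_j^{c_j})`, baseline
`f0 = 0.05`. The per-site genotype relative risk comes from the marginal
population attributable risk via `GRR = PAR/(MAF (1 - PAR)) + 1`, so rarer
causal variants get larger effects. Continuous traits are additive:
`Y = mu + sum_l a_l (x_l - 1) + e` with `mu = 100`,
`e ~ N(0, sigma2_e = 100)`, and `a_l` calibrated under Hardy–Weinberg so
QTL `l` explains its target fraction `h2_l` of trait variance (defaults
0.001–0.006 per QTL). The mean and error variance are immaterial — the
test is location and scale invariant — and the optional within-genotype
spread `sigma2_g` of the genotypic value defaults to 0 (its value is
absorbed into the `h2` calibration when set). Causal sites default to
indices 10, 20, 30, 40, 50 whatever their simulated frequency: causal
variants are not forced to be rare. Families are not ascertained on
affection status by default.

`run_experiment()` wires these together: per replicate a fresh pool,
families, a trait, and one `ada_test()`; it reports rejection proportions
of the adjusted P-value at nominal levels 0.01–0.05 with binomial standard
errors. In the measure-zero event that a simulated trait is constant (and
the region untestable by definition) the trait is redrawn.

## Problem sizes and validation design

The package's own statistical checks run at desk scale, chosen to keep the
full suite in the tens of minutes while leaving every conclusion
Monte-Carlo-resolvable:

* type-I error: 1000 null replicates (2000 in the acceptance script) of 50
  families x 100 sites with `B = 200`, assessed within three binomial
  standard errors of each nominal level — `B = 200` leaves the add-one
  estimator enough resolution at the 0.01 level (granularity 1/201);
* power trend: 500 replicates per effect point at `B = 200`, asserting
  monotone power in the overall PAR (0.05, 0.15, 0.30) and in total
  variance explained (0.005, 0.015, 0.03), not any absolute level;
* kinship: the recursion against a `10^6`-drop identity-by-descent
  Monte-Carlo oracle for parent–offspring, full-sib, avuncular and
  first-cousin pairs;
* calibration: 2500 per-site P-values under the related-individuals null,
  Kolmogorov–Smirnov against uniform at the 1% level (founder MAF >= 0.05,
  for the reasons above).

## Known limitations

* Phased input is required; phasing itself (e.g. Beagle) is out of scope,
  and phase uncertainty from statistical phasing of real data is not
  propagated.
* Missing genotypes, missing traits and ungenotyped founders are rejected,
  not imputed: the permutation null conditions on complete founder
  haplotypes.
* Autosomal inheritance only; multi-allelic sites and dosages are not
  supported; the sex column is read but unused.
* The adjustment model is linear for both trait types by design; no
  logistic or mixed-model residualisation.
* Unrelated controls cannot be incorporated: every individual must belong
  to a pedigree with genotyped founders.
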