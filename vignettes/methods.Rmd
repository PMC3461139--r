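---
title: "Methods: temporal genetic monitoring with tempomon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal genetic monitoring with tempomon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempomon)
```

`tempomon` implements the analysis chain of a multi-year genetic monitoring
program for a small, hatchery-supplemented fish population: per-sample
diversity with sample-size correction, Hardy–Weinberg and linkage
disequilibrium quality control, hierarchical F/Φ-statistics, four effective
population size (N~e~) estimators, association tests against density, flow
and supplementation records, and a forward simulator with known truth. This
vignette explains the models, the tunable parameters, the numerical
conventions, and the design choices made where the methods literature leaves
the design open.

## Data model

Diploid microsatellite genotypes live in a `genotype_table` (individuals ×
loci × 2 integer allele labels, with a missing mask); mtDNA haplotypes in a
`haplotype_table` (one label per individual, maternal, haploid). Genepop
(2- or 3-digit) is the exchange format; haplotypes, metadata, broodstock and
environmental records are plain CSV. A half-missing diploid call (one of the
two gene copies unreadable) is treated as fully missing at that locus — the
simplest rule consistent with how allele counts enter every downstream
statistic; monitoring datasets rarely distinguish the two cases.

Published tables print frequencies to three decimals, while exact
recomputation needs integer counts. `counts_from_published_frequencies`
inverts the rounding by `round(freq * n)` followed by a largest-remainder
repair so the counts total `n`, warning when a cell moves by more than one
count and refusing (error) beyond two — at that point the frequencies and
the stated sample size are mutually inconsistent. Ties are broken by index
order, so the recovery is deterministic.

## Diversity

Unbiased gene diversity uses the haploid form
$h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$ and its diploid analogue
with $2n$ gene copies. Richness is corrected for sample size by
hypergeometric rarefaction,
$A_R(g) = \sum_i \left[1 - \binom{n - n_i}{g} \big/ \binom{n}{g}\right]$,
computed on log-binomial coefficients for stability. The rarefaction unit is
gene copies for diploid loci and sequences for mtDNA; when comparing
haploid samples the default rarefaction size is the smallest haploid sample
size among the samples compared, since no universal convention exists.

The resampling correction draws `B` subsamples of `n_star` individuals
without replacement (convention: `B = 1000`), computes per-locus statistics
on the individuals non-missing at each locus within the subsample, averages
across loci per subsample, and reports means and empirical 2.5/97.5
percentiles across subsamples. Per-locus percentile intervals are also kept
for parity with toolkit output. Samples smaller than `n_star` are skipped
with a warning rather than extrapolated. `F_IS` uses the Weir–Cockerham
within-sample variance components, with loci combined by summing components
(a variance-weighted mean); monomorphic loci drop out.

## Quality control

The Hardy–Weinberg test is the conditional exact test: the p-value is the
total probability, given the allele counts, of genotype arrays no more
probable than the observed one (ties inclusive). Small tables (`n <= 12`,
up to 4 alleles) are enumerated exactly by recursion over genotype count
arrays; otherwise the same quantity is estimated by repeatedly shuffling the
pool of gene copies into random diploid genotypes — a simple unbiased
batching scheme rather than a Markov chain, which is adequate at monitoring
scale and trivially seedable. Inter-locus tests use the log-likelihood G
statistic on the genotype-by-genotype table with permutation of one locus
across individuals; the p-value includes the observed arrangement, so its
floor is `1/(n_perm + 1)`. Multiple testing uses the sequential Bonferroni
(Holm) rule, checked in the tests against `stats::p.adjust`.

## Structure

`weir_cockerham_fst` is the standard per-allele a/b/c variance-component
estimator summed over alleles and loci. The three-level AMOVA partitions
variance among groups, among samples within groups, and within samples. For
diploid data the within-sample term retains the nested among-/within-
individual levels; because every retained individual contributes exactly two
gene copies, the expected-mean-square coefficients at the individual level
are exactly 2 and the two-level special case reproduces Weir–Cockerham θ to
machine precision (asserted at 1e-10 in the tests). Haploid (Φ) mode uses
squared inter-haplotype distances, identity by default; a substitution-count
matrix can be supplied when sequence divergence is known. Negative variance
components are reported as estimated — never truncated — so small negative
indices (a common outcome under weak structure) survive into the output.
Permutation schemes: whole samples among groups (F~CT~), individuals among
samples within groups (F~SC~), individuals among all samples (F~ST~). With
few samples the F~CT~ permutation floor is the probability of redrawing an
equivalent partition, not `1/(n_perm+1)`; the tests respect that.

## Effective size

All temporal estimators consume a `temporal_pair_stats` object: per-locus
allele frequencies `x` (first sample) and `y` (second), sample sizes, the
number of generations `t`, the sampling plan, and the census size `N` for
Plan I (sampling before reproduction, nondestructively, so sampled fish may
be parents). Alleles absent or fixed at both times are dropped. Sample
years are equated with generations (annual spawner, generation length
G ≈ 1.27 years), and the analytical overlapping-generation rescaling
`Ne_adj = (C/G) * Ne` is available but off by default because the
correction factor C is program-specific.

* **Moments**: Nei–Tajima
  $F_c = \frac{1}{K}\sum_i \frac{(x_i-y_i)^2}{(x_i+y_i)/2 - x_i y_i}$ per
  locus, loci weighted by allele count; the Pollak variant is not exposed.
  Sampling correction $F' = F_c - \tfrac{1}{2S_0} - \tfrac{1}{2S_t} + \tfrac1N$
  (the $1/N$ term only under Plan I), $N_e = t/(2F')$. Confidence intervals
  are chi-square with $df = \sum_l (K_l - 1)$ independent alleles.
* **Unbiased F~s~**: $F_s = \sum_i (x_i-y_i)^2 \big/ \sum_i z_i(1-z_i)$ with
  numerators and denominators pooled across loci. The bias correction was
  re-derived for binomial gene-copy sampling: with
  $A = F + \tfrac{1}{2S_0} + \tfrac{1-F}{2S_t}$, $E[F_s] = A/(1 - A/4)$,
  whose inversion is
  $F_s' = \frac{F_s\,(1 - 1/(4\tilde n)) - 1/\tilde n + 1/N}
               {(1 + F_s/4)(1 - 1/(2S_t))}$,
  $\tilde n$ the harmonic mean sample size in individuals. The binding check
  is recovery of simulated truth (median within ±20% at the study design of
  9 loci × 8 alleles, S = 50, t = 2), not a transcribed constant. CIs are
  delete-one-locus jackknifes on the corrected-F~s~ scale.
* **Pseudo-maximum-likelihood**: each allele (allele-vs-rest, factors
  multiplied over alleles and loci) contributes
  $\sum_{p_0} \Pr(p_0)\,\mathrm{Bin}(c_0 \mid 2S_0, p_0)
   \sum_{p_t} W^t(p_t \mid p_0, N_e)\,\mathrm{Bin}(c_t \mid 2S_t, p_t)$
  with a uniform prior on a 128-bin frequency grid and Wright–Fisher
  binomial matrix transitions in a pool of `ploidy × Ne` gene copies; the
  likelihood is profiled over a log-spaced `ne_grid` (default 60 points,
  10–10^4). A maximum at the top bound is reported as +∞; the CI is the
  2-unit support interval. This is an independent implementation, validated
  distributionally against simulated truth, not a port of any program.
* **LD**: Burrows composite
  $\hat\Delta_{AB} = \frac{n}{n-1}\left(\frac{1}{2n}\sum_i X_i Y_i - 2\hat p_A \hat p_B\right)$
  over every allele pair of every locus pair (alleles rarer than `Pcrit`
  screened; default 0.02, the conventional middle choice of
  {0.05, 0.02, 0.01}), $r^2 = \hat\Delta^2/[p_A(1-p_A)p_B(1-p_B)]$ averaged
  with weights proportional to the individuals used. The sampling
  expectation $E[r^2\mid S] = 1/S + 3.19/S^2$ ($S \ge 30$; small-sample
  form $0.0018 + 0.907/S + 4.44/S^2$) is subtracted and the random-mating
  drift relation inverted,
  $N_e = \big(1/3 + \sqrt{1/9 - 2.76\,r^{2\prime}}\big)/(2 r^{2\prime})$
  (constants 0.308 and 2.08 below S = 30). $r^{2\prime} \le 0$ yields +∞; a
  negative discriminant is reported as 0 with a "below estimable minimum"
  flag. CIs are delete-one locus-pair jackknifes.
* **Haploid**: $N_{ef} = t/(F_c - 1/S_0 - 1/S_t)$ with sizes in sequences —
  the implemented convention for the mtDNA (female) effective size; the
  F~s~ estimator is not offered for haploid data because its correction
  assumes diploidy.

Everywhere, a corrected drift signal at or below zero maps to +∞ — never a
negative size — and +∞ propagates through the overlap rescaling and into
reports as the literal `inf`, so downstream rank and regression steps must
(and do) exclude it explicitly with logged counts.

## Monitoring associations

Density (October CPUE, fish/100 m²) is transformed as log₁₀(x+1) (base and
offset configurable; the transformation source conventions vary). Spring
runoff is scored categorically from the May 1–June 30 daily hydrograph at a
3000 cfs threshold: 10 when at most 14 days exceed it, 15 for 15–30 days,
20 above 30 days. The published rule leaves a duration of exactly 30 days
between its classes; this implementation closes the middle class at 30.
Series pairing follows the generation logic: environmental conditions of
year *t* are matched with the temporal estimate labelled *t*+1 (the
generation those conditions recruited) and with the single-sample LD
estimate labelled *t*+2 (which measures that cohort's parents). Era
comparisons split at the first supplementation year (2004, inclusive by
default) and use Mann–Whitney U; reach comparisons use Kruskal–Wallis with
midrank ties; the broodstock association is an OLS regression of LD-N~e~ on
`4 Nm Nf / (Nm + Nf)` per captive lot.

## The simulator and what passing its tests shows

The generator is a monoecious Wright–Fisher population. Each generation,
every potential parent receives a gamma-distributed reproductive weight and
offspring draw two parents with probability proportional to weight; the
weight CV sets the family-size overdispersion and thereby N~e~/N~c~
(shape = Ne/(Nc − Ne); equal weights recover the ideal case). Gamma weights
were chosen over literal negative-binomial family sizes because a mean-2
negative binomial cannot reach family-size variance below 4 and therefore
cannot span the range from ideal to sweepstakes reproduction; the resulting
family sizes are negative-binomial-like mixed multinomials. Realized
effective size is booked per generation from realized family sizes,
$N_e = (N\bar k - 1)/(\bar k - 1 + V_k/\bar k)$, and serves as the truth for
recovery tests. mtDNA is a single non-recombining maternal locus; mutation
is off by default at both marker types (negligible over a 12-year horizon)
but available as stepwise (microsatellite) and infinite-alleles (mtDNA)
knobs.

Supplementation replaces a fraction φ of the breeding pool with members of
captive lots bred from `Nm + Nf` broodstock by paired or communal matings.
Broodstock are drawn either from a sliding earlier generation
(`broodstock_lag`) or from one fixed generation (`broodstock_source_gen`) —
the latter emulating a hatchery program whose captive pool was founded from
a single large pre-decline egg collection and reused for years.

Scenario presets define the study conditions once:

* `isolated_wf`: Nc = 1000, target Ne = 100, 9 loci × 8 alleles
  (Dirichlet(1) initial frequencies), Plan I samples of 50 at generations 0
  and 2 — the estimator-recovery design (200 replicates for the temporal
  estimators; the LD check uses the same generator with target Ne = 200 and
  S = 100 after eight generations so drift LD is at quasi-equilibrium).
* `wild_decline`: a census crash 10^5 → 10^3 with Ne/Nc = 0.01 (exploratory;
  not part of the validation battery).
* `supplemented_sink`: census decline 2000 → 600 with wild sweepstakes
  recruitment (Ne target falling to 60), supplementation rising to φ = 0.8
  but fluctuating year to year, lots of 50 from 15-pair broodstocks drawn
  from the persistent generation-2 pool. The fluctuating origin composition
  of successive cohorts, drawn from sources that have drifted apart,
  inflates temporal allele-frequency change far beyond what the (large)
  parental count implies — so LD-based N~e~ exceeds temporal N~e~, the
  source–sink signature. The validation asserts the direction of that
  inequality over 100 replicates, not its magnitude.

What the simulator does *not* emulate: age structure and overlapping
generations (the G/C rescaling is applied downstream instead), spatial
reach structure and downstream larval transport, marker mutation at
realistic rates, genotyping error and null alleles. Passing the recovery
tests therefore shows the estimators are correctly implemented and
approximately unbiased under clean Wright–Fisher conditions at study-like
sample sizes — not that field estimates are unbiased in the presence of age
structure, migration, or scoring artifacts.

## Numerical conventions and problem sizes

Fixed seeds make every stochastic routine reproducible (`set.seed` on entry;
the pipeline derives per-stage seeds from its `seed` argument). Exact-test
ties count toward the p-value; permutation p-values include the observed
arrangement. The test battery runs at deliberately desk-sized problems —
200 replicates for temporal-estimator recovery, 100 for LD and for the
source–sink direction, 1000 for test-calibration checks with 150 shuffles
or 99 permutations each — sizes at which median-recovery tolerances of
±20–30% have comfortable Monte-Carlo margins while the whole suite stays in
the low minutes.

## Known limitations

The pseudo-likelihood estimator's grid bounds cap detectable N~e~ (by
design: a maximum at the bound reports +∞). The LD inversion assumes random
mating and unlinked loci; physically linked markers would need a different
expectation. The AMOVA assumes every individual contributes two gene copies
at retained loci, so oddly ploid data are out of scope. The resampling
correction treats loci as exchangeable when averaging; strongly
heterogeneous locus sets would warrant per-locus reporting (which is
emitted, but the headline numbers are across-locus means). Broodstock
records enter only through `4NmNf/(Nm+Nf)`; unequal family contributions
within a lot are modelled in the simulator but not estimable from census
records alone.
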