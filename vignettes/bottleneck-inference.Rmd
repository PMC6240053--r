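---
title: "Inferring recent population bottlenecks from microsatellites: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring recent population bottlenecks from microsatellites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msatabc)
```

This vignette is the package's own account of the science it implements:
the demographic models and their priors, the mutation-model conventions,
how the ABC machinery and the heterozygosity-excess test are put together,
the numerical choices that were genuinely open, and what the package's
green tests do and do not establish.

## The inference problem

A single contemporary sample of diploid microsatellite genotypes is all the
data. The question is whether the sampled population passed through a
severe, recent reduction in effective size — of the kind caused by a few
decades of intense exploitation — and if so, how severe. Because a single
sample carries no explicit time axis, all temporal information must come
from the shape of present-day variation: how many alleles survive, how they
are spread over the size lattice, and how heterozygosity compares with what
the allele count implies at equilibrium.

## Demographic models

Both models describe a single, unstructured population whose diploid size
is piecewise constant in time; every size change is instantaneous.

* **Bottleneck model** (7 parameters): backwards from the present the size
  is `Ne` until `t_bot_end`, `Ne_bot` between `t_bot_end` and
  `t_bot_start`, and `Ne_hist` earlier. Priors: `Ne`, `Ne_hist` ~
  lognormal(meanlog 10.5, sdlog 1) — median about 36,000, concentrating
  mass between thousands and tens of thousands with occasional draws in
  the hundreds of thousands; `Ne_bot` ~ U[1, 500]; `t_bot_start` ~
  U[10, 70] and `t_bot_end` ~ U[1, 30] generations before present;
  `mu` ~ U[1e-5, 1e-4] per locus per generation; `gsm_par` ~ U[0, 0.3].
* **Non-bottleneck model** (5 parameters): `Ne` until `t_hist` ~ U[10, 70],
  `Ne_hist` earlier; the remaining priors are shared.

All priors are independent, so the current size can be larger or smaller
than the historical one: both models capture longer-term growth or decline,
and only the bottleneck model adds a short, severe crash. The overlapping
time priors admit draws with `t_bot_end >= t_bot_start`; such an inverted
bottleneck is meaningless, and `sample_priors()` rejects and redraws the
pair jointly, which preserves both marginal supports.

### Size units

The package distinguishes two conventions, because the literature this
design follows mixes them silently. A `demographic_params()` object built
directly defaults to `size_units = "diploid"`: sizes count diploid
individuals, the pairwise coalescence rate is 1/(2N) per generation, and
for two gene copies E[TMRCA] = 2N. Prior draws (`sample_priors()`,
`build_reference_table()`, the synthetic panel) instead carry
`size_units = "gene_copies"`: the numbers above are interpreted as numbers
of gene copies (rate 1/N), which is the input convention of the
continuous-time coalescent simulator family these priors were calibrated
in — simulator parameter files specify "effective sizes (number of
genes)". The distinction matters: under the gene-copies reading every size
acts at twice the drift of the diploid reading, and the package's
cross-validation reproduces the reference classification rates only under
it. The choice is explicit in every parameter object and printable, and
either convention is available everywhere.

## Mutation models

Microsatellites mutate mainly by gaining or losing one repeat unit, with
occasional multistep jumps. Every model in the package draws a signed step
per mutation with equiprobable direction:

* `smm_model()` — strict stepwise: every step is one unit.
* `tpm_model(p_single, variance)` — two-phase: with probability `p_single`
  the step is one unit, otherwise its magnitude is geometric on {1, 2, ...}
  with parameter `q` solving `(1-q)/q^2 = variance` (the conventional
  "variance of the geometric distribution"; the default 0.30 gives
  q = 0.8054). Presets TPM70/80/90 (70/80/90% single-step) are bundled as
  `het_excess_presets()`.
* `gsm_model(gsm_par)` — generalized stepwise: magnitude geometric with
  P(S = s) = (1-g)·g^(s-1), so `gsm_par = g` is literally the proportion of
  multistep (S >= 2) mutations. This is the convention used for the ABC
  prior on `gsm_par`; it is isolated in one place (`mutation_model`
  objects) because other programs parameterise the same geometric
  differently.

Mutations are dropped on the genealogy as a Poisson process of intensity
`mu` per generation per branch; allele states propagate from a fixed root
state (100 repeat units by default) and are floored at one repeat unit. No
upper allele-size boundary is imposed; none was specified for the design
this mirrors, and at the mutation rates involved the unbounded random walk
stays within realistic fragment sizes.

## Summary statistics and their standardisation

Five statistics, each the mean across loci: allele count `k`, allele size
range `r` (in repeat units), Nei's gene diversity `He` (the unbiased
estimator 2n/(2n-1)·(1 - sum p²) on gene copies by default; the plug-in
version is a switch because the original analysis code's choice is not
documented), the M-ratio `M = k/(r+1)`, and the proportion of alleles at
sample frequency strictly below 5% (`lfa`). `M` lives on the repeat-unit
lattice, so base-pair data are first converted by `to_repeat_units()`,
which estimates each locus's motif as the modal gap among sorted distinct
allele sizes and maps off-lattice alleles to the nearest unit — an explicit
approximation for published panels with imperfect periodicity.

Observed datasets of any size are made comparable with the simulated
40-individual reference datasets by resampling 40 individuals with
replacement 1000 times and averaging (`resampled_stats(what = "abc")`);
datasets smaller than the target are used whole. Cross-species diversity
reporting uses the same mechanism at 10 individuals with 2.5/97.5
percentile intervals. Resampling with replacement duplicates some
individuals — a negligible distortion for panels of hundreds of
individuals (the intended use; the reference panel median is 253), but for
datasets barely above the resampling size it depresses allele counts
relative to the simulated references. Individuals missing a genotype are
excluded from that locus only.

## The ABC engine

* **Distance and rejection.** Euclidean distance on the five statistics,
  each scaled by its median absolute deviation over the whole reference
  table; a statistic with zero MAD is dropped from the distance with a
  warning. `abc_reject()` accepts the `ceiling(tolerance × rows)` closest
  rows with a deterministic index tie-break — at the full scale this
  design targets, a tolerance of 5e-4 retains 5000 of 1e7 rows per model.
* **Model choice.** The rejection estimate is the accepted-label
  proportion. The regression estimate fits a weighted logistic regression
  of the model indicator on the scaled statistics over the accepted rows
  (Epanechnikov weights 1-(d/d_max)²) and evaluates it at the observation;
  with two models the multinomial and binomial logistic coincide, which is
  why `stats::glm.fit` suffices. Non-convergence or separation (common
  when classification is near-certain) falls back to the rejection
  proportions, flagged in the returned object.
* **Parameter estimation.** Local-linear adjustment: weighted least
  squares of each transformed parameter on the scaled statistics among the
  accepted rows of the chosen model (the tolerance applies within that
  model's rows), each draw replaced by the fit at the observation plus its
  residual. The lognormal sizes (`Ne`, `Ne_hist`) are log-transformed;
  every bounded-uniform parameter (`Ne_bot`, times, `mu`, `gsm_par`) is
  logit-transformed to its prior support. A pure log transform for
  `Ne_bot` and `mu` was considered and rejected: it cannot guarantee that
  adjusted draws respect the upper prior bound, and support containment
  after back-transformation is a contract of the posterior object. A
  singular design triggers a small ridge fallback, flagged.
* **Point estimates.** Mode = argmax of a Gaussian kernel density
  (Silverman bandwidth) over the weighted draws; median and 95% interval
  from weighted quantiles. A constant sample collapses to that constant.
* **Diagnostics.** `cv_model_choice()` reports both the mean posterior
  probability per true model and the correct-classification (argmax) rate
  — the two are often conflated; the rate is what "correctly classified
  X% of the time" means. `cv_param_error()` uses rejection-only posterior
  medians and normalises squared error by the variance of the true values,
  so 1 means "no better than the prior". `goodness_of_fit()` compares the
  observed median accepted distance with its null distribution over
  pseudo-observations from the model. `posterior_predictive()` re-simulates
  from jointly sampled adjusted draws, preserving cross-parameter
  dependence.

## The heterozygosity-excess test

For each polymorphic locus the observed gene diversity is compared with the
equilibrium distribution of gene diversity conditional on the observed
allele count `k` and sample size, under a chosen mutation model.
`heq_simulate()` produces that conditional distribution in two steps: a
stochastic bisection first calibrates the scaled mutation rate theta so
that the mean simulated allele count equals `k`; loci are then simulated at
that theta and replicates with exactly `k` alleles are kept. This rejection
conditioning samples the stationary law of He given K = k up to the weak
residual dependence of He | K on theta.

An alternative conditioning — adding mutations to a fixed genealogy one at
a time and stopping the first time the allele count reaches `k` — was
implemented first and rejected on measurement: first-hit stopping selects
minimal-mutation histories with skewed frequency spectra, biasing H_eq low
(a stable population then shows 61% of loci "in excess") and, because
stepwise mutation lets the allele count overshoot and merge, it wastes
almost all of its placement budget. The calibrate-and-reject scheme
restores calibration (51–56% at equilibrium) at a thirtieth of the cost.

Two properties of the test are worth stating plainly. First, even with
perfect conditioning the expected proportion of loci in excess for a
stable population is slightly above one half (about 0.55 at theta near 1),
because the conditional distribution of He given K is left-skewed, so He
exceeds its conditional mean more often than not; the idealised "0.5 for a
stable population" is an approximation, and the original sign-test
formulation corrects for exactly this. Second, the equilibrium H_eq given
k is *highest* under the strict SMM and decreases as multistep mutations
become more common; the proportion of loci in excess therefore increases
from SMM through TPM90/80/70 on the same data — matching the reference
ordering of the cross-species means.

The per-locus excess decision compares He with the *mean* of the H_eq
draws by default (the median is a switch). The test is a detector of
*ongoing or just-ended* declines: a century-old crash that reduced a
population to a handful of breeders for many generations re-equilibrates,
and its heterozygosity-excess fades even while the ABC allele-deficit
signal remains strong. The two measures are complementary, not redundant.

## Synthetic panels

`generate_panel()` emulates a pooled multi-species study: per-species
dimensions are drawn from truncated lognormal samplers centred on the
empirical medians (253 individuals in [16, 2386]; 14 loci in [5, 35]), a
configurable fraction of species (default 11/30) is bottlenecked, and
parameters come from the standard priors unless fixed. Everything is
determined by one master seed, and the truth manifest (JSON) records the
generating parameters per species. What the generator does *not* emulate:
population structure, missing-data patterns beyond uniform random
missingness (default rate 0), null alleles, allele-calling error, and
linkage. A green end-to-end test therefore establishes that the inference
machinery recovers the truth of *this* idealised world — single panmictic
populations genotyped without error — not that it is robust to the
artefacts of real panels; the HWE filters and largest-cluster rerun hooks
exist precisely because real data violate these assumptions.

## Hardy–Weinberg QC

Per locus: a chi-square test over all genotype classes against
Hardy–Weinberg expectations from sample allele frequencies (no pooling of
rare classes — the companion Monte-Carlo test is the robust one where
expected counts are small; whether the original analysis pooled is
undocumented), and an exact test that permutes gene copies among
individuals and ranks configurations by their Levene conditional
probability, with p = (1 + hits)/(n_mc + 1) so it is never exactly zero.
A locus is *deviating* only if both tests are significant after Bonferroni
correction — table-wide across all testable loci of the analysis run by
default, per-dataset as an option; monomorphic loci are untestable and
excluded from the correction denominator.

## Numerical choices and degenerate inputs

* Rejection tie-breaks are by row index; results are bit-reproducible for
  a fixed seed on one platform.
* Zero-MAD statistics drop out of distances with a warning rather than
  producing NaN.
* A monomorphic locus has He = Ho = 0 and M = 1 by definition, not by
  error; loci with all calls missing are invalid in a dataset and
  untestable in QC.
* Logit transforms clamp at 1e-9 from the support boundaries.
* `heq_simulate()` errors, with diagnostics, if the target allele count
  cannot be reached within its attempt budget (e.g. k close to the sample
  size under a low-homoplasy model).
* Every stochastic function takes an optional integer seed and restores
  the caller's RNG state, so seeded calls are pure.

## Known limitations

* Single population, no migration, no structure: the ABC models will
  misattribute structure-induced allele deficits to bottlenecks; the
  external-cluster subsetting hook is the mitigation.
* Desk-scale reference tables (1e5–3e5 rows per model) reproduce the
  full-scale cross-validation rates to within a few percentage points but
  not exactly; model-choice accuracy at the reference scale of 1e7 rows
  per model is approached from below.
* The conditional H_eq simulation inherits the weak theta-dependence of
  He | K; no attempt is made to integrate over a theta prior.
* Posterior modes from kernel densities are bandwidth-dependent;
  Silverman's rule is the fixed choice.
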