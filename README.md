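# msatabc

Coalescent ABC inference of recent population bottlenecks from
microsatellite genotypes.

## The problem

Commercial exploitation, habitat loss and other recent pressures can crash a
population's effective size (N<sub>e</sub>) within a few tens of
generations. Long after census numbers recover, such a bottleneck leaves a
transient genetic footprint in neutral markers: allelic states are lost
faster than gene diversity, depressing the M-ratio *M* = *k*/(*r*+1) (allele
count over allele-size range) and creating a temporary *excess* of
heterozygosity relative to a stable population with the same number of
alleles. `msatabc` infers the presence and strength of such declines from a
single contemporary sample of diploid microsatellite genotypes, the standard
situation for historical wildlife panels where no time series exists.

Two complementary inferences are implemented:

1. **Coalescent ABC model choice and estimation.** A single-population
   continuous-time coalescent with piecewise-constant size and a generalized
   stepwise mutation (GSM) model simulates reference datasets under two
   demographies: a *bottleneck* model (sizes N<sub>e</sub>,
   N<sub>e_bot</sub> ~ U[1, 500], N<sub>e_hist</sub>, with instantaneous
   changes at t<sub>bot_end</sub> ~ U[1, 30] and t<sub>bot_start</sub> ~
   U[10, 70] generations ago) and a *non-bottleneck* model (N<sub>e</sub> to
   N<sub>e_hist</sub> at t<sub>hist</sub> ~ U[10, 70]); sizes are lognormal
   (meanlog 10.5, sdlog 1), mu ~ U[10⁻⁵, 10⁻⁴] per locus per generation, and
   GSM<sub>par</sub> ~ U[0, 0.3] is the proportion of multistep mutations.
   Five summary statistics (means across loci of allele count, allele size
   range, Nei gene diversity, M-ratio, and the proportion of alleles below
   5% frequency) feed rejection ABC (MAD-scaled Euclidean distance),
   multinomial-logistic model choice (posterior bottleneck probability
   p<sub>bot</sub>), and Beaumont-style local-linear parameter adjustment.
   Leave-one-out cross-validation, prior-predictive goodness of fit, and
   posterior predictive checks quantify what the method can and cannot
   resolve.
2. **Heterozygosity-excess test** (Cornuet–Luikart): per locus, observed
   gene diversity is compared with the equilibrium expectation
   H<sub>eq</sub> conditional on the observed allele count, simulated under
   SMM, two-phase (TPM 70/80/90% single-step, geometric variance 0.30) or
   GSM mutation. The fraction of loci in excess (prop<sub>het-exc</sub>) is
   0.5 for a stable population, above it after a recent decline, below it
   after an expansion.

A synthetic-data module generates whole multi-species panels (16–2386
individuals, 5–35 loci per species, configurable bottlenecked fraction) with
a JSON truth manifest, so the entire pipeline is testable without any
external data. GenePop reading/writing, Hardy–Weinberg QC (chi-square +
Monte-Carlo exact tests, Bonferroni correction), and resampling-standardised
diversity statistics round out the per-species workflow.

## Worked example

A small synthetic bottlenecked species (48 individuals, 9 loci; generated
under N<sub>e_bot</sub> = 60 with the bottleneck ending 8 generations ago)
ships with the package:

```r
library(msatabc)
ds <- read_genepop(system.file("extdata", "synthetic_bottleneck.gen",
                               package = "msatabc"),
                   encoding = "repeat_units")
ds
#> Microsatellite genotype dataset: synthetic_bottleneck_species
#>   48 individuals x 9 loci; allele encoding: repeat_units
#>   missing genotypes: 0.0%

round(mean_sumstats(ds), 3)
#>     k     r    He     M   lfa
#> 2.556 3.333 0.434 0.672 0.037
```

The depressed M-ratio (0.67) already hints at lost allelic states. The
heterozygosity-excess test under the TPM80 mutation model:

```r
prop_het_excess(ds, tpm_model(0.8), n_sims = 2000, seed = 11)
#> Heterozygosity-excess test (TPM, 80% single-step; 2000 simulations/locus)
#>   prop_het_exc = 0.875 over 8 polymorphic loci (0.5 = stable)
```

7 of 8 polymorphic loci show more diversity than a stable population with
the same allele counts would — the signature of a recent decline. ABC model
choice against a (here deliberately small) reference table of 20,000
simulations per model, with the observation standardised by resampling 40
individuals:

```r
tab <- build_reference_table(20000, seed = 1)      # ~10 s; scale up for real use
obs <- resampled_stats(ds, n_ind = 40, n_reps = 1000, what = "abc", seed = 13)
model_posterior(obs, tab, tolerance = 0.01)
#> ABC model choice (rejection, tolerance 0.01)
#>   p(bottleneck)     = 0.9975
#>   p(non-bottleneck) = 0.0025
```

(With 399 of 400 accepted simulations coming from the bottleneck model the
logistic regression is degenerate, so the method falls back to rejection
proportions and says so.) Parameter estimation under the preferred model:

```r
param_posterior(obs, tab, model = "bottleneck", tolerance = 0.025)
#> ABC posterior sample (bottleneck model): 500 draws, tolerance 0.025
#>    parameter      mode    median     lower     upper
#>       Ne_bot 6.679e+01 7.687e+01 1.891e+01 2.184e+02
#>           mu 8.041e-05 5.767e-05 1.371e-05 9.749e-05
#>      ...
```

The posterior mode for the bottleneck size, 67, sits close to the
generating value of 60, with a 95% credible interval of [19, 218]. The
full per-species chain — HWE QC, diversity standardisation, model choice,
estimation, goodness of fit, posterior predictive check and the
heterozygosity-excess panel — is one call:
`analyze_species(ds, tab, seed = 1)`, and `panel_report()` aggregates many
species into one table with cross-species summaries.

## Acceptance script

`scripts/acceptance.R` recomputes the package's method-validation numbers
from scratch: it builds a reference table of 3 × 10⁵ simulations per
demographic model under the standard priors (datasets of 40 individuals and
10 loci), runs leave-one-out cross-validation of the ABC model choice and
reports the correct-classification rate for each model (in percent), and
simulates constant-size species to measure the calibration of the
heterozygosity-excess test (expected proportion of loci in excess for a
stable population). Run it from the repository root against the installed
package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It finishes in about 3 minutes on one CPU and writes one JSON object with
one entry per quantity.

## Package layout

- `R/genepop.R`, `R/dataset.R`, `R/hwe.R` — genotype IO, container, QC
- `R/sumstats.R` — diversity statistics and resampling standardisation
- `R/priors.R`, `R/mutation.R`, `R/coalsim.R`, `src/coalsim.cpp` — priors,
  mutation models, and the compiled coalescent simulator
- `R/abc.R`, `R/cv.R` — ABC engine and its diagnostics
- `R/het_excess.R` — the heterozygosity-excess test
- `R/synthetic.R`, `R/pipeline.R` — synthetic panels and the per-species /
  panel orchestration
- `vignettes/bottleneck-inference.Rmd` — the methods vignette (model
  assumptions, parameter conventions, design choices, limitations)
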