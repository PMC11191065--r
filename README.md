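# lfsrisk

Mendelian risk prediction for families with Li-Fraumeni syndrome (LFS) —
the hereditary cancer syndrome caused by deleterious germline mutations in
*TP53* — together with the validation machinery needed to judge such
predictions on family data of clinical (rather than research) quality.

The package is written for statistical genetics and cancer-epidemiology
researchers, and for developers of genetic-counseling decision tools. It
provides, as composable tidyverse-style functions over pedigree tibbles:

- **Carrier inference.** Exact Elston–Stewart peeling over the 3-state
  genotype factor graph turns a family's cancer history into a posterior
  probability that any member carries a deleterious *TP53* allele,
  `P(G ≥ 1 | family data)`, with test results usable as genotype clamps
  under counseling scenarios (ignore all tests / clamp the proband / use
  every test). A brute-force configuration enumerator is the built-in
  exactness oracle.
- **Cause-specific (CS) penetrance.** Competing risks — sarcoma, breast
  cancer, other cancers, death — with Weibull proportional hazards
  λ_k(t|X,Z) = Z λ0k(t) exp(β_k·{G, S, G×S}) and gamma frailty Z
  (mean 1, variance θ). The crude incidence q_k(t|X) integrates the
  frailty-marginal subdensity; Σ_k q_k(t) + S(t) = 1 holds identically.
- **Multiple-primary-cancer (MPC) penetrance.** Cancer onsets as a
  nonhomogeneous Poisson process with intensity covariates
  {G, S, G×S, D(t), G×D(t)}, where D(t) flags a prior primary. The gamma
  frailty is conjugate, giving the closed-form next-primary penetrance
  q(t|t₀,n) = 1 − [(1/θ + Λ(0,t₀)) / (1/θ + Λ(0,t))]^(1/θ+n), supported to
  the second primary.
- **Prediction.** Genotype-weighted risk curves for untested counselees
  (`predict_carrier()`, `predict_first_primary()`,
  `predict_second_primary()`), plus the Classic and Chompret clinical
  criteria as rule-based comparators and a Kaplan–Meier comparator
  penetrance.
- **Synthetic cohorts.** A generator of research-protocol-like (complete)
  and clinical-counseling-like (missingness-ridden) family cohorts:
  Mendelian genotypes with a seeded carrier lineage, phenotypes drawn from
  the CS/MPC models themselves, carrier-proband ascertainment, and
  structured age-blanking at clinical rates (53/41/4/2 percent complete /
  missing last contact / missing diagnosis age / missing both).
- **Validation pipeline.** Exclusion rules, subject grouping, midrank
  ROC/AUC, observed/expected calibration, family-resampled percentile
  bootstrap CIs, and clinical-style cohort summary tables.
- **Estimation.** Box-constrained maximum likelihood for the penetrance
  parameters on family data (peeling-based likelihood, optional
  proband-conditioning ascertainment correction), used for
  parameter-recovery verification.

See `vignettes/lfsrisk-methods.Rmd` for the models, assumptions, numerical
choices and limitations.

## Worked example

A seven-member family ships with the package: grandparents, an affected
proband (breast cancer at 28, confirmed carrier), her brother (sarcoma at
12), her partner and two young children.

```r
library(lfsrisk)
ped <- read_pedigree(system.file("extdata", "demo_family.ped",
                                 package = "lfsrisk"), "ped")

predict_carrier(ped, "6", scenario = "all_tests")
#> # A tibble: 1 × 3
#>   id     prob scenario
#>   <chr> <dbl> <chr>
#> 1 6     0.489 all_tests
```

With the mother's positive test used, her daughter's carrier probability is
essentially the Mendelian one half, shaded down slightly by eight healthy
years of her own. Ignoring all test results (pre-test counseling) the same
posterior collapses towards the population prior (about 0.0011 at allele
frequency 6e-4): with the default placeholder penetrance parameters, this
small family's history alone cannot overcome a 1-in-833 prior.

```r
predict_first_primary(ped, "6", ages = c(20, 40, 60))
#> # A tibble: 12 × 3
#>      age outcome     prob
#>  1    20 sarcoma 0.0372
#>  2    40 sarcoma 0.0777
#>  3    60 sarcoma 0.0936
#>  4    20 breast  0.00925
#>  5    40 breast  0.0499
#>  6    60 breast  0.0949
#>  7    20 other   0.0384
#>  8    40 other   0.157
#>  9    60 other   0.259
#> ...
```

Each value is the probability that the named outcome occurs first, by that
age, mixing carrier and wildtype CS penetrances by the carrier posterior —
e.g. a 15.7% chance of a first primary in the "other cancers" group by age
40. The proband's own second-primary risk and the clinical criteria:

```r
predict_second_primary(ped, "3", ages = c(40, 50))$prob
#> [1] 0.869 0.973
as.logical(chompret_criteria(ped))   # TRUE  (breast cancer before 31)
as.logical(classic_criteria(ped))    # FALSE (no sarcoma in the proband)
```

Validation runs on whole cohorts; on a synthetic clinical-style cohort:

```r
cfg <- cohort_config(n_families = 40, seed = 9, test_prob = 0.4,
                     missingness = "ccb")
coh <- simulate_cohort(cfg)
run_mutation_validation(coh, "A", params = cfg$mpc, f = cfg$f, B = 200)
#> <lfs_validation_report> task: mutation-A
#>   AUC and O/E with 95% family-bootstrap CIs, TPR/FPR at cutoff 0.20
```

Reports expose `tidy()`, `glance()` and `autoplot()` (ROC staircase);
risk curves and KM fits have `autoplot()` methods too.

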