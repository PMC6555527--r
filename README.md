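# diallelGP

Genomic analysis of incomplete half-diallel trials: combining-ability
mixed models with marker-based kernels, genetic parameters, heterosis and
treatment-responsiveness summaries, and two-stage genomic prediction of
untested single-cross hybrids.

The package targets greenhouse experiments in which single crosses from a
diallel among inbred parents are evaluated under two treatments — a
nutrient-stress control and the same stress plus a plant growth-promoting
inoculant — across years, blocks and countertops. Typical questions:

* How much of the variation is general (GCA) versus specific (SCA)
  combining ability, and how heritable is the trait?
* Which hybrids show strong heterosis, and which respond most (or least)
  to inoculation?
* How accurately can untested hybrids, or hybrids tested only in some
  environments, be predicted from parental genotypes?

## The model

For a trait measured on hybrid records, the joint analysis fits

```
y = Xb + Z_G u_G + Z_H u_H + Z_GE u_GE + Z_HE u_HE + Z_GI u_GI + Z_HI u_HI + e
```

with fixed year, block-within-year, countertop-within-block, inoculation
and year-by-inoculation effects, and random effects:

* `u_G ~ N(0, s2_G * G)` — per-parent GCA with genomic kernel `G`
  (VanRaden `GB` or Gaussian `GK`); each record loads on **both** parents
  of its hybrid;
* `u_H ~ N(0, s2_H * I)` — per-cross SCA;
* year and inoculation interactions of both terms.

Genetic parameters follow the diallel conventions `s2_a = 4 s2_G`,
`s2_d = 4 s2_H`, narrow/broad-sense heritability and Baker's ratio
`2 s2_G / (2 s2_G + s2_H)`. Estimation is by EM-REML on eigen-whitened
random terms, with a compiled Gibbs sampler (`gibbs_vc()`) as the Bayesian
counterpart; the sampler's missing-value augmentation is also the
prediction engine. Fixed effects get Wald chi-square tests; random terms
get boundary-corrected likelihood-ratio tests (`0.5 chi2_0 + 0.5 chi2_1`).

See the vignette (`vignettes/diallel-genomic-prediction.Rmd`) for the full
methods write-up, including the hybrid SCA kernel, the Hadamard-product
interaction covariances, the heterosis/responsiveness pipeline and the
CV1/CV2 cross-validation schemes.

## Worked example

Simulate a small study, build the kernel, and fit the joint diallel model:

```r
library(diallelGP)

cfg <- sim_config(n_parents = 8, n_markers = 500, n_crosses = 16,
                  n_blocks = 2, seed = 42)
study <- simulate_study(cfg, include_parents = TRUE)
study
#> <simulated_study> 8 parents, 16 crosses, 192 phenotype records

ph <- study$phenotypes[study$phenotypes$parent1 != study$phenotypes$parent2, ]
fit <- fit_joint_diallel(ph, study$G, study$design)
tidy(fit)
#> # A tibble: 7 x 5
#>   term     variance boundary    lrt  p_value
#>   <chr>       <dbl> <lgl>     <dbl>    <dbl>
#> 1 GCA        6.36   FALSE     6.60   0.00509
#> 2 SCA        0.0222 FALSE     0      1
#> 3 GCAxY      0.320  FALSE     0.481  0.244
#> 4 SCAxY      1.14   FALSE     0.343  0.279
#> 5 GCAxI      0.740  FALSE     1.88   0.0851
#> 6 SCAxI      0.0808 FALSE     0      1
#> 7 residual  18.4    FALSE    NA     NA

genetic_params(fit)
#> # A tibble: 1 x 10
#>   trait analysis sigma_G2 sigma_H2 sigma_e2 sigma_a2 sigma_d2    h2    H2 baker
#>   <chr> <chr>       <dbl>    <dbl>    <dbl>    <dbl>    <dbl> <dbl> <dbl> <dbl>
#> 1 RV    joint        6.36   0.0222     18.4     25.4   0.0886 0.579 0.581 0.998
```

Heterosis and responsiveness run off least-squares adjusted means:

```r
am <- adjusted_means(study$phenotypes)
het <- heterosis(am, study$design)
deltas <- delta_response(am, control = "Nstress", inoculated = "NstressAzo")
```

Genomic prediction uses stage-one adjusted values per environment and a
Gibbs-fitted kernel model under CV1 (untested hybrids) or CV2 (hybrids
tested in some environments):

```r
adj <- stage1_adjust(ph)
one <- dplyr::filter(adj, treatment == "Nstress", trait == "RV")
cv1 <- run_cv(one, study$G, study$design, variant = "GB",
              plan = cv_plan("CV1", k_folds = 5, n_repeats = 10, seed = 1))
cv1$summary
autoplot(cv1)
```

## License

MIT (see `LICENSE`).
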