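---
title: "Genomic diallel analysis and hybrid prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic diallel analysis and hybrid prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(diallelGP)
```

This vignette documents the statistical models implemented in `diallelGP`,
the assumptions behind them, and the numerical choices made by the engines.
The package targets greenhouse diallel studies of single-cross hybrids
evaluated under two treatments — a stress control and the same stress plus a
plant growth-promoting inoculant — with the goal of partitioning combining
ability variances, quantifying heterosis and responsiveness, and predicting
untested hybrids from genomic kernels.

## The data layout

A study consists of

* a panel of fully homozygous inbred parents genotyped at biallelic SNPs
  (dosages 0/2),
* an incomplete half-diallel of single crosses (no selfs, no reciprocals;
  parent pairs are stored in canonical lexicographic order),
* phenotypes recorded per pot in a nested design: years, blocks within
  years, countertops within blocks, and the two treatments.

`sim_config()` / `simulate_study()` generate such studies synthetically. The
default configuration mirrors the design the package targets: 19 parents,
118 of the 171 possible crosses, 2 years x 3 blocks x 2 countertops x 2
treatments, one plant per pot, about 1,400 hybrid records plus parental
line records. The default true variance components are the joint-analysis
estimates for root volume from the motivating study, so that default
simulations live on a realistic scale. The generator is deliberately
simple where simplicity does not matter for the methods: allele frequencies
are drawn independently per marker (no linkage disequilibrium), hybrids are
exact Mendelian combinations of homozygous parents, and residuals are
homoscedastic Gaussian. An optional two-subpopulation mode adds mild
allele-frequency divergence, and a missing-call rate exercises the marker
QC path.

```{r}
cfg <- sim_config(n_parents = 8, n_markers = 500, n_crosses = 16,
                  n_blocks = 2, seed = 42)
study <- simulate_study(cfg, include_parents = TRUE)
study
```

## Genomic kernels

Let $W$ be the marker matrix centered by twice the allele frequency and
scaled by $\sqrt{2p(1-p)}$ (`standardize_markers()`). Two parental kernels
are provided:

* **GB** (`compute_GB()`): the linear (VanRaden) kernel $G_B = WW'/m$;
* **GK** (`compute_GK()`): the Gaussian kernel
  $G_K = \exp(-h\,d^2_{ii'})$ with $d^2$ the squared Euclidean distance
  between genotype rows of $W$ and bandwidth $h$.

For GK the default `scale = "mean_offdiag"` divides the squared distances
by their mean off-diagonal value, so `h = 1` gives a comparable decay rate
at any marker count; `scale = "none"` applies the literal formula. The
diagonal is exactly one.

The hybrid-level SCA kernel (`build_H()`) follows the single-cross
covariance rule: for crosses $(i,j)$ and $(i',j')$,
$H_{(ij),(i'j')} = C_{ii'}\,C_{jj'}$, where $C$ is either parental kernel.
Because reciprocals are not modeled, parent pairs are canonically sorted
before this rule is applied. The multi-environment interaction covariances
(`build_VG_VH()`) are record-level Hadamard products
$V_G = (Z_G\,C\,Z_G')\circ(Z_EZ_E')$ and
$V_H = (Z_H\,H\,Z_H')\circ(Z_EZ_E')$: two records covary through the
genomic kernel only if they share the environment.

```{r}
M <- qc_markers(study$parents)
GB <- compute_GB(M)
H <- build_H(GB, study$design)
GB
H
```

## The joint diallel mixed model

For one trait, `fit_joint_diallel()` fits

$$y = X\beta + Z_G u_G + Z_H u_H + Z_{GE}u_{GE} + Z_{HE}u_{HE}
      + Z_{GI}u_{GI} + Z_{HI}u_{HI} + \varepsilon$$

with fixed year, block-within-year, countertop-within-block, inoculation
and year-by-inoculation effects, and random effects

* $u_G \sim N(0, \sigma^2_G\,G)$ — GCA, with $Z_G$ mapping each record to
  *both* parents of its hybrid;
* $u_H \sim N(0, \sigma^2_H\,I)$ — SCA per cross;
* year and inoculation interactions with Kronecker covariances
  $I \otimes G$ (GCA side) and identity (SCA side).

`fit_individual_diallel()` fits the same model within one treatment,
without the inoculation terms. Fixed effects are tested by Wald chi-square
statistics on the REML-based covariance of the estimates
(`wald_fixed()`); each random term is tested by a likelihood-ratio test
against the refitted reduced model (`lrt_random()`).

### Genetic parameters

`genetic_params()` converts GCA/SCA/residual variances into
$\sigma^2_a = 4\sigma^2_G$, $\sigma^2_d = 4\sigma^2_H$,
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_d + \sigma^2_\varepsilon)$,
$H^2 = (\sigma^2_a + \sigma^2_d) /
(\sigma^2_a+\sigma^2_d+\sigma^2_\varepsilon)$ and Baker's ratio
$2\sigma^2_G / (2\sigma^2_G + \sigma^2_H)$. The arithmetic is exact; the
package ships a reference table of published maize diallel variance
components (`inst/extdata/reported_variance_components.csv`) whose printed
heritabilities are reproduced at two decimals:

```{r}
ref <- readr::read_csv(
  system.file("extdata", "reported_variance_components.csv",
              package = "diallelGP"),
  show_col_types = FALSE)
genetic_params(ref)[, c("trait", "analysis", "h2", "H2", "baker")]
```

## Numerical engines

### Eigen-whitening

Every random term $u_k \sim N(0, \sigma^2_k K_k)$ is reparameterized
through the eigendecomposition $K_k = U D U'$: with
$T = U_+ D_+^{1/2}$ over the positive eigenvalues, $u_k = T\alpha_k$ and
$\alpha_k$ is iid normal. This serves both engines with one
representation and transparently handles rank-deficient covariances — the
centered genomic kernel (rank $n-1$ by construction) and the record-level
$V_G$, $V_H$ matrices (rank bounded by parents x environments) simply
contribute fewer whitened columns.

### EM-REML (`fit_reml()`)

Variance components are estimated by EM iterations on the mixed-model
equations of the whitened terms. The EM updates are sums of squares plus
trace terms, so estimates are nonnegative by construction and the
restricted log-likelihood is non-decreasing (the trace is returned and
tested). Components that collapse to numerical zero are reported with a
`boundary` flag rather than being silently dropped. With
`constrain = FALSE` the EM solution is refined by a direct Nelder-Mead
maximization of the restricted likelihood that permits negative
components, as some REML software reports near boundaries; the total
covariance must stay positive definite.

The boundary-corrected LRT refers $2(\ell_f - \ell_r)$, floored at zero,
to the 50:50 mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; the p-value is
$P(T \ge t)$ under the mixture, which equals 1 at $t = 0$ and
$\tfrac12 P(\chi^2_1 \ge t)$ otherwise.

### Gibbs sampler (`gibbs_vc()`)

The Bayesian counterpart is a scalar Gibbs sampler (compiled C++) with
flat priors on fixed effects and scaled-inverse-chi-square conditionals
for the variances, using the whole-genome-regression prior convention:
`df0` degrees of freedom and scales chosen so a fraction `R2` of the
phenotypic variance is split equally across the random terms. Missing
responses are treated as unobserved records and imputed each iteration;
the posterior mean of the linear predictor at those rows is the model's
genomic prediction. The sampler draws through R's RNG, so runs are
reproducible under `set.seed()`. The package's analysis default is a
50,000-iteration chain with 5,000 burn-in; cross-validation uses a
scaled-down 6,000/1,000 profile, which agreement checks against REML show
to be adequate for posterior means of variance components at these data
sizes.

```{r}
ph <- study$phenotypes[study$phenotypes$parent1 !=
                         study$phenotypes$parent2, ]
fit <- fit_joint_diallel(ph, study$G, study$design)
tidy(fit)
genetic_params(fit)
```

## Heterosis and responsiveness

`adjusted_means()` computes least-squares genotype means per treatment and
trait, adjusting for year, block and countertop on equal weights. Hybrids
and inbred lines are adjusted as separate sets, since they are grown as
separate experiments; inoculation never enters these models because the
means are reported per treatment. From the means,

* `heterosis()` computes $MPH = 100\,(F_1 - MP)/MP$ and
  $HPH = 100\,(F_1 - BP)/BP$ against mid- and better-parent values;
* `delta_response()` computes the inoculation response
  $\Delta = T_2 - T_1$ per hybrid and labels the bottom/top
  `round(0.15 n)` responders (ties broken deterministically by hybrid ID);
* `heterozygosity_correlations()` relates genomic heterozygosity (the
  fraction of dosage-1 loci, `heterozygosity()`) to performance and to
  $\Delta$, including the diagnostic negative correlation between
  $\Delta$ and the control-treatment means.

Degenerate cases (zero denominators, constant inputs) are flagged, not
silently dropped.

## Two-stage genomic prediction

Stage one (`stage1_adjust()`) removes block and countertop effects within
each environment by fixed-effects least squares, returning one adjusted
value per hybrid and environment. Stage two (`fit_prediction_model()`)
fits, by Gibbs sampling,

$$\bar y = Z_E\beta_E + Z_G g + Z_H h + \varepsilon,\qquad
g \sim N(0, \sigma^2_G C),\quad h \sim N(0, \sigma^2_H H)$$

with $C$ either GB or GK (variants `"GB"`, `"GK"`), optionally extended by
record-level interaction effects with covariances $V_G$ and $V_H$
(variants `"GB+GxE"`, `"GK+GxE"`).

`run_cv()` evaluates a variant under two cross-validation schemes: **CV1**
masks every environment of the validation hybrids (hybrids never tested),
**CV2** masks one random environment per validation hybrid (hybrids tested
elsewhere). Folds partition hybrids with sizes differing by at most one;
each repeat reshuffles under a deterministic per-repeat seed. Accuracy is
the Pearson correlation of predictions with held-out adjusted values,
computed within environment, averaged over environments and folds.

```{r, eval = FALSE}
adj <- stage1_adjust(ph)
one <- dplyr::filter(adj, treatment == "Nstress", trait == "RV")
cv1 <- run_cv(one, GB, study$design, variant = "GB",
              plan = cv_plan("CV1", k_folds = 5, n_repeats = 10, seed = 1))
cv1
autoplot(cv1)
```

## Conventions worth knowing

* All tabular results are tibbles; model objects have `tidy()` /
  `glance()` methods and plots are `autoplot()` / `plot_*()` functions.
* The 15% responder subsets use `round(0.15 n)` per extreme.
* `lrt_random()` reports $p = 1$ at a zero statistic (mixture
  convention).
* Kernel rank-deficiency by one (centering) is expected and silent;
  deeper deficiency triggers a jitter warning in the simulator.
* `qc_markers()` filters on call rate then minor allele frequency, and
  mean-imputes what remains, reporting every count in the `qc_report`
  attribute.
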