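---
title: "Bayesian disease mapping with the Leroux CAR prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian disease mapping with the Leroux CAR prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lerouxmap)
```

## The model

`lerouxmap` analyses region-level mortality counts for ecological
(area-level) association studies — the canonical example being the
relationship between regional medical-resource densities and acute
myocardial infarction mortality across a country's health-service areas.
The outcome is the standardized mortality ratio (SMR) of each region, and
the model is a hierarchical Bayesian Poisson regression with a spatially
structured random effect:

$$
O_i \sim \mathrm{Poisson}(\mu_i), \qquad
\log \mu_i = \log E_i + \beta_0 + x_i^\top \beta + \phi_i .
$$

Here $O_i$ is the observed death count of region $i$, $E_i$ the expected
count from indirect standardization (the offset), $x_i$ the covariates,
and $\phi_i$ a spatial random effect with the Leroux conditional
autoregressive (CAR) prior

$$
\phi \sim \mathrm{N}\!\left(0,\; \tau^2 \, Q(\rho)^{-1}\right), \qquad
Q(\rho) = \rho\,(D - W) + (1 - \rho)\,I ,
$$

where $W$ is the symmetric binary neighborhood matrix ($w_{ij}=1$ when
regions $i$ and $j$ are contiguous), $D = \mathrm{diag}(d_i)$ holds the
neighbor counts, $\tau^2 > 0$ is the spatial variance and
$\rho \in [0, 1)$ interpolates between independent effects ($\rho = 0$)
and the intrinsic CAR ($\rho \to 1$). Its full conditionals are

$$
\phi_i \mid \phi_{-i} \sim
\mathrm{N}\!\left(
\frac{\rho \sum_j w_{ij}\phi_j}{\rho d_i + 1 - \rho},\;
\frac{\tau^2}{\rho d_i + 1 - \rho}
\right),
$$

so an isolated region (an island, $d_i = 0$) keeps the proper prior
$\mathrm{N}(0, \tau^2/(1-\rho))$ — no ad hoc linking of islands is needed,
one reason to prefer the Leroux form over the intrinsic CAR. Exponentiated
coefficients $e^{\beta_j}$ are relative risks (RR) per covariate unit; an
association is called significant when the 95% credible interval of the RR
excludes 1.

### Indirect standardization

`national_rates()` pools deaths and person counts over regions within each
of 16 strata (2 sexes × 8 age bands), `expected_deaths()` applies those
rates to each region's stratum populations, and `smr()` forms
$\mathrm{SMR}_i = O_i / E_i$. When the rates come from the same table
(the default), $\sum_i E_i = \sum_i O_i$ exactly — a property the test
suite asserts. Rates from an external reference population can be supplied
instead. Regions with zero population in a stratum simply contribute
nothing to $E_i$ for that stratum. One boundary choice: published age-band
labels of the form "< 20, 21–30, …" leave age exactly 20 ambiguous; the
synthetic labels here are contiguous bands and no claim is made about any
particular study's convention.

### Spatial autocorrelation

`morans_i()` implements Moran's I with the binary (not row-standardized)
$W$, for consistency with the CAR prior. Inference is by random
permutation of the region labels (default 999 permutations, one-sided
greater, add-one-corrected p-value so $p > 0$ always); a
normal-approximation z test under randomization moments is available but
the permutation route is the default because it makes no distributional
assumption and is exactly reproducible under a seed. Isolated regions stay
in the vector: they contribute variance but no cross-product.

### Covariate screening

`vif()` computes $\mathrm{VIF}_j = 1/(1 - R^2_j)$ by least squares of each
covariate on the rest; exact dependence reports `Inf` rather than failing.
`screen_covariates()` removes the single worst covariate above the
threshold (default 2.5, the conventional cutoff in this literature),
recomputes, and repeats — one at a time, because VIFs change after each
removal. Ties break by column order; `protected` covariates are never
removed but trigger a warning if still collinear at convergence. A
threshold that would force the design below two covariates raises an error
rather than returning a trivial answer.

## The sampler

`fit_leroux()` runs a Metropolis-within-Gibbs scheme (compiled inner loop):

* **β block** — random-walk Metropolis on all coefficients jointly, prior
  $\mathrm{N}(0, 10^5)$ each. The proposal is shaped by the Poisson GLM
  covariance initially and reshaped during burn-in from the empirical
  covariance of the accumulated draws (normalized so that a single
  Robbins–Monro scalar, targeting 0.35 acceptance, owns the overall
  scale).
* **Interweaving translations** — for each coefficient a likelihood-
  invariant move $\beta_j \mathrel{+}= \delta$, $\phi \mathrel{-}= \delta
  x_j$ whose Metropolis ratio involves only the priors. Regression effects
  and the spatial field are strongly confounded along spatially structured
  covariate patterns (and the intercept along the field's level); plain
  blockwise updates cross those ridges extremely slowly, while these
  translations move along them directly. In our profiling they raised the
  worst-case effective sample size by roughly two orders of magnitude.
* **φ scan** — univariate random-walk Metropolis per region against
  likelihood × CAR full conditional, one shared adaptive scale targeting
  0.44 acceptance.
* **τ² draw** — conjugate inverse-gamma,
  $\mathrm{IG}(a + n/2,\; b + \phi^\top Q(\rho)\phi/2)$, prior
  $\mathrm{IG}(1, 0.01)$.
* **ρ step** — random-walk Metropolis reflected into $[0, 1-10^{-6}]$,
  uniform prior, with $\log\det Q(\rho) = \sum_k \log(\rho\lambda_k + 1 -
  \rho)$ from the eigenvalues $\lambda_k$ of $D - W$, computed once per
  graph.

Covariates are centered internally before sampling — a pure
reparameterization (slopes and RRs are unchanged; the raw-scale intercept
is recovered by back-substitution) that removes the severe
intercept/covariate ridge which raw covariate scales such as body-mass
index (~23) or step counts (~716) would otherwise induce. All adaptation
happens during burn-in only and is frozen afterwards, preserving detailed
balance for the retained draws. Initialization is cheap and stable: β at
the Poisson ML fit with $\phi = 0$, $\phi = 0$, $\tau^2 = 0.01$,
$\rho = 0.5$. No sum-to-zero constraint is placed on φ: the Leroux prior
is proper for $\rho < 1$, which identifies the intercept through the
prior. The sampler uses R's RNG, so a seed makes retained chains
bit-reproducible.

Two iteration profiles are bundled: `"paper"` (110,000 iterations, 10,000
burn-in), matching the protocol of the motivating analysis, and `"desk"`
(20,000 / 2,000) for simulation studies and the test suite. With the
interweaving and centered parameterization, desk-profile worst-case
effective sample sizes on 349-region data are around 2,000 of 18,000
retained draws, which is ample for medians and 95% quantiles.

### Diagnostics and model comparison

`geweke_z()` compares the first 10% and last 50% of a chain with spectral
standard errors estimated by an AIC-selected autoregressive fit
(order-zero fits reduce to the sample variance); $|z| \ge 1.96$ flags
non-convergence, and the pipeline warns when any monitored parameter
trips. `waic()` uses the posterior-variance form of the effective
parameter count ($p_{\mathrm{WAIC}} = \sum_i \mathrm{var}_s \log p(O_i
\mid \theta_s)$, unbiased denominator) on the deviance scale
$-2(\mathrm{lppd} - p_{\mathrm{WAIC}})$, with log-mean-exp computed
stably; `fit_nonspatial()` provides the no-φ Poisson baseline and
`compare_waic()` the contrast. Lower WAIC is better.

## The synthetic-data generator

Because the motivating study's survey and vital-statistics inputs are not
redistributable, `generate_dataset()` builds complete synthetic studies
with the same statistical anatomy, and the whole test suite runs against
it. Defaults were fixed once, at values a regional-epidemiology dataset of
this kind would plausibly take, and are not tuned per experiment:

* 349 regions on a random geometric graph (unit square, radius set for
  mean degree ≈ 6, components linked through nearest pairs; a rook grid
  layout is available), matching the number of secondary medical service
  areas the motivating study covers.
* Region populations log-normal around 250,000 (a ~128M national
  population split into 349 areas), divided into 16 strata with an
  aged-country age pyramid, jittered per region, allocated by largest
  remainder so strata sum exactly to the drawn totals.
* Baseline stratum mortality geometric in age (factor 3 per band) with a
  1.6 male:female ratio — steep enough that crude and standardized ratios
  genuinely differ.
* Ten covariates with marginal medians and IQRs mirroring published
  region-level descriptive tables of this literature (resource densities
  per 100,000 population near 0.9–6.3, percentages near 6–43, log
  population density near 2, BMI near 23). Log population density gets one
  pass of neighbor smoothing, standing in for geographic structure.
  `add_collinear_covariates()` appends income and university-graduate
  proportions strongly correlated with population density to exercise the
  VIF screen.
* Generative truth: log RRs at the magnitudes published analyses of this
  outcome report (the CTA-like covariate at $\log 0.900$, near-null
  clinical resources, modest lifestyle effects), $\rho = 0.444$,
  $\tau^2 = 0.1$. The spatial variance is not printed in the motivating
  study; 0.1 puts the field's marginal spread near the observed SMR
  dispersion (sd ≈ 0.3) and was chosen once on that argument.
* Deaths: $O_i \sim \mathrm{Poisson}(E_i \exp(\beta_0 + x_i^\top\beta +
  \phi_i))$, then allocated to strata multinomially proportional to
  stratum-expected deaths, so regional totals are conserved exactly.

A root seed drives named substreams (graph, populations, covariates, φ,
deaths), so one component can be varied while the rest stay fixed.

What the generator does **not** emulate: real national geography and
adjacency (so published Moran's I values of ~0.3 for actual SMR maps are
not reproducible here), survey measurement error, prefecture-level
covariates constant across areas, or within-region covariate
heterogeneity. Passing tests therefore demonstrate that the machinery is
correct under the assumed model, not that any particular substantive
finding holds in real data.

## A worked run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  synthetic = synthetic_config(seed = 1),
  mcmc = mcmc_config(profile = "desk"),
  outdir = "run1", seed = 7)
res <- run_pipeline(cfg)
res$summary
```

The pipeline standardizes, tests the SMR for spatial autocorrelation,
screens covariates, fits both models, checks Geweke diagnostics, compares
WAIC, and writes publication-shaped outputs (`summary.csv` with Median /
2.50% / 97.50% columns on the RR scale and ρ on its own scale,
`smr.csv`, `moran.json`, `screening.json`, `diagnostics.json`,
`comparison.csv`, choropleth-ready `region,value` tables, and a manifest
with the seed and configuration). Intermediate synthetic data are written
under `data/` so any stage can be re-run from files.

## Numerical choices and limitations

* Parameter-recovery experiments fit with the generative expected counts
  as offsets — the standard design in CAR-prior simulation studies — so
  they measure the inference engine under a correctly specified offset;
  the full pipeline (internal standardization included) is exercised
  end-to-end separately. One caveat these experiments expose: the
  raw-scale intercept is an extrapolation far outside the observed
  covariate range (body-mass index alone sits ~23 units from zero), so
  tiny slope perturbations are amplified into the intercept and its
  frequentist coverage sits near the low-90s rather than at the nominal
  95% (the motivating literature's own intercept intervals, spanning two
  orders of magnitude, reflect the same phenomenon). Covariate RRs — the
  quantities of scientific interest — are calibrated.
* Problem sizes in the test suite: oracle comparisons run at $n \le 50$
  (dense brute force), sampler checks at 80–150 regions, and the
  parameter-recovery and WAIC-ordering studies at the full 349-region
  study scale with the desk profile (50 and 20 replicates respectively) —
  sizes chosen to give informative Monte-Carlo evidence at desk runtimes.
* Quantiles of RR summaries are computed as $\exp$ of the β quantiles, so
  RR intervals are exact monotone transforms of log-scale intervals.
* The permutation p-value is never zero by construction; the smallest
  attainable value is $1/(1+\text{permutations})$.
* `graph_from_polygons()` uses exact coordinate predicates (no snapping):
  queen contiguity means sharing at least one boundary point, rook a
  positive-length collinear overlap. Dirty geometries (slivers,
  near-touching boundaries) must be cleaned upstream; the function is
  intended for modest numbers of polygons, not continent-scale GIS work.
* $\rho = 1$ (intrinsic CAR) is rejected everywhere rather than treated as
  a limit; the eigenvalue log-determinant would be $-\infty$.
* Single-chain inference: Geweke is the bundled convergence check;
  multi-chain diagnostics (R-hat) are out of scope.
* WAIC is the only comparison criterion (no DIC, no cross-validation), and
  only queen/rook binary contiguity weights are offered — distance-band or
  k-nearest weights are deliberately excluded to keep $W$ consistent with
  the CAR prior's binary neighborhood assumption.
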