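# lerouxmap

Bayesian disease mapping for region-level (ecological) mortality studies:
indirect standardization, spatial autocorrelation testing, and a
hierarchical Poisson regression with a Leroux conditional autoregressive
(CAR) spatial random effect, fitted by Metropolis-within-Gibbs MCMC and
compared against a non-spatial baseline by WAIC.

The package is aimed at health-services and spatial-epidemiology analyses
of the form "is regional density of some medical resource associated with
regional standardized mortality, after accounting for spatial
autocorrelation?" — for example, associations between CT-angiography
availability and acute myocardial infarction mortality across a country's
secondary medical service areas.

## The model

For region *i* with observed deaths *O<sub>i</sub>* and expected deaths
*E<sub>i</sub>* (from indirect standardization over 2 × 8 sex/age strata):

```
O_i ~ Poisson(mu_i),   log mu_i = log E_i + beta_0 + x_i' beta + phi_i
phi  ~ N(0, tau^2 Q(rho)^-1),   Q(rho) = rho (D - W) + (1 - rho) I
```

`W` is the symmetric binary contiguity matrix (queen or rook, from an edge
list or GeoJSON polygons), `D` the diagonal of neighbor counts,
`tau^2 > 0` the spatial variance and `rho ∈ [0, 1)` the spatial-dependence
parameter. Exponentiated coefficients are relative risks (RR) per
covariate unit; an effect is "significant" when the 95% credible interval
of its RR excludes 1. Moran's I (binary weights, permutation inference)
quantifies spatial autocorrelation of the SMR; variance inflation factors
screen collinear covariates (default cutoff 2.5); WAIC compares the
spatial model with an ordinary Bayesian Poisson regression; Geweke's
diagnostic (|z| < 1.96) checks chain convergence.

Because the class of study that motivates the package builds on
non-redistributable national survey data, a first-class synthetic-data
generator (`generate_dataset()`) produces complete stand-in studies — 349
regions on a contiguity graph, stratified populations, covariates at
published descriptive scales, a Leroux spatial field, and Poisson deaths —
with the generative truth saved for recovery experiments.

## Worked example

```r
library(lerouxmap)

cfg <- pipeline_config(
  synthetic = synthetic_config(seed = 1),   # 349 regions, 16 strata
  mcmc = mcmc_config(profile = "desk"),     # 20,000 iter / 2,000 burn-in
  outdir = "run1", seed = 1)
res <- run_pipeline(cfg)
print(res)
#> pipeline_result: 349 regions
#>   mean SMR 0.986; Moran's I 0.118 (p = 0.002)
#>   WAIC spatial 2907.3 vs nonspatial 5708.9 (better: spatial)

subset(res$summary, parameter %in% c("cta_institutions", "rho"))
#>          parameter scale    median     lower     upper significant  geweke_z
#> 3 cta_institutions    RR 0.9070745 0.8830856 0.9310408        TRUE 0.6961942
#> 12             rho   rho 0.3967410 0.2383450 0.5973312          NA 0.4748116
```

Reading the output: the CTA-like covariate was generated at RR 0.900 per
institution per 100,000 population and is recovered with a credible
interval excluding 1 (a "significant" protective association); `rho` was
generated at 0.444 and its posterior sits on top of it; the spatial
model's WAIC is roughly half the non-spatial model's, the expected
verdict when the data carry strong spatial structure. `run1/` receives
`smr.csv`, `moran.json`, `screening.json`, `summary.csv` (Median / 2.50% /
97.50%, RR scale), `diagnostics.json`, `comparison.csv`,
choropleth-ready `region,value` CSVs, the synthetic inputs, and a
manifest. A thin command-line wrapper for the same pipeline ships in
`inst/scripts/lerouxmap-pipeline.R`.

Individual stages are plain functions: `smr()`, `morans_i_test()`,
`screen_covariates()`, `fit_leroux()`, `fit_nonspatial()`, `waic()`,
`geweke_z()` — see the vignette in `vignettes/` for the model, sampler
and generator details.

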