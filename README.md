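# meadowmrr

Analysis of mark–release–recapture (MRR) surveys of butterflies living in
fragmented meadow landscapes, built around the question of how mowing
management shapes movement and demography. Given individually marked capture
records and habitat-patch polygons, the package:

- classifies per-individual movements into within-patch **displacement** and
  between-patch **dispersal**, with geodesic distances from the capture
  coordinates;
- estimates per-patch **emigration probability** — the fraction of recaptured
  individuals ever recaptured outside their patch of first capture;
- computes the standard patch **connectivity** index
  S_j = Σ_{k≠j, d_jk ≤ 3 km} exp(−α·d_jk)·A_k^ξ (d in km, A in m², ξ = 0.5,
  α = 1 / mean dispersal distance);
- fits time-constant **Cormack–Jolly–Seber** models by maximum likelihood on
  the m-array, with optional sex structure and AIC selection; ϕ is daily
  survival, so unequal session gaps enter as ϕ^l;
- derives occasion abundances N_i = n_i/p̂, recruitment
  B_i = N_{i+1} − ϕ^l·N_i corrected for individuals that emerge and die
  within an interval (factor l(1−ϕ)/(1−ϕ^l)), and the seasonal total
  N_total = N_1 + Σ B*_i;
- compares regimes with in-package **GLM/GLMM machinery** (IRLS; Laplace
  approximation over a locality random intercept; binomial, gamma, Poisson
  and Gaussian families; ΔAIC < 2 simplicity rule);
- and ships an individual-based **synthetic metapopulation generator** with
  known truth, whose defaults encode the study conditions (46 patches in 5
  localities, 41-day season, ϕ = 0.79, p = 0.32, lifetime emigration
  0.22/0.16/0.09 for mown/recovered/unmown, dispersal kernel means
  102/198/246 m, displacement step means 57 m female / 43 m male).

It is intended for movement ecologists and population biologists who want a
tested, self-contained reimplementation of this analysis chain that they can
run on their own MRR data or use for study design via simulation.

## Worked example

Simulate a full season under the default study conditions, then estimate
emigration, survival, capture probability and the seasonal total:

```r
library(meadowmrr)

cfg <- sim_config()
sim <- simulate_mrr(cfg, seed = 1)
sim$dataset
#> MRR dataset: 3668 individuals, 7254 captures, 46 patches, 34 occasions
#> Regimes: mown 18, recovered 13, unmown 15

pool_emigration_by_regime(emigration_table(sim$dataset))
#>      regime n_recaptured n_emigrants emigration_probability          se
#> 1    unmown          947          84             0.08870116 0.009238896
#> 2 recovered          352          52             0.14772727 0.018912472
#> 3      mown          561         120             0.21390374 0.017312733

chm <- capture_history(sim$dataset)
fit <- fit_cjs(chm, models = "phi(.)p(.)")$fits[[1]]
round(c(phi = fit$phi[["all"]], p = fit$p[["all"]]), 3)
#>   phi     p
#> 0.790 0.318

abundance_estimate(chm, fit$phi[["all"]], fit$p[["all"]], fit$p_se[["all"]])
#> Abundance estimate: N_total = 5763.5 over 34 occasions (phi = 0.79 , p = 0.318 )
sim$truth$n_emerged
#> [1] 5735
```

The pooled emigration estimates sit on the generating per-regime rates
(0.22/0.16/0.09), the CJS estimates recover ϕ = 0.79 and p = 0.32, and the
recruitment-based seasonal total (5763) matches the true number of
individuals that ever lived during the season (5735) to half a percent.

## The analysis workflow

`analysis/` contains the numbered drivers of the full study pipeline; each is
a thin script over package functions and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic season -> records/patches/truth
Rscript analysis/02_movements.R       # movements, emigration, connectivity
Rscript analysis/03_demography.R      # per-patch CJS + seasonal totals
Rscript analysis/04_regime_models.R   # GLMM regime comparisons (full pipeline)
```

`run_all()` performs the same end-to-end analysis in one call and returns a
report object with every table; it accepts either a simulation config or
paths to real `records.csv` + `patches.geojson` inputs.

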