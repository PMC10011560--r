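# forestprod

Instantaneous forest woody productivity from two-census tree data, and the
community-level analysis of why warm forests are more productive.

## The problem

Repeated forest inventories record every stem's diameter (or mass) at two
censuses a few years apart. The conventional productivity estimate,
`P_simple = Σ (B_T − Bsurv_0) / T`, mixes growth with mortality turnover and
is biased by the census interval. `forestprod` implements instantaneous
demographic-rate estimators that remove this bias, plus the scaling models
and null-model projections needed to decompose stand productivity
differences along a temperature gradient. It is aimed at forest ecologists
working with plot-census data (or simulations of them).

For a species population *i* with census biomasses *B*<sub>0*i*</sub>,
*B*<sub>*Ti*</sub> and surviving initial biomass *B*surv<sub>0*i*</sub> over
an interval *T*:

- relative woody productivity: *p*<sub>*i*</sub> = ln(*B*<sub>*Ti*</sub> / *B*surv<sub>0*i*</sub>) / *T* (yr⁻¹)
- relative loss to mortality: *l*<sub>*i*</sub> = ln(*B*<sub>0*i*</sub> / *B*surv<sub>0*i*</sub>) / *T*
- period-mean biomass (logarithmic mean): *B*<sub>*i*</sub> = (*B*<sub>*Ti*</sub> − *B*<sub>0*i*</sub>) / ln(*B*<sub>*Ti*</sub> / *B*<sub>0*i*</sub>)
- stand totals: *B* = Σ *B*<sub>*i*</sub>, *P* = Σ *p*<sub>*i*</sub> *B*<sub>*i*</sub>, *L* = Σ *l*<sub>*i*</sub> *B*<sub>*i*</sub>

Scaling across species and stands is modelled as a lognormal power law,
ln *y* ~ Normal(*k* + *b* ln *x* + *c* MAT, σ), back-transformed with the
lognormal mean correction *a* = exp(*k* + σ²/2) to
*y* = *a x*<sup>*b*</sup> exp(*c* MAT). Two null models decompose
temperature dependence: a **species-response** projection
(*P*<sub>specRes</sub> = *a*<sub>plot</sub> *B* (Σ<sub>plot</sub>Σ<sub>*i*</sub> *B*<sub>*i*</sub><sup>1+*b*</sup>) / Σ<sub>plot</sub> *B*)
in which all plots share one species-biomass distribution, and a
**community-structure** projection in which each species' productivity is
replaced by weighted resampling from similar-biomass species across all
plots (weights 1/(Δln *B*)², 10,000 draws).

## Worked example

Simulate a 500-tree cohort growing at 2.5% yr⁻¹ with 1.2% yr⁻¹ mortality
over a 5-year census interval, then recover the rates:

```r
library(forestprod)
sim    <- census_sim_spec(n_trees = 500, g = 0.025, m = 0.012, T_years = 5)
census <- generate_census(sim, seed = 1)
rates  <- build_populations(census, plot_area = 1) |> species_rates()
rates |> dplyr::select(species, B0, BT, Bsurv0, p, l, B, P, P_simple)
#> # A tibble: 1 × 9
#>   species    B0    BT Bsurv0     p       l     B     P P_simple
#>   <chr>   <dbl> <dbl>  <dbl> <dbl>   <dbl> <dbl> <dbl>    <dbl>
#> 1 sp1      115.  124.   110. 0.025 0.00969  120.  2.99     2.92
```

The estimated `p` is exactly the simulated growth rate 0.025 (survivor
growth is deterministic), `l` ≈ 0.012 up to sampling noise in which trees
died, and the conventional `P_simple` (2.92) underestimates the
instantaneous `P` (2.99) because mortality removes growing biomass during
the interval.

Fit the species productivity–biomass power law on a synthetic two-forest
community generated under a common scaling law:

```r
tab <- generate_species_table(synthetic_forest_spec("community-structure"),
                              seed = 1)
fit_power_law(tab, p, B)
#> Lognormal power-law fit (log-log pooled), n = 1900
#>   k (log intercept) = -3.6003 (se 0.0146)
#>   b (exponent)      = -0.1478 (se 0.0075)
#>   sigma = 0.5802;  a = exp(k + sigma^2/2) = 0.0323;  R2 = 0.1714
```

The generator's preset intercept (−3.6) and slope (−0.15) are recovered.
A MAT coefficient of 0.048 °C⁻¹ implies productivity at fixed biomass
doubles every `doubling_span(0.048)` = 14.4 °C of warming.

For real data, start from `read_census_table()` + `read_plot_metadata()`
(+ `apply_allometry()` if the census records diameters rather than
masses), or run everything at once with
`run_pipeline(run_config(census, plots, ...))`, which also produces the
null-model projections, contribution ratios, biome predictions at a
reference biomass of 160 Mg C ha⁻¹, and per-plot small-biomass-species
shares. A thin CLI over the same functions is in
`inst/scripts/forestprod.R`.

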