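---
title: "Instantaneous woody productivity, scaling models and null-model decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instantaneous woody productivity, scaling models and null-model decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestprod)
library(dplyr)
```

## The estimation problem

Forest plots are censused every few years: each stem ≥ 5 cm diameter is
measured, its survival recorded, and new stems crossing the threshold
(recruits) tagged. Aboveground woody productivity — carbon fixed into wood
per area and time — must be inferred from these two snapshots. The naive
interval estimate $(B_T - B\mathrm{surv}_0)/T$ depends on the interval
length and on how growth and mortality interleave within it: a fast-growing
population that also loses trees mid-interval has part of its production
erased before it is ever measured.

`forestprod` instead treats each species population as growing and dying
exponentially over the interval. With $B_0$, $B_T$ the census biomasses
per area and $B\mathrm{surv}_0$ the initial biomass of trees that survived
to the second census,

$$p = \frac{\ln(B_T / B\mathrm{surv}_0)}{T}, \qquad
  l = \frac{\ln(B_0 / B\mathrm{surv}_0)}{T}, \qquad
  B = \frac{B_T - B_0}{\ln(B_T/B_0)} .$$

$p$ is the instantaneous relative productivity (yr⁻¹), $l$ the relative
loss rate to mortality, and $B$ the logarithmic-mean period biomass —
the time-average of an exponentially changing stock. Absolute rates are
$P = pB$ and $L = lB$, and stand totals are the sums over populations.
Under exact exponential dynamics these estimators are *exact*: if
survivors grow at rate $g$, $p = g$ to machine precision regardless of
which trees die (the suite asserts this on deterministic simulations).
A useful exact identity follows from the estimator forms:
$P - L = (B_T^{tot} - B_0^{tot})/T$, i.e. net biomass change is always
partitioned consistently between production and loss; the suite checks it
to 1e−12.

### Bookkeeping rules

* Species with ≥ 2 trees surviving both censuses are named populations;
  all rarer species in a plot are pooled into one aggregate population
  (biomass conserved exactly).
* Non-positive $p$ (diameter shrinkage of large trees) is retained in
  stand totals but flagged `valid_p = FALSE` and excluded from scaling-fit
  input; the exclusion count is reported.
* $B_0 = B_T$ is a removable singularity of the log-mean; below a
  log-ratio guard of 1e−9 the arithmetic mean is returned, the
  second-order-accurate continuation.
* The conventional estimate `P_simple` is also computed for comparison;
  recruits enter it at the mass of a threshold-size (5 cm) tree when an
  allometry is configured, and at full final mass (with the caveat
  documented here) when only population sums are available.
* Abundance uses the same log-mean; a zero count at exactly one census
  falls back to the arithmetic mean with a warning, both-zero gives 0.
* A population with no surviving biomass (possible only for the pooled
  aggregate) has undefined rates; it contributes its biomass to stand $B$
  but nothing to $P$ or $L$, and the case is messaged.

## Allometry

Diameters are converted to aboveground carbon mass by a log-polynomial
map $W_{dry}(d) = \rho\,\exp\{c_0 + c_1 \ln d + \dots\}$ with a
wood-density multiplier $\rho$ resolved through a species → genus →
family → lifeform fallback chain from a user-supplied table, then scaled
by the fixed 0.5 oven-dry-mass-to-carbon factor. The interface is
deliberately generic — published coefficient sets vary by region and
forest type and are supplied by the user — and models are validated for
strict monotonicity in diameter at construction. Censuses that already
carry masses bypass allometry entirely.

## Scaling models

All scaling relations share one lognormal log-linear form,
$\ln y \sim \mathrm{Normal}(k + b \ln x + c\,\mathrm{MAT}, \sigma)$,
fitted by OLS, with the natural-scale intercept corrected for the
lognormal mean: $a = \exp(k + \sigma^2/2)$. Choices worth stating:

* $\sigma$ uses the unbiased residual variance (denominator $n - $
  number of coefficients) — standard OLS practice.
* Plot-specific intercepts are fixed-effect dummies with a common slope;
  each plot's $a_{plot}$ carries the same $\sigma^2/2$ correction.
* Confidence bounds are Wald-type on the log scale from the coefficient
  covariance (delta method), exponentiated. The $\sigma^2/2$ correction
  is applied to the mean *and* both bounds, so the bounds always bracket
  the mean and collapse to $\exp(\hat\mu \pm 1.96\,\mathrm{se})$ at
  $\sigma = 0$.
* MAT enters in °C directly rather than as inverse absolute temperature:
  over the 0–30 °C range of interest the two are linear to
  $R^2 \approx 0.999$ (`inverse_temperature_linearity()`; the default
  31-point grid is a documented choice — the check is insensitive to it).
* $R^2$ is computed about the mean of $\ln y$ in every form, including
  the no-global-intercept plot-dummy form where `summary.lm` would
  otherwise inflate it.
* Biomes are assigned from MAT by fixed thresholds (tropical ≥ 24,
  subtropical 20–24, warm-temperate 12–20, cool-temperate 5–12,
  sub-boreal < 5 °C), boundaries belonging to the warmer class.

`doubling_span(c)` converts the MAT coefficient into the warming needed
to double productivity at fixed biomass, $\ln 2 / c$.

## Null-model projections

Two projections ask *why* warm stands are more productive.

**Species response.** Suppose every species obeys its plot's fitted law
$p_i = a_{plot} B_i^{b}$ while all plots share one species-biomass
distribution (that of all named populations pooled). Then

$$P_{\mathrm{specRes}} = a_{plot}\,B\,
  \Big(\sum_{plot}\sum_i B_i^{1+b}\Big) \Big/ \sum_{plot} B,$$

with the shared ratio computed once across all plots. As printed, the
formula implies plot species richness proportional to plot biomass; it is
implemented exactly as stated, with no richness re-normalisation. The
aggregate population is excluded from the double sum and from the plot
$B$ entering the formula, and its own observed $P$ is added back
unchanged.

**Community structure.** Each named population's $P_i$ is replaced by the
mean of 10,000 weighted draws (with replacement) from all other named
populations across plots, weight $1/(\ln B_j - \ln B_i)^2$ — donors of
similar standing biomass dominate. $P_{\mathrm{commStr}}$ is the plot sum
of replaced values plus the untouched aggregate. Exact $\ln B$ ties would
give infinite weight; candidates within 1e−9 are sampled uniformly among
themselves, which is the limit of the stated weight. Sampling is with
replacement, matching the mean-of-draws estimator. A deterministic mode
returns the closed-form weighted expectation
$\sum_j w_j P_j / \sum_j w_j$ (the infinite-draw limit); tests use it for
exactness, the stochastic mode is the analysis default.

**Contribution ratio.** Each projection's explanatory power for observed
$\ln P$ is
$(\mathrm{Var}(\ln P) - \mathrm{RSS}_{null}/n) /
 (\mathrm{Var}(\ln P) - \mathrm{RSS}_{orig}/n)$: 1 when the null matches
the observed-data model of $\ln P$ on $(\ln B, \mathrm{MAT})$, 0 when it
explains nothing. Whether the null series should be re-fitted with the
same model form (its fitted surface then predicting $\ln P$) or used
directly as predictions is genuinely ambiguous; both are implemented,
`method = "refit"` being the default as it mirrors applying *the
regression model of* the null series to the original data.

## The synthetic community generator

The generator is first-class, tested code, and defines the study
conditions for every downstream test.

**Species tables.** $\ln B_i \sim N(\mu_B, s_B)$ and
$\ln p_i = k + b \ln B_i + \varepsilon$,
$\varepsilon \sim N(0, \sqrt{s_p^2 - b^2 s_B^2})$, so the *marginal* SD
of $\ln p$ is exactly $s_p$ and the regression slope is $b$. Presets:
common slope $b = -0.15$; species-response hypothesis $k = -3.4$
(tropical) vs $-3.8$ (temperate) with a shared biomass distribution
($\mu_B = -0.6$, $s_B = 2.0$, $s_p = 0.65$); community-structure
hypothesis $k = -3.6$ everywhere but $\mu_B = -1.0, s_B = 1.6, s_p = 0.6$
(tropical) vs $\mu_B = -0.2, s_B = 2.0, s_p = 0.65$ (temperate); 10
stands per forest. Species richness per stand is not a
calibrated constant of the construction; the defaults (150 tropical / 40
temperate) are illustrative. Biomass-range clipping is available but off
by default — such ranges describe display axes, not the generative law. Species are drawn independently per stand; one seed
governs the whole table.

**Census simulations.** A cohort with lognormal initial masses grows at
$g$ (survivor mass $w_1 e^{gT}$ — no growth noise, so $p$ recovery is
exact), survives with probability $e^{-mT}$, and recruits enter before
census 2. A deterministic-mortality variant kills exactly
$\mathrm{round}(n(1-e^{-mT}))$ trees in id order; with equal masses and
an integer kill count, $l = m$ to machine precision, which the tests
exploit.

**What passing tests do and do not show.** The generator realises ideal
exponential dynamics with homogeneous rates within populations, a single
common census interval, no measurement error, no size-dependent growth or
mortality, and no spatial structure. Tests against it validate the
estimators' algebra and the pipeline's statistics, not robustness to the
messiness of real inventories (buttressed stems, taper changes, interval
heterogeneity), which the input layer flags but does not model.

## Problem sizes and numerical choices

The test suite works at deliberately modest scales — 5,000-species
communities for moment/slope recovery, $10^4$-tree cohorts on a
$(g, m)$ grid of $\{0.01, 0.03, 0.05\} \times \{0.005, 0.02\}$ yr⁻¹ with
a 3-standard-error acceptance band, 20-stand two-forest communities for
the hypothesis-contrast checks, and a 4-plot census fixture for the
end-to-end pipeline — sizes at which Monte-Carlo tolerances are tight
enough to be meaningful while the whole suite runs in seconds. Stochastic
checks fix their seeds; stochastic resampling in the package itself is
seeded per call via an explicit `seed` argument and never disturbs the
caller's RNG state.

## Known limitations

* Two censuses only; multi-census chains and per-tree interval weighting
  are out of scope (heterogeneous intervals are collapsed to the plot
  mean with a warning).
* Fixed-effect plot intercepts, not mixed models; no conditional $R^2$.
* The species-response formula's richness-proportionality assumption is
  inherited as printed, which is why the two contribution ratios need not
  sum to 1.
* Allometric coefficient sets, height–diameter models and climate-raster
  handling are the user's responsibility.
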