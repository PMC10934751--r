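# espartoflux

Transpiration of esparto grass (*Macrochloa tenacissima*) under Aleppo pine
competition: chamber-flux computation, competition indexing, seasonal
Spearman screening, and the combined exponential power model of
transpiration versus soil water content with site dummy effects.

Esparto is a perennial tussock grass of semi-arid Mediterranean woodlands.
Its leaf-level transpiration T (mm h⁻¹) responds to soil water content Sw
(%) as a right-skewed hump, and pine competition (open "clear" stands vs.
closed "dense" stands) modifies that response. The package is written for
plant ecophysiologists and environmental biostatisticians who want that
analysis chain as tested, reusable functions rather than a point-and-click
session.

## The model

The core is the combined exponential power model with a site dummy S:

```
T = exp(β0 + β0′S + (β1 + β1′S)·Sw) · Sw^(β2 + β2′S) · ε
```

* `β0, β1, β2` — log-scale intercept, linear slope on Sw, and exponent on Sw
  for the baseline site (S = 0, the dense stand);
* `β0′, β1′, β2′` — site increments giving the clear-site (S = 1) line;
* `ε` — multiplicative error, i.e. additive Gaussian on the log scale.

Estimation follows the original analysis protocol: logarithmic
linearisation (design columns `[1, S, Sw, S·Sw, ln Sw, S·ln Sw]`), ordinary
least squares, one DFFITS influential-point pass (cut-off `2·√(p/n)`), then
backward stepwise elimination at α = 0.05. Senescent-leaf strata typically
collapse to the intercept-only model, whose `exp(β0)` is exactly the
geometric mean rate.

Upstream, raw chamber readings are converted to rates via
`E = F(Ws−Wr)/(100·S·(D−Ws))` (both the as-printed `D = 100` and the
instrument-manual `D = 1000` dialects are supported) and
`T = E × 64.8576 mm h⁻¹`; pine pressure is summarised by the competition
index `CI = Σ perimeter/distance` (m m⁻¹). A synthetic-study generator
reproduces the factorial design (3 slots × 2 leaf types × 8 bushes × 14
days = 672 records) with seasonal microclimate and model-generated
transpiration, so the whole pipeline runs with no field data.

## Worked example

```r
library(espartoflux)

sim <- simulate_study(synthetic_config(seed = 42))
fit <- ep_fit(sim$observations, leaf_type = "green", period = "yearly")
fit
#> Exponential power transpiration model  [green leaves, yearly]
#>   baseline site: dense (S = 0); n used = 309, removed = 27, excluded = 0
#>             estimate std_error     p
#> (Intercept)  -7.4130    0.2387 0e+00
#> S             0.8111    0.1773 0e+00
#> Sw           -0.3303    0.0395 0e+00
#> S_Sw         -0.0529    0.0144 3e-04
#> lnSw          3.7238    0.2844 0e+00
#>   SEE = 0.556 (log scale), adj. R2 = 66.1%, F p = <2e-16
```

Out of 336 green-leaf records, 27 were removed by the DFFITS rule and none
excluded for non-positive T or Sw. The retained terms say: transpiration
rises with soil water as `Sw^3.72` damped by `exp(−0.33·Sw)`, and the clear
site (S = 1) transpires more at a given Sw (positive `S`), with a slightly
steeper damping (`S_Sw`). The site lines collapse via

```r
round(composite_coefficients(fit), 4)
#>           baseline composite se_composite
#> intercept  -7.4130   -6.6019       0.2958
#> slope      -0.3303   -0.3833       0.0358
#> exponent    3.7238    3.7238       0.2844

site_effect_test(fit)$joint
#> joint site-effect F = 7.8 on (3, 304) df, p = 4.8e-05
```

i.e. the dense line is `T = e^(−7.41 − 0.33·Sw)·Sw^3.72` and the clear line
`T = e^(−6.60 − 0.38·Sw)·Sw^3.72`, with the site effect jointly
significant — the generator's built-in competition contrast, recovered by
the fit. Leaf-type means behave like the field study's
(green ≫ senescent):

```r
group_summary(sim$observations, by = "leaf_type")
#>   leaf_type       mean           se   n
#> 1     green 0.10542616 0.0042235027 336
#> 2 senescent 0.02354786 0.0004894875 336
```

`run_pipeline(synthetic_config(seed = 42), out_dir = "out")` performs the
whole chain (simulate → flux → correlate → fit → predict → report) and
writes per-stage CSV/JSON outputs, a markdown report and a manifest whose
row counts reconcile at every stage boundary. A thin command-line front
end with the same verbs lives at `inst/scripts/espartoflux`.

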