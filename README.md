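# ricecompete

Modelling rice grain yield under simultaneous weed interference and
elevated temperature.

## The problem

Paddy weeds (late watergrass, water chestnut) depress rice yield through
density-dependent competition, while accumulated heat first raises and then
— past the crop's thermal optimum and into spikelet-sterility territory —
collapses the weed-free yield. Agronomists studying this joint effect in
temperature-gradient (phytotron) pot trials need: thermal-time bookkeeping,
a nested family of yield-loss regressions, a formal lack-of-fit test to
decide how far the family can be reduced, and prediction surfaces for
weed-management decisions under warming.

`ricecompete` implements that pipeline as a tidyverse-style R package:
data frames in, tibbles out, `tidy()`/`glance()` accessors and
`autoplot()` graphics for every result type.

## The models

Weed density $X$ (plants m⁻²) acts through the Cousens rectangular
hyperbola; accumulated growing degree days to flowering
($\mathrm{GDD} = \sum_d \max(T_d - 10\,°C, 0)$, June 1 – August 28) act on
its two parameters. The nested family, richest first:

| model | form | parameters |
|---|---|---|
| per-level (full) | $Y = Y_{0i} / (1 + \beta_i X)$ | $2k$ |
| intermediate | $Y = (a + b\,\mathrm{GDD} + c\,\mathrm{GDD}^2)/(1 + \beta_i X)$ | $3 + k$ |
| combined | $Y = (a + b\,\mathrm{GDD} + c\,\mathrm{GDD}^2)/(1 + (l + m\,\mathrm{GDD})X)$ | $5$ |

Reductions are judged by the lack-of-fit statistic
$F = \frac{(RSS_{red} - RSS_{pred})/(df_{red} - df_{pred})}{RSS_{full}/df_{full}}$,
always scaled by the full (per-level) model's residual mean square, against
the tabulated F value at the 5% level.

Because no raw pot-level data are published for this kind of trial, the
package ships a first-class synthetic-trial generator (`generate_trial()`)
that emulates the 3-year × 4-regime × 5-density × 3-replicate design,
including the heat-sterility collapse of a hot year — see the methods
vignette (`vignettes/competition-modelling.Rmd`) for what it does and does
not emulate.

## Worked example

```r
library(ricecompete)

trial  <- generate_trial(trial_design(), generator_config(seed = 42))
f_full <- fit_per_level_pooled(trial$observations)
f_int  <- fit_intermediate(trial$observations)
f_comb <- fit_combined(trial$observations)

compare_models(f_full, f_int, f_comb)
```

```
<rh_comparison> nested lack-of-fit tests (alpha = 0.05 )
# A tibble: 3 × 4
  model_id     df_resid   rss n_params
1 per_level         118  26.0       20
2 intermediate      125  33.0       13
3 combined          133  42.8        5

  comparison             f_value df_num df_den critical_f  p_value significant
1 intermediate-per_level    4.58      7    118       2.09  1.47e-4 TRUE
2 combined-intermediate     5.59      8    118       2.02  5.26e-6 TRUE
```

Ten of the twelve year × regime levels pass the inclusion rule (the two
hottest regimes of the heat-collapse year have weed-free yields below
1 t ha⁻¹ and carry no competitiveness information), so the full model has
20 parameters on 118 residual df. Both reductions are formally rejected at
5% — the sterility cliff is not a quadratic — yet the combined model still
explains most of the structure:

```r
tidy(f_comb)
#   term     estimate  std.error
# 1 a     -57.4       4.63
# 2 b       0.0864    0.00590
# 3 c      -0.0000290 0.00000185
# 4 l      -0.0220    0.00641
# 5 m       0.0000208 0.00000430

quadratic_peak(-57.4, 0.0864, -0.0000290)
#   gdd_at_max y0_max
# 1      1488.   6.90
```

The fitted weed-free yield peaks near GDD 1490 and the competitiveness
slope `m` is positive: weeds hurt more per plant as heat accumulates. At
80 plants m⁻² the predicted yield falls to

```r
round(percent_of_weed_free(as_combined_params(f_comb), 80,
                           c(1300, 1500, 1700, 1900)), 1)
# [1] 71.1 57.5 48.2 41.5
```

percent of the weed-free yield at GDD 1300/1500/1700/1900. Prediction
surfaces (`predict_surface()` + `autoplot()`), two-stage parameter plots
(`plot_stage2()`) and a yield-component correlation screen
(`correlation_screen()`) complete the reporting side.

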