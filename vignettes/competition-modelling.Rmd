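---
title: "Modelling rice-weed competition under elevated temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rice-weed competition under elevated temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricecompete)
library(dplyr)
```

## The problem

Paddy weeds such as late watergrass (*Echinochloa oryzicola*) and water
chestnut (*Eleocharis kuroguwai*) reduce rice grain yield through season-long
competition, and a warming climate changes both sides of that interaction:
heat accelerates weed growth and competitiveness while pushing rice through
its thermal optimum into spikelet-sterility territory. `ricecompete`
implements an empirical modelling pipeline for exactly this joint effect:
thermal-time (growing degree day, GDD) accounting, a nested family of
yield-loss regression models, formal model selection, and prediction
surfaces, together with a synthetic phytotron-trial generator that stands in
for unpublished raw data.

## Thermal time

Daily mean air temperature $T$ is converted to growing degree days above a
base temperature $T_{base}$:

$$\mathrm{GDD} = \sum_d \max(T_d - T_{base},\, 0)$$

- `t_base` defaults to 10 °C, the convention for temperate paddy rice.
- Accumulation windows are **closed** (both endpoint dates included), and
  the default stage calendar is transplanting June 1, tillering August 10,
  flowering August 28, maturity October 15, so the transplanting-to-flowering
  window spans 89 days.
- We accumulate **daily clamped** contributions rather than applying
  $(\bar T - T_{base}) \times \text{days}$ to the window mean. For Korean
  summer conditions the two coincide (temperatures sit far above 10 °C), but
  per-day clamping is the robust standard and is what the additivity and
  monotonicity properties in the test suite assert.

The flowering GDD is the covariate used by all the regression models, since
the yield components that respond to heat (grain number, ripened fraction,
grain weight) are set by flowering.

## The model family

Yield loss from weed density $X$ (plants m⁻²) follows the Cousens
rectangular hyperbola. Three nested parameterisations are fitted, richest
first:

1. **Per-level** (the "full" model): at every year × temperature-regime
   level $i$, its own weed-free yield and competitiveness,
   $$Y = \frac{Y_{0i}}{1 + \beta_i X},$$
   2 parameters per level.
2. **Intermediate**: weed-free yield pooled into a quadratic in flowering
   GDD, competitiveness still level-specific,
   $$Y = \frac{a + b\,\mathrm{GDD} + c\,\mathrm{GDD}^2}{1 + \beta_i X},$$
   $3 + k$ parameters for $k$ levels.
3. **Combined**: competitiveness linear in GDD too,
   $$Y = \frac{a + b\,\mathrm{GDD} + c\,\mathrm{GDD}^2}{1 + (l + m\,\mathrm{GDD})\, X},$$
   5 parameters in total.

The quadratic captures a thermal optimum ($c < 0$; peak at
$-b/(2c)$, see `quadratic_peak()`), and $m > 0$ expresses weeds gaining
competitiveness with accumulated heat. Model functions always return the
algebraic value — the quadratic can go negative at extreme GDD, and clamping
to zero happens only in the reporting layer (`predict_surface()` flags
clamped cells), never inside anything a least-squares fit sees.

## Fitting

All nonlinear fits use Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with analytic Jacobians. Numerical choices that
matter:

- **Conditioning.** GDD enters the joint fits rescaled by 1/1000, so the
  quadratic coefficients are O(1) during optimisation; estimates and
  standard errors are mapped back afterwards.
- **Initialisation** is deterministic: for a single hyperbola, $Y_0$ starts
  at the mean yield at the lowest density and $\beta$ at the
  slope/intercept ratio of the reciprocal-yield linearisation
  $1/Y = 1/Y_0 + (\beta/Y_0)X$; the joint fits start from the two-stage
  regressions (`fit_stage2_quadratic()` of per-level $\hat Y_0$ on GDD,
  `fit_stage2_linear()` of per-level $\hat\beta$ on GDD). A deterministic
  multi-start fallback (5–6 starts) engages only if the primary start fails
  to converge or converges to something no better than the grand-mean fit.
- **Box constraints** keep the optimiser out of pole regions:
  $Y_0 \ge 0$ and $\beta > -0.99/\max(X)$ per level, so the denominator
  $1 + \beta X$ stays positive at every observed density.
- **Convergence** uses relative step/objective tolerances of $10^{-13}$;
  noise-free data are recovered to machine precision, and the test suite
  checks the two-parameter fit against an independent zoomed grid-search
  oracle to $10^{-6}$ in RSS.
- **Standard errors** are the conventional asymptotic ones,
  $\widehat{\mathrm{cov}} = (J^\top J)^{-1}\, RSS/df$ with $J$ the residual
  Jacobian at the optimum.
- **Fit quality** is reported as RMS $=\sqrt{RSS/df}$ and pseudo-$R^2$
  $= 1 - RSS/TSS$. (Other definitions of a nonlinear pseudo-$R^2$ exist;
  this plain one is implemented and documented.)

### Level inclusion

Pooled fits exclude year × regime levels whose weed-free mean yield is
below 1 t ha⁻¹ (`min_weedfree_yield`, configurable). Such near-collapse
levels — the hottest regimes of a heat-collapse year — contain essentially no
information about weed competitiveness (every pot is near zero regardless of
density), and their $\beta$ estimates are wildly unstable; `fit_hyperbola()`
warns about the wide standard errors if you fit them anyway.

## Model selection

Reductions are tested with a lack-of-fit F statistic,

$$F = \frac{(RSS_{reduced} - RSS_{pred}) / (df_{reduced} - df_{pred})}{RSS_{full}/df_{full}},$$

where the denominator is **always** the per-level (full) model's residual
mean square, for both sequential steps. This denominator convention is
hard-coded deliberately: it is the convention under which the published
comparison tables for this model family are exactly reproducible from their
printed RSS and df, which the acceptance test verifies to two decimals. The
reduction is accepted when $F$ falls below the tabulated critical value at
the 5% level (exact p-values are also reported). On data simulated from the
combined model itself, the test suite checks that the reduction is rejected
at roughly the nominal 5% rate (band 2–9% over 500 replicates) — the usual
approximate validity of F-tests for nonlinear least squares.

Note an honest tension the package preserves: on heat-collapse data the
sequential tests typically *reject* the reductions (the sterility cliff is
not a quadratic), yet the combined model can still be a useful smooth
description; `compare_models()` reports the formal outcome and leaves the
pragmatic call to the analyst.

## The synthetic trial generator

No raw observation-level data are published for this kind of phytotron
study, so `generate_trial()` builds datasets with the study's design and
statistical structure:

- **Design** (defaults of `trial_design()`): 3 years × 4 regimes (ambient
  +0/+1.5/+3.0/+5.0 °C) × 5 densities (0/10/20/40/80 plants m⁻² in the
  first year, 0/20/40/80/160 after) × 3 replicates; 8% of pots drop out,
  emulating the small residual-df shortfall seen in real trials.
- **Temperatures**: a seasonal cosine (amplitude 6 °C, peak in early
  August) anchored so the ambient flowering-window mean is 24.1 / 26.4 /
  29.0 °C in 2014/2015/2016, plus day-to-day noise (SD 1.5 °C). Offset
  regimes differ from ambient by exactly their offset in the deterministic
  part. Published per-regime GDD tables are treated as *given inputs* of
  that experiment, not as recomputation targets — the daily series behind
  them are unavailable, so the generator is anchored to the window means
  instead.
- **Yields**: `combined_yield(truth, GDD, X)` × a heat-sterility
  multiplier + Gaussian noise (SD 0.5 t ha⁻¹, matching the magnitude of
  per-level RMS values in practice), clamped at zero. The clamp introduces
  a mild truncation bias only where yields are already near zero.
- **Sterility**: a logistic fraction `1/(1+exp(slope (T̄ - t50)))` of yield
  retained, with defaults t50 = 31 °C, slope = 2 °C⁻¹. These two numbers
  are *invented calibration choices*, not estimates from any dataset: they
  are chosen so the collapse sets in once flowering-period means exceed
  about 30 °C, which qualitatively reproduces a hot year in which the two
  hottest regimes lose nearly everything while ambient is barely touched.
  They are config knobs, clearly labelled as such.
- **Components**: `generate_components()` decomposes the pre-noise yield
  multiplicatively — density depresses panicle count, heat depresses the
  ripened fraction, grains per panicle absorbs the rest — reconstructing
  the yield to $10^{-9}$. This gives the correlation screen
  (`correlation_screen()`, Pearson with two-sided t-tests; the classic
  screen for which correlation flavour is rarely stated — Pearson is the
  documented, swappable choice) the dissociation pattern expected of real
  trials: density ↔ panicles, GDD ↔ ripened fraction, and density ⊥
  ripened fraction.

What passing tests on this generator do **not** show: the generator has no
crop physiology (no tillering dynamics, no weed biomass, no CO₂), its noise
is homoscedastic Gaussian by assumption (least squares and ANOVA usage imply
it, but it is unstated for real data), and the true missing-pot pattern of
any real trial is unknowable. Parameter-recovery and calibration results on
synthetic data therefore validate the *estimation machinery*, not the
biology.

When the acceptance-style simulations need data generated *exactly* from
the combined model (noise-free closure, coverage of the asymptotic standard
errors, F-test calibration), the sterility multiplier is switched off —
with it on, the generating process is deliberately misspecified relative to
the quadratic, which is precisely what makes the default trials realistic.

## Problem sizes used in the checks

The test suite fits the full nested family on 50 simulated trials for the
nesting invariant, 200 trials (σ = 0.5 t ha⁻¹) for ±3-SE coverage of all
five combined-model parameters (≥ 90% per parameter), and 500 trials for
the F-test calibration band; each trial is ~165 pots. These sizes give
Monte-Carlo standard errors comfortably inside the asserted bands while
keeping a full run of the suite in a few minutes on one core.

## A worked run

```{r pipeline, eval = FALSE}
trial <- generate_trial(trial_design(), generator_config(seed = 42))

f_full <- fit_per_level_pooled(trial$observations)
f_int  <- fit_intermediate(trial$observations)
f_comb <- fit_combined(trial$observations)

compare_models(f_full, f_int, f_comb)
tidy(f_comb)

surf <- predict_surface(as_combined_params(f_comb),
                        gdd_values = seq(1300, 1900, by = 100),
                        densities = seq(0, 160, by = 10))
autoplot(surf)
```

## Known limitations

- Single-weed-species interference only; no mixed-stand model and no
  asymptote-capped hyperbola variant.
- Asymptotic standard errors only (no bootstrap or Bayesian intervals).
- The combined model is an empirical description: extrapolating the
  quadratic beyond the observed GDD range quickly yields negative weed-free
  yields (the surface reports them clamped and flagged), and the sterility
  cliff of very hot years is outside what a quadratic can represent.
- Published parameter tables for this model family are typically rounded
  too coarsely to reproduce headline relative-yield percentages; derived
  quantities should always be computed from unrounded fitted parameters
  (see `percent_of_weed_free()` for the documented example).
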