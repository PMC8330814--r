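test_that("temperature generation is deterministic and offsets shift pointwise", {
  a <- generate_temperature_year(2014, 0, seed = 5)
  b <- generate_temperature_year(2014, 0, seed = 5)
  expect_identical(a, b)
  hot <- generate_temperature_year(2014, 5.0, seed = 5)
  expect_equal(hot$t_mean_c - a$t_mean_c, rep(5.0, nrow(a)))
  quiet0 <- generate_temperature_year(2014, 0, noise_sd = 0, seed = 1)
  quiet5 <- generate_temperature_year(2014, 5.0, noise_sd = 0, seed = 2)
  expect_equal(quiet5$t_mean_c - quiet0$t_mean_c, rep(5.0, nrow(quiet0)))
})

test_that("the 2014 ambient profile is calibrated to a ~24.1 C flowering mean", {
  s <- generate_temperature_year(2014, 0, noise_sd = 0, seed = 1)
  cal <- stage_calendar(2014)
  fl <- accumulate_gdd(s, cal$transplanting, cal$flowering)
  expect_equal(fl$mean_t, 24.1, tolerance = 1e-9)
  noisy <- generate_temperature_year(2014, 0, seed = 3)
  fl2 <- accumulate_gdd(noisy, cal$transplanting, cal$flowering)
  expect_equal(fl2$mean_t, 24.1, tolerance = 0.6)
})

test_that("trial generation is reproducible and has the design arithmetic", {
  des <- trial_design(dropout_rate = 0)
  cfg <- generator_config(seed = 11)
  t1 <- generate_trial(des, cfg)
  t2 <- generate_trial(des, cfg)
  expect_identical(t1$observations, t2$observations)
  expect_identical(t1$temperatures, t2$temperatures)
  # 3 years x 4 regimes x 5 densities x 3 reps x 1 species
  expect_equal(nrow(t1$observations), 180)
  expect_equal(nrow(t1$levels), 12)
  t3 <- generate_trial(des, generator_config(seed = 12))
  expect_false(identical(t1$observations$yield_t_ha, t3$observations$yield_t_ha))
})

test_that("dropout removes roughly the configured fraction of pots", {
  des <- trial_design(dropout_rate = 0.08)
  n <- nrow(generate_trial(des, generator_config(seed = 13))$observations)
  expect_lt(n, 180)
  expect_gt(n, 180 * 0.8)
})

test_that("noise-free, sterility-off observations equal the model predictions", {
  tr <- sim_exact_trial(seed = 14, noise_sd = 0, dropout = 0)
  p <- truth_lw()
  mu <- mapply(function(g, x) combined_yield(p, g, x),
               tr$observations$gdd_flowering, tr$observations$density)
  expect_equal(tr$observations$yield_t_ha, pmax(mu, 0), tolerance = 1e-12)
})

test_that("the sterility knob collapses the hottest year like the observed pattern", {
  expect_equal(sterility_multiplier(31, 31, 2), 0.5)
  expect_gt(sterility_multiplier(24), 0.999)
  tt <- seq(25, 37, by = 0.5)
  expect_true(all(diff(sterility_multiplier(tt)) < 0))

  tr <- generate_trial(trial_design(dropout_rate = 0),
                       generator_config(seed = 15, noise_sd = 0.3))
  inc <- included_levels(tr$observations)
  hot16 <- inc$year == 2016 & inc$regime_label %in% c("A+3.0", "A+5.0")
  expect_true(all(inc$weedfree_mean[hot16] < 1.5))
  cool14 <- inc$year == 2014
  expect_true(all(inc$weedfree_mean[cool14] > 4))
})

test_that("yield components multiply back to the pre-noise yield", {
  cfg <- generator_config(seed = 16, noise_sd = 0.4)
  tr <- generate_trial(trial_design(dropout_rate = 0), cfg)
  comp <- generate_components(tr$observations, cfg)
  recon <- comp$panicles_m2 * comp$grains_per_panicle * (comp$pct_ripened / 100) *
    comp$grain_weight_g / 1000 * 0.01
  p <- truth_lw()
  mu <- mapply(function(g, x) combined_yield(p, g, x),
               comp$gdd_flowering, comp$density) *
    sterility_multiplier(comp$mean_t_flowering)
  expect_equal(recon, mu, tolerance = 1e-9)

  # density depresses panicle count; heat depresses % ripened at density 0
  d0 <- comp[comp$density == 0, ]
  expect_true(all(d0$panicles_m2 == max(comp$panicles_m2)))
  by_lev <- comp |>
    dplyr::group_by(year, regime_label) |>
    dplyr::summarise(p0 = max(panicles_m2), rip = mean(pct_ripened),
                     t = mean(mean_t_flowering), .groups = "drop")
  expect_lt(by_lev$rip[which.max(by_lev$t)], by_lev$rip[which.min(by_lev$t)])
  hi <- comp[comp$density == max(comp$density), ]
  expect_true(all(hi$panicles_m2 < max(comp$panicles_m2)))
})

test_that("end-to-end closure: zero-noise generator output returns the truth", {
  tr <- sim_exact_trial(seed = 17, noise_sd = 0, dropout = 0)
  f <- fit_combined(tr$observations)
  est <- setNames(tidy(f)$estimate, tidy(f)$term)
  expect_equal(est, unlist(unclass(truth_lw())), tolerance = 1e-4)
})
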