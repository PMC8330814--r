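test_that("noise-free hyperbola data returns the generating parameters", {
  d <- make_level_data(5, 0.01)
  f <- fit_hyperbola(d)
  expect_s3_class(f, "rh_fit")
  expect_equal(tidy(f)$estimate, c(5, 0.01), tolerance = 1e-6)
  expect_equal(f$rss, 0, tolerance = 1e-10)
  expect_true(f$converged)
  expect_equal(glance(f)$df_resid, nrow(d) - 2)
})

test_that("flat yields give zero competitiveness and the mean as weed-free yield", {
  d <- tidyr::expand_grid(density = c(0, 20, 40, 80), replicate = 1:3)
  d$yield_t_ha <- 5
  f <- fit_hyperbola(d)
  expect_equal(tidy(f)$estimate[1], 5, tolerance = 1e-6)
  expect_equal(tidy(f)$estimate[2], 0, tolerance = 1e-6)
})

test_that("fit_hyperbola enforces its design preconditions", {
  expect_error(fit_hyperbola(tibble::tibble(density = c(0, 10), yield_t_ha = c(5, 4))),
               "at least 3")
  d <- tibble::tibble(density = rep(40, 5), yield_t_ha = rnorm(5, 4, 0.1))
  expect_error(fit_hyperbola(d), "distinct")
  near0 <- make_level_data(0.3, 0.01, sd = 0.05, seed = 2)
  expect_warning(fit_hyperbola(near0), "unstable")
})

test_that("optimizer matches the dense grid-search oracle on noisy instances", {
  set.seed(7)
  for (i in 1:10) {
    d <- make_level_data(runif(1, 3, 7), runif(1, 0.002, 0.05), sd = 0.5)
    f <- fit_hyperbola(d)
    oracle <- oracle_grid_rss(d$density, d$yield_t_ha)
    expect_lte(f$rss, oracle$rss + 1e-6)
    expect_equal(f$rss, oracle$rss, tolerance = 1e-6)
  }
})

test_that("standard errors contract as noise shrinks and come from the Jacobian", {
  d_hi <- make_level_data(5, 0.01, sd = 0.6, seed = 5)
  d_lo <- make_level_data(5, 0.01, sd = 0.1, seed = 5)
  se_hi <- tidy(fit_hyperbola(d_hi))$std.error
  se_lo <- tidy(fit_hyperbola(d_lo))$std.error
  expect_true(all(se_lo < se_hi))
  expect_true(all(se_lo > 0))
})

test_that("pooled per-level fit sums level RSS and counts two parameters per level", {
  tr <- sim_exact_trial(seed = 21, noise_sd = 0.4, dropout = 0)
  f <- fit_per_level_pooled(tr$observations)
  lp <- f$level_params
  expect_equal(f$rss, sum(lp$rss))
  expect_equal(f$n_params, 2L * nrow(lp))
  expect_equal(f$n_obs, sum(lp$n_obs))
  expect_equal(f$df_resid, f$n_obs - f$n_params)
  # single level reduces to fit_hyperbola
  one <- dplyr::filter(tr$observations, year == 2014, regime_label == "A")
  f1 <- fit_hyperbola(one)
  expect_equal(lp$y0[lp$year == 2014 & lp$regime_label == "A"],
               tidy(f1)$estimate[1], tolerance = 1e-8)
})

test_that("the level-inclusion rule drops near-collapse levels", {
  tr <- generate_trial(trial_design(dropout_rate = 0),
                       generator_config(seed = 31, noise_sd = 0.2))
  inc <- included_levels(tr$observations)
  expect_equal(nrow(inc), 12)
  collapsed <- inc$weedfree_mean < 1
  expect_true(any(collapsed))  # sterility-on default wipes out the hottest 2016 levels
  expect_equal(inc$included, !collapsed)
  f <- suppressWarnings(fit_per_level_pooled(tr$observations))
  expect_equal(f$n_params, 2L * sum(inc$included))
})

test_that("noise-free data from the combined truth is recovered by all joint fits", {
  tr <- sim_exact_trial(seed = 41, noise_sd = 0, dropout = 0)
  truth <- unlist(unclass(truth_lw()))

  f4 <- suppressWarnings(fit_intermediate(tr$observations))
  est4 <- setNames(tidy(f4)$estimate, tidy(f4)$term)
  expect_equal(est4[c("a", "b", "c")], truth[c("a", "b", "c")], tolerance = 1e-4)
  # each level's beta equals l + m * GDD of that level
  lev <- tr$levels
  beta_terms <- tidy(f4)[grepl("^beta_", tidy(f4)$term), ]
  expect_equal(sort(beta_terms$estimate),
               sort(linear_beta(truth["l"], truth["m"], lev$gdd_flowering)),
               tolerance = 1e-3, ignore_attr = TRUE)

  f5 <- fit_combined(tr$observations)
  est5 <- setNames(tidy(f5)$estimate, tidy(f5)$term)
  expect_equal(est5, truth, tolerance = 1e-4)
  expect_equal(f5$n_params, 5L)
})

test_that("nested fits have monotone RSS on simulated data", {
  for (seed in c(61, 62, 63)) {
    tr <- sim_exact_trial(seed = seed, noise_sd = 0.5)
    obs <- tr$observations
    f3 <- suppressWarnings(fit_per_level_pooled(obs))
    f4 <- suppressWarnings(fit_intermediate(obs))
    f5 <- fit_combined(obs)
    expect_gte(f4$rss, f3$rss - 1e-8)
    expect_gte(f5$rss, f4$rss - 1e-8)
  }
})

test_that("stage-2 regressions match their closed forms", {
  # exact parabola -> exact coefficients, zero RSS, pseudo-R2 = 1
  g <- c(1300, 1450, 1600, 1750, 1900)
  d <- tibble::tibble(gdd_flowering = g, y0 = quadratic_y0(-16, 0.03, -1e-5, g))
  fq <- fit_stage2_quadratic(d)
  expect_equal(tidy(fq)$estimate, c(-16, 0.03, -1e-5), tolerance = 1e-6)
  expect_equal(fq$rss, 0, tolerance = 1e-12)
  expect_equal(fq$pseudo_r2, 1, tolerance = 1e-9)

  # noisy line: slope equals the covariance / variance closed form
  set.seed(9)
  dl <- tibble::tibble(gdd_flowering = g, beta = linear_beta(-0.02, 2e-5, g) + rnorm(5, 0, 1e-3))
  fl <- fit_stage2_linear(dl)
  slope_cf <- cov(dl$gdd_flowering, dl$beta) / var(dl$gdd_flowering)
  expect_equal(tidy(fl)$estimate[2], slope_cf, tolerance = 1e-12)
  expect_equal(tidy(fl)$estimate[1], mean(dl$beta) - slope_cf * mean(dl$gdd_flowering),
               tolerance = 1e-12)

  expect_error(fit_stage2_quadratic(d[1:3, ]), "at least 4")
  expect_error(fit_stage2_linear(dl[1:2, ]), "at least 3")
})

test_that("fit statistics follow their definitions", {
  y <- c(1, 2, 3, 4)
  expect_equal(pseudo_r2(0, y), 1)
  expect_equal(pseudo_r2(sum((y - mean(y))^2), y), 0)
  expect_lt(pseudo_r2(10, y), 0)  # worse than the mean is allowed
  expect_error(pseudo_r2(1, c(2, 2, 2)), "zero variance")
  expect_equal(rms(0, 7), 0)
  expect_equal(rms(4, 4), 1)
  expect_error(rms(1, 0), "positive")
})

test_that("default-noise simulations give per-level RMS in the plausible band", {
  tr <- sim_exact_trial(seed = 77, noise_sd = 0.5, dropout = 0)
  f <- fit_per_level_pooled(tr$observations)
  expect_true(all(f$level_params$rms > 0.15 & f$level_params$rms < 1.1))
  expect_true(median(f$level_params$rms) > 0.3 && median(f$level_params$rms) < 0.9)
})

test_that("stochastic recovery: truth within 3 SEs for most replicates", {
  truth <- unlist(unclass(truth_lw()))
  hits <- matrix(NA, 30, 5, dimnames = list(NULL, names(truth)))
  for (i in seq_len(nrow(hits))) {
    tr <- sim_exact_trial(seed = 300 + i, noise_sd = 0.5)
    f <- suppressWarnings(fit_combined(tr$observations))
    td <- tidy(f)
    hits[i, ] <- abs(td$estimate - truth) <= 3 * td$std.error
  }
  expect_true(all(colMeans(hits) >= 0.85))
})
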