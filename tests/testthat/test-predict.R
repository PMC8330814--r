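test_that("the prediction surface composes model evaluations elementwise", {
  p <- truth_lw()
  s <- predict_surface(p, c(1300, 1500, 1700, 1900), c(0, 20, 40, 80))
  expect_equal(nrow(s), 16)
  d0 <- s[s$density == 0, ]
  expect_equal(d0$yield, pmax(quadratic_y0(p$a, p$b, p$c, d0$gdd), 0))
  expect_equal(d0$relative, rep(1, 4))
  one <- predict_surface(p, 1500, 80)
  expect_equal(one$yield, combined_yield(p, 1500, 80))
  # relative values stay in (0, 1] where competitiveness is non-negative
  pos <- linear_beta(p$l, p$m, s$gdd) >= 0
  expect_true(all(s$relative[pos] > 0 & s$relative[pos] <= 1))
})

test_that("negative model yields are clamped and flagged in reporting only", {
  p <- suppressWarnings(combined_params(-33.4, 0.05, -0.00002, -0.031, 0.00003))
  s <- predict_surface(p, c(1500, 2400), c(0, 40))
  far <- s[s$gdd == 2400, ]
  expect_true(all(far$yield == 0))
  expect_true(all(far$clamped))
  expect_lt(quadratic_y0(p$a, p$b, p$c, 2400), 0)  # the model value stays algebraic
})

test_that("percent of weed-free yield matches the hand-computed caveat value", {
  p <- truth_lw()
  expect_equal(percent_of_weed_free(p, 0, 1300), 100)
  expect_equal(percent_of_weed_free(p, 80, 1300), 100 / 1.4, tolerance = 1e-12)
  expect_equal(round(percent_of_weed_free(p, 80, 1300), 1), 71.4)
  g <- c(1300, 1500, 1700, 1900)
  expect_true(all(diff(percent_of_weed_free(p, 80, g)) < 0))
})

test_that("moisture adjustment rescales to the 12% basis", {
  expect_equal(moisture_adjust(5, 0.12), 5)
  expect_equal(moisture_adjust(5.0, 0.20), 5 * 0.8 / 0.88)
  expect_equal(moisture_adjust(0, 0.5), 0)
  expect_error(moisture_adjust(5, 1), "moisture")
  expect_error(moisture_adjust(5, -0.1), "moisture")
})

test_that("the correlation screen is symmetric with unit diagonal and exact on lines", {
  set.seed(1)
  d <- tibble::tibble(a = rnorm(40))
  d$b <- 2 * d$a + 1          # exactly linear
  d$c <- rnorm(40)
  cs <- correlation_screen(d)
  expect_equal(cs$r[cs$var1 == "a" & cs$var2 == "b"], 1, tolerance = 1e-12)
  expect_equal(cs$r[cs$var1 == "a" & cs$var2 == "a"], 1)
  wide <- tidyr::pivot_wider(cs[, c("var1", "var2", "r")],
                             names_from = "var2", values_from = "r")
  m <- as.matrix(wide[, -1])
  expect_equal(m, t(m), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(correlation_screen(tibble::tibble(a = rep(1, 5), b = rnorm(5))),
               "constant")
  expect_error(correlation_screen(d[1:2, ]), "at least 3")
})

test_that("independent variables are flagged ns at roughly the nominal rate", {
  set.seed(2)
  flags <- replicate(200, {
    d <- tibble::tibble(u = rnorm(60), v = rnorm(60))
    cs <- correlation_screen(d)
    cs$signif[cs$var1 == "u" & cs$var2 == "v"]
  })
  expect_gt(mean(flags == "ns"), 0.90)
})

test_that("the synthetic-trial screen mirrors the component dissociation", {
  cfg <- generator_config(seed = 19, noise_sd = 0.3)
  tr <- generate_trial(trial_design(dropout_rate = 0), cfg)
  comp <- generate_components(tr$observations, cfg)
  cs <- correlation_screen(comp, vars = c("gdd_flowering", "density",
                                          "panicles_m2", "pct_ripened",
                                          "yield_t_ha"))
  r_of <- function(a, b) cs$r[cs$var1 == a & cs$var2 == b]
  sig_of <- function(a, b) cs$signif[cs$var1 == a & cs$var2 == b]
  expect_lt(r_of("density", "panicles_m2"), 0)
  expect_equal(sig_of("density", "panicles_m2"), "*")
  expect_lt(r_of("gdd_flowering", "pct_ripened"), 0)
  expect_equal(sig_of("gdd_flowering", "pct_ripened"), "*")
  expect_equal(sig_of("density", "pct_ripened"), "ns")
})
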