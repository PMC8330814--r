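# Small dataset builders and brute-force oracles used across the suite.

make_level_data <- function(y0, beta, densities = c(0, 20, 40, 80, 160),
                            reps = 3, sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- tidyr::expand_grid(density = densities, replicate = seq_len(reps))
  d$yield_t_ha <- hyperbola(y0, beta, d$density) + rnorm(nrow(d), 0, sd)
  d
}

# Independent brute-force oracle for the two-parameter hyperbola fit:
# iteratively zoomed dense grid search over (y0, beta). Never touches the
# package optimizer.
oracle_grid_rss <- function(x, y, y0_range = c(0, 10), beta_range = c(-0.01, 0.2),
                            n_grid = 41, zooms = 8) {
  best <- list(rss = Inf, y0 = NA, beta = NA)
  for (z in seq_len(zooms)) {
    y0s <- seq(y0_range[1], y0_range[2], length.out = n_grid)
    bes <- seq(beta_range[1], beta_range[2], length.out = n_grid)
    for (y0 in y0s) {
      for (be in bes) {
        den <- 1 + be * x
        if (any(den <= 1e-6)) next
        rss <- sum((y - y0 / den)^2)
        if (rss < best$rss) best <- list(rss = rss, y0 = y0, beta = be)
      }
    }
    sy <- diff(y0_range) / (n_grid - 1)
    sb <- diff(beta_range) / (n_grid - 1)
    y0_range <- c(best$y0 - 2 * sy, best$y0 + 2 * sy)
    beta_range <- c(best$beta - 2 * sb, best$beta + 2 * sb)
  }
  best
}

# Generating truth used throughout: the rounded combined-model estimates
# for the grass weed.
truth_lw <- function() combined_params(-16.0, 0.03, -0.00001, -0.021, 0.00002)

# A trial simulated exactly from the combined model (no sterility factor).
sim_exact_trial <- function(seed, noise_sd = 0.5, dropout = 0.08,
                            truth = truth_lw()) {
  generate_trial(
    trial_design(dropout_rate = dropout),
    generator_config(truth = truth, noise_sd = noise_sd,
                     sterility_enabled = FALSE, seed = seed)
  )
}

const_series <- function(t, n = 89, start = "2014-06-01") {
  tibble::tibble(date = seq(as.Date(start), by = 1, length.out = n),
                 t_mean_c = rep_len(t, n))
}
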