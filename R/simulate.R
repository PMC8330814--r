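# Seed hygiene: run `code` under a fixed RNG state, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Ambient flowering-window mean air temperatures (degrees C) used for the
# default year profiles; 2016 is the heat-collapse year.
default_year_profiles <- c(`2014` = 24.1, `2015` = 26.4, `2016` = 29.0)

#' Trial design for the synthetic phytotron experiment
#'
#' The default emulates a 3-year pot study: four temperature regimes
#' (ambient plus offsets of 0, 1.5, 3.0 and 5.0 degrees C), five weed
#' densities per year (0/10/20/40/80 plants per m^2 in the first year,
#' 0/20/40/80/160 thereafter), three replicates, one weed species, and a
#' small fraction of pots lost.
#'
#' @param years Named list mapping year to its density set (plants/m^2;
#'   must include 0).
#' @param regime_offsets Temperature offsets above ambient, degrees C.
#' @param replicates Replicates per density (>= 1).
#' @param species Weed species labels (`"late_watergrass"`,
#'   `"water_chestnut"`, or both).
#' @param dropout_rate Fraction of pots missing at harvest.
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(years = list(`2014` = c(0, 10, 20, 40, 80),
                                      `2015` = c(0, 20, 40, 80, 160),
                                      `2016` = c(0, 20, 40, 80, 160)),
                         regime_offsets = c(0, 1.5, 3.0, 5.0),
                         replicates = 3,
                         species = "late_watergrass",
                         dropout_rate = 0.08) {
  stopifnot(replicates >= 1, all(regime_offsets >= 0),
            dropout_rate >= 0, dropout_rate < 1)
  if (!all(vapply(years, function(d) 0 %in% d, logical(1)))) {
    stop("every year's density set must include 0 (the weed-free check)", call. = FALSE)
  }
  structure(list(years = years, regime_offsets = regime_offsets,
                 replicates = as.integer(replicates), species = species,
                 dropout_rate = dropout_rate),
            class = "trial_design")
}

#' Generator configuration for synthetic trials
#'
#' @param truth A [combined_params()] object (applied to every species) or
#'   a named list of them keyed by species. Default: the rounded
#'   late-watergrass combined-model estimates.
#' @param noise_sd Additive yield noise SD, t/ha (default 0.5, within the
#'   range of per-level fit RMS values seen in practice).
#' @param sterility_enabled Apply the heat-sterility yield multiplier
#'   (logistic in mean flowering temperature)? Default `TRUE`; turn off to
#'   simulate exactly from the combined model.
#' @param sterility_t50 Temperature of 50% spikelet sterility, degrees C.
#'   Default 31 — an invented calibration knob (not an estimated value)
#'   chosen so that yields collapse when flowering-period means exceed
#'   about 30 degrees C.
#' @param sterility_slope Logistic steepness, per degree C (default 2;
#'   invented calibration, as above).
#' @param temp_noise_sd Day-to-day temperature noise SD, degrees C.
#' @param seed Integer RNG seed; the whole trial is reproducible from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(truth = combined_params(-16.0, 0.03, -0.00001, -0.021, 0.00002),
                             noise_sd = 0.5,
                             sterility_enabled = TRUE,
                             sterility_t50 = 31,
                             sterility_slope = 2,
                             temp_noise_sd = 1.5,
                             seed = 1L) {
  stopifnot(noise_sd >= 0, temp_noise_sd >= 0)
  if (inherits(truth, "combined_params")) truth <- list(.all = truth)
  stopifnot(all(vapply(truth, inherits, logical(1), "combined_params")))
  structure(list(truth = truth, noise_sd = noise_sd,
                 sterility_enabled = sterility_enabled,
                 sterility_t50 = sterility_t50, sterility_slope = sterility_slope,
                 temp_noise_sd = temp_noise_sd, seed = as.integer(seed)),
            class = "generator_config")
}

truth_for_species <- function(config, species) {
  if (!is.null(config$truth[[species]])) config$truth[[species]]
  else if (!is.null(config$truth$.all)) config$truth$.all
  else stop("no truth parameters for species ", species, call. = FALSE)
}

#' Heat-sterility yield multiplier
#'
#' Logistic fraction of potential yield retained at a given mean air
#' temperature over the flowering period:
#' `1 / (1 + exp(slope * (t - t50)))`. Near 1 well below `t50`, 0.5 at
#' `t50`, near 0 well above — the spikelet-sterility collapse that sets in
#' when flowering-period means exceed about 30 degrees C.
#'
#' @param mean_flowering_t Mean air temperature over flowering, degrees C.
#' @param t50 Midpoint temperature, degrees C.
#' @param slope Steepness, per degree C.
#' @return Fraction in (0, 1). Vectorised.
#' @export
sterility_multiplier <- function(mean_flowering_t, t50 = 31, slope = 2) {
  stopifnot(is.finite(mean_flowering_t), is.finite(t50), is.finite(slope))
  1 / (1 + exp(slope * (mean_flowering_t - t50)))
}

#' Generate one season of daily mean temperatures for a regime
#'
#' A seasonal cosine over transplanting (June 1) to maturity (October 15)
#' whose flowering-window (June 1 to August 28) mean equals
#' `flowering_mean + regime_offset` in the noise-free part, plus
#' day-to-day Gaussian noise. With the same `seed`, regimes differ
#' pointwise by exactly their offset difference.
#'
#' @param year Season year.
#' @param regime_offset Offset above ambient, degrees C.
#' @param flowering_mean Ambient flowering-window mean, degrees C; default
#'   looked up from the built-in year profiles (24.1 / 26.4 / 29.0 for
#'   2014 / 2015 / 2016, else 25).
#' @param amplitude Seasonal cosine amplitude, degrees C.
#' @param peak_doy Day of year of the seasonal peak (default 217, early
#'   August).
#' @param noise_sd Day-to-day noise SD, degrees C.
#' @param seed RNG seed for the noise (same seed, same noise draws).
#' @param regime_label Label stored in the output.
#' @return Tibble with columns `regime_label`, `year`, `date`, `t_mean_c`.
#' @export
generate_temperature_year <- function(year, regime_offset = 0,
                                      flowering_mean = NULL,
                                      amplitude = 6, peak_doy = 217,
                                      noise_sd = 1.5, seed = 1L,
                                      regime_label = NULL) {
  if (is.null(flowering_mean)) {
    flowering_mean <- default_year_profiles[as.character(year)]
    if (is.na(flowering_mean)) flowering_mean <- 25
  }
  if (is.null(regime_label)) {
    regime_label <- if (regime_offset == 0) "A" else sprintf("A+%.1f", regime_offset)
  }
  cal <- stage_calendar(year)
  dates <- seq(cal$transplanting, cal$maturity, by = "day")
  doy <- as.integer(format(dates, "%j"))
  shape <- amplitude * cos(2 * pi * (doy - peak_doy) / 365)
  in_flower <- dates <= cal$flowering
  base <- flowering_mean + regime_offset - mean(shape[in_flower])
  noise <- with_seed(seed, rnorm(length(dates), 0, noise_sd))
  tibble::tibble(
    regime_label = regime_label, year = as.integer(year),
    date = dates, t_mean_c = base + shape + noise
  )
}

#' Generate a synthetic competition trial
#'
#' Builds daily temperature series for every year-by-regime level,
#' accumulates flowering GDD, and draws pot-level grain yields from the
#' combined rectangular hyperbolic model:
#' `Y = combined_yield(truth, GDD, X) * sterility + N(0, noise_sd)`,
#' clamped at zero, with optional random pot dropout. Fully reproducible
#' from `config$seed`.
#'
#' @param design A [trial_design()].
#' @param config A [generator_config()].
#' @return A list of class `rh_trial`: `observations` (one row per pot:
#'   `year`, `regime_label`, `regime_offset`, `gdd_flowering`,
#'   `mean_t_flowering`, `species`, `density`, `replicate`,
#'   `yield_t_ha`), `levels` (per-level GDD and temperature bookkeeping),
#'   `temperatures` (daily series), and the design/config used.
#' @examples
#' tr <- generate_trial(trial_design(), generator_config(seed = 42))
#' dplyr::count(tr$observations, year, regime_label)
#' @export
generate_trial <- function(design = trial_design(), config = generator_config()) {
  stopifnot(inherits(design, "trial_design"), inherits(config, "generator_config"))
  with_seed(config$seed, {
    years <- as.integer(names(design$years))
    grid <- tidyr::expand_grid(year = years, regime_offset = design$regime_offsets)
    series_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))

    levels <- purrr::pmap(
      list(grid$year, grid$regime_offset, series_seeds),
      function(yr, off, sseed) {
        ser <- generate_temperature_year(yr, off, noise_sd = config$temp_noise_sd,
                                         seed = sseed)
        cal <- stage_calendar(yr)
        ss <- stage_summary(ser, cal)
        tibble::tibble(
          year = as.integer(yr), regime_label = ser$regime_label[1],
          regime_offset = off,
          gdd_tillering = ss$gdd[ss$window_label == "to_tillering"],
          gdd_flowering = ss$gdd[ss$window_label == "to_flowering"],
          gdd_maturity = ss$gdd[ss$window_label == "to_maturity"],
          mean_t_flowering = ss$mean_t[ss$window_label == "to_flowering"],
          series = list(ser)
        )
      }
    ) |> purrr::list_rbind()

    temperatures <- purrr::list_rbind(levels$series)
    levels$series <- NULL
    levels$sterility <- sterility_multiplier(levels$mean_t_flowering,
                                             config$sterility_t50,
                                             config$sterility_slope)

    obs <- purrr::imap(design$years, function(dens, yr) {
      tidyr::expand_grid(year = as.integer(yr),
                         regime_offset = design$regime_offsets,
                         species = design$species,
                         density = dens,
                         replicate = seq_len(design$replicates))
    }) |>
      purrr::list_rbind() |>
      dplyr::inner_join(levels[, c("year", "regime_offset", "regime_label",
                                   "gdd_flowering", "mean_t_flowering", "sterility")],
                        by = c("year", "regime_offset"))

    mu <- purrr::map_dbl(seq_len(nrow(obs)), function(i) {
      combined_yield(truth_for_species(config, obs$species[i]),
                     obs$gdd_flowering[i], obs$density[i])
    })
    if (config$sterility_enabled) mu <- mu * obs$sterility
    obs$yield_t_ha <- pmax(mu + rnorm(nrow(obs), 0, config$noise_sd), 0)
    obs$sterility <- NULL

    if (design$dropout_rate > 0) {
      obs <- obs[runif(nrow(obs)) >= design$dropout_rate, , drop = FALSE]
    }
    obs <- dplyr::arrange(obs, .data$year, .data$regime_offset, .data$species,
                          .data$density, .data$replicate) |>
      dplyr::relocate("year", "regime_label", "regime_offset", "gdd_flowering",
                      "mean_t_flowering", "species", "density", "replicate",
                      "yield_t_ha")

    structure(list(observations = obs, levels = levels,
                   temperatures = temperatures,
                   design = design, config = config),
              class = "rh_trial")
  })
}

#' @export
print.rh_trial <- function(x, ...) {
  cat("<rh_trial>", nrow(x$observations), "pot observations,",
      nrow(x$levels), "year-by-regime levels, seed", x$config$seed, "\n")
  print(x$levels, n = 12)
  invisible(x)
}

#' Decompose synthetic yields into yield components
#'
#' Adds a multiplicative yield-component decomposition to generated
#' observations: weed density depresses panicle count hyperbolically,
#' flowering-period heat depresses the percentage of ripened grain
#' logistically, and grains per panicle absorbs the remaining (thermal
#' time) signal so that
#' `panicles * grains * ripened * grain_wt/1000 * 0.01` reconstructs the
#' pre-noise yield exactly.
#'
#' @param observations Observation tibble from [generate_trial()] (needs
#'   `gdd_flowering`, `mean_t_flowering`, `species`, `density`).
#' @param config The [generator_config()] the trial was generated with.
#' @param panicle_max Weed-free panicle count, per m^2.
#' @param grain_weight_g 1000-grain weight, g.
#' @return The input with columns `panicles_m2`, `grains_per_panicle`,
#'   `pct_ripened` (percent) and `grain_weight_g` appended.
#' @export
generate_components <- function(observations, config,
                                panicle_max = 400, grain_weight_g = 22) {
  stopifnot(all(c("gdd_flowering", "mean_t_flowering", "species", "density")
                %in% names(observations)))
  n <- nrow(observations)
  mu <- purrr::map_dbl(seq_len(n), function(i) {
    combined_yield(truth_for_species(config, observations$species[i]),
                   observations$gdd_flowering[i], observations$density[i])
  })
  ripened <- sterility_multiplier(observations$mean_t_flowering,
                                  config$sterility_t50, config$sterility_slope)
  if (config$sterility_enabled) mu <- mu * ripened
  beta_now <- purrr::map_dbl(seq_len(n), function(i) {
    tr <- truth_for_species(config, observations$species[i])
    max(linear_beta(tr$l, tr$m, observations$gdd_flowering[i]), 0)
  })
  panicles <- panicle_max / (1 + beta_now * observations$density)
  # t/ha = panicles/m2 * grains * ripened * (g/1000 grains) / 1000 g/kg * 10 (kg/m2 -> t/ha)
  scale <- grain_weight_g / 1000 * 0.01
  grains <- mu / (panicles * ripened * scale)
  dplyr::mutate(tibble::as_tibble(observations),
                panicles_m2 = panicles,
                grains_per_panicle = grains,
                pct_ripened = 100 * ripened,
                grain_weight_g = grain_weight_g)
}
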