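obs_required_cols <- c("year", "regime_label", "gdd_flowering",
                       "species", "density", "replicate", "yield_t_ha")

#' Read and validate a long-format observation table
#'
#' One row per pot: design coordinates plus grain yield. Lines starting
#' with `#` are treated as metadata comments (as written by
#' [write_trial()]). Schema violations are reported with row numbers;
#' plausibility range checks guard against unit mix-ups (density must be
#' within 0-1000 plants/m^2, yield within 0-20 t/ha).
#'
#' @param path CSV file with columns `year`, `regime_label`,
#'   `gdd_flowering`, `species`, `density`, `replicate`, `yield_t_ha`.
#' @return Validated tibble.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  miss <- setdiff(obs_required_cols, names(d))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  problems <- character()
  row_msg <- function(idx, what) {
    if (any(idx, na.rm = TRUE)) {
      problems <<- c(problems,
                     paste0(what, " at row(s) ", paste(utils::head(which(idx), 5), collapse = ", ")))
    }
  }
  num_cols <- c("year", "gdd_flowering", "density", "replicate", "yield_t_ha")
  for (cc in num_cols) {
    row_msg(!is.finite(suppressWarnings(as.numeric(d[[cc]]))),
            paste0("unparsable/missing `", cc, "`"))
  }
  row_msg(d$density < 0 | d$density > 1000, "density outside [0, 1000] plants/m^2")
  row_msg(d$yield_t_ha < 0 | d$yield_t_ha > 20, "yield outside [0, 20] t/ha")
  key <- paste(d$year, d$regime_label, d$species, d$density, d$replicate)
  row_msg(duplicated(key), "duplicate (year, regime, species, density, replicate) key")
  if (length(problems)) {
    stop("invalid observation file:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  }
  d
}

#' Read a daily temperature table
#'
#' @param path CSV with columns `date` (ISO-8601), `regime_label` (or
#'   `regime`), `year`, `t_mean_c`.
#' @return Tibble with parsed dates, ready for [accumulate_gdd()] after
#'   filtering to one regime-year.
#' @export
read_temperatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if ("regime" %in% names(d) && !"regime_label" %in% names(d)) {
    d <- dplyr::rename(d, regime_label = "regime")
  }
  miss <- setdiff(c("date", "regime_label", "year", "t_mean_c"), names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d$date <- as.Date(d$date)
  if (anyNA(d$date)) stop("unparsable dates (expect ISO-8601)", call. = FALSE)
  d
}

#' Write a generated trial to CSV
#'
#' Writes `observations.csv` and `temperatures.csv` under `dir`, each
#' headed by `#`-comment metadata recording the seed and generator
#' settings, so any downstream file is self-describing and the run can be
#' reproduced.
#'
#' @param trial An `rh_trial` from [generate_trial()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "rh_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- trial$config
  truth_txt <- paste(vapply(names(cfg$truth), function(sp) {
    p <- cfg$truth[[sp]]
    sprintf("%s: a=%g b=%g c=%g l=%g m=%g", sp, p$a, p$b, p$c, p$l, p$m)
  }, character(1)), collapse = "; ")
  header <- c(
    sprintf("# seed: %d", cfg$seed),
    sprintf("# noise_sd_t_ha: %g", cfg$noise_sd),
    sprintf("# sterility: enabled=%s t50=%g slope=%g",
            cfg$sterility_enabled, cfg$sterility_t50, cfg$sterility_slope),
    sprintf("# dropout_rate: %g", trial$design$dropout_rate),
    sprintf("# truth: %s", truth_txt)
  )
  obs_path <- file.path(dir, "observations.csv")
  tmp_path <- file.path(dir, "temperatures.csv")
  writeLines(header, obs_path)
  readr::write_csv(trial$observations, obs_path, append = TRUE, col_names = TRUE)
  writeLines(header, tmp_path)
  readr::write_csv(trial$temperatures, tmp_path, append = TRUE, col_names = TRUE)
  invisible(c(observations = obs_path, temperatures = tmp_path))
}
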