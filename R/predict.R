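#' Yield prediction surface over GDD and weed density
#'
#' Evaluates the combined rectangular hyperbolic model on a grid of
#' flowering GDD values and weed densities. Negative model yields are
#' reported as 0 with `clamped = TRUE` (a reporting-layer clamp only;
#' model functions themselves return the algebraic value). A grid cell at
#' a pole of the model is flagged, not fatal.
#'
#' @param params A [combined_params()] object (or a combined-model
#'   `rh_fit` via [as_combined_params()]).
#' @param gdd_values Flowering GDD grid, degrees C x days.
#' @param densities Weed density grid, plants/m^2.
#' @return Long-format tibble of class `rh_surface`: `gdd`, `density`,
#'   `yield` (t/ha, clamped at 0), `relative` (fraction of the weed-free
#'   yield at the same GDD), `clamped`, `pole` flags.
#' @export
predict_surface <- function(params, gdd_values, densities) {
  if (inherits(params, "rh_fit")) params <- as_combined_params(params)
  p <- as.list(params)
  grid <- tidyr::expand_grid(gdd = gdd_values, density = densities)
  beta <- linear_beta(p$l, p$m, grid$gdd)
  denom <- 1 + beta * grid$density
  pole <- abs(denom) < 1e-9 | denom < 0
  y_raw <- ifelse(pole, NA_real_, quadratic_y0(p$a, p$b, p$c, grid$gdd) / denom)
  rel <- ifelse(pole, NA_real_, 1 / denom)
  out <- dplyr::mutate(grid,
                       yield = pmax(y_raw, 0),
                       relative = rel,
                       clamped = !pole & y_raw < 0,
                       pole = pole)
  class(out) <- c("rh_surface", class(out))
  out
}

#' Predicted yield as a percentage of the weed-free yield
#'
#' `100 / (1 + (l + m gdd) x)`: the share of the weed-free yield retained
#' at density `x`, which depends only on the competitiveness parameters.
#' Decreasing in GDD whenever the competitiveness slope `m` is positive.
#'
#' @param params A [combined_params()] object.
#' @param x Weed density, plants/m^2.
#' @param gdd Flowering GDD, degrees C x days.
#' @return Percentage (100 at `x = 0`). Vectorised over `x` and `gdd`.
#' @examples
#' p <- combined_params(-16.0, 0.03, -0.00001, -0.021, 0.00002)
#' percent_of_weed_free(p, 80, 1300)  # 71.4
#' @export
percent_of_weed_free <- function(params, x, gdd) {
  p <- as.list(params)
  100 * relative_yield(linear_beta(p$l, p$m, gdd), x)
}

#' Pairwise correlation screen
#'
#' Product-moment (Pearson) correlations among the numeric columns of a
#' trial table — typically GDD windows, weed density, yield components
#' and grain yield — with two-sided t-test significance flags at `alpha`.
#'
#' @param data Data frame; all columns in `vars` must be numeric with
#'   nonzero variance, and at least 3 complete rows are required.
#' @param vars Columns to screen (default: every numeric column).
#' @param alpha Significance level for the flag (default 0.05).
#' @return Tibble of class `rh_corr`: `var1`, `var2`, `r`, `n`,
#'   `p_value`, `signif` (`"*"` or `"ns"`; `""` on the diagonal). The
#'   full symmetric matrix, one row per ordered pair.
#' @export
correlation_screen <- function(data, vars = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  stopifnot(length(vars) >= 2, all(vars %in% names(data)))
  d <- stats::na.omit(data[, vars, drop = FALSE])
  if (nrow(d) < 3) stop("need at least 3 complete rows", call. = FALSE)
  bad <- vars[vapply(d, function(v) var(v) == 0, logical(1))]
  if (length(bad)) {
    stop("undefined correlation: constant variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(d)
  out <- tidyr::expand_grid(var1 = vars, var2 = vars) |>
    dplyr::mutate(
      r = purrr::map2_dbl(.data$var1, .data$var2, ~ cor(d[[.x]], d[[.y]])),
      n = n
    ) |>
    dplyr::mutate(
      t_stat = .data$r * sqrt((n - 2) / pmax(1 - .data$r^2, 1e-300)),
      p_value = ifelse(.data$var1 == .data$var2, NA_real_,
                       2 * pt(abs(.data$t_stat), n - 2, lower.tail = FALSE)),
      signif = dplyr::case_when(
        .data$var1 == .data$var2 ~ "",
        .data$p_value < alpha ~ "*",
        TRUE ~ "ns"
      )
    ) |>
    dplyr::select(-"t_stat")
  class(out) <- c("rh_corr", class(out))
  out
}

#' Adjust fresh grain yield to 12% moisture
#'
#' Standard reporting basis for paddy rice: dry matter is preserved and
#' re-expressed at 12% grain moisture,
#' `yield * (1 - moisture) / (1 - 0.12)`.
#'
#' @param fresh_yield Yield at harvest moisture, t/ha.
#' @param moisture_fraction Grain moisture at harvest, in `[0, 1)`.
#' @return Yield at 12% moisture, t/ha.
#' @export
moisture_adjust <- function(fresh_yield, moisture_fraction) {
  if (any(!is.finite(moisture_fraction)) ||
      any(moisture_fraction < 0) || any(moisture_fraction >= 1)) {
    stop("moisture_fraction must be in [0, 1)", call. = FALSE)
  }
  fresh_yield * (1 - moisture_fraction) / 0.88
}
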