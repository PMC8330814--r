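#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   facet_wrap labs theme_minimal scale_fill_viridis_c geom_smooth
NULL

#' Plot a synthetic trial: yield against weed density per level
#'
#' The classic panel layout of a competition trial: observed grain yield
#' against weed density, one panel per year, coloured by regime.
#'
#' @param object An `rh_trial` from [generate_trial()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rh_trial
#' @export
autoplot.rh_trial <- function(object, ...) {
  ggplot(object$observations,
         aes(x = .data$density, y = .data$yield_t_ha,
             colour = .data$regime_label)) +
    geom_point(alpha = 0.7) +
    facet_wrap(~year) +
    labs(x = expression(Weed~density~(plants~m^-2)),
         y = expression(Grain~yield~(t~ha^-1)),
         colour = "Regime") +
    theme_minimal()
}

#' Plot a fitted competition model
#'
#' For a per-level fit, observed yields with the fitted rectangular
#' hyperbola per level (the yield-density panels). For a combined fit,
#' fitted yield-density curves at each level's GDD over the observed
#' density range. For the stage-2 regressions, the per-level estimates
#' with the fitted quadratic/linear curve.
#'
#' @param object An `rh_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rh_fit
#' @export
autoplot.rh_fit <- function(object, ...) {
  if (object$model_id == "per_level" && !is.null(object$level_params)) {
    lp <- object$level_params
    curves <- purrr::pmap(
      list(lp$year, lp$regime_label, lp$gdd_flowering, lp$y0, lp$beta),
      function(yr, reg, gdd, y0, beta) {
        xmax <- max(object$data$density[object$data$year == yr &
                                          object$data$regime_label == reg])
        tibble::tibble(year = yr, regime_label = reg,
                       density = seq(0, xmax, length.out = 60),
                       yield_t_ha = hyperbola(y0, beta, seq(0, xmax, length.out = 60)))
      }
    ) |> purrr::list_rbind()
    return(
      ggplot(object$data, aes(x = .data$density, y = .data$yield_t_ha,
                              colour = .data$regime_label)) +
        geom_point(alpha = 0.6) +
        geom_line(data = curves) +
        facet_wrap(~year) +
        labs(x = expression(Weed~density~(plants~m^-2)),
             y = expression(Grain~yield~(t~ha^-1)), colour = "Regime") +
        theme_minimal()
    )
  }
  if (object$model_id == "combined") {
    p <- as_combined_params(object)
    gdds <- sort(unique(object$data$gdd_flowering))
    xmax <- max(object$data$density)
    curves <- tidyr::expand_grid(gdd_flowering = gdds,
                                 density = seq(0, xmax, length.out = 60)) |>
      dplyr::mutate(yield_t_ha = purrr::map2_dbl(.data$gdd_flowering, .data$density,
                                                 ~ combined_yield(p, .x, .y)))
    return(
      ggplot(object$data, aes(x = .data$density, y = .data$yield_t_ha)) +
        geom_point(alpha = 0.5) +
        geom_line(data = curves, colour = "firebrick") +
        facet_wrap(~round(gdd_flowering)) +
        labs(x = expression(Weed~density~(plants~m^-2)),
             y = expression(Grain~yield~(t~ha^-1)),
             title = "Combined model fit by flowering GDD") +
        theme_minimal()
    )
  }
  if (object$model_id %in% c("quadratic_stage2", "linear_stage2")) {
    stop("use plot_stage2() with the per-level fit for the stage-2 view", call. = FALSE)
  }
  stop("no autoplot method for model_id ", object$model_id, call. = FALSE)
}

#' Two-stage view: per-level parameters against GDD
#'
#' Plots the per-level weed-free yield estimates with the fitted
#' quadratic, and the per-level competitiveness estimates with the fitted
#' line, side by side (patchwork-free: returns a single faceted plot).
#'
#' @param per_level_fit An `rh_fit` from [fit_per_level_pooled()].
#' @return A ggplot object.
#' @export
plot_stage2 <- function(per_level_fit) {
  stopifnot(inherits(per_level_fit, "rh_fit"),
            !is.null(per_level_fit$level_params))
  lp <- per_level_fit$level_params
  q <- fit_stage2_quadratic(lp)
  l <- fit_stage2_linear(lp)
  gg <- seq(min(lp$gdd_flowering), max(lp$gdd_flowering), length.out = 100)
  qe <- q$parameters$estimate
  le <- l$parameters$estimate
  pts <- dplyr::bind_rows(
    tibble::tibble(panel = "weed-free yield y0 (t/ha)",
                   gdd = lp$gdd_flowering, value = lp$y0),
    tibble::tibble(panel = "competitiveness beta",
                   gdd = lp$gdd_flowering, value = lp$beta)
  )
  lines <- dplyr::bind_rows(
    tibble::tibble(panel = "weed-free yield y0 (t/ha)", gdd = gg,
                   value = quadratic_y0(qe[1], qe[2], qe[3], gg)),
    tibble::tibble(panel = "competitiveness beta", gdd = gg,
                   value = linear_beta(le[1], le[2], gg))
  )
  ggplot(pts, aes(x = .data$gdd, y = .data$value)) +
    geom_point() +
    geom_line(data = lines, colour = "firebrick") +
    facet_wrap(~panel, scales = "free_y") +
    labs(x = expression(GDD~to~flowering~(degree*C%.%days)), y = NULL) +
    theme_minimal()
}

#' Plot a prediction surface
#'
#' Heat-map of predicted yield over the GDD-by-density grid.
#'
#' @param object An `rh_surface` from [predict_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rh_surface
#' @export
autoplot.rh_surface <- function(object, ...) {
  ggplot(object, aes(x = .data$gdd, y = .data$density, fill = .data$yield)) +
    geom_tile() +
    scale_fill_viridis_c(name = expression(Yield~(t~ha^-1))) +
    labs(x = expression(GDD~to~flowering~(degree*C%.%days)),
         y = expression(Weed~density~(plants~m^-2))) +
    theme_minimal()
}

#' Plot a correlation screen
#'
#' Tile map of the pairwise correlation matrix with significance marks.
#'
#' @param object An `rh_corr` from [correlation_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rh_corr
#' @export
autoplot.rh_corr <- function(object, ...) {
  ggplot(object, aes(x = .data$var1, y = .data$var2, fill = .data$r)) +
    geom_tile() +
    ggplot2::geom_text(aes(label = ifelse(.data$signif == "", "",
                                          sprintf("%.2f%s", .data$r,
                                                  ifelse(.data$signif == "*", "*", "")))),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
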