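#' Rectangular hyperbolic yield-loss model
#'
#' Cousens-type yield-density response: `y0 / (1 + beta * x)`, where `y0`
#' is the weed-free crop yield and `beta` measures per-plant weed
#' competitiveness. Strictly decreasing in `x` for positive `y0`, `beta`;
#' equal to `y0` at zero density.
#'
#' @param y0 Weed-free grain yield, t/ha.
#' @param beta Weed competitiveness, per (plants/m^2).
#' @param x Weed density, plants/m^2. Vectorised (usual recycling).
#' @return Yield, t/ha.
#' @examples
#' hyperbola(5.39, 0.0070, c(0, 80))
#' @export
hyperbola <- function(y0, beta, x) {
  denom <- 1 + beta * x
  if (any(abs(denom) < 1e-12)) {
    stop("rectangular hyperbola evaluated at its pole (1 + beta*x = 0)", call. = FALSE)
  }
  y0 / denom
}

#' Quadratic weed-free yield response to thermal time
#'
#' Weed-free grain yield as a quadratic in accumulated growing degree
#' days: `a + b*gdd + c*gdd^2`. With `c < 0` the response is concave,
#' rising to an optimum and falling as heat stress sets in. The algebraic
#' value is returned even when negative; any clamping belongs to the
#' reporting layer so that least squares is never distorted.
#'
#' @param a Intercept, t/ha.
#' @param b Linear coefficient, t/ha per degree C x days.
#' @param c Quadratic coefficient, t/ha per (degree C x days)^2.
#' @param gdd Accumulated growing degree days, degrees C x days.
#' @return Weed-free yield, t/ha (possibly negative at extreme `gdd`).
#' @export
quadratic_y0 <- function(a, b, c, gdd) {
  a + b * gdd + c * gdd^2
}

#' Linear weed competitiveness response to thermal time
#'
#' Competitiveness of the weed as a linear function of GDD:
#' `l + m * gdd`. A positive slope `m` means the weed gains ground on the
#' crop as thermal time accumulates.
#'
#' @param l Intercept, per (plants/m^2).
#' @param m Slope, per (plants/m^2) per degree C x days.
#' @param gdd Accumulated growing degree days.
#' @return Competitiveness, per (plants/m^2). May be negative at low GDD.
#' @export
linear_beta <- function(l, m, gdd) {
  l + m * gdd
}

#' Combined rectangular hyperbolic model
#'
#' Yield under simultaneous weed interference and thermal-time effects:
#' `(a + b*gdd + c*gdd^2) / (1 + (l + m*gdd) * x)`. The numerator is the
#' weed-free yield ([quadratic_y0()]), the denominator carries weed
#' competitiveness ([linear_beta()]); five parameters in total.
#'
#' @param params Named list or vector with elements `a`, `b`, `c`, `l`,
#'   `m` (see [combined_params()]).
#' @param gdd Accumulated growing degree days.
#' @param x Weed density, plants/m^2.
#' @return Yield, t/ha.
#' @examples
#' p <- combined_params(-16.0, 0.03, -0.00001, -0.021, 0.00002)
#' combined_yield(p, 1500, 0)  # 6.5, the weed-free quadratic
#' @export
combined_yield <- function(params, gdd, x) {
  p <- as.list(params)
  denom <- 1 + linear_beta(p$l, p$m, gdd) * x
  if (any(abs(denom) < 1e-12)) {
    stop("combined model evaluated at its pole (1 + (l + m*gdd)*x = 0)", call. = FALSE)
  }
  quadratic_y0(p$a, p$b, p$c, gdd) / denom
}

#' Construct a combined-model parameter set
#'
#' @param a,b,c Quadratic weed-free yield coefficients (t/ha; t/ha per
#'   degree C x days; t/ha per squared degree C x days).
#' @param l,m Competitiveness intercept and slope.
#' @return Named list of class `combined_params`.
#' @export
combined_params <- function(a, b, c, l, m) {
  p <- list(a = a, b = b, c = c, l = l, m = m)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), logical(1)))) {
    stop("all of a, b, c, l, m must be single finite numbers", call. = FALSE)
  }
  if (c >= 0) warning("c >= 0: yield response to GDD is not concave", call. = FALSE)
  structure(p, class = "combined_params")
}

#' Yield relative to the weed-free condition
#'
#' The fraction of weed-free yield retained under density `x`:
#' `1 / (1 + beta * x)`. Independent of the weed-free yield itself, in
#' (0, 1] whenever `beta >= 0` and `x >= 0`.
#'
#' @param beta Weed competitiveness, per (plants/m^2).
#' @param x Weed density, plants/m^2.
#' @return Dimensionless fraction.
#' @export
relative_yield <- function(beta, x) {
  denom <- 1 + beta * x
  if (any(denom <= 1e-12)) {
    stop("relative yield undefined: 1 + beta*x must be positive", call. = FALSE)
  }
  1 / denom
}

#' Location and value of the weed-free yield optimum
#'
#' For a concave quadratic (`c < 0`) the weed-free yield peaks at
#' `gdd = -b / (2c)`.
#'
#' @inheritParams quadratic_y0
#' @return Tibble with `gdd_at_max` (degrees C x days) and `y0_max` (t/ha).
#' @examples
#' quadratic_peak(-16.0, 0.03, -0.00001)  # peak 6.5 t/ha at GDD 1500
#' @export
quadratic_peak <- function(a, b, c) {
  if (!is.finite(c) || c >= 0) {
    stop("no maximum: quadratic coefficient `c` must be negative", call. = FALSE)
  }
  gdd_star <- -b / (2 * c)
  tibble::tibble(gdd_at_max = gdd_star, y0_max = quadratic_y0(a, b, c, gdd_star))
}
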