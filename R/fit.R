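#' @importFrom stats lm coef qf pf pt cor var setNames rnorm rbinom runif
NULL

# ---- fit-result container ----------------------------------------------

new_rh_fit <- function(model_id, parameters, rss, n_obs, n_params, y,
                       converged = TRUE, data = NULL, level_params = NULL,
                       fitted = NULL) {
  df_resid <- n_obs - n_params
  if (df_resid <= 0) stop("no residual degrees of freedom (n_obs <= n_params)", call. = FALSE)
  tss <- sum((y - mean(y))^2)
  structure(
    list(
      model_id = model_id,
      parameters = parameters,
      level_params = level_params,
      rss = rss,
      df_resid = df_resid,
      n_params = n_params,
      n_obs = n_obs,
      rms = rms(rss, df_resid),
      pseudo_r2 = if (tss > 0) 1 - rss / tss else NA_real_,
      converged = converged,
      data = data,
      fitted = fitted,
      fingerprint = fit_fingerprint(y)
    ),
    class = "rh_fit"
  )
}

fit_fingerprint <- function(y) {
  c(n = length(y), sum = sum(y), sumsq = sum(y^2))
}

#' @export
print.rh_fit <- function(x, ...) {
  cat("<rh_fit> model:", x$model_id,
      sprintf("| n = %d, params = %d, df = %d", x$n_obs, x$n_params, x$df_resid), "\n")
  cat(sprintf("  RSS = %.4f   RMS = %.3f t/ha   pseudo-R2 = %.3f   converged: %s\n",
              x$rss, x$rms, x$pseudo_r2, x$converged))
  print(x$parameters, n = 12)
  invisible(x)
}

#' Tidy a fitted competition model
#'
#' @param x An `rh_fit` object.
#' @param ... Unused.
#' @return Tibble of parameter estimates and asymptotic standard errors
#'   (one row per parameter; per-level fits carry the level key columns).
#' @method tidy rh_fit
#' @export
tidy.rh_fit <- function(x, ...) x$parameters

#' One-row fit summary
#'
#' @param x An `rh_fit` object.
#' @param ... Unused.
#' @return Tibble with `model_id`, `n_obs`, `n_params`, `df_resid`, `rss`,
#'   `rms` (t/ha), `pseudo_r2` and `converged`.
#' @method glance rh_fit
#' @export
glance.rh_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, n_obs = x$n_obs, n_params = x$n_params,
    df_resid = x$df_resid, rss = x$rss, rms = x$rms,
    pseudo_r2 = x$pseudo_r2, converged = x$converged
  )
}

# ---- fit statistics -----------------------------------------------------

#' Pseudo-R-squared of a (possibly nonlinear) least-squares fit
#'
#' `1 - rss / sum((y - mean(y))^2)`. Can be negative for fits worse than
#' the grand mean.
#'
#' @param rss Residual sum of squares.
#' @param y Observed response values the model was fitted to.
#' @return Dimensionless value <= 1.
#' @export
pseudo_r2 <- function(rss, y) {
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("undefined pseudo-R2: response has zero variance", call. = FALSE)
  1 - rss / tss
}

#' Root mean square error of a fit
#'
#' @param rss Residual sum of squares, (t/ha)^2.
#' @param df_resid Residual degrees of freedom (> 0).
#' @return RMS, t/ha.
#' @export
rms <- function(rss, df_resid) {
  if (df_resid <= 0) stop("df_resid must be positive", call. = FALSE)
  sqrt(rss / df_resid)
}

# ---- Levenberg-Marquardt backbone --------------------------------------

rh_lm_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-13, ptol = 1e-13, gtol = 0, maxiter = 500)
}

# Run nls.lm from the primary start; if it converges to a credible
# optimum (no worse than `baseline`, normally the fit of the grand mean),
# use it, otherwise fall back to the remaining deterministic starts and
# keep the best RSS among converged runs (or the best overall if none
# converged). `lower`/`upper` box constraints keep the optimizer away
# from pole regions; starts are clamped into the box.
lm_multistart <- function(starts, resid_fn, jac_fn, lower = NULL, upper = NULL,
                          baseline = NULL) {
  np <- length(starts[[1]])
  if (is.null(lower)) lower <- rep(-Inf, np)
  if (is.null(upper)) upper <- rep(Inf, np)
  best <- NULL
  for (i in seq_along(starts)) {
    p0 <- pmin(pmax(starts[[i]], lower + 1e-10), upper - 1e-10)
    # convergence is judged from the info code, not nls.lm's warnings
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = p0, fn = resid_fn, jac = jac_fn,
                           lower = lower, upper = upper,
                           control = rh_lm_control())
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- fit$deviance
    conv <- fit$info %in% 1:4
    if (is.null(best) ||
        (conv && !best$conv) ||
        (conv == best$conv && rss < best$rss - 1e-12)) {
      best <- list(fit = fit, rss = rss, conv = conv)
    }
    if (i == 1L && conv && (is.null(baseline) || rss <= baseline)) break
  }
  if (is.null(best)) {
    stop("nonlinear least squares failed from every start; widen the multi-start set",
         call. = FALSE)
  }
  best
}

# Asymptotic covariance from the residual Jacobian at the optimum.
se_from_jacobian <- function(J, rss, df_resid) {
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ) * rss / df_resid, error = function(e) NULL)
  if (is.null(cov)) return(rep(NA_real_, ncol(J)))
  se <- sqrt(pmax(diag(cov), 0))
  se
}

# ---- single-level rectangular hyperbola --------------------------------

hyperbola_start <- function(x, y) {
  y0 <- mean(y[x == min(x)])
  if (!is.finite(y0) || y0 <= 0) y0 <- max(mean(y), max(y) / 2, 0.1)
  pos <- y > 0.05
  beta <- 0.01
  if (sum(pos) >= 3 && length(unique(x[pos])) >= 2) {
    ll <- lm(I(1 / y[pos]) ~ x[pos])
    b <- unname(coef(ll)[2] / coef(ll)[1])
    if (is.finite(b) && abs(b) < 1) beta <- b
  }
  c(y0 = y0, beta = beta)
}

#' Fit the rectangular hyperbolic model to one temperature level
#'
#' Least-squares estimation of `(y0, beta)` in `Y = y0 / (1 + beta X)`
#' from yield-density observations of a single year-by-regime level.
#' Levenberg-Marquardt with an analytic Jacobian; the start is the mean
#' yield at the lowest density for `y0` and the reciprocal-yield
#' linearisation slope/intercept for `beta`, with a deterministic
#' multi-start fallback. Standard errors are the conventional asymptotic
#' ones (inverse Gauss-Newton Hessian times residual mean square).
#'
#' @param data Data frame with columns `density` (plants/m^2) and
#'   `yield_t_ha` (t/ha). At least 3 rows over at least 2 distinct
#'   densities, ideally including density 0.
#' @return An `rh_fit` (model_id `"per_level"`); `tidy()` gives the
#'   parameter table, `glance()` the fit statistics.
#' @examples
#' d <- tidyr::crossing(density = c(0, 20, 40, 80, 160), replicate = 1:3)
#' d$yield_t_ha <- hyperbola(5, 0.01, d$density)
#' tidy(fit_hyperbola(d))
#' @export
fit_hyperbola <- function(data) {
  stopifnot(is.data.frame(data), all(c("density", "yield_t_ha") %in% names(data)))
  x <- data$density
  y <- data$yield_t_ha
  if (length(y) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("design error: need at least 2 distinct weed densities", call. = FALSE)
  }
  if (max(y) < 1) {
    warning("near-zero yields at every density: competitiveness estimate will be unstable (wide SE)",
            call. = FALSE)
  }

  resid_fn <- function(p) {
    den <- pmax(1 + p[2] * x, 1e-6)
    y - p[1] / den
  }
  jac_fn <- function(p) {
    den <- pmax(1 + p[2] * x, 1e-6)
    cbind(-1 / den, p[1] * x / den^2)
  }

  s0 <- hyperbola_start(x, y)
  starts <- list(
    s0,
    c(s0[1] * 1.5, max(s0[2] * 2, 0.02)),
    c(s0[1] * 0.5, s0[2] * 0.5),
    c(max(y), 0.001),
    c(max(mean(y), 0.05), 0),
    c(max(y), 0.05)
  )
  beta_low <- if (max(x) > 0) -0.99 / max(x) else -Inf
  best <- lm_multistart(starts, resid_fn, jac_fn,
                        lower = c(0, beta_low),
                        baseline = sum((y - mean(y))^2) + 1e-9)
  p <- unname(best$fit$par)
  rss <- best$rss
  n <- length(y)
  se <- se_from_jacobian(jac_fn(p), rss, n - 2L)
  pars <- tibble::tibble(
    term = c("y0", "beta"),
    estimate = p,
    std.error = se
  )
  new_rh_fit("per_level", pars, rss, n, 2L, y,
             converged = best$conv, data = tibble::as_tibble(data),
             fitted = p[1] / (1 + p[2] * x))
}

# ---- level bookkeeping for pooled fits ---------------------------------

level_cols <- c("year", "regime_label", "gdd_flowering")

check_pooled_data <- function(data) {
  need <- c(level_cols, "density", "yield_t_ha")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("pooled fits need columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(data)
}

#' Level inclusion rule for pooled fits
#'
#' Pooled multi-level fits exclude levels whose weed-free mean yield
#' (mean yield at that level's lowest density) falls below a threshold:
#' such near-collapse levels carry no usable information about weed
#' competitiveness and destabilise the joint fit.
#'
#' @param data Long-format observations (see [fit_per_level_pooled()]).
#' @param min_weedfree_yield Inclusion threshold, t/ha (default 1.0).
#' @return Tibble with one row per `(year, regime_label, gdd_flowering)`
#'   level: `n_obs`, `weedfree_mean` and logical `included`.
#' @export
included_levels <- function(data, min_weedfree_yield = 1) {
  check_pooled_data(data)
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(level_cols))) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      weedfree_mean = mean(.data$yield_t_ha[.data$density == min(.data$density)]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$year, .data$gdd_flowering) |>
    dplyr::mutate(included = .data$weedfree_mean >= min_weedfree_yield)
}

pooled_subset <- function(data, min_weedfree_yield) {
  lev <- included_levels(data, min_weedfree_yield)
  keep <- lev[lev$included, level_cols]
  list(
    data = dplyr::inner_join(tibble::as_tibble(data), keep, by = level_cols),
    levels = keep
  )
}

#' Per-level rectangular hyperbola fits pooled across levels
#'
#' The saturated ("full") model of the nested family: a separate
#' `(y0_i, beta_i)` pair for every included year-by-regime level. The
#' pooled residual sum of squares is the sum of the level RSS, and the
#' parameter count is twice the number of levels.
#'
#' @param data Long-format observations with columns `year`,
#'   `regime_label`, `gdd_flowering`, `density`, `yield_t_ha`.
#' @param min_weedfree_yield Level-inclusion threshold, t/ha
#'   (see [included_levels()]).
#' @return An `rh_fit` (model_id `"per_level"`); `tidy()` returns one row
#'   per level with `y0`, `beta`, standard errors, and per-level RMS and
#'   pseudo-R2 (the per-level fit table).
#' @export
fit_per_level_pooled <- function(data, min_weedfree_yield = 1) {
  sub <- pooled_subset(data, min_weedfree_yield)
  d <- sub$data
  if (nrow(sub$levels) < 1L) stop("no levels pass the inclusion rule", call. = FALSE)
  fits <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(level_cols))) |>
    dplyr::group_map(function(g, key) {
      f <- fit_hyperbola(g)
      dplyr::bind_cols(
        key,
        tibble::tibble(
          y0 = f$parameters$estimate[1], se_y0 = f$parameters$std.error[1],
          beta = f$parameters$estimate[2], se_beta = f$parameters$std.error[2],
          rss = f$rss, n_obs = f$n_obs, df_resid = f$df_resid,
          rms = f$rms, pseudo_r2 = f$pseudo_r2, converged = f$converged
        )
      )
    }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$year, .data$gdd_flowering)

  k <- nrow(fits)
  rss <- sum(fits$rss)
  n <- sum(fits$n_obs)
  new_rh_fit("per_level", fits, rss, n, 2L * k, d$yield_t_ha,
             converged = all(fits$converged), data = d, level_params = fits)
}

# Shared machinery for the joint (intermediate / combined) fits. GDD is
# rescaled by 1/1000 internally so the quadratic coefficients are well
# conditioned; estimates and SEs are mapped back to the natural scale.
GDD_SCALE <- 1000

joint_start_stage2 <- function(per_level) {
  lp <- per_level$level_params
  q <- fit_stage2_quadratic(lp)
  l <- fit_stage2_linear(lp)
  list(abc = q$parameters$estimate, lm_ = l$parameters$estimate, levels = lp)
}

#' Intermediate model fit: quadratic weed-free yield, level-specific betas
#'
#' Joint least squares of `Y = (a + b GDD + c GDD^2) / (1 + beta_i X)`
#' over all included levels: the weed-free yield is pooled into one
#' quadratic in GDD while each level keeps its own competitiveness
#' `beta_i` (3 + k parameters for k levels).
#'
#' @inheritParams fit_per_level_pooled
#' @return An `rh_fit` (model_id `"intermediate"`).
#' @export
fit_intermediate <- function(data, min_weedfree_yield = 1) {
  sub <- pooled_subset(data, min_weedfree_yield)
  d <- sub$data
  k <- nrow(sub$levels)
  if (k < 4L) stop("design error: need at least 4 levels for the intermediate model", call. = FALSE)
  gdds <- sort(unique(d$gdd_flowering))
  if (length(gdds) < 3L) stop("design error: need at least 3 distinct GDD values", call. = FALSE)

  lev_key <- interaction(d$year, d$regime_label, drop = TRUE)
  lev_idx <- as.integer(lev_key)
  k <- length(levels(lev_key))
  gs <- d$gdd_flowering / GDD_SCALE
  x <- d$density
  y <- d$yield_t_ha
  n <- length(y)

  resid_fn <- function(p) {
    q <- p[1] + p[2] * gs + p[3] * gs^2
    den <- pmax(1 + p[3 + lev_idx] * x, 1e-6)
    y - q / den
  }
  jac_fn <- function(p) {
    q <- p[1] + p[2] * gs + p[3] * gs^2
    den <- pmax(1 + p[3 + lev_idx] * x, 1e-6)
    J <- matrix(0, n, 3 + k)
    J[, 1] <- -1 / den
    J[, 2] <- -gs / den
    J[, 3] <- -gs^2 / den
    for (j in seq_len(k)) {
      rows <- lev_idx == j
      J[rows, 3 + j] <- q[rows] * x[rows] / den[rows]^2
    }
    J
  }

  per_level <- suppressWarnings(fit_per_level_pooled(d, min_weedfree_yield = -Inf))
  st <- joint_start_stage2(per_level)
  # map per-level betas onto the interaction ordering
  lp <- st$levels
  lp_key <- interaction(lp$year, lp$regime_label, drop = TRUE)
  beta0 <- lp$beta[match(levels(lev_key), as.character(lp_key))]
  beta0[!is.finite(beta0)] <- 0.01
  abc_s <- st$abc * c(1, GDD_SCALE, GDD_SCALE^2)
  starts <- list(
    c(abc_s, beta0),
    c(abc_s * 0.8, beta0 * 0.5),
    c(mean(y), 0, 0, rep(0.01, k)),
    c(abc_s * 1.2, pmax(beta0, 0.001) * 2),
    c(max(y), 0, 0, rep(0.005, k))
  )
  max_x_lev <- vapply(seq_len(k), function(j) max(x[lev_idx == j]), numeric(1))
  beta_low <- ifelse(max_x_lev > 0, -0.99 / max_x_lev, -Inf)
  best <- lm_multistart(starts, resid_fn, jac_fn,
                        lower = c(-Inf, -Inf, -Inf, beta_low),
                        baseline = sum((y - mean(y))^2) + 1e-9)
  p <- unname(best$fit$par)
  rss <- best$rss
  scale_back <- c(1, 1 / GDD_SCALE, 1 / GDD_SCALE^2, rep(1, k))
  se <- se_from_jacobian(jac_fn(p), rss, n - (3L + k)) * scale_back
  est <- p * scale_back
  pars <- tibble::tibble(
    term = c("a", "b", "c", paste0("beta_", levels(lev_key))),
    estimate = est,
    std.error = se
  )
  new_rh_fit("intermediate", pars, rss, n, 3L + k, y,
             converged = best$conv, data = d)
}

#' Combined rectangular hyperbolic model fit
#'
#' Joint least squares of the five-parameter combined model
#' `Y = (a + b GDD + c GDD^2) / (1 + (l + m GDD) X)`: quadratic weed-free
#' yield and linear weed competitiveness, both in flowering GDD.
#' Initialised from the two-stage regressions (quadratic of per-level
#' `y0` on GDD; linear of per-level `beta` on GDD) with deterministic
#' multi-start fallback.
#'
#' @inheritParams fit_per_level_pooled
#' @return An `rh_fit` (model_id `"combined"`) whose `tidy()` table holds
#'   `a`, `b`, `c`, `l`, `m` with asymptotic standard errors.
#' @export
fit_combined <- function(data, min_weedfree_yield = 1) {
  sub <- pooled_subset(data, min_weedfree_yield)
  d <- sub$data
  if (nrow(sub$levels) < 4L) stop("design error: need at least 4 levels", call. = FALSE)
  if (length(unique(d$gdd_flowering)) < 3L) {
    stop("design error: need at least 3 distinct GDD values", call. = FALSE)
  }
  gs <- d$gdd_flowering / GDD_SCALE
  x <- d$density
  y <- d$yield_t_ha
  n <- length(y)

  resid_fn <- function(p) {
    q <- p[1] + p[2] * gs + p[3] * gs^2
    den <- pmax(1 + (p[4] + p[5] * gs) * x, 1e-6)
    y - q / den
  }
  jac_fn <- function(p) {
    q <- p[1] + p[2] * gs + p[3] * gs^2
    den <- pmax(1 + (p[4] + p[5] * gs) * x, 1e-6)
    cbind(-1 / den, -gs / den, -gs^2 / den,
          q * x / den^2, q * gs * x / den^2)
  }

  per_level <- suppressWarnings(fit_per_level_pooled(d, min_weedfree_yield = -Inf))
  st <- joint_start_stage2(per_level)
  abc_s <- st$abc * c(1, GDD_SCALE, GDD_SCALE^2)
  lm_s <- st$lm_ * c(1, GDD_SCALE)
  starts <- list(
    c(abc_s, lm_s),
    c(abc_s * 0.8, lm_s * 0.5),
    c(abc_s * 1.2, lm_s * 2),
    c(mean(y), 0, 0, 0, 0.01),
    c(max(y), 0, 0, 0.005, 0)
  )
  best <- lm_multistart(starts, resid_fn, jac_fn,
                        baseline = sum((y - mean(y))^2) + 1e-9)
  p <- unname(best$fit$par)
  rss <- best$rss
  scale_back <- c(1, 1 / GDD_SCALE, 1 / GDD_SCALE^2, 1, 1 / GDD_SCALE)
  se <- se_from_jacobian(jac_fn(p), rss, n - 5L) * scale_back
  pars <- tibble::tibble(
    term = c("a", "b", "c", "l", "m"),
    estimate = p * scale_back,
    std.error = se
  )
  new_rh_fit("combined", pars, rss, n, 5L, y,
             converged = best$conv, data = d)
}

# ---- stage-2 regressions (on per-level parameter estimates) ------------

wrap_lm_fit <- function(model_id, fit, terms, y) {
  # summary.lm warns on exact fits; SEs of 0 are the correct answer there
  sm <- suppressWarnings(summary(fit))
  pars <- tibble::tibble(
    term = terms,
    estimate = unname(coef(fit)),
    std.error = unname(sm$coefficients[, "Std. Error"])
  )
  rss <- sum(fit$residuals^2)
  new_rh_fit(model_id, pars, rss, length(y), length(terms), y,
             converged = TRUE, fitted = unname(fit$fitted.values))
}

#' Quadratic regression of weed-free yield on GDD
#'
#' Ordinary least squares of per-level weed-free yield estimates on
#' `(1, GDD, GDD^2)`; supplies the starting values for the joint fits and
#' the classical two-stage view of the temperature response.
#'
#' @param data Data frame with columns `gdd_flowering` and `y0`
#'   (typically `tidy(fit_per_level_pooled(...))`). At least 4 rows.
#' @return An `rh_fit` (model_id `"quadratic_stage2"`) with terms
#'   `a`, `b`, `c`.
#' @export
fit_stage2_quadratic <- function(data) {
  stopifnot(all(c("gdd_flowering", "y0") %in% names(data)))
  if (nrow(data) < 4L) stop("design error: need at least 4 (GDD, y0) pairs", call. = FALSE)
  fit <- lm(y0 ~ gdd_flowering + I(gdd_flowering^2), data = data)
  wrap_lm_fit("quadratic_stage2", fit, c("a", "b", "c"), data$y0)
}

#' Linear regression of weed competitiveness on GDD
#'
#' Ordinary least squares of per-level competitiveness estimates on
#' `(1, GDD)`.
#'
#' @param data Data frame with columns `gdd_flowering` and `beta`. At
#'   least 3 rows.
#' @return An `rh_fit` (model_id `"linear_stage2"`) with terms `l`, `m`.
#' @export
fit_stage2_linear <- function(data) {
  stopifnot(all(c("gdd_flowering", "beta") %in% names(data)))
  if (nrow(data) < 3L) stop("design error: need at least 3 (GDD, beta) pairs", call. = FALSE)
  fit <- lm(beta ~ gdd_flowering, data = data)
  wrap_lm_fit("linear_stage2", fit, c("l", "m"), data$beta)
}

#' Extract combined-model parameters from a fit
#'
#' @param fit An `rh_fit` with model_id `"combined"`.
#' @return A [combined_params()] object.
#' @export
as_combined_params <- function(fit) {
  stopifnot(inherits(fit, "rh_fit"), fit$model_id == "combined")
  p <- setNames(fit$parameters$estimate, fit$parameters$term)
  suppressWarnings(combined_params(p[["a"]], p[["b"]], p[["c"]], p[["l"]], p[["m"]]))
}
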