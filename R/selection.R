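#' Lack-of-fit F statistic for nested least-squares models
#'
#' Compares a reduced model against its one-step-richer predecessor,
#' scaling the RSS increase per lost parameter by the residual mean
#' square of the *full* (saturated, per-level) model:
#' \deqn{F = \frac{(RSS_{reduced} - RSS_{pred}) / (df_{reduced} - df_{pred})}
#'            {RSS_{full} / df_{full}}}
#' The denominator is always the full model's residual mean square, for
#' both steps of the sequential comparison — the convention under which
#' the published comparison tables for this model family reproduce.
#'
#' @param rss_reduced,df_reduced Residual SS and df of the reduced model.
#' @param rss_predecessor,df_predecessor Residual SS and df of its
#'   predecessor (the next-richer model).
#' @param rss_full,df_full Residual SS and df of the full model.
#' @return The F statistic (>= 0 whenever the models are truly nested).
#' @examples
#' lack_of_fit_f(51.88, 125, 37.19, 118, 37.19, 118)  # 6.66
#' @export
lack_of_fit_f <- function(rss_reduced, df_reduced,
                          rss_predecessor, df_predecessor,
                          rss_full, df_full) {
  stopifnot(df_reduced > df_predecessor, df_full > 0,
            rss_reduced >= 0, rss_predecessor >= 0, rss_full >= 0)
  ms_full <- rss_full / df_full
  if (ms_full <= 0) {
    stop("undefined test: full-model residual mean square is zero", call. = FALSE)
  }
  ((rss_reduced - rss_predecessor) / (df_reduced - df_predecessor)) / ms_full
}

#' Upper critical value of the F distribution
#'
#' @param alpha Upper-tail probability (0 < alpha < 1).
#' @param df_num,df_den Numerator and denominator degrees of freedom.
#' @return The upper-`alpha` quantile.
#' @export
critical_f <- function(alpha, df_num, df_den) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (df_num < 1 || df_den < 1) stop("degrees of freedom must be >= 1", call. = FALSE)
  qf(1 - alpha, df_num, df_den)
}

#' Sequential lack-of-fit comparison of the nested model family
#'
#' Runs the two sequential tests — intermediate vs per-level, then
#' combined vs intermediate — using the per-level fit's residual mean
#' square as the common F denominator. A reduction is *accepted* when its
#' F value falls below the tabulated critical value at level `alpha`.
#'
#' @param fit_full Per-level fit ([fit_per_level_pooled()]).
#' @param fit_intermediate Intermediate fit ([fit_intermediate()]).
#' @param fit_combined Combined fit ([fit_combined()]).
#' @param alpha Significance level (default 0.05).
#' @return An `rh_comparison`: list with `rows` (model, df, RSS, number of
#'   parameters, ordered full to most reduced) and `tests` (comparison
#'   label, F, df pair, critical F, p value, `significant`, `accepted`).
#' @export
compare_models <- function(fit_full, fit_intermediate, fit_combined, alpha = 0.05) {
  fits <- list(fit_full, fit_intermediate, fit_combined)
  stopifnot(all(vapply(fits, inherits, logical(1), "rh_fit")))
  ids <- vapply(fits, `[[`, character(1), "model_id")
  if (!identical(ids, c("per_level", "intermediate", "combined"))) {
    stop("expected fits in order per_level, intermediate, combined", call. = FALSE)
  }
  fps <- lapply(fits, `[[`, "fingerprint")
  if (!isTRUE(all.equal(fps[[1]], fps[[2]], tolerance = 1e-9)) ||
      !isTRUE(all.equal(fps[[1]], fps[[3]], tolerance = 1e-9))) {
    stop("consistency error: the three fits were not computed on the identical observation set",
         call. = FALSE)
  }

  rows <- purrr::map(fits, glance) |>
    purrr::list_rbind() |>
    dplyr::select("model_id", "df_resid", "rss", "n_params")

  one_test <- function(label, red, pred) {
    f <- lack_of_fit_f(red$rss, red$df_resid, pred$rss, pred$df_resid,
                       fit_full$rss, fit_full$df_resid)
    df1 <- red$df_resid - pred$df_resid
    df2 <- fit_full$df_resid
    fc <- critical_f(alpha, df1, df2)
    tibble::tibble(
      comparison = label, f_value = f, df_num = df1, df_den = df2,
      critical_f = fc, p_value = pf(f, df1, df2, lower.tail = FALSE),
      significant = f >= fc, accepted = f < fc
    )
  }
  tests <- dplyr::bind_rows(
    one_test("intermediate-per_level", fit_intermediate, fit_full),
    one_test("combined-intermediate", fit_combined, fit_intermediate)
  )
  structure(list(rows = rows, tests = tests, alpha = alpha), class = "rh_comparison")
}

#' @export
print.rh_comparison <- function(x, ...) {
  cat("<rh_comparison> nested lack-of-fit tests (alpha =", x$alpha, ")\n")
  print(x$rows)
  t <- x$tests
  cat("\n")
  print(dplyr::mutate(t, f_label = sprintf("%.2f%s", .data$f_value,
                                           ifelse(.data$significant, "*", ""))))
  invisible(x)
}

#' Tidy the test table of a model comparison
#'
#' @param x An `rh_comparison`.
#' @param ... Unused.
#' @return The tests tibble.
#' @method tidy rh_comparison
#' @export
tidy.rh_comparison <- function(x, ...) x$tests

#' Model rows of a comparison (the published-table mirror)
#'
#' @param x An `rh_comparison`.
#' @param ... Unused.
#' @return The per-model df / RSS / parameter-count tibble.
#' @method glance rh_comparison
#' @export
glance.rh_comparison <- function(x, ...) x$rows
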