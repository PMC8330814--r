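#' Daily growing degree day contribution
#'
#' Heat units accumulated by a single day with mean air temperature
#' `t_mean`, relative to a base temperature. Contributions are clamped at
#' zero: days colder than the base add nothing, they never subtract.
#'
#' @param t_mean Daily mean air temperature, degrees C. Vectorised.
#' @param t_base Base temperature, degrees C (default 10, the convention
#'   for temperate paddy rice).
#' @return Degree-day contribution(s), degrees C x days, always >= 0.
#' @examples
#' daily_gdd(24.1)        # 14.1
#' daily_gdd(c(25, 9, 30)) # 15, 0, 20
#' @export
daily_gdd <- function(t_mean, t_base = 10) {
  if (!is.numeric(t_mean) || anyNA(t_mean) || !all(is.finite(t_mean))) {
    stop("`t_mean` must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(t_base) || length(t_base) != 1L || !is.finite(t_base)) {
    stop("`t_base` must be a single finite number", call. = FALSE)
  }
  pmax(t_mean - t_base, 0)
}

check_temperature_series <- function(series) {
  stopifnot(is.data.frame(series))
  if (!all(c("date", "t_mean_c") %in% names(series))) {
    stop("temperature series needs columns `date` and `t_mean_c`", call. = FALSE)
  }
  d <- as.Date(series$date)
  if (nrow(series) < 1L) stop("temperature series is empty", call. = FALSE)
  dd <- diff(as.integer(d))
  if (length(dd) && any(dd != 1L)) {
    stop("temperature series dates must be strictly increasing and daily-contiguous",
         call. = FALSE)
  }
  if (anyNA(series$t_mean_c) || !all(is.finite(series$t_mean_c))) {
    stop("temperature series `t_mean_c` must be finite", call. = FALSE)
  }
  invisible(d)
}

#' Accumulate growing degree days over a date window
#'
#' Sums per-day clamped degree-day contributions over the closed window
#' `[start, end]` (both endpoints included).
#'
#' @param series Data frame with columns `date` (coercible to `Date`) and
#'   `t_mean_c` (daily mean air temperature, degrees C); dates must be
#'   consecutive calendar days.
#' @param start,end Window bounds (coercible to `Date`); must lie within
#'   the series' span.
#' @param t_base Base temperature, degrees C.
#' @param window_label Label stored with the result.
#' @return One-row tibble: `window_label`, `gdd` (degrees C x days),
#'   `n_days`, `t_base`, `mean_t` (plain window mean temperature).
#' @examples
#' s <- tibble::tibble(date = seq(as.Date("2014-06-01"), by = 1, length.out = 89),
#'                     t_mean_c = 24.1)
#' accumulate_gdd(s, "2014-06-01", "2014-08-28")  # 14.1 * 89 = 1254.9
#' @export
accumulate_gdd <- function(series, start, end, t_base = 10, window_label = NA_character_) {
  d <- check_temperature_series(series)
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop("`start` must be <= `end`", call. = FALSE)
  if (start < min(d) || end > max(d)) {
    stop("window [", format(start), ", ", format(end),
         "] outside the series span [", format(min(d)), ", ", format(max(d)), "]",
         call. = FALSE)
  }
  in_win <- d >= start & d <= end
  t <- series$t_mean_c[in_win]
  tibble::tibble(
    window_label = window_label,
    gdd = sum(daily_gdd(t, t_base)),
    n_days = length(t),
    t_base = t_base,
    mean_t = mean(t)
  )
}

#' Growth-stage calendar
#'
#' Transplanting, tillering, flowering and maturity dates for one season.
#' Defaults follow the conventional Korean paddy calendar: transplanting
#' June 1, tillering August 10, flowering August 28, maturity October 15.
#'
#' @param year Season year (used to build the default dates).
#' @param transplanting,tillering,flowering,maturity Override dates.
#' @return A list of four `Date`s, validated to be strictly ordered.
#' @export
stage_calendar <- function(year,
                           transplanting = NULL, tillering = NULL,
                           flowering = NULL, maturity = NULL) {
  mk <- function(x, default) if (is.null(x)) as.Date(sprintf("%d-%s", year, default)) else as.Date(x)
  cal <- list(
    transplanting = mk(transplanting, "06-01"),
    tillering     = mk(tillering, "08-10"),
    flowering     = mk(flowering, "08-28"),
    maturity      = mk(maturity, "10-15")
  )
  if (!(cal$transplanting < cal$tillering && cal$tillering < cal$flowering &&
        cal$flowering < cal$maturity)) {
    stop("stage calendar must satisfy transplanting < tillering < flowering < maturity",
         call. = FALSE)
  }
  cal
}

#' Per-stage mean temperature and GDD summary
#'
#' The standard trial bookkeeping: mean air temperature and accumulated
#' GDD from transplanting to tillering, to flowering, and to maturity
#' (nested windows, all starting at transplanting).
#'
#' @inheritParams accumulate_gdd
#' @param calendar Output of [stage_calendar()]; must lie within the
#'   series span.
#' @return Tibble with one row per window (`to_tillering`, `to_flowering`,
#'   `to_maturity`): `window_label`, `gdd`, `n_days`, `t_base`, `mean_t`.
#' @export
stage_summary <- function(series, calendar, t_base = 10) {
  ends <- list(to_tillering = calendar$tillering,
               to_flowering = calendar$flowering,
               to_maturity  = calendar$maturity)
  purrr::imap(ends, function(end, lab) {
    accumulate_gdd(series, calendar$transplanting, end, t_base, window_label = lab)
  }) |>
    purrr::list_rbind()
}
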