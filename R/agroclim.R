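#' Effective temperature sum (growing degree days)
#'
#' Accumulates the daily excess of mean air temperature over a base
#' temperature across the supplied days:
#' \deqn{x = \sum_i \left(\frac{T_{min,i} + T_{max,i}}{2} - T_{base}\right)}
#' with base 5 degrees C, the minimal temperature for hop vegetation. By
#' default negative daily terms are kept (the literal accumulation formula);
#' `clamp_negative = TRUE` replaces each daily term by `max(term, 0)`, the
#' common degree-day convention.
#'
#' @param days a [weather_series()] or data frame with `tmin_c`, `tmax_c`.
#' @param base_c base temperature, degrees C.
#' @param clamp_negative clamp negative daily terms to zero?
#' @return Effective temperature sum in degree C day.
#' @examples
#' d <- weather_series(as.Date("2001-05-01") + 0:2,
#'                     tmin_c = c(4, 0, 10), tmax_c = c(6, 4, 20),
#'                     rain_mm = c(0, 0, 0))
#' effective_temperature_sum(d)                       # 0 - 3 + 10 = 7
#' effective_temperature_sum(d, clamp_negative = TRUE) # 0 + 0 + 10 = 10
#' @export
effective_temperature_sum <- function(days, base_c = 5,
                                      clamp_negative = FALSE) {
  if (nrow(days) == 0L) stop("no days supplied", call. = FALSE)
  if (!is.finite(base_c)) stop("base_c must be finite", call. = FALSE)
  term <- (days$tmin_c + days$tmax_c) / 2 - base_c
  if (clamp_negative) term <- pmax(term, 0)
  sum(term)
}

#' Rainfall sum over a set of days
#'
#' @param days a [weather_series()] or data frame with `rain_mm`.
#' @return Total rainfall in mm.
#' @export
rainfall_sum <- function(days) {
  if (nrow(days) == 0L) stop("no days supplied", call. = FALSE)
  sum(days$rain_mm)
}

#' Mean July reference crop evapotranspiration
#'
#' Arithmetic mean of the 31 daily ET0 values (mm/day) of July of the given
#' year. All 31 July days must be present with ET0 recorded; this quantity
#' gates the reliability of the alpha-acid prediction.
#'
#' @param series a [weather_series()].
#' @param year calendar year; defaults to the series' year attribute.
#' @return Mean July ET0, mm/day.
#' @export
july_mean_et0 <- function(series, year = NULL) {
  if (is.null(year)) year <- attr(series, "year")
  if (!"et0_mm_day" %in% names(series)) {
    stop("series has no et0_mm_day column", call. = FALSE)
  }
  jul <- series$date >= as.Date(sprintf("%d-07-01", year)) &
         series$date <= as.Date(sprintf("%d-07-31", year))
  vals <- series$et0_mm_day[jul]
  if (length(vals) != 31L || anyNA(vals)) {
    stop(sprintf("need all 31 July %d days with ET0; found %d non-missing",
                 year, sum(!is.na(vals))), call. = FALSE)
  }
  mean(vals)
}

#' Season summary: the model's independent variables
#'
#' @param x_eff_temp_sum effective temperature sum over the window,
#'   degree C day.
#' @param w_rain_sum rainfall sum over the window, mm.
#' @param et0_july_mean mean July ET0, mm/day; `NA` when unavailable.
#' @param year calendar year.
#' @param window the [phenology_window()], or `NULL`.
#' @return An object of class `season_summary`.
#' @export
season_summary <- function(x_eff_temp_sum, w_rain_sum,
                           et0_july_mean = NA_real_, year = NA_integer_,
                           window = NULL) {
  if (!is.na(w_rain_sum) && w_rain_sum < 0) {
    stop("w_rain_sum must be >= 0", call. = FALSE)
  }
  if (!is.na(et0_july_mean) && et0_july_mean < 0) {
    stop("et0_july_mean must be >= 0", call. = FALSE)
  }
  structure(list(x_eff_temp_sum = as.numeric(x_eff_temp_sum),
                 w_rain_sum = as.numeric(w_rain_sum),
                 et0_july_mean = as.numeric(et0_july_mean),
                 year = as.integer(year),
                 window = window),
            class = "season_summary")
}

#' @export
print.season_summary <- function(x, ...) {
  cat(sprintf(
    "<season_summary> year=%s x=%.1f degC.day  w=%.1f mm  ET0(July)=%s\n",
    ifelse(is.na(x$year), "?", x$year), x$x_eff_temp_sum, x$w_rain_sum,
    ifelse(is.na(x$et0_july_mean), "absent",
           sprintf("%.2f mm/day", x$et0_july_mean))))
  invisible(x)
}

#' Summarize a season's weather over the phenological window
#'
#' Computes the three model inputs from daily records: the effective
#' temperature sum and rainfall sum over the F3-F9 window, and the mean July
#' ET0 of the season year. When the series carries no ET0 column the summary
#' leaves it `NA`; downstream prediction then proceeds ungated with a
#' warning reason.
#'
#' @param series a [weather_series()].
#' @param window a [phenology_window()].
#' @param base_c base temperature for degree days, degrees C.
#' @param clamp_negative clamp negative daily degree-day terms?
#' @return A [season_summary()].
#' @export
summarize_season <- function(series, window, base_c = 5,
                             clamp_negative = FALSE) {
  days <- extract_window(series, window)
  year <- as.integer(format(window$f3_date, "%Y"))
  any_july <- any(format(series$date, "%Y-%m") == sprintf("%d-07", year))
  et0 <- if ("et0_mm_day" %in% names(series) && any_july) {
    july_mean_et0(series, year)
  } else {
    NA_real_
  }
  season_summary(
    x_eff_temp_sum = effective_temperature_sum(days, base_c = base_c,
                                               clamp_negative = clamp_negative),
    w_rain_sum = rainfall_sum(days),
    et0_july_mean = et0,
    year = year,
    window = window)
}
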