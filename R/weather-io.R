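#' Construct a daily weather series
#'
#' A weather series is a data frame of station-days with columns `date`
#' (class `Date`), `tmin_c`, `tmax_c` (degrees Celsius), `rain_mm` (mm) and
#' optionally `et0_mm_day` (reference crop evapotranspiration, mm per day).
#' Rows must be in strictly increasing date order with no duplicates;
#' `tmin_c <= tmax_c`, `rain_mm >= 0`, and `et0_mm_day >= 0` where present.
#'
#' @param date vector coercible to `Date`.
#' @param tmin_c,tmax_c daily minimum/maximum air temperature, degrees C.
#' @param rain_mm daily rainfall depth, mm.
#' @param et0_mm_day optional daily reference crop evapotranspiration,
#'   mm/day. `NULL` means the station does not report ET0.
#' @param station_id station label.
#' @param year calendar year of the series; defaults to the year of the
#'   first record.
#' @return An object of class `weather_series` (a data frame).
#' @examples
#' ws <- weather_series(as.Date("2001-07-01") + 0:2,
#'                      tmin_c = c(12, 13, 11), tmax_c = c(24, 26, 22),
#'                      rain_mm = c(0, 4.2, 0))
#' @export
weather_series <- function(date, tmin_c, tmax_c, rain_mm, et0_mm_day = NULL,
                           station_id = NA_character_, year = NULL) {
  date <- as.Date(date)
  df <- data.frame(date = date,
                   tmin_c = as.numeric(tmin_c),
                   tmax_c = as.numeric(tmax_c),
                   rain_mm = as.numeric(rain_mm))
  if (!is.null(et0_mm_day)) df$et0_mm_day <- as.numeric(et0_mm_day)
  validate_weather_records(df)
  if (is.null(year)) year <- as.integer(format(df$date[1], "%Y"))
  structure(df,
            station_id = station_id,
            year = as.integer(year),
            class = c("weather_series", "data.frame"))
}

# Checks per-row invariants and date ordering; stops with row numbers.
validate_weather_records <- function(df) {
  if (anyNA(df$date)) {
    stop("malformed or missing date on row(s): ",
         paste(which(is.na(df$date)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$date)) {
    stop("duplicate dates on row(s): ",
         paste(which(duplicated(df$date)), collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(df$date, strictly = TRUE)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  bad <- which(!is.na(df$tmin_c) & !is.na(df$tmax_c) & df$tmin_c > df$tmax_c)
  if (length(bad)) {
    stop("tmin_c > tmax_c on row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(df$rain_mm) & df$rain_mm < 0)
  if (length(bad)) {
    stop("negative rain_mm on row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if ("et0_mm_day" %in% names(df)) {
    bad <- which(!is.na(df$et0_mm_day) & df$et0_mm_day < 0)
    if (length(bad)) {
      stop("negative et0_mm_day on row(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(df)
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf("<weather_series> station=%s year=%d, %d days (%s to %s)\n",
              attr(x, "station_id"), attr(x, "year"), nrow(x),
              format(x$date[1]), format(x$date[nrow(x)])))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' Read a daily weather table from CSV
#'
#' Expects columns `date,tmin_c,tmax_c,rain_mm` and optionally `et0_mm_day`;
#' dates are ISO-8601 (`YYYY-MM-DD`). Rows violating the record invariants
#' are rejected with their row numbers.
#'
#' @param path CSV file path.
#' @param dec decimal separator; `","` accepts comma-decimal exports from
#'   some regional station software.
#' @param station_id optional station label attached to the series.
#' @return A [weather_series()].
#' @export
read_weather_table <- function(path, dec = c(".", ","),
                               station_id = NA_character_) {
  dec <- match.arg(dec)
  if (!file.exists(path)) stop("weather file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, dec = dec, stringsAsFactors = FALSE)
  need <- c("date", "tmin_c", "tmax_c", "rain_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("weather table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  weather_series(dates, df$tmin_c, df$tmax_c, df$rain_mm,
                 et0_mm_day = if ("et0_mm_day" %in% names(df)) df$et0_mm_day,
                 station_id = station_id)
}

#' Write a weather series to CSV
#'
#' Numeric columns are written with enough digits that
#' [read_weather_table()] recovers them exactly (lossless round trip).
#'
#' @param series a [weather_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_weather_table <- function(series, path) {
  df <- as.data.frame(series)
  out <- data.frame(date = format(df$date, "%Y-%m-%d"))
  for (col in setdiff(names(df), "date")) {
    out[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Define a phenological accumulation window
#'
#' The window runs from second germination after spring pruning (stage F3)
#' to technological maturity of the cones (stage F9), both endpoints
#' included. All model accumulations (degree days, rainfall) are taken over
#' this closed interval.
#'
#' @param f3_date,f9_date dates (or strings coercible to `Date`) of stages
#'   F3 and F9; must lie in the same calendar year with `f3_date <= f9_date`.
#' @return An object of class `phenology_window`.
#' @export
phenology_window <- function(f3_date, f9_date) {
  to_date <- function(d) {
    tryCatch(as.Date(d), error = function(e) as.Date(NA))
  }
  f3 <- to_date(f3_date)
  f9 <- to_date(f9_date)
  if (is.na(f3) || is.na(f9)) stop("malformed phenology date", call. = FALSE)
  if (f3 > f9) stop("f3_date must not be after f9_date", call. = FALSE)
  if (format(f3, "%Y") != format(f9, "%Y")) {
    stop("F3 and F9 must fall in the same calendar year", call. = FALSE)
  }
  structure(list(f3_date = f3, f9_date = f9), class = "phenology_window")
}

#' @export
print.phenology_window <- function(x, ...) {
  cat(sprintf("<phenology_window> F3 %s -> F9 %s (%d days)\n",
              format(x$f3_date), format(x$f9_date), n_window_days(x)))
  invisible(x)
}

n_window_days <- function(window) {
  as.integer(window$f9_date - window$f3_date) + 1L
}

#' Read phenology dates from a config file
#'
#' The file (JSON or YAML, by extension) maps season year to
#' `{f3_date, f9_date}`.
#'
#' @param path config file path.
#' @return Named list of [phenology_window()] objects, names are years.
#' @export
read_phenology <- function(path) {
  if (!file.exists(path)) stop("phenology file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  out <- lapply(raw, function(entry) {
    phenology_window(entry$f3_date, entry$f9_date)
  })
  stats::setNames(out, names(raw))
}

#' Extract the records inside a phenological window
#'
#' Returns exactly the station-days with `f3_date <= date <= f9_date`. Every
#' calendar day of the window must be present: accumulations over gapped
#' records would be biased low, so gaps are an error rather than silently
#' skipped.
#'
#' @param series a [weather_series()].
#' @param window a [phenology_window()].
#' @return A [weather_series()] restricted to the window.
#' @export
extract_window <- function(series, window) {
  stopifnot(inherits(window, "phenology_window"))
  span <- range(series$date)
  if (window$f3_date < span[1] || window$f9_date > span[2]) {
    stop(sprintf("window %s..%s extends beyond series span %s..%s",
                 format(window$f3_date), format(window$f9_date),
                 format(span[1]), format(span[2])), call. = FALSE)
  }
  keep <- series$date >= window$f3_date & series$date <= window$f9_date
  sub <- as.data.frame(series)[keep, , drop = FALSE]
  expected <- seq(window$f3_date, window$f9_date, by = "day")
  missing <- setdiff(format(expected), format(sub$date))
  if (length(missing)) {
    stop("window has missing day(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rownames(sub) <- NULL
  structure(sub,
            station_id = attr(series, "station_id"),
            year = attr(series, "year"),
            class = c("weather_series", "data.frame"))
}

#' Generate a synthetic season hitting prescribed accumulation targets
#'
#' Builds a daily series over the window whose effective temperature sum
#' (base 5 degrees C) equals `target_x` and whose rainfall sum equals
#' `target_w`, both to floating-point accuracy, and whose mean July ET0
#' equals `et0_july_mean` on the July days the window covers. Daily mean
#' temperature is the base plus the constant excess `target_x / n_days`,
#' perturbed by a seeded zero-sum jitter (capped so no daily excess goes
#' negative, keeping clamped and unclamped degree-day sums identical); the
#' min/max pair is placed symmetrically around that mean. Rain falls as a
#' uniform 0.1 mm-quantized daily amount with the remainder on the final
#' day. Generation is deterministic given `seed`.
#'
#' @param target_x target effective temperature sum, degree C day; `>= 0`.
#' @param target_w target rainfall sum, mm; `>= 0`.
#' @param window a [phenology_window()] of at least one day.
#' @param et0_july_mean mean July reference evapotranspiration, mm/day;
#'   `NA` to emulate a station without an ET0 sensor (no ET0 column).
#' @param seed integer seed for the jitter.
#' @param base_c base temperature, degrees C.
#' @return A [weather_series()] covering exactly the window.
#' @export
synth_season <- function(target_x, target_w, window,
                         et0_july_mean = NA_real_, seed = 1L, base_c = 5) {
  stopifnot(inherits(window, "phenology_window"))
  if (!is.finite(target_x) || target_x < 0) {
    stop("infeasible target_x (must be finite and >= 0): ", target_x,
         call. = FALSE)
  }
  if (!is.finite(target_w) || target_w < 0) {
    stop("infeasible target_w (must be finite and >= 0): ", target_w,
         call. = FALSE)
  }
  n <- n_window_days(window)
  dates <- seq(window$f3_date, window$f9_date, by = "day")

  excess0 <- target_x / n
  rng <- local({
    set.seed(as.integer(seed))
    list(jitter = stats::runif(n, -1, 1),
         spread = stats::runif(n, 3, 6),
         et0 = stats::runif(n, -0.5, 0.5))
  })
  amp <- 0.999 * min(excess0, 2)
  jit <- rng$jitter * amp
  jit <- jit - mean(jit)
  peak <- max(abs(jit))
  if (peak > amp) jit <- jit * (amp / peak)  # centering must not overshoot
  excess <- excess0 + jit
  excess[n] <- excess[n] + (target_x - sum(excess))  # pin the sum exactly
  mean_t <- base_c + excess
  tmin <- mean_t - rng$spread
  tmax <- mean_t + rng$spread

  per_day <- floor(10 * target_w / n) / 10
  rain <- rep(per_day, n)
  rain[n] <- target_w - per_day * (n - 1L)

  et0 <- NULL
  if (!is.na(et0_july_mean)) {
    if (et0_july_mean < 0) stop("et0_july_mean must be >= 0", call. = FALSE)
    et0 <- 3.5 + rng$et0
    et0[format(dates, "%m") == "07"] <- et0_july_mean
  }

  weather_series(dates, tmin, tmax, rain, et0_mm_day = et0,
                 station_id = sprintf("synthetic-seed%d", as.integer(seed)))
}
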