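# Shared fixtures, built in code.

aurora <- function() hop_cultivar("Aurora")

# Calibration observations from the packaged reference seasons.
aurora_obs <- function() {
  ref <- aurora_seasons()
  data.frame(year = ref$year,
             x = ref$x_eff_temp_sum,
             w = ref$w_rain_sum,
             alpha_assay_pct = ref$alpha_assay_pct,
             reliable = ref$et0_july_mean <= aurora()$et0_threshold)
}

# A small well-formed series for window/sum tests.
toy_series <- function(start = "2001-04-01", n = 183, seed = 42) {
  set.seed(seed)
  dates <- as.Date(start) + 0:(n - 1)
  tmin <- stats::runif(n, 5, 15)
  tmax <- tmin + stats::runif(n, 2, 12)
  weather_series(dates, tmin, tmax,
                 rain_mm = round(stats::rexp(n, 1 / 3), 1),
                 et0_mm_day = stats::runif(n, 1, 6),
                 station_id = "toy")
}

may_aug_window <- function(year = 2001) {
  phenology_window(sprintf("%d-05-03", year), sprintf("%d-08-30", year))
}
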