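test_that("a well-formed CSV reads into a validated weather series", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,tmin_c,tmax_c,rain_mm,et0_mm_day",
               "2001-05-01,10.2,21.5,0,3.1",
               "2001-05-02,11.0,19.9,4.2,2.8",
               "2001-05-03,9.8,22.3,0.5,3.6"), path)
  ws <- read_weather_table(path)
  expect_s3_class(ws, "weather_series")
  expect_equal(nrow(ws), 3)
  expect_equal(ws$date, as.Date("2001-05-01") + 0:2)
  expect_equal(ws$rain_mm, c(0, 4.2, 0.5))
  expect_equal(attr(ws, "year"), 2001L)
})

test_that("rows violating record invariants are rejected with row numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,tmin_c,tmax_c,rain_mm",
               "2001-05-01,10,20,0",
               "2001-05-02,12,8,0",
               "2001-05-03,9,18,1"), path)
  expect_error(read_weather_table(path), "tmin_c > tmax_c.*2")

  writeLines(c("date,tmin_c,tmax_c,rain_mm",
               "2001-05-01,10,20,0",
               "2001-05-01,11,21,0"), path)
  expect_error(read_weather_table(path), "duplicate dates")

  writeLines(c("date,tmin_c,tmax_c,rain_mm",
               "2001-05-01,10,20,-1"), path)
  expect_error(read_weather_table(path), "negative rain_mm")

  writeLines(c("date,tmin_c,tmax_c,rain_mm",
               "not-a-date,10,20,0"), path)
  expect_error(read_weather_table(path), "malformed or missing date")

  expect_error(read_weather_table(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("comma-decimal dialect is accepted behind the dec flag", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,tmin_c,tmax_c,rain_mm",
               '2003-05-01,"10,5","20,5","1,2"'), path)
  ws <- read_weather_table(path, dec = ",")
  expect_equal(ws$tmin_c, 10.5)
  expect_equal(ws$rain_mm, 1.2)
})

test_that("write/read round trip is lossless on generated series", {
  s <- synth_season(1698.4, 393.7, may_aug_window(), et0_july_mean = 4.26,
                    seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weather_table(s, path)
  s2 <- read_weather_table(path, station_id = attr(s, "station_id"))
  expect_equal(as.data.frame(s2), as.data.frame(s), tolerance = 0)
})

test_that("extract_window returns the closed F3..F9 interval", {
  s <- toy_series("2001-04-01", n = 183)  # Apr 1 .. Sep 30
  w <- phenology_window("2001-05-01", "2001-08-20")
  sub <- extract_window(s, w)
  expect_equal(nrow(sub), 112)  # 31 + 30 + 31 + 20 days, endpoints included
  expect_equal(sub$date[1], as.Date("2001-05-01"))
  expect_equal(sub$date[112], as.Date("2001-08-20"))

  one <- extract_window(s, phenology_window("2001-06-15", "2001-06-15"))
  expect_equal(nrow(one), 1)

  full <- extract_window(s, phenology_window("2001-04-01", "2001-09-30"))
  expect_equal(as.data.frame(full), as.data.frame(s))
})

test_that("windows beyond the span or containing gaps are errors", {
  s <- toy_series("2001-04-01", n = 60)
  expect_error(extract_window(s, phenology_window("2001-03-20", "2001-04-10")),
               "beyond series span")
  gapped <- as.data.frame(s)[-10, ]
  g <- weather_series(gapped$date, gapped$tmin_c, gapped$tmax_c,
                      gapped$rain_mm)
  expect_error(extract_window(g, phenology_window("2001-04-05", "2001-04-15")),
               "missing day")
})

test_that("phenology windows validate their dates", {
  expect_error(phenology_window("2001-09-01", "2001-05-01"), "not be after")
  expect_error(phenology_window("2001-09-01", "2002-05-01"), "same calendar")
  expect_error(phenology_window("junk", "2001-05-01"), "malformed")
  w <- may_aug_window()
  expect_equal(as.integer(w$f9_date - w$f3_date) + 1L, 120L)
})

test_that("phenology config files read from JSON and YAML", {
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"2001": {"f3_date": "2001-05-03", "f9_date": "2001-08-30"}}',
             js)
  ph <- read_phenology(js)
  expect_named(ph, "2001")
  expect_equal(ph[["2001"]]$f3_date, as.Date("2001-05-03"))

  ym <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("2012:", "  f3_date: 2012-04-28", "  f9_date: 2012-08-25"),
             ym)
  ph <- read_phenology(ym)
  expect_equal(ph[["2012"]]$f9_date, as.Date("2012-08-25"))
})

test_that("synthetic seasons hit their accumulation targets exactly", {
  w <- may_aug_window()
  s <- synth_season(1698.4, 393.7, w, et0_july_mean = 4.26, seed = 1)
  expect_equal(nrow(s), 120)
  expect_equal(effective_temperature_sum(s), 1698.4, tolerance = 1e-9)
  expect_equal(rainfall_sum(s), 393.7, tolerance = 1e-9)
  expect_equal(july_mean_et0(s, 2001), 4.26, tolerance = 1e-9)

  # determinism
  s2 <- synth_season(1698.4, 393.7, w, et0_july_mean = 4.26, seed = 1)
  expect_identical(as.data.frame(s), as.data.frame(s2))
  s3 <- synth_season(1698.4, 393.7, w, et0_july_mean = 4.26, seed = 2)
  expect_false(identical(s$tmin_c, s3$tmin_c))
})

test_that("zero-target synthetic season sits on the vegetation base", {
  w <- phenology_window("2001-06-01", "2001-06-10")
  s <- synth_season(0, 0, w, seed = 5)
  expect_equal((s$tmin_c + s$tmax_c) / 2, rep(5, 10))
  expect_equal(s$rain_mm, rep(0, 10))
  expect_false("et0_mm_day" %in% names(s))
  expect_error(synth_season(-5, 0, w), "infeasible target_x")
  expect_error(synth_season(10, -1, w), "infeasible target_w")
})

test_that("generator targets are recovered across random targets and seeds", {
  set.seed(99)
  for (i in 1:12) {
    tx <- stats::runif(1, 0, 2500)
    tw <- stats::runif(1, 0, 600)
    et0 <- stats::runif(1, 2, 6)
    seed <- sample.int(1e6, 1)
    s <- synth_season(tx, tw, may_aug_window(), et0_july_mean = et0,
                      seed = seed)
    expect_equal(effective_temperature_sum(s), tx, tolerance = 1e-9)
    # clamped sum agrees: jitter never drives a daily excess negative
    expect_equal(effective_temperature_sum(s, clamp_negative = TRUE), tx,
                 tolerance = 1e-9)
    expect_equal(rainfall_sum(s), tw, tolerance = 1e-9)
    expect_equal(july_mean_et0(s, 2001), et0, tolerance = 1e-9)
  }
})
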