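test_that("threshold ladder is validated and unit-consistent", {
  thr <- hypoxia_thresholds()
  expect_equal(as.character(thr$level),
               c("weak", "mild", "moderate", "severe"))
  expect_equal(thr$do_mgL, c(5, 4, 3, 2))
  expect_equal(thr$do_umol_kg, c(153, 122, 92, 61))
  implied <- convert_o2(thr$do_umol_kg, "umol/kg", "mg/L", temperature = 29.5)
  expect_true(all(abs(implied - thr$do_mgL) / thr$do_mgL < 0.02))
  expect_error(hypoxia_thresholds(do_mgL = c(weak = 4, mild = 5)),
               "decreasing")
  expect_error(
    hypoxia_thresholds(do_mgL = c(weak = 5, mild = 4),
                       do_umol_kg = c(200, 100)),
    "disagree"
  )
})

test_that("regridding a series already on the grid is the identity", {
  s <- make_series(function(t) 6 + sin(t), days = 1)
  out <- regrid_do(s)
  expect_equal(out$timestamp, s$timestamp)
  expect_equal(out$do_mgL, s$do_mgL, tolerance = 1e-12)
  expect_true(all(out$n_sensors == 1))
})

test_that("aggregation across sensors matches the stated statistic", {
  sensors <- lapply(c(5, 6, 7, 8), function(v) {
    make_series(function(t) rep(v, length(t)), days = 1)
  })
  med <- regrid_do(sensors, method = "median")
  expect_true(all(med$do_mgL == 6.5))
  avg <- regrid_do(sensors, method = "mean")
  expect_true(all(avg$do_mgL == 6.5))

  # two offset sinusoids aggregated by mean equal the analytic mean curve
  f1 <- function(t) 6 + sin(2 * pi * t / 24)
  f2 <- function(t) 6 + sin(2 * pi * (t - 3) / 24)
  two <- list(make_series(f1, days = 2, dt_min = 5),
              make_series(f2, days = 2, dt_min = 5))
  out <- regrid_do(two, target_dt = 15, method = "mean")
  t_h <- as.numeric(out$timestamp - out$timestamp[1], units = "hours")
  analytic <- (f1(t_h) + f2(t_h)) / 2
  # linear interpolation of a sinusoid is second-order in the source step
  expect_lt(max(abs(out$do_mgL - analytic)), (2 * pi * 5 / 60 / 24)^2)
})

test_that("no extrapolation beyond a sensor's own record", {
  s1 <- make_series(function(t) rep(4, length(t)), days = 2)
  s2 <- make_series(function(t) rep(8, length(t)), days = 1)
  out <- regrid_do(list(s1, s2), method = "mean")
  first_day <- out$timestamp < s1$timestamp[1] + 86400 - 450
  expect_true(all(out$do_mgL[first_day] == 6))
  expect_true(all(out$do_mgL[!first_day] %in% c(4, 6)))
  expect_true(any(out$n_sensors[!first_day] == 1))
  expect_error(regrid_do(list()), "at least one")
})

test_that("daily durations follow the strict-threshold counting rule", {
  const <- make_series(function(t) rep(6, length(t)), days = 2)
  d <- hypoxia_duration(const)
  expect_true(all(d$weak_h == 0) && all(d$severe_h == 0))
  expect_true(all(d$n_valid == 96))

  # 8 hours at 1.5 mg/L trips every level for exactly those samples
  step_fun <- function(t) ifelse(t %% 24 >= 2 & t %% 24 < 10, 1.5, 6)
  d2 <- hypoxia_duration(make_series(step_fun, days = 2))
  expect_true(all(d2$weak_h == 8) && all(d2$mild_h == 8) &&
                all(d2$moderate_h == 8) && all(d2$severe_h == 8))
})

test_that("diel sinusoid durations match the analytic crossing fraction", {
  s <- make_series(function(t) 5 + 2 * sin(2 * pi * t / 24), days = 3)
  d <- hypoxia_duration(s)
  # DO < 5 exactly where sin < 0: half of each day, to sample resolution
  expect_true(all(abs(d$weak_h - 12) <= 0.25))
  expect_true(all(d$severe_h == 0))
})

test_that("durations are nested and missing samples are tallied", {
  synth <- gen_do_series(days = 4, mean_do = 4.5, diel_amplitude = 2,
                         noise_sd = 0.3, seed = 5)
  s <- synth$series
  s$do_mgL[c(10, 50, 200)] <- NA
  d <- hypoxia_duration(s)
  expect_true(all(d$severe_h <= d$moderate_h))
  expect_true(all(d$moderate_h <= d$mild_h))
  expect_true(all(d$mild_h <= d$weak_h))
  expect_true(all(d$weak_h <= 24))
  expect_equal(sum(d$n_missing), 3)
  expect_equal(sum(d$n_valid + d$n_missing), nrow(s))
})

test_that("durations are invariant to splitting a series at midnight", {
  synth <- gen_do_series(days = 4, mean_do = 5, diel_amplitude = 1.8,
                         noise_sd = 0.2, seed = 9)
  s <- synth$series
  whole <- hypoxia_duration(s)
  cut <- s$timestamp[1] + 2 * 86400
  parts <- dplyr::bind_rows(
    hypoxia_duration(s[s$timestamp < cut, ]),
    hypoxia_duration(s[s$timestamp >= cut, ])
  )
  expect_equal(as.data.frame(whole), as.data.frame(parts))
})

test_that("irregular cadence is rejected with advice to regrid", {
  s <- make_series(function(t) rep(6, length(t)), days = 1)
  s <- s[-5, ]
  expect_error(hypoxia_duration(s), "regrid")
})

test_that("per-mass thresholds agree with mg/L thresholds on smooth series", {
  synth <- gen_do_series(days = 3, mean_do = 4.8, diel_amplitude = 1.5,
                         noise_sd = 0, seed = 1)
  thr <- hypoxia_thresholds()
  thr_mass <- hypoxia_thresholds(
    do_mgL = setNames(
      convert_o2(thr$do_umol_kg, "umol/kg", "mg/L", temperature = 29.5),
      as.character(thr$level)),
    do_umol_kg = thr$do_umol_kg
  )
  d1 <- hypoxia_duration(synth$series, thr)
  d2 <- hypoxia_duration(synth$series, thr_mass)
  for (lv in c("weak_h", "mild_h", "moderate_h", "severe_h")) {
    expect_true(all(abs(d1[[lv]] - d2[[lv]]) <= 0.25 + 1e-9))
  }
})

test_that("sensor CSV round-trips preserve the series", {
  synth <- gen_do_series(days = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(synth$series, path)
  back <- read_do_series(path)
  expect_equal(back$do_mgL, synth$series$do_mgL, tolerance = 1e-9)
  expect_equal(as.numeric(back$timestamp),
               as.numeric(synth$series$timestamp))
})
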