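test_that("bottle BOD and daily rates follow the mass balance", {
  b <- tibble::tibble(
    incubation_id = "A", role = "sargassum", sargassum_mass_mg = 50,
    do_initial_mgL = 8.0, do_final_mgL = 5.0, volume_L = 0.3, duration_d = 5
  )
  r <- bod_rates(b)
  expect_equal(r$bod_mgL, 3.0)
  expect_equal(r$total_consumed_mg, 0.9)
  expect_equal(r$daily_rate_mg_d, 0.18)

  # identity: no DO change, no consumption
  b$do_final_mgL <- b$do_initial_mgL
  expect_equal(bod_rates(b)$daily_rate_mg_d, 0)

  # a +2 mg/L GGA addition consumed over 5 days in a 0.3 l bottle
  b2 <- tibble::tibble(
    incubation_id = "A", role = "gga_standard", sargassum_mass_mg = 0,
    do_initial_mgL = 7.5, do_final_mgL = 5.5, volume_L = 0.3, duration_d = 5
  )
  expect_equal(bod_rates(b2)$daily_rate_mg_d, 0.12)
})

test_that("rates are linear in the DO drop and negative BOD is flagged", {
  b <- line_bottles(masses = c(0, 40, 80), incubations = "A")
  r1 <- bod_rates(b)
  b2 <- b
  b2$do_final_mgL <- b2$do_initial_mgL - 2 * (b$do_initial_mgL - b$do_final_mgL)
  expect_equal(bod_rates(b2)$daily_rate_mg_d, 2 * r1$daily_rate_mg_d)

  bneg <- b
  bneg$do_final_mgL[1] <- bneg$do_initial_mgL[1] + 0.2
  rneg <- bod_rates(bneg)
  expect_true(rneg$negative_bod[1])
  expect_false(any(rneg$negative_bod[-1]))
})

test_that("bottle validation enforces the schema", {
  b <- line_bottles()
  expect_error(bod_rates(dplyr::mutate(b, volume_L = 0)), "volume")
  expect_error(bod_rates(dplyr::mutate(b, duration_d = -1)), "duration")
  expect_error(bod_rates(dplyr::mutate(b, role = "blank")), "role")
  expect_warning(
    bod_rates(dplyr::mutate(b, sargassum_mass_mg = sargassum_mass_mg + 100)),
    "111.1"
  )
  # missing volume/duration columns default to 0.3 l and 5 d
  r <- bod_rates(b[setdiff(names(b), c("volume_L", "duration_d"))])
  expect_equal(unique(r$volume_L), 0.3)
  expect_equal(unique(r$duration_d), 5)
})

test_that("an exact linear relationship is recovered to numerical precision", {
  b <- line_bottles(slope = 0.004, intercept = 0.06,
                    masses = seq(0, 100, by = 10),
                    incubations = c("A", "B", "C"))
  fit <- fit_bod(b)
  expect_equal(fit$slope, 0.004, tolerance = 1e-8)
  expect_equal(fit$intercept, 0.06, tolerance = 1e-8)
})

test_that("degenerate designs fall back or fail loudly", {
  one_inc <- line_bottles(incubations = "A", masses = c(0, 50, 100))
  expect_warning(fit <- fit_bod(one_inc), "least squares")
  expect_equal(fit$fit_method, "ols_fallback")
  expect_error(fit_bod(one_inc, method = "lmm"), "2 incubations")

  same_mass <- line_bottles(masses = c(50, 50, 50))
  expect_error(fit_bod(same_mass), "identical")
})

test_that("balanced-design mixed-model slope agrees with pooled OLS", {
  # with identical mass designs in every incubation the GLS fixed effects
  # coincide with ordinary least squares, whatever the variance components
  synth <- gen_bod_dataset(seed = 11)
  f_mix <- fit_bod(synth$bottles)
  f_ols <- fit_bod(synth$bottles, method = "ols")
  expect_equal(f_mix$slope, f_ols$slope, tolerance = 1e-6)
  expect_equal(f_mix$intercept, f_ols$intercept, tolerance = 1e-6)
  expect_match(f_mix$fit_method, "^lmm")
})

test_that("slope recovery improves as residual noise vanishes", {
  rmse <- vapply(c(0.05, 0.01, 0.001), function(sd) {
    errs <- vapply(1:8, function(i) {
      synth <- gen_bod_dataset(resid_sd = sd, re_sd_slope = 0,
                               re_sd_intercept = 0, seed = 100 + i)
      fit_bod(synth$bottles)$slope - synth$truth$slope
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("GGA quality assurance flags per-incubation recovery", {
  mk <- function(id, gga_bod, control_bod = 0.3) {
    tibble::tibble(
      incubation_id = id,
      role = c("control", "gga_standard"),
      sargassum_mass_mg = 0,
      do_initial_mgL = 8,
      do_final_mgL = 8 - c(control_bod, control_bod + gga_bod),
      volume_L = 0.3, duration_d = 5
    )
  }
  b <- dplyr::bind_rows(
    mk("a", 2.0), mk("b", 2.1), mk("c", 1.9), mk("d", 2.3), mk("e", 1.7)
  )
  qa <- qa_gga(b)
  expect_true(all(qa$status == "pass"))
  expect_equal(attr(qa, "mean_difference"), 2.0)

  qa_bad <- qa_gga(dplyr::bind_rows(mk("a", 3.0), mk("b", 2.0)))
  expect_equal(qa_bad$status[qa_bad$incubation_id == "a"], "fail")

  no_gga <- mk("a", 2.0)[1, ]
  expect_equal(qa_gga(no_gga)$status, "incomplete")
})

test_that("synthetic incubations pass the GGA check at the expected rate", {
  status <- unlist(lapply(1:200, function(seed) {
    qa_gga(gen_bod_dataset(n_incubations = 1, seed = seed)$bottles)$status
  }))
  expect_gte(mean(status == "pass"), 0.95)
})

test_that("tidy, glance and bottle CSV round-trips are faithful", {
  synth <- gen_bod_dataset(seed = 3)
  fit <- fit_bod(synth$bottles)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_incubations, 5L)
  expect_gt(gl$slope_se, 0)

  path <- withr::local_tempfile(fileext = ".csv")
  write_bottles(synth$bottles, path)
  expect_equal(as.data.frame(read_bottles(path)),
               as.data.frame(synth$bottles))

  jpath <- withr::local_tempfile(fileext = ".json")
  write_bod_fit(fit, jpath)
  js <- jsonlite::read_json(jpath)
  expect_equal(js$slope, fit$slope, tolerance = 1e-12)
  expect_equal(js$fit_method, fit$fit_method)

  expect_s3_class(autoplot(fit), "ggplot")
})
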