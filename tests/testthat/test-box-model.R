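test_that("production forcing is a half-sine peaking at noon", {
  p <- scenario(residence_time = 1, temperature = 28)
  expect_equal(forcing_pp(12, p), 40)
  expect_equal(forcing_pp(0, p), 0)
  expect_equal(forcing_pp(9, p), 40 * sin(pi / 4), tolerance = 1e-12)
  expect_equal(forcing_pp(c(6, 18, 3, 21), p), c(0, 0, 0, 0))
  expect_error(forcing_pp(24, p), "hour")
})

test_that("respiration terms follow the Q10 law", {
  expect_equal(forcing_r(scenario(1, temperature = 28)), 12)
  expect_equal(forcing_r(scenario(1, temperature = 31)), 12 * 2^0.3,
               tolerance = 1e-12)
  expect_equal(forcing_r(scenario(1, temperature = 18)), 6)
  expect_equal(forcing_fs(scenario(1, temperature = 28)), 0)
  expect_equal(forcing_fs(scenario(1, temperature = 28,
                                   sargassum_biomass = 1)), 4.95)
  expect_equal(forcing_fs(scenario(1, temperature = 31,
                                   sargassum_biomass = 2)),
               9.9 * 2^0.3, tolerance = 1e-12)
})

test_that("scenario validation rejects unphysical parameters", {
  expect_error(scenario(0, 28), "residence_time")
  expect_error(scenario(1, 28, sargassum_biomass = -1), "biomass")
  expect_error(scenario(1, 28, dt = 20), "dt")
  expect_error(scenario(1, 28, sim_days = 3), "sim_days")
})

test_that("with no biological forcing the solution is exponential relaxation", {
  p <- scenario(residence_time = 2, temperature = 28, p_max = 0,
                r_base = 0, fs_base = 0, sim_days = 5, dt = 5,
                initial_do = 3)
  traj <- simulate_do(p)
  c_in <- o2_saturation(28, 35)
  expected <- c_in + (3 - c_in) * exp(-traj$time_h / 2)
  expect_equal(traj$do_mgL, expected, tolerance = 1e-6)
  expect_false(attr(traj, "floor_reached"))
  # trajectory length contract
  expect_equal(nrow(traj), 5 * 24 * 60 / 5 + 1)
})

test_that("nightly minimum approaches the quasi-steady night balance", {
  # for tau much shorter than the night, DO relaxes to
  # C_in - tau * (F_R + F_S) / depth by the end of the night
  for (b in c(0, 2)) {
    p <- scenario(residence_time = 0.25, temperature = 28,
                  sargassum_biomass = b, sim_days = 6, dt = 1)
    nm <- nightly_min(simulate_do(p))
    pred <- o2_saturation(28, 35) -
      convert_o2(0.25 * (forcing_r(p) + forcing_fs(p)), "mmol/m3", "mg/L")
    expect_equal(nm, pred, tolerance = 0.01)
  }
})

test_that("nightly minimum extraction scans only the final nights", {
  p <- scenario(residence_time = 1, temperature = 28, sim_days = 6, dt = 15)
  traj <- simulate_do(p)
  # constant trajectory: minimum equals the constant
  flat <- traj
  flat$do_mgL <- 6.0
  attr(flat, "params") <- attr(traj, "params")
  expect_equal(nightly_min(flat), 6.0)
  # a dip at 03:00 on the final night is picked up
  dip <- flat
  dip$do_mgL[which.min(abs(dip$time_h - (5 * 24 + 3)))] <- 1.5
  expect_equal(nightly_min(dip), 1.5)
  # ...but an early-day dip outside the window is not
  early <- flat
  early$do_mgL[which.min(abs(early$time_h - 3))] <- 1.5
  expect_equal(nightly_min(early), 6.0)
  expect_error(nightly_min(traj, last_n_days = 6), "spin-up")
})

test_that("halving the output step leaves the nightly minimum unchanged", {
  p1 <- scenario(residence_time = 5, temperature = 31,
                 sargassum_biomass = 2, sim_days = 6, dt = 2)
  p2 <- scenario(residence_time = 5, temperature = 31,
                 sargassum_biomass = 2, sim_days = 6, dt = 1)
  expect_lt(abs(nightly_min(simulate_do(p1)) - nightly_min(simulate_do(p2))),
            0.01)
})

test_that("nightly minimum decreases with biomass, residence time and warming", {
  nm <- function(tau, temp, b) {
    nightly_min(simulate_do(scenario(tau, temp, sargassum_biomass = b,
                                     sim_days = 6, dt = 5)))
  }
  for (b in c(0, 5)) {
    expect_gt(nm(1, 28, b), nm(5, 28, b))   # longer residence, lower DO
    expect_gt(nm(1, 28, b), nm(1, 31, b))   # warmer, lower DO
  }
  mins <- vapply(c(0, 2, 4, 8), function(b) nm(5, 28, b), numeric(1))
  expect_true(all(diff(mins) < 0))
})

test_that("threshold crossings are located and ordered on the ladder", {
  p <- scenario(residence_time = 5, temperature = 31, sim_days = 6, dt = 5)
  curve <- threshold_biomass_curve(p, biomass_grid = seq(0, 6, by = 0.5))
  cross <- attr(curve, "crossings")
  # strictly decreasing until the zero floor, nonincreasing throughout
  expect_true(all(diff(curve$nightly_min_do_mgL) <= 0))
  pos <- curve$nightly_min_do_mgL > 0
  expect_true(all(diff(curve$nightly_min_do_mgL[pos]) < 0))
  found <- cross$biomass_kg[!is.na(cross$biomass_kg)]
  expect_true(all(diff(found) >= 0)) # weak <= mild <= moderate <= severe
  expect_error(threshold_biomass_curve(p, biomass_grid = c(2, 1)), "sorted")
})

test_that("with all sinks and sources off no threshold is ever crossed", {
  p <- scenario(residence_time = 1, temperature = 28, p_max = 0,
                r_base = 0, fs_base = 0, sim_days = 5, dt = 15)
  curve <- threshold_biomass_curve(p, biomass_grid = c(0, 5, 10))
  expect_true(all(is.na(attr(curve, "crossings")$biomass_kg)))
})

test_that("trajectories and curves export and plot", {
  p <- scenario(residence_time = 5, temperature = 31, sargassum_biomass = 2,
                sim_days = 5, dt = 15)
  traj <- simulate_do(p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$do_mgL, traj$do_mgL, tolerance = 1e-9)

  curve <- threshold_biomass_curve(p, biomass_grid = c(0, 5, 10))
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_threshold_curve(curve, cpath)
  expect_true(file.exists(sub("\\.csv$", ".json", cpath)))

  expect_s3_class(autoplot(traj), "ggplot")
  expect_s3_class(autoplot(curve), "ggplot")
})
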