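#' Generate a synthetic bottle-incubation dataset
#'
#' Emulates the structure of a series of Sargassum BOD incubations: each
#' incubation draws its own slope and intercept around the shared truth
#' (random slopes and intercepts), every bottle's daily oxygen consumption
#' is `intercept_i + slope_i * mass` plus residual noise, and final DO is
#' back-computed from the initial DO, bottle volume and duration. Each
#' incubation holds one control (0 mg), one glutamic glucose acid standard
#' bottle whose consumption corresponds to its nominal +2 mg l^-1 BOD, and
#' Sargassum treatments evenly spaced up to `mass_max`.
#'
#' Default parameters are the study conditions the generator emulates:
#' five incubations of twelve bottles, masses up to 111.1 mg, truth slope
#' 0.0038 mg DO d^-1 mg^-1 and intercept 0.06 mg DO d^-1. Residual noise
#' (0.012 mg DO d^-1, i.e. 0.2 mg l^-1 on a 5-day BOD) reproduces the
#' observed spread of the GGA standards. Noisy final-DO draws are floored
#' at zero (a probe cannot read negative oxygen), which censors the linear
#' rate model; the default initial DO of 9.0 mg l^-1 leaves enough
#' headroom that this floor is never reached under default noise.
#'
#' @param n_incubations Number of independent incubations (>= 1).
#' @param bottles_per Bottles per incubation (>= 3): control + GGA +
#'   Sargassum treatments.
#' @param mass_max Largest Sargassum treatment, mg wet weight.
#' @param true_slope,true_intercept Population-level rate parameters,
#'   mg DO d^-1 mg^-1 and mg DO d^-1.
#' @param re_sd_slope,re_sd_intercept Between-incubation standard
#'   deviations of slope and intercept.
#' @param resid_sd Bottle-level residual s.d. of the daily rate, mg DO d^-1.
#' @param do_initial Initial DO of every bottle, mg l^-1 (freshly
#'   oxygenated source water).
#' @param volume Bottle volume, l.
#' @param duration Incubation length, days.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `bottles` (a bottle-record tibble accepted by
#'   [bod_rates()] and [fit_bod()]) and `truth` (generating parameters
#'   plus the per-incubation slopes and intercepts).
#' @examples
#' synth <- gen_bod_dataset(seed = 42)
#' nrow(synth$bottles) # 60
#' @export
gen_bod_dataset <- function(n_incubations = 5, bottles_per = 12,
                            mass_max = 111.1,
                            true_slope = 0.0038, true_intercept = 0.06,
                            re_sd_slope = 0.0005, re_sd_intercept = 0.04,
                            resid_sd = 0.012,
                            do_initial = 9.0, volume = 0.3, duration = 5,
                            seed) {
  if (n_incubations < 1) abort("`n_incubations` must be >= 1.")
  if (bottles_per < 3) abort("`bottles_per` must be >= 3 (control + GGA + treatments).")
  max_rate <- true_intercept + true_slope * mass_max
  if (do_initial - max_rate * duration / volume < 0) {
    abort(paste0("Deterministic final DO at the largest treatment is negative; ",
                 "use smaller masses/rates, a larger volume, or higher initial DO."))
  }
  withr::with_seed(seed, {
    slopes <- stats::rnorm(n_incubations, true_slope, re_sd_slope)
    intercepts <- stats::rnorm(n_incubations, true_intercept, re_sd_intercept)
    n_treat <- bottles_per - 2
    masses <- seq(mass_max / n_treat, mass_max, length.out = n_treat)
    rows <- purrr::map(seq_len(n_incubations), function(i) {
      mass <- c(0, 0, masses)
      role <- c("control", "gga_standard", rep("sargassum", n_treat))
      rate <- intercepts[i] + slopes[i] * mass +
        stats::rnorm(bottles_per, 0, resid_sd)
      # GGA standard consumes its nominal added BOD on top of source water
      rate[2] <- intercepts[i] + (2.0 * volume) / duration +
        stats::rnorm(1, 0, resid_sd)
      do_final <- pmax(do_initial - rate * duration / volume, 0)
      tibble::tibble(
        incubation_id = sprintf("inc%02d", i), role = role,
        sargassum_mass_mg = mass,
        do_initial_mgL = do_initial, do_final_mgL = do_final,
        volume_L = volume, duration_d = duration
      )
    })
    bottles <- dplyr::bind_rows(rows)
    list(
      bottles = bottles,
      truth = list(
        slope = true_slope, intercept = true_intercept,
        re_sd_slope = re_sd_slope, re_sd_intercept = re_sd_intercept,
        resid_sd = resid_sd,
        incubation_slopes = slopes, incubation_intercepts = intercepts,
        seed = seed
      )
    )
  })
}

#' Generate a synthetic diel dissolved-oxygen series
#'
#' Emulates a moored-sensor DO record: a diel cosine with its minimum in
#' the early morning, optional event-driven depressions (raised-cosine
#' pulses by default, square pulses for exact-duration tests), Gaussian
#' measurement noise, floored at zero. The analytic (noise-free) daily
#' hypoxia durations are returned as ground truth, evaluated on a fine
#' grid (0.005 h) of the clean curve.
#'
#' @param days Length of the series, days (>= 1).
#' @param dt Sampling interval, minutes (default 15).
#' @param mean_do Diel mean DO, mg l^-1.
#' @param diel_amplitude Half-range of the diel cycle, mg l^-1.
#' @param min_phase_hour Local hour of the daily minimum (default 5,
#'   just before sunrise).
#' @param events List of depressions, each
#'   `list(start_h =, duration_h =, depression =, shape = "cosine"|"square")`,
#'   with times in hours from the series start and depression depth in
#'   mg l^-1 at the pulse peak.
#' @param noise_sd Measurement noise s.d., mg l^-1.
#' @param start Series start instant (POSIXct, default midnight
#'   2023-08-18 UTC).
#' @param seed Integer seed.
#' @return A list with `series` (tibble `timestamp`, `do_mgL`) and
#'   `truth` (`clean` curve at the sample times, `durations` from the
#'   fine-grid clean curve via [hypoxia_duration()]'s counting rule,
#'   and the generating parameters).
#' @export
gen_do_series <- function(days, dt = 15, mean_do = 5.5, diel_amplitude = 1.5,
                          min_phase_hour = 5, events = list(),
                          noise_sd = 0.1,
                          start = as.POSIXct("2023-08-18 00:00:00", tz = "UTC"),
                          seed) {
  if (days < 1) abort("`days` must be >= 1.")
  clean_fun <- function(t_h) {
    base <- mean_do - diel_amplitude * cos(2 * pi * (t_h - min_phase_hour) / 24)
    for (ev in events) {
      shape <- ev$shape %||% "cosine"
      inside <- t_h >= ev$start_h & t_h <= ev$start_h + ev$duration_h
      pulse <- if (shape == "square") {
        ev$depression * inside
      } else {
        ev$depression / 2 *
          (1 - cos(2 * pi * (t_h - ev$start_h) / ev$duration_h)) * inside
      }
      base <- base - pulse
    }
    pmax(base, 0)
  }
  t_h <- seq(0, days * 24 - dt / 60, by = dt / 60)
  clean <- clean_fun(t_h)
  series <- withr::with_seed(seed, {
    tibble::tibble(
      timestamp = start + t_h * 3600,
      do_mgL = pmax(clean + stats::rnorm(length(t_h), 0, noise_sd), 0)
    )
  })
  fine_h <- seq(0, days * 24 - 0.005, by = 0.005)
  fine <- tibble::tibble(
    timestamp = start + fine_h * 3600,
    do_mgL = clean_fun(fine_h)
  )
  truth_durations <- hypoxia_duration(fine)
  list(
    series = series,
    truth = list(
      clean = tibble::tibble(timestamp = series$timestamp, do_mgL = clean),
      durations = truth_durations,
      mean_do = mean_do, diel_amplitude = diel_amplitude,
      min_phase_hour = min_phase_hour, events = events,
      noise_sd = noise_sd, seed = seed
    )
  )
}

#' Generate a synthetic two-band reflectance scene
#'
#' Builds a water background with disk-shaped floating-Sargassum patches
#' of vegetation-like reflectance (NIR well above red) and an optional
#' random cloud mask, returning the exact Sargassum pixel mask as ground
#' truth.
#'
#' @param shape `c(rows, cols)` of the scene.
#' @param pixel_size Ground pixel edge, m.
#' @param water_nir,water_red Background reflectances (water: red above
#'   NIR, so NDVI < 0).
#' @param patches List of disks, each
#'   `list(center = c(x, y) in metres, radius = metres, nir =, red =)`;
#'   defaults 0.35/0.08 give strongly positive NDVI.
#' @param cloud_fraction Fraction of pixels masked invalid at random.
#' @param noise_sd Reflectance noise s.d. added to both bands.
#' @param seed Integer seed.
#' @return A list with `scene` (a [raster_scene()]) and `truth`
#'   (`sargassum_mask`, `n_sargassum_px`, parameters).
#' @export
gen_scene <- function(shape = c(60, 60), pixel_size = 3,
                      water_nir = 0.02, water_red = 0.05,
                      patches = list(), cloud_fraction = 0,
                      noise_sd = 0, seed) {
  if (any(shape < 1)) abort("`shape` must be positive.")
  if (cloud_fraction < 0 || cloud_fraction > 1) {
    abort("`cloud_fraction` must be in [0, 1].")
  }
  nr <- shape[1]; nc <- shape[2]
  cx <- (rep(seq_len(nc), each = nr) - 0.5) * pixel_size
  cy <- (rep(seq_len(nr), times = nc) - 0.5) * pixel_size
  nir <- matrix(water_nir, nr, nc)
  red <- matrix(water_red, nr, nc)
  sarg <- matrix(FALSE, nr, nc)
  for (p in patches) {
    inside <- (cx - p$center[1])^2 + (cy - p$center[2])^2 <= p$radius^2
    nir[inside] <- p$nir %||% 0.35
    red[inside] <- p$red %||% 0.08
    sarg <- sarg | matrix(inside, nr, nc)
  }
  withr::with_seed(seed, {
    if (noise_sd > 0) {
      nir <- pmin(pmax(nir + stats::rnorm(nr * nc, 0, noise_sd), 0), 1.5)
      red <- pmin(pmax(red + stats::rnorm(nr * nc, 0, noise_sd), 0), 1.5)
    }
    valid <- matrix(TRUE, nr, nc)
    if (cloud_fraction > 0) {
      n_cloud <- round(cloud_fraction * nr * nc)
      valid[sample.int(nr * nc, n_cloud)] <- FALSE
    }
    scene <- raster_scene(nir, red, valid_mask = valid,
                          pixel_size = pixel_size)
    list(
      scene = scene,
      truth = list(
        sargassum_mask = sarg,
        n_sargassum_px = sum(sarg),
        cloud_fraction = cloud_fraction,
        seed = seed
      )
    )
  })
}
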