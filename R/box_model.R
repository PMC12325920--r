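#' Define a box-model scenario
#'
#' Parametrises one run of the 1 m^3 coastal dissolved-oxygen mass
#' balance. The box exchanges water with an offshore reservoir at the
#' oxygen-saturation concentration on a residence timescale `residence_time`,
#' gains oxygen from a half-sine gross-primary-production forcing peaking
#' at noon, and loses oxygen to temperature-dependent background
#' respiration and to respiration by decaying Sargassum proportional to
#' its biomass. Both respiration terms scale with temperature by a Q10
#' law referenced to `t_ref`.
#'
#' @param residence_time Water residence time tau, hours.
#' @param temperature Scenario seawater temperature, degrees C.
#' @param salinity Practical salinity (default 35).
#' @param sargassum_biomass Fresh Sargassum wet biomass in the box, kg.
#' @param depth Box depth, m (the box is 1 m^3 over 1 m^2).
#' @param p_max Peak gross primary production at noon, mmol O2 m^-2 h^-1.
#' @param r_base Background respiration at `t_ref`, mmol O2 m^-2 h^-1.
#' @param fs_base Sargassum respiration per biomass at `t_ref`,
#'   mmol O2 m^-2 h^-1 kg^-1 (4.95 corresponds to the incubation-derived
#'   0.0038 mg DO d^-1 mg^-1).
#' @param q10 Q10 temperature coefficient applied to both respiration
#'   terms (default 2).
#' @param t_ref Reference temperature for the Q10 scaling, degrees C.
#' @param sim_days Simulated length, days (>= 5: spin-up plus the four
#'   analysis nights).
#' @param dt Output time step, minutes (0 < dt <= 15).
#' @param day_start,day_end Local hours bounding the 12 h light window.
#' @param initial_do Initial DO, mg l^-1; defaults to saturation at the
#'   scenario temperature and salinity.
#' @return A validated list of class `scenario`.
#' @examples
#' scenario(residence_time = 5, temperature = 31, sargassum_biomass = 2)
#' @export
scenario <- function(residence_time, temperature, salinity = 35,
                     sargassum_biomass = 0, depth = 1,
                     p_max = 40, r_base = 12, fs_base = 4.95,
                     q10 = 2, t_ref = 28,
                     sim_days = 14, dt = 1,
                     day_start = 6, day_end = 18,
                     initial_do = NULL) {
  check_seawater_state(temperature, salinity)
  if (residence_time <= 0) abort("`residence_time` must be positive.")
  if (sargassum_biomass < 0) abort("`sargassum_biomass` must be >= 0.")
  if (depth <= 0) abort("`depth` must be positive.")
  if (dt <= 0 || dt > 15) abort("`dt` must be in (0, 15] minutes.")
  if (sim_days < 5) abort("`sim_days` must be >= 5 (spin-up plus four analysis nights).")
  if (!(day_start >= 0 && day_end <= 24 && day_start < day_end)) {
    abort("Need 0 <= day_start < day_end <= 24.")
  }
  if (is.null(initial_do)) initial_do <- o2_saturation(temperature, salinity)
  if (initial_do < 0) abort("`initial_do` must be >= 0.")
  structure(list(
    residence_time = residence_time, temperature = temperature,
    salinity = salinity, sargassum_biomass = sargassum_biomass,
    depth = depth, p_max = p_max, r_base = r_base, fs_base = fs_base,
    q10 = q10, t_ref = t_ref, sim_days = sim_days, dt = dt,
    day_start = day_start, day_end = day_end, initial_do = initial_do
  ), class = "scenario")
}

#' Box-model forcing terms
#'
#' `forcing_pp()` is the gross-primary-production oxygen flux: a half-sine
#' over the light window, zero at night, peaking at `p_max` at noon.
#' `forcing_r()` is the background community respiration:
#' `r_base * q10^((T - t_ref)/10)`. `forcing_fs()` is the Sargassum
#' respiration, `fs_base * biomass * q10^((T - t_ref)/10)`.
#'
#' @param hour Hour of day in \[0, 24), vectorised (for `forcing_pp`).
#' @param params A [scenario()] object.
#' @return Flux in mmol O2 m^-2 h^-1.
#' @examples
#' p <- scenario(residence_time = 1, temperature = 28)
#' forcing_pp(12, p) # 40 at noon
#' forcing_r(p)      # 12 at the reference temperature
#' @export
forcing_pp <- function(hour, params) {
  stopifnot(inherits(params, "scenario"))
  if (any(hour < 0 | hour >= 24)) abort("`hour` must lie in [0, 24).")
  daylen <- params$day_end - params$day_start
  out <- numeric(length(hour))
  day <- hour >= params$day_start & hour <= params$day_end
  out[day] <- params$p_max * sin(pi * (hour[day] - params$day_start) / daylen)
  out
}

#' @rdname forcing_pp
#' @export
forcing_r <- function(params) {
  stopifnot(inherits(params, "scenario"))
  params$r_base * params$q10^((params$temperature - params$t_ref) / 10)
}

#' @rdname forcing_pp
#' @export
forcing_fs <- function(params) {
  stopifnot(inherits(params, "scenario"))
  params$fs_base * params$sargassum_biomass *
    params$q10^((params$temperature - params$t_ref) / 10)
}

#' Simulate the dissolved-oxygen mass balance
#'
#' Integrates `dC/dt = (C_in - C)/tau + (F_PP(t) - F_R - F_S)/depth` with
#' C in mmol m^-3 and inflowing water at the oxygen-saturation
#' concentration for the scenario temperature and salinity, using the
#' adaptive `lsoda` solver from \pkg{deSolve} at relative tolerance 1e-8.
#' Output is converted to mg l^-1 and floored at zero (the model is not
#' valid in anoxia); whether the floor was reached is flagged.
#'
#' @param params A [scenario()] object.
#' @return A tibble of class `do_trajectory` with columns `time_h`,
#'   `do_mgL`, `is_night` (true where the production forcing is zero),
#'   and attributes `params` and `floor_reached`.
#' @examples
#' traj <- simulate_do(scenario(residence_time = 5, temperature = 31,
#'                              sargassum_biomass = 2, sim_days = 6))
#' nightly_min(traj)
#' @export
simulate_do <- function(params) {
  stopifnot(inherits(params, "scenario"))
  c_in <- o2_saturation(params$temperature, params$salinity, unit = "mmol/m3")
  c0 <- convert_o2(params$initial_do, "mg/L", "mmol/m3")
  fr <- forcing_r(params)
  fs <- forcing_fs(params)
  tau <- params$residence_time
  depth <- params$depth
  day_start <- params$day_start
  day_end <- params$day_end
  daylen <- day_end - day_start
  p_max <- params$p_max

  deriv <- function(t, y, parms) {
    hod <- t %% 24
    fpp <- if (hod >= day_start && hod <= day_end) {
      p_max * sin(pi * (hod - day_start) / daylen)
    } else 0
    list((c_in - y) / tau + (fpp - fr - fs) / depth)
  }
  times <- seq(0, params$sim_days * 24, by = params$dt / 60)
  out <- tryCatch(
    deSolve::ode(y = c(C = c0), times = times, func = deriv, parms = NULL,
                 method = "lsoda", rtol = 1e-8, atol = 1e-8),
    error = function(e) e, warning = function(w) w
  )
  if (inherits(out, "condition") || attr(out, "istate")[1] < 0) {
    abort(paste0("ODE solver failed for scenario: tau=", tau,
                 " h, T=", params$temperature, " C, biomass=",
                 params$sargassum_biomass, " kg."))
  }
  conc <- out[, 2]
  floor_reached <- any(conc < 0)
  conc <- pmax(conc, 0)
  hod <- out[, 1] %% 24
  traj <- tibble::tibble(
    time_h = out[, 1],
    do_mgL = convert_o2(conc, "mmol/m3", "mg/L"),
    is_night = forcing_pp(hod, params) == 0
  )
  attr(traj, "params") <- params
  attr(traj, "floor_reached") <- floor_reached
  class(traj) <- c("do_trajectory", class(traj))
  traj
}

#' Minimum night-time dissolved oxygen over the final nights
#'
#' Extracts the minimum DO over the dark hours of the last `last_n_days`
#' simulated days, the box model's headline output. Earlier days serve as
#' spin-up from the initial condition.
#'
#' @param traj A `do_trajectory` from [simulate_do()].
#' @param last_n_days Number of final days to scan (default 4).
#' @return Minimum night-time DO, mg l^-1.
#' @export
nightly_min <- function(traj, last_n_days = 4) {
  stopifnot(inherits(traj, "do_trajectory"))
  params <- attr(traj, "params")
  if (params$sim_days < last_n_days + 1) {
    abort("`sim_days` must exceed `last_n_days` to leave spin-up.")
  }
  keep <- traj$is_night & traj$time_h >= (params$sim_days - last_n_days) * 24
  if (!any(keep)) abort("No night-time samples in the analysis window.")
  min(traj$do_mgL[keep])
}

#' Nightly-minimum DO and hypoxia onset across a Sargassum biomass grid
#'
#' Runs the box model for every biomass on a grid, records the nightly
#' minimum DO, and locates, for each level of the threshold ladder, the
#' smallest biomass whose nightly minimum falls strictly below the
#' threshold.
#'
#' @param params A [scenario()] object; its `sargassum_biomass` is
#'   replaced by each grid value in turn.
#' @param biomass_grid Ascending biomass grid, kg (default 0 to 10 by
#'   0.25, resolving roughly half-kilogram readouts).
#' @param thresholds A ladder from [hypoxia_thresholds()].
#' @return A tibble of class `threshold_curve` with columns `biomass_kg`
#'   and `nightly_min_do_mgL`, and attribute `crossings`: a tibble with
#'   `level`, `threshold_mgL`, `biomass_kg` (NA when never crossed).
#' @examples
#' \donttest{
#' curve <- threshold_biomass_curve(
#'   scenario(residence_time = 5, temperature = 31),
#'   biomass_grid = seq(0, 4, by = 1)
#' )
#' attr(curve, "crossings")
#' }
#' @export
threshold_biomass_curve <- function(params,
                                    biomass_grid = seq(0, 10, by = 0.25),
                                    thresholds = hypoxia_thresholds()) {
  stopifnot(inherits(params, "scenario"))
  if (is.unsorted(biomass_grid, strictly = TRUE)) {
    abort("`biomass_grid` must be sorted strictly ascending.")
  }
  if (any(biomass_grid < 0)) abort("`biomass_grid` must be non-negative.")
  mins <- vapply(biomass_grid, function(b) {
    p <- params
    p$sargassum_biomass <- b
    nightly_min(simulate_do(p))
  }, numeric(1))
  curve <- tibble::tibble(biomass_kg = biomass_grid, nightly_min_do_mgL = mins)
  crossings <- thresholds |>
    dplyr::mutate(biomass_kg = purrr::map_dbl(.data$do_mgL, function(thr) {
      idx <- which(mins < thr)
      if (length(idx)) biomass_grid[min(idx)] else NA_real_
    })) |>
    dplyr::select("level", threshold_mgL = "do_mgL", "biomass_kg")
  attr(curve, "params") <- params
  attr(curve, "crossings") <- crossings
  class(curve) <- c("threshold_curve", class(curve))
  curve
}

#' Plot box-model outputs
#'
#' `autoplot.do_trajectory()` draws the DO time series with night-time
#' shading at the hypoxia thresholds; `autoplot.threshold_curve()` draws
#' nightly-minimum DO against Sargassum biomass with the threshold ladder.
#'
#' @param object A `do_trajectory` or `threshold_curve`.
#' @param thresholds A ladder from [hypoxia_thresholds()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot do_trajectory
#' @export
autoplot.do_trajectory <- function(object, thresholds = hypoxia_thresholds(), ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h / 24, y = .data$do_mgL)) +
    ggplot2::geom_hline(data = thresholds,
                        ggplot2::aes(yintercept = .data$do_mgL),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day", y = expression("DO (mg " * l^-1 * ")")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.do_trajectory
#' @method autoplot threshold_curve
#' @export
autoplot.threshold_curve <- function(object, thresholds = hypoxia_thresholds(), ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$biomass_kg,
                                       y = .data$nightly_min_do_mgL)) +
    ggplot2::geom_hline(data = thresholds,
                        ggplot2::aes(yintercept = .data$do_mgL),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Fresh Sargassum biomass (kg)",
                  y = expression("Nightly minimum DO (mg " * l^-1 * ")")) +
    ggplot2::theme_minimal()
}

#' Export box-model outputs as plain-text files
#'
#' `write_trajectory()` writes `time_h,do_mgL,is_night`;
#' `write_threshold_curve()` writes `biomass_kg,nightly_min_do_mgL` plus a
#' JSON sidecar of threshold crossings.
#'
#' @param traj A `do_trajectory`.
#' @param path Output CSV path (the crossing JSON replaces the extension
#'   with `.json`).
#' @return The input, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj), path)
  invisible(traj)
}

#' @rdname write_trajectory
#' @param curve A `threshold_curve`.
#' @export
write_threshold_curve <- function(curve, path) {
  readr::write_csv(tibble::as_tibble(curve), path)
  cross <- attr(curve, "crossings")
  cross$level <- as.character(cross$level)
  jsonlite::write_json(cross, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(curve)
}
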