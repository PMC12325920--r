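# Noiseless bottle records lying exactly on rate = intercept + slope * mass,
# back-computed into DO endpoints.
line_bottles <- function(slope = 0.004, intercept = 0.06,
                         masses = seq(0, 100, by = 20),
                         incubations = c("A", "B"),
                         do_initial = 8.3, volume = 0.3, duration = 5) {
  rows <- lapply(incubations, function(id) {
    rate <- intercept + slope * masses
    tibble::tibble(
      incubation_id = id,
      role = ifelse(masses == 0, "control", "sargassum"),
      sargassum_mass_mg = masses,
      do_initial_mgL = do_initial,
      do_final_mgL = do_initial - rate * duration / volume,
      volume_L = volume, duration_d = duration
    )
  })
  dplyr::bind_rows(rows)
}

# Regular DO series from a function of time in hours.
make_series <- function(fun, days = 2, dt_min = 15,
                        start = as.POSIXct("2023-08-18 00:00:00", tz = "UTC")) {
  t_h <- seq(0, days * 24 - dt_min / 60, by = dt_min / 60)
  tibble::tibble(timestamp = start + t_h * 3600, do_mgL = fun(t_h))
}
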