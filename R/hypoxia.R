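#' The four-level hypoxia threshold ladder
#'
#' Dissolved-oxygen thresholds used throughout the package: weak (< 5),
#' mild (< 4), moderate (< 3) and severe (< 2) mg l^-1, with the
#' corresponding per-mass values 153, 122, 92 and 61 umol kg^-1. The two
#' ladders are mutually consistent through seawater density at warm
#' tropical surface conditions; the constructor checks agreement to within
#' 2% at 29.5 degrees C, S = 35.
#'
#' @param do_mgL Named numeric vector of threshold values in mg l^-1,
#'   strictly decreasing, named by level.
#' @param do_umol_kg Matching thresholds in umol kg^-1, or `NULL` to derive
#'   them from `do_mgL` at the reference state.
#' @return A tibble with columns `level` (ordered factor), `do_mgL`,
#'   `do_umol_kg`.
#' @examples
#' hypoxia_thresholds()
#' @export
hypoxia_thresholds <- function(do_mgL = c(weak = 5, mild = 4, moderate = 3, severe = 2),
                               do_umol_kg = c(weak = 153, mild = 122,
                                              moderate = 92, severe = 61)) {
  if (is.null(names(do_mgL)) || any(!nzchar(names(do_mgL)))) {
    abort("`do_mgL` must be a named vector of threshold levels.")
  }
  if (any(diff(do_mgL) >= 0)) {
    abort("Hypoxia thresholds must be strictly decreasing from weak to severe.")
  }
  if (is.null(do_umol_kg)) {
    do_umol_kg <- convert_o2(do_mgL, "mg/L", "umol/kg",
                             temperature = 29.5, salinity = 35)
  } else {
    if (length(do_umol_kg) != length(do_mgL)) {
      abort("`do_umol_kg` must match `do_mgL` in length.")
    }
    implied <- convert_o2(do_umol_kg, "umol/kg", "mg/L",
                          temperature = 29.5, salinity = 35)
    if (any(abs(implied - do_mgL) / do_mgL > 0.02)) {
      abort("mg/L and umol/kg threshold ladders disagree by more than 2% at reference conditions (29.5 C, S = 35).")
    }
  }
  tibble::tibble(
    level = factor(names(do_mgL), levels = names(do_mgL), ordered = TRUE),
    do_mgL = unname(do_mgL),
    do_umol_kg = unname(do_umol_kg)
  )
}

#' Consolidate dissolved-oxygen sensor series onto a common grid
#'
#' Linearly interpolates each input series onto a shared regular grid and
#' aggregates across sensors point by point, mirroring how replicate moored
#' optodes are combined into a single site record (median of four sensors
#' in summer, mean of two in winter). No series is extrapolated beyond its
#' own support; grid points covered by no series are missing.
#'
#' @param series_list A data frame with columns `timestamp` (POSIXct) and
#'   `do_mgL`, or a list of such data frames (one per sensor).
#' @param target_dt Grid spacing in minutes (default 15, the instrument
#'   cadence).
#' @param method Aggregation across sensors at each grid point: `"median"`
#'   or `"mean"`.
#' @return A tibble with columns `timestamp`, `do_mgL` and `n_sensors`
#'   (number of series contributing at each point), at regular `target_dt`
#'   spacing.
#' @export
regrid_do <- function(series_list, target_dt = 15, method = c("median", "mean")) {
  method <- match.arg(method)
  if (is.data.frame(series_list)) series_list <- list(series_list)
  if (length(series_list) == 0) abort("`series_list` must contain at least one series.")
  series_list <- lapply(series_list, check_do_series)

  starts <- vapply(series_list, function(s) as.numeric(min(s$timestamp)), 0)
  ends <- vapply(series_list, function(s) as.numeric(max(s$timestamp)), 0)
  dt_s <- target_dt * 60
  t0 <- ceiling(min(starts) / dt_s) * dt_s
  t1 <- floor(max(ends) / dt_s) * dt_s
  if (t1 < t0) abort("Series are too short to cover a single grid point.")
  grid <- seq(t0, t1, by = dt_s)

  vals <- vapply(series_list, function(s) {
    tt <- as.numeric(s$timestamp)
    out <- rep(NA_real_, length(grid))
    inside <- grid >= min(tt) & grid <= max(tt)
    if (any(inside)) {
      ok <- !is.na(s$do_mgL)
      if (sum(ok) >= 2) {
        out[inside] <- approx(tt[ok], s$do_mgL[ok], xout = grid[inside],
                              method = "linear", rule = 1)$y
      } else if (sum(ok) == 1) {
        hit <- inside & grid == tt[ok]
        out[hit] <- s$do_mgL[ok]
      }
    }
    out
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))

  n_sensors <- rowSums(!is.na(vals))
  agg_fun <- if (method == "median") {
    function(x) median(x, na.rm = TRUE)
  } else {
    function(x) mean(x, na.rm = TRUE)
  }
  do <- apply(vals, 1, function(x) if (all(is.na(x))) NA_real_ else agg_fun(x))
  if (all(n_sensors == 0)) {
    warn("Input series do not overlap the common grid; output is all-missing.")
  }
  tz <- attr(series_list[[1]]$timestamp, "tzone") %||% "UTC"
  tibble::tibble(
    timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = tz),
    do_mgL = do,
    n_sensors = as.integer(n_sensors)
  )
}

#' Daily hypoxia duration below each threshold
#'
#' For each local calendar day, counts the time dissolved oxygen spent
#' strictly below each level of the threshold ladder. Each valid sample on
#' the regular grid contributes one sample period; missing samples
#' contribute nothing and are tallied in `n_missing`. Durations are nested
#' by construction: time below the severe threshold is also below the
#' moderate, mild and weak ones.
#'
#' @param series A data frame with columns `timestamp` (POSIXct, regular
#'   cadence) and `do_mgL`, e.g. the output of [regrid_do()].
#' @param thresholds A threshold ladder from [hypoxia_thresholds()].
#' @return A tibble with one row per calendar day: `date`, one
#'   `<level>_h` column of hours below each threshold, `n_valid`,
#'   `n_missing`.
#' @export
hypoxia_duration <- function(series, thresholds = hypoxia_thresholds()) {
  series <- check_do_series(series)
  tt <- as.numeric(series$timestamp)
  if (length(tt) < 2) abort("`series` needs at least two samples.")
  steps <- diff(tt)
  dt_s <- median(steps)
  if (any(abs(steps - dt_s) > 1e-6 * dt_s)) {
    abort("`series` has irregular cadence; consolidate with regrid_do() first.")
  }
  dt_h <- dt_s / 3600
  date <- as.Date(format(series$timestamp, "%Y-%m-%d",
                         tz = attr(series$timestamp, "tzone") %||% "UTC"))
  valid <- !is.na(series$do_mgL)

  per_level <- lapply(seq_len(nrow(thresholds)), function(i) {
    below <- valid & series$do_mgL < thresholds$do_mgL[i]
    tapply(below, date, sum) * dt_h
  })
  names(per_level) <- paste0(as.character(thresholds$level), "_h")

  days <- sort(unique(date))
  out <- tibble::tibble(date = days)
  for (nm in names(per_level)) {
    out[[nm]] <- as.numeric(per_level[[nm]][as.character(days)])
  }
  out$n_valid <- as.integer(tapply(valid, date, sum)[as.character(days)])
  out$n_missing <- as.integer(tapply(!valid, date, sum)[as.character(days)])
  out
}

check_do_series <- function(series) {
  if (!is.data.frame(series) || !all(c("timestamp", "do_mgL") %in% names(series))) {
    abort("A DO series must be a data frame with columns `timestamp` and `do_mgL`.")
  }
  if (!inherits(series$timestamp, "POSIXct")) {
    abort("`timestamp` must be POSIXct (parse with read_do_series() or as.POSIXct()).")
  }
  if (nrow(series) == 0) abort("DO series is empty.")
  if (is.unsorted(as.numeric(series$timestamp), strictly = TRUE)) {
    abort("`timestamp` must be strictly increasing.")
  }
  if (any(series$do_mgL < 0, na.rm = TRUE)) {
    abort("`do_mgL` must be non-negative (or missing).")
  }
  series
}

#' Read and write dissolved-oxygen sensor CSVs
#'
#' `read_do_series()` expects a header `timestamp,do_mgL` with optional
#' `temp_C` and `sal_psu` columns and ISO-8601 timestamps.
#' `write_daily_durations()` writes the output of [hypoxia_duration()]
#' with the header `date,weak_h,mild_h,moderate_h,severe_h,n_valid,n_missing`.
#'
#' @param path File path.
#' @param tz Time zone used to interpret the timestamps (default UTC).
#' @return `read_do_series()` returns a tibble; `write_daily_durations()`
#'   returns its input invisibly.
#' @export
read_do_series <- function(path, tz = "UTC") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("timestamp", "do_mgL") %in% names(df))) {
    abort("Expected columns `timestamp,do_mgL` in the sensor CSV.")
  }
  if (!inherits(df$timestamp, "POSIXct")) {
    df$timestamp <- as.POSIXct(df$timestamp, tz = tz,
                               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  }
  check_do_series(df)
}

#' @rdname read_do_series
#' @param durations Output of [hypoxia_duration()].
#' @export
write_daily_durations <- function(durations, path) {
  readr::write_csv(durations, path)
  invisible(durations)
}
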