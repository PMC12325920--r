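#' Seawater density at atmospheric pressure
#'
#' Density of seawater from the EOS-80 (UNESCO 1983) one-atmosphere
#' polynomial. Sufficient for converting oxygen concentrations between
#' per-mass and per-volume units in shallow coastal work; any standard
#' seawater equation of state agrees to well under 0.1% at the surface.
#'
#' @param temperature In-situ temperature, degrees C. Must lie in
#'   \[-2, 40\].
#' @param salinity Practical salinity (dimensionless). Must lie in
#'   \[0, 42\]. Defaults to 35, typical of open Caribbean surface water.
#' @param pressure Sea pressure, dbar. Only the surface value 0 is
#'   supported.
#' @return Density in kg m^-3, vectorised over `temperature` and
#'   `salinity`.
#' @examples
#' sw_density(29.5, 35) # ~1021.6 kg m^-3
#' @export
sw_density <- function(temperature, salinity = 35, pressure = 0) {
  check_seawater_state(temperature, salinity)
  if (any(pressure != 0)) {
    abort("sw_density() implements the surface (p = 0 dbar) equation of state only.")
  }
  t <- temperature
  s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  cc <- 4.8314e-4
  rho_w + a * s + b * s^1.5 + cc * s^2
}

#' Oxygen saturation concentration in seawater
#'
#' Equilibrium dissolved-oxygen concentration at 1 atm total pressure from
#' the Garcia and Gordon (1992) combined fit to the Benson and Krause data,
#' converted from umol kg^-1 to mg l^-1 with [sw_density()]. Strictly
#' decreasing in both temperature and salinity.
#'
#' @inheritParams sw_density
#' @param unit Output unit, one of `"mg/L"`, `"umol/kg"`, `"mmol/m3"`.
#' @return Saturation concentration in the requested unit, vectorised.
#' @references Garcia, H. E. and Gordon, L. I. (1992) Oxygen solubility in
#'   seawater: better fitting equations. Limnology and Oceanography 37,
#'   1307-1312.
#' @examples
#' o2_saturation(28, 35) # ~6.4 mg l^-1
#' o2_saturation(31, 35) # warmer water holds less oxygen
#' @export
o2_saturation <- function(temperature, salinity = 35, unit = "mg/L") {
  check_seawater_state(temperature, salinity)
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  b <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  c0 <- -2.75915e-7
  ln_c <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity^2
  sat_umol_kg <- exp(ln_c)
  convert_o2(sat_umol_kg, "umol/kg", unit,
             temperature = temperature, salinity = salinity)
}

o2_conc_units <- c("umol/kg", "mg/L", "mmol/m3")

#' Convert dissolved-oxygen concentrations between units
#'
#' Converts between mass-per-volume (`"mg/L"`), amount-per-volume
#' (`"mmol/m3"`) and amount-per-mass (`"umol/kg"`) oxygen concentration
#' units. Conversions involving `"umol/kg"` require the seawater state,
#' since they go through density.
#'
#' @param value Numeric vector of concentrations, >= 0.
#' @param from,to Unit tags; one of `"umol/kg"`, `"mg/L"`, `"mmol/m3"`.
#' @inheritParams sw_density
#' @return Numeric vector in the `to` unit.
#' @examples
#' convert_o2(153, "umol/kg", "mg/L", temperature = 29.5) # ~5.0
#' convert_o2(61, "umol/kg", "mg/L", temperature = 29.5)  # ~2.0
#' @export
convert_o2 <- function(value, from, to, temperature = NULL, salinity = 35) {
  from <- match_unit(from, o2_conc_units)
  to <- match_unit(to, o2_conc_units)
  if (any(value < 0, na.rm = TRUE)) {
    abort("Oxygen concentrations must be non-negative.")
  }
  if (from == to) return(value)
  needs_rho <- "umol/kg" %in% c(from, to)
  if (needs_rho) {
    if (is.null(temperature)) {
      abort("Converting to or from umol/kg requires `temperature` (and `salinity`) for seawater density.")
    }
    rho <- sw_density(temperature, salinity) # kg m^-3
  }
  # canonical intermediate: mmol/m3
  mmol_m3 <- switch(from,
    "mmol/m3" = value,
    "mg/L" = value * 1000 / O2_MOLAR_MASS,
    "umol/kg" = value * rho / 1000
  )
  switch(to,
    "mmol/m3" = mmol_m3,
    "mg/L" = mmol_m3 * O2_MOLAR_MASS / 1000,
    "umol/kg" = mmol_m3 * 1000 / rho
  )
}

o2_rate_units <- c("mg/d", "mmol/h", "mg/d/mgS", "mg/d/kgS", "mmol/h/kgS")

#' Convert oxygen consumption rates between units
#'
#' Converts bulk rates between `"mg/d"` and `"mmol/h"`, and
#' Sargassum-biomass-normalised rates among `"mg/d/mgS"`, `"mg/d/kgS"` and
#' `"mmol/h/kgS"`. Mass-molar interconversion uses the molar mass of O2
#' (31.998 g mol^-1); per-mg to per-kg biomass multiplies by 1e6.
#' Bulk and per-biomass units are dimensionally incompatible.
#'
#' @param value Numeric vector of rates.
#' @param from,to Unit tags from `"mg/d"`, `"mmol/h"`, `"mg/d/mgS"`,
#'   `"mg/d/kgS"`, `"mmol/h/kgS"`.
#' @return Numeric vector in the `to` unit.
#' @examples
#' convert_o2_rate(12, "mmol/h", "mg/d")            # 9215.4 ~ 9216
#' convert_o2_rate(0.0038, "mg/d/mgS", "mg/d/kgS")  # 3800
#' convert_o2_rate(3800, "mg/d/kgS", "mmol/h/kgS")  # ~4.95
#' @export
convert_o2_rate <- function(value, from, to) {
  from <- match_unit(from, o2_rate_units)
  to <- match_unit(to, o2_rate_units)
  if (from == to) return(value)
  bulk <- c("mg/d", "mmol/h")
  if (xor(from %in% bulk, to %in% bulk)) {
    abort(sprintf("Cannot convert '%s' to '%s': bulk and per-biomass rates are dimensionally incompatible.",
                  from, to))
  }
  # canonical intermediates: mg/d (bulk) or mg/d/kgS (per biomass)
  mg_d_per <- O2_MOLAR_MASS * 24 # mg/d per mmol/h
  x <- switch(from,
    "mg/d" = value,
    "mmol/h" = value * mg_d_per,
    "mg/d/kgS" = value,
    "mg/d/mgS" = value * 1e6,
    "mmol/h/kgS" = value * mg_d_per
  )
  switch(to,
    "mg/d" = x,
    "mmol/h" = x / mg_d_per,
    "mg/d/kgS" = x,
    "mg/d/mgS" = x / 1e6,
    "mmol/h/kgS" = x / mg_d_per
  )
}

check_seawater_state <- function(temperature, salinity) {
  if (any(!is.finite(temperature)) || any(temperature < -2 | temperature > 40)) {
    abort("`temperature` must be finite and within [-2, 40] degrees C.")
  }
  if (any(!is.finite(salinity)) || any(salinity < 0 | salinity > 42)) {
    abort("`salinity` must be finite and within [0, 42].")
  }
  invisible(NULL)
}

match_unit <- function(unit, choices) {
  if (!is.character(unit) || length(unit) != 1 || !unit %in% choices) {
    abort(sprintf("Unknown unit '%s'; expected one of: %s.",
                  paste(unit, collapse = ","), paste(choices, collapse = ", ")))
  }
  unit
}
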