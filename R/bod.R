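#' Bottle-level biochemical oxygen demand and daily consumption rate
#'
#' Computes the 5-day BOD and daily oxygen consumption for each incubation
#' bottle: BOD is the drop in dissolved oxygen over the incubation, the
#' total oxygen consumed is BOD times bottle volume, and the daily rate is
#' the total divided by the incubation duration. Negative BOD (final DO
#' above initial) is retained and flagged rather than dropped.
#'
#' @param bottles A data frame of bottle records with columns
#'   `incubation_id`, `role` (one of `"control"`, `"gga_standard"`,
#'   `"sargassum"`), `sargassum_mass_mg`, `do_initial_mgL`, `do_final_mgL`,
#'   and optionally `volume_L` (default 0.3) and `duration_d` (default 5).
#' @return The input as a tibble with added columns `bod_mgL`,
#'   `total_consumed_mg`, `daily_rate_mg_d` and `negative_bod`.
#' @examples
#' bottles <- tibble::tibble(
#'   incubation_id = "A", role = "sargassum", sargassum_mass_mg = 50,
#'   do_initial_mgL = 8, do_final_mgL = 5, volume_L = 0.3, duration_d = 5
#' )
#' bod_rates(bottles)
#' @export
bod_rates <- function(bottles) {
  bottles <- check_bottles(bottles)
  dplyr::mutate(bottles,
    bod_mgL = .data$do_initial_mgL - .data$do_final_mgL,
    total_consumed_mg = .data$bod_mgL * .data$volume_L,
    daily_rate_mg_d = .data$total_consumed_mg / .data$duration_d,
    negative_bod = .data$bod_mgL < 0
  )
}

#' Quality assurance against the glutamic glucose acid standard
#'
#' Each incubation carries one bottle spiked with a glutamic glucose acid
#' (GGA) standard of nominal +2.0 mg l^-1 BOD. This check computes, per
#' incubation, the GGA bottle's BOD minus the control bottle's BOD and
#' flags it against a window around the nominal value. Incubations missing
#' either bottle are marked `"incomplete"` rather than failing.
#'
#' @inheritParams bod_rates
#' @param nominal Nominal BOD added by the GGA standard, mg l^-1.
#' @param tol Half-width of the acceptance window, mg l^-1 (default 0.6,
#'   twice the between-incubation spread observed in practice).
#' @return A tibble with one row per incubation: `incubation_id`,
#'   `gga_bod_mgL`, `control_bod_mgL`, `difference_mgL`, `status`
#'   (`"pass"`, `"fail"` or `"incomplete"`); the aggregate mean and s.d.
#'   of the differences are attached as attributes `"mean_difference"`
#'   and `"sd_difference"`.
#' @export
qa_gga <- function(bottles, nominal = 2.0, tol = 0.6) {
  rates <- bod_rates(bottles)
  per <- rates |>
    dplyr::group_by(.data$incubation_id) |>
    dplyr::summarise(
      gga_bod_mgL = if (any(.data$role == "gga_standard"))
        mean(.data$bod_mgL[.data$role == "gga_standard"]) else NA_real_,
      control_bod_mgL = if (any(.data$role == "control"))
        mean(.data$bod_mgL[.data$role == "control"]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      difference_mgL = .data$gga_bod_mgL - .data$control_bod_mgL,
      status = dplyr::case_when(
        is.na(.data$difference_mgL) ~ "incomplete",
        abs(.data$difference_mgL - nominal) <= tol ~ "pass",
        TRUE ~ "fail"
      )
    )
  attr(per, "mean_difference") <- mean(per$difference_mgL, na.rm = TRUE)
  attr(per, "sd_difference") <- stats::sd(per$difference_mgL, na.rm = TRUE)
  per
}

#' Estimate the per-biomass Sargassum oxygen demand rate
#'
#' Fits daily oxygen consumption (mg DO d^-1) against fresh Sargassum wet
#' mass (mg) across incubations. The fixed-effect slope is the respiration
#' rate per unit Sargassum biomass (mg DO d^-1 mg Sargassum^-1) and the
#' fixed-effect intercept is the source-water respiration rate
#' (mg DO d^-1). Random slopes and intercepts by incubation absorb
#' between-incubation differences in algal material and source water.
#'
#' Fitting uses restricted maximum likelihood via [lmerTest::lmer()],
#' with the mass covariate internally rescaled to units of 100 mg so the
#' slope and its variance component are well conditioned (estimates are
#' reported on the original mg scale). When the full random-slope model is
#' singular or fails to converge the model is refit with random intercepts
#' only, and failing that by ordinary least squares; the path taken is
#' recorded in `fit_method`. GGA standard
#' bottles are excluded: their added organic demand is not Sargassum and
#' would bias the intercept.
#'
#' @inheritParams bod_rates
#' @param method `"auto"` (fallback ladder, the default), `"lmm"` (error
#'   rather than fall back to OLS), or `"ols"` (pooled least squares).
#' @return An object of class `bod_fit`; see [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' synth <- gen_bod_dataset(seed = 1)
#' fit <- fit_bod(synth$bottles)
#' glance(fit)
#' @export
fit_bod <- function(bottles, method = c("auto", "lmm", "ols")) {
  method <- match.arg(method)
  rates <- bod_rates(bottles)
  dat <- dplyr::filter(rates, .data$role != "gga_standard")
  dat$incubation_id <- factor(dat$incubation_id)
  if (nrow(dat) < 3) abort("Need at least 3 non-GGA bottles to fit.")
  if (length(unique(dat$sargassum_mass_mg)) < 2) {
    abort("All Sargassum masses are identical; the slope is not identifiable.")
  }
  n_inc <- nlevels(dat$incubation_id)

  # fit on a rescaled mass (per 100 mg) so the slope and its variance
  # component are O(1); coefficients are rescaled back afterwards
  dat$mass_100mg <- dat$sargassum_mass_mg / 100

  fit_method <- NULL
  fit <- NULL
  if (method != "ols" && n_inc >= 2) {
    fit <- try_lmer(daily_rate_mg_d ~ mass_100mg +
                      (mass_100mg | incubation_id), dat)
    if (!is.null(fit)) fit_method <- "lmm"
    if (is.null(fit)) {
      fit <- try_lmer(daily_rate_mg_d ~ mass_100mg +
                        (1 | incubation_id), dat)
      if (!is.null(fit)) fit_method <- "lmm_intercept_only"
    }
    if (is.null(fit) && method == "lmm") {
      abort("Mixed-model fit failed to converge and `method = \"lmm\"` forbids the OLS fallback.")
    }
  } else if (method == "lmm") {
    abort("A mixed model needs at least 2 incubations.")
  }
  if (is.null(fit)) {
    if (method != "ols" && n_inc < 2) {
      warn("Single incubation: falling back to ordinary least squares.")
    }
    fit <- lm(daily_rate_mg_d ~ mass_100mg, data = dat)
    fit_method <- "ols_fallback"
  }

  is_mixed <- inherits(fit, "merMod")
  fe <- if (is_mixed) lme4::fixef(fit) else coef(fit)
  # suppressWarnings: summary.lm complains on exactly collinear toy data
  se <- suppressWarnings(sqrt(diag(as.matrix(vcov(fit)))))
  if (is_mixed) {
    # Satterthwaite degrees of freedom for t-based intervals; with a
    # handful of incubations the slope df is far below the bottle count
    df <- tryCatch(suppressWarnings(coef(summary(fit))[, "df"]),
                   error = function(e) rep(nrow(dat) - 2, 2))
  } else {
    df <- rep(stats::df.residual(fit), 2)
  }
  re_sd <- c(intercept = NA_real_, slope = NA_real_)
  if (is_mixed) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    sd_int <- vc$sdcor[vc$grp == "incubation_id" & vc$var1 == "(Intercept)" &
                         is.na(vc$var2)]
    sd_slo <- vc$sdcor[vc$grp == "incubation_id" &
                         vc$var1 == "mass_100mg" & is.na(vc$var2)]
    if (length(sd_int)) re_sd["intercept"] <- sd_int
    if (length(sd_slo)) re_sd["slope"] <- sd_slo
  }

  structure(list(
    slope = unname(fe["mass_100mg"]) / 100,
    slope_se = unname(se["mass_100mg"]) / 100,
    slope_df = unname(df[2]),
    intercept = unname(fe["(Intercept)"]),
    intercept_se = unname(se["(Intercept)"]),
    intercept_df = unname(df[1]),
    random_effect_sd_slope = unname(re_sd["slope"]) / 100,
    random_effect_sd_intercept = unname(re_sd["intercept"]),
    n_bottles = nrow(dat),
    n_incubations = n_inc,
    fit_method = fit_method,
    model = fit,
    data = dat
  ), class = "bod_fit")
}

try_lmer <- function(formula, data) {
  res <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(formula, data = data, REML = TRUE,
                     control = lme4::lmerControl(check.conv.singular =
                       lme4::.makeCC(action = "ignore", tol = 1e-4))),
      error = function(e) NULL
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (is.null(res)) return(NULL)
  conv <- res@optinfo$conv$lme4
  failed <- !is.null(conv$code) && conv$code != 0
  if (failed || lme4::isSingular(res, tol = 1e-4)) return(NULL)
  res
}

#' @export
print.bod_fit <- function(x, ...) {
  cat("Sargassum oxygen-demand fit (", x$fit_method, ")\n", sep = "")
  cat(sprintf("  slope:     %.4f +/- %.4f mg DO d^-1 mg Sargassum^-1\n",
              x$slope, x$slope_se))
  cat(sprintf("  intercept: %.3f +/- %.3f mg DO d^-1 (source water)\n",
              x$intercept, x$intercept_se))
  cat(sprintf("  %d bottles in %d incubations\n", x$n_bottles, x$n_incubations))
  invisible(x)
}

#' Tidy and summarise Sargassum oxygen-demand fits
#'
#' `tidy()` returns one row per fixed effect with estimate, standard error
#' and a t-based 95% confidence interval (Satterthwaite degrees of freedom
#' for mixed fits, residual degrees of freedom otherwise); `glance()` returns
#' a one-row model summary including the random-effect standard
#' deviations and the fitting path taken.
#'
#' @param x A `bod_fit` object from [fit_bod()].
#' @param conf.level Confidence level for the interval.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bod_fit
#' @export
tidy.bod_fit <- function(x, conf.level = 0.95, ...) {
  tcrit <- qt(1 - (1 - conf.level) / 2, df = c(x$intercept_df, x$slope_df))
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se),
    df = c(x$intercept_df, x$slope_df),
    conf.low = .data$estimate - tcrit * .data$std.error,
    conf.high = .data$estimate + tcrit * .data$std.error
  )
}

#' @rdname tidy.bod_fit
#' @method glance bod_fit
#' @export
glance.bod_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, slope_se = x$slope_se,
    intercept = x$intercept, intercept_se = x$intercept_se,
    random_effect_sd_slope = x$random_effect_sd_slope,
    random_effect_sd_intercept = x$random_effect_sd_intercept,
    n_bottles = x$n_bottles, n_incubations = x$n_incubations,
    fit_method = x$fit_method
  )
}

#' @rdname tidy.bod_fit
#' @param object A `bod_fit` object.
#' @method autoplot bod_fit
#' @export
autoplot.bod_fit <- function(object, ...) {
  dat <- object$data
  line <- tibble::tibble(
    sargassum_mass_mg = seq(0, max(dat$sargassum_mass_mg), length.out = 50)
  )
  line$fit <- object$intercept + object$slope * line$sargassum_mass_mg
  z <- stats::qnorm(0.975)
  line$lo <- object$intercept - z * object$intercept_se +
    (object$slope - z * object$slope_se) * line$sargassum_mass_mg
  line$hi <- object$intercept + z * object$intercept_se +
    (object$slope + z * object$slope_se) * line$sargassum_mass_mg
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sargassum_mass_mg,
                                    y = .data$daily_rate_mg_d)) +
    ggplot2::geom_ribbon(data = line,
                         ggplot2::aes(y = .data$fit, ymin = .data$lo,
                                      ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(data = line, ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$incubation_id)) +
    ggplot2::labs(x = "Fresh Sargassum (mg)",
                  y = expression(Delta * "DO (mg "  * d^-1 * ")"),
                  colour = "Incubation") +
    ggplot2::theme_minimal()
}

#' Read and write bottle-record CSVs and fit summaries
#'
#' `read_bottles()` expects the header
#' `incubation_id,role,sargassum_mass_mg,do_initial_mgL,do_final_mgL,volume_L,duration_d`.
#' `write_bottles()` writes the same layout. `write_bod_fit()` serialises a
#' fit summary (the [glance()] row) as JSON.
#'
#' @param path File path.
#' @return `read_bottles()` returns a validated tibble of bottle records.
#' @export
read_bottles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_bottles(df)
}

#' @rdname read_bottles
#' @param bottles A bottle-record data frame.
#' @export
write_bottles <- function(bottles, path) {
  readr::write_csv(check_bottles(bottles), path)
  invisible(bottles)
}

#' @rdname read_bottles
#' @param fit A `bod_fit` object.
#' @export
write_bod_fit <- function(fit, path) {
  stopifnot(inherits(fit, "bod_fit"))
  jsonlite::write_json(as.list(glance(fit)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}

check_bottles <- function(bottles) {
  needed <- c("incubation_id", "role", "sargassum_mass_mg",
              "do_initial_mgL", "do_final_mgL")
  if (!is.data.frame(bottles) || !all(needed %in% names(bottles))) {
    abort(paste0("Bottle records need columns: ",
                 paste(needed, collapse = ", "),
                 " (plus optional volume_L, duration_d)."))
  }
  bottles <- tibble::as_tibble(bottles)
  if (!"volume_L" %in% names(bottles)) bottles$volume_L <- 0.3
  if (!"duration_d" %in% names(bottles)) bottles$duration_d <- 5
  bad_role <- setdiff(unique(bottles$role),
                      c("control", "gga_standard", "sargassum"))
  if (length(bad_role)) {
    abort(sprintf("Unknown bottle role(s): %s.", paste(bad_role, collapse = ", ")))
  }
  if (any(bottles$sargassum_mass_mg < 0)) abort("`sargassum_mass_mg` must be >= 0.")
  if (any(bottles$volume_L <= 0)) abort("`volume_L` must be positive.")
  if (any(bottles$duration_d <= 0)) abort("`duration_d` must be positive.")
  if (any(bottles$sargassum_mass_mg > 111.1)) {
    warn("Sargassum mass above 111.1 mg: outside the aerobic incubation domain the rate model was calibrated on.")
  }
  bottles
}
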