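# Characterization stages: away-along (energy-dependence) comparison
# against the reference table, angular-dependence summaries, and the
# linear temperature model with its correction factor.

#' Compare a normalized measured grid to the reference table
#'
#' Per-node percent difference 100 × (measured − reference)/reference,
#' summarized as mean ± SD of the |percent| values (signed values are
#' kept per point for plotting). Also reports the transverse-plane
#' (z = 0) radial-profile subset and, per away distance, the maximum
#' |percent| over the z profile.
#'
#' @param grid Normalized grid from [normalize_to_reference()] (`$grid`,
#'   or any data frame with `y`, `z`, `dose_rate`).
#' @param reference An [away_along_table()].
#' @param exclude_anchor Optional `c(y0, z0)` node excluded from the
#'   summary statistics (the normalization anchor matches the reference
#'   by construction); it stays in `per_point`.
#' @return List of class `comparison_stats`: `mean_pct`, `sd_pct`,
#'   `max_abs_pct` (over |pct|), `mean_signed_pct`, `per_point`
#'   (data frame `y`, `z`, `pct`), `radial_z0` (same stats restricted to
#'   z = 0) and `z_profile_max` (per-away maxima of |pct|).
#' @export
away_along_comparison <- function(grid, reference, exclude_anchor = NULL) {
  if (is.list(grid) && !is.data.frame(grid) && !is.null(grid$grid))
    grid <- grid$grid
  stopifnot(inherits(reference, "away_along_table"),
            all(c("y", "z", "dose_rate") %in% names(grid)))
  if (!nrow(grid))
    stop("away_along_comparison: empty grid", call. = FALSE)
  ref <- vapply(seq_len(nrow(grid)), function(i)
    dose_rate_at(reference, grid$y[i], grid$z[i], sk = 1), numeric(1))
  pct <- 100 * (grid$dose_rate - ref) / ref
  per_point <- data.frame(y = grid$y, z = grid$z, pct = pct)
  keep <- rep(TRUE, nrow(per_point))
  if (!is.null(exclude_anchor))
    keep <- !(abs(per_point$y - exclude_anchor[1]) < 1e-9 &
              abs(per_point$z - exclude_anchor[2]) < 1e-9)
  if (!any(keep))
    stop("away_along_comparison: no nodes left after anchor exclusion",
         call. = FALSE)
  stat <- function(p) list(
    mean_pct = mean(abs(p)), sd_pct = stats::sd(abs(p)),
    max_abs_pct = max(abs(p)), mean_signed_pct = mean(p))
  s <- stat(per_point$pct[keep])
  z0 <- keep & abs(per_point$z) < 1e-9
  radial_z0 <- if (any(z0)) stat(per_point$pct[z0]) else NULL
  zmax <- stats::aggregate(abs(pct) ~ y, data = per_point[keep, ],
                           FUN = max)
  names(zmax) <- c("y", "max_abs_pct")
  structure(c(s, list(per_point = per_point, radial_z0 = radial_z0,
                      z_profile_max = zmax)),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("<comparison_stats> |pct|: (%.2f +/- %.2f)%% (k=1), max %.2f%%\n",
              x$mean_pct, x$sd_pct, x$max_abs_pct))
  if (!is.null(x$radial_z0))
    cat(sprintf("  z=0 radial profile: (%.2f +/- %.2f)%%\n",
                x$radial_z0$mean_pct, x$radial_z0$sd_pct))
  invisible(x)
}

#' Angular-dependence summary
#'
#' Percent deviation of each angle's stem-corrected net rate from the
#' sweep mean response (no angle is singled out as reference), then the
#' mean ± SD over the |percent| values.
#'
#' @param angles Angles in degrees, strictly increasing within [0, 360).
#' @param net_rates Stem-corrected net rates, one per angle, or a
#'   `corrected_signals` frame with `angle`/`net_rate` in place of both
#'   arguments.
#' @return `comparison_stats` list with `per_point` columns `angle`,
#'   `pct`.
#' @export
angular_summary <- function(angles, net_rates = NULL) {
  if (is.null(net_rates) && is.data.frame(angles)) {
    net_rates <- angles$net_rate
    angles <- angles$angle
  }
  stopifnot(length(angles) == length(net_rates), length(angles) >= 2)
  if (any(diff(angles) <= 0) || any(angles < 0) || any(angles >= 360))
    stop("angular_summary: angles must be strictly increasing in [0, 360)",
         call. = FALSE)
  m <- mean(net_rates)
  pct <- 100 * (net_rates - m) / m
  structure(list(
    mean_pct = mean(abs(pct)), sd_pct = stats::sd(abs(pct)),
    max_abs_pct = max(abs(pct)), mean_signed_pct = mean(pct),
    per_point = data.frame(angle = angles, pct = pct)),
    class = "comparison_stats")
}

#' Linear temperature response model
#'
#' S(T)/S(T0) = 1 + a·(T − T0): the PSD signal varies linearly with the
#' water temperature, with relative slope `a` (1/°C) about the reference
#' temperature T0 (25 °C, the usual room temperature).
#'
#' @param a Relative slope in 1/°C; |a| < 0.05 as a sanity bound.
#' @param t0 Reference temperature (°C).
#' @param s0 Signal at `t0` (count rate), > 0.
#' @param u_a Standard uncertainty of `a` (1/°C, k = 1).
#' @return An object of class `temperature_model`.
#' @export
temperature_model <- function(a, t0 = 25, s0 = 1, u_a = 0) {
  stopifnot(is.numeric(a), abs(a) < 0.05, s0 > 0, u_a >= 0)
  structure(list(a = a, t0 = t0, s0 = s0, u_a = u_a,
                 t_range = c(NA_real_, NA_real_)),
            class = "temperature_model")
}

#' @export
print.temperature_model <- function(x, ...) {
  cat(sprintf(
    "<temperature_model> a = %.5f 1/degC (u = %.5f, k=1), S0 = %.4g at %.1f degC\n",
    x$a, x$u_a, x$s0, x$t0))
  invisible(x)
}

#' Fit the linear temperature model
#'
#' Unweighted ordinary least squares of signal vs temperature,
#' reparameterized to (S0 at T0, a = slope/S0). The slope uncertainty
#' combines the OLS standard error with the temperature Type B
#' contribution (each set's temperature uncertainty propagated through
#' the design) in quadrature. Weighted least squares is available via
#' `weights`.
#'
#' @param temps Set temperatures (°C); each the mean of the initial and
#'   final readings of the two sensors.
#' @param signals Signal (count rate) per acquisition, same length.
#' @param t0 Reference temperature (°C), default 25.
#' @param u_temp Per-set temperature standard uncertainties (°C, k = 1,
#'   recycled), e.g. from [uniform_interval_u()]; default 0.
#' @param weights Optional OLS weights (default unweighted).
#' @return A [temperature_model()] with `t_range` set to the fitted
#'   temperature range.
#' @export
fit_temperature_model <- function(temps, signals, t0 = 25, u_temp = 0,
                                  weights = NULL) {
  stopifnot(length(temps) == length(signals))
  if (length(unique(temps)) < 3L)
    stop("fit_temperature_model: need >= 3 distinct temperatures",
         call. = FALSE)
  if (stats::sd(temps) == 0)
    stop("fit_temperature_model: no temperature spread", call. = FALSE)
  fit <- stats::lm(signals ~ temps, weights = weights)
  b <- stats::coef(fit)
  s0 <- unname(b[1] + b[2] * t0)
  if (s0 <= 0)
    stop("fit_temperature_model: non-positive fitted signal at t0",
         call. = FALSE)
  a <- unname(b[2]) / s0
  # noiseless (synthetic) data triggers summary.lm's perfect-fit warning;
  # the SE it returns (~0) is exactly what we want there
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  se_slope <- sm$coefficients["temps", "Std. Error"]
  # temperature (Type B) contribution: an error u_T on every abscissa
  # maps to a slope error ~ |slope| * u_T / sqrt(S_xx / n)
  u_temp <- rep_len(u_temp, length(temps))
  sxx <- sum((temps - mean(temps))^2)
  u_slope_temp <- abs(b[2]) * sqrt(mean(u_temp^2)) *
    sqrt(length(temps) / sxx)
  u_a <- sqrt((se_slope / s0)^2 + (u_slope_temp / s0)^2)
  mod <- temperature_model(a = a, t0 = t0, s0 = s0, u_a = unname(u_a))
  mod$t_range <- range(temps)
  mod
}

#' Relative response at a temperature
#'
#' S(T)/S(T0) = 1 + a·(T − t0) under the fitted model.
#'
#' @param model A [temperature_model()].
#' @param t_meas Temperature (°C).
#' @return Dimensionless relative response.
#' @export
relative_response <- function(model, t_meas) {
  stopifnot(inherits(model, "temperature_model"))
  1 + model$a * (t_meas - model$t0)
}

#' Temperature correction factor
#'
#' Multiplying a signal measured at `t_meas` by this factor restores the
#' T0-equivalent response: factor = 1 / (1 + a·(t_meas − t0)). Warns when
#' `t_meas` falls more than 5 °C outside the fitted range.
#'
#' @param model A [temperature_model()].
#' @param t_meas Measurement temperature (°C).
#' @return Correction factor (dimensionless, > 0).
#' @export
temperature_correction <- function(model, t_meas) {
  resp <- relative_response(model, t_meas)
  if (resp <= 0)
    stop("temperature_correction: model response non-positive at t_meas",
         call. = FALSE)
  tr <- model$t_range
  if (!any(is.na(tr)) && (t_meas < tr[1] - 5 || t_meas > tr[2] + 5))
    warning(sprintf(
      "temperature_correction: %.1f degC is outside the fitted range [%.1f, %.1f] +/- 5 degC",
      t_meas, tr[1], tr[2]))
  1 / resp
}
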