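# GUM-style uncertainty engine: Type A repeatability, the uniform-interval
# rule for before/after temperature readings, quadrature combination, and
# coverage-factor expansion.

#' Type A relative uncertainty of repeated measurements
#'
#' 100 × sample SD / mean of a set of repeats (k = 1). By convention the
#' SD of the set is reported, not the SD of the mean; set
#' `of_mean = TRUE` for the latter.
#'
#' @param values Numeric vector of at least 3 repeated measurements.
#' @param of_mean Report SD of the mean (SD/√n) instead of the set SD.
#' @return Relative uncertainty in percent (k = 1).
#' @export
type_a <- function(values, of_mean = FALSE) {
  stopifnot(is.numeric(values))
  if (length(values) < 3L)
    stop("type_a: need at least 3 repeated measurements", call. = FALSE)
  m <- mean(values)
  if (m == 0)
    stop("type_a: mean of measurements is zero", call. = FALSE)
  s <- stats::sd(values)
  if (of_mean) s <- s / sqrt(length(values))
  100 * s / abs(m)
}

#' Temperature reading pair (before/after irradiation)
#'
#' @param t_initial,t_final Water temperature (°C) immediately before and
#'   after a set of irradiations (each the average of the two sensors).
#' @param u_cal Thermometer calibration standard uncertainty (°C, k = 1).
#' @return An object of class `temperature_reading`.
#' @export
temperature_reading <- function(t_initial, t_final, u_cal = 0.045) {
  stopifnot(is.finite(t_initial), is.finite(t_final),
            is.numeric(u_cal), u_cal >= 0)
  structure(list(t_initial = t_initial, t_final = t_final, u_cal = u_cal),
            class = "temperature_reading")
}

#' Standard uncertainty of a before/after temperature pair
#'
#' The temperature is only known to lie between the initial and final
#' readings; assuming a uniform density over that interval, its standard
#' uncertainty is the interval amplitude divided by √12, combined in
#' quadrature with the thermometer calibration uncertainty.
#'
#' @param r A [temperature_reading()].
#' @return Standard uncertainty in °C (k = 1).
#' @export
uniform_interval_u <- function(r) {
  stopifnot(inherits(r, "temperature_reading"))
  u_unif <- abs(r$t_initial - r$t_final) / sqrt(12)
  sqrt(u_unif^2 + r$u_cal^2)
}

#' Quadrature combination of uncertainty components
#'
#' √(Σ uᵢ²) over non-negative components (any common unit, typically
#' relative percent at k = 1).
#'
#' @param components Numeric vector of components, all >= 0.
#' @return Combined uncertainty, same unit as the inputs.
#' @export
combine_quadrature <- function(components) {
  stopifnot(is.numeric(components), all(components >= 0))
  sqrt(sum(components^2))
}

#' Expanded uncertainty
#'
#' @param u Standard uncertainty (any unit, k = 1).
#' @param k Coverage factor, > 0.
#' @return k × u.
#' @export
expand_uncertainty <- function(u, k = 2) {
  stopifnot(is.numeric(u), is.numeric(k), k > 0)
  k * u
}

#' Signal uncertainty induced by temperature uncertainty
#'
#' Propagates a temperature uncertainty through the linear temperature
#' response: u_signal = |a| × u_T × 100 (percent), with a the fitted
#' relative slope in 1/°C.
#'
#' @param u_temp Temperature uncertainty in °C (at whatever coverage the
#'   caller intends; the result carries the same coverage).
#' @param model A [temperature_model()].
#' @return Relative signal uncertainty in percent.
#' @export
temperature_signal_uncertainty <- function(u_temp, model) {
  stopifnot(inherits(model, "temperature_model"),
            is.numeric(u_temp), u_temp >= 0)
  abs(model$a) * u_temp * 100
}

#' Uncertainty budget
#'
#' A named set of Type A / Type B relative components (percent, k = 1)
#' whose combined value is recomputed by quadrature on construction and
#' on every [print()]; never stored stale.
#'
#' @param components `data.frame` with columns `name`, `kind` ("A"/"B")
#'   and `value` (percent, >= 0), or a list of such records.
#' @return An object of class `uncertainty_budget` with a `combined`
#'   element (percent, k = 1, full precision).
#' @export
uncertainty_budget <- function(components) {
  if (!is.data.frame(components))
    components <- do.call(rbind, lapply(components, function(cc)
      data.frame(name = cc$name, kind = cc$kind, value = cc$value)))
  stopifnot(all(c("name", "kind", "value") %in% names(components)))
  if (!all(components$kind %in% c("A", "B")))
    stop("uncertainty_budget: kind must be 'A' or 'B'", call. = FALSE)
  if (any(components$value < 0))
    stop("uncertainty_budget: components must be >= 0", call. = FALSE)
  structure(list(components = components,
                 combined = combine_quadrature(components$value)),
            class = "uncertainty_budget")
}

#' Read an uncertainty-budget fixture
#'
#' @param path JSON file with a `components` array of
#'   `{name, kind, value}` records (percent, k = 1).
#' @return An [uncertainty_budget()].
#' @export
load_budget <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  uncertainty_budget(raw$components)
}

#' Round half-up to a number of decimals
#'
#' Display rounding for budget tables: 1.95 renders as 2.0, not the
#' banker's 1.9 that [round()] would give. Internal values stay at full
#' precision; this is presentation only.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  df <- x$components
  cat("<uncertainty_budget> (relative %, k = 1)\n")
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-40s Type %s  %4.1f\n", df$name[i], df$kind[i],
                df$value[i]))
  cat(sprintf("  %-40s         %4.1f\n", "Total combined",
              round_half_up(x$combined, 1)))
  invisible(x)
}

#' Render a budget as a data frame for CSV/Markdown export
#'
#' @param budget An [uncertainty_budget()].
#' @param digits Display decimals (half-up).
#' @return `data.frame` of components plus a total row.
#' @export
render_budget <- function(budget, digits = 1) {
  stopifnot(inherits(budget, "uncertainty_budget"))
  df <- budget$components
  out <- data.frame(
    name = c(df$name, "Total combined uncertainty"),
    kind = c(df$kind, ""),
    value_pct = round_half_up(c(df$value, budget$combined), digits))
  out
}
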