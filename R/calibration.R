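#' TRS-398 constants for the reference Co-60 quality
#'
#' Holds the chamber-specific constants the calibration chain needs:
#' the product [s_w,air · p]_Q0 for Co-60 (1.112 for the PMMA Farmer
#' chamber, taken directly from IAEA TRS-398 rather than simulated) and
#' the Co-60 absorbed-dose-to-water calibration factor N_D,w.
#'
#' @param sw_air_p_co60 Dimensionless stopping-power-ratio × perturbation
#'   product at Co-60; must exceed 1.
#' @param nd_w_co60 N_D,w,Co-60 in Gy per electrometer reading unit.
#' @return An object of class `trs398_constants`.
#' @export
trs398_constants <- function(sw_air_p_co60 = 1.112, nd_w_co60 = NA_real_) {
  stopifnot(is.numeric(sw_air_p_co60), sw_air_p_co60 > 1)
  stopifnot(is.numeric(nd_w_co60))
  if (!is.na(nd_w_co60)) stopifnot(nd_w_co60 > 0)
  structure(list(sw_air_p_co60 = sw_air_p_co60, nd_w_co60 = nd_w_co60),
            class = "trs398_constants")
}

#' Ionization chamber reading with influence-quantity corrections
#'
#' @param m_raw Raw electrometer reading (nC).
#' @param temperature Air temperature in the chamber cavity (°C).
#' @param pressure Ambient pressure (kPa), > 0.
#' @param ks Ion-recombination correction, within (0.9, 1.1).
#' @param kpol Polarity correction, within (0.9, 1.1).
#' @return An object of class `chamber_reading`.
#' @export
chamber_reading <- function(m_raw, temperature, pressure,
                            ks = 1, kpol = 1) {
  stopifnot(is.numeric(m_raw), is.numeric(temperature),
            is.numeric(pressure), pressure > 0)
  for (k in c(ks = ks, kpol = kpol))
    if (k <= 0.9 || k >= 1.1)
      stop("chamber_reading: correction factors must lie in (0.9, 1.1)",
           call. = FALSE)
  structure(list(m_raw = m_raw, temperature = temperature,
                 pressure = pressure, ks = ks, kpol = kpol),
            class = "chamber_reading")
}

#' Beam-quality conversion factor from dose ratios
#'
#' k_Q,Q0 = (D_w / D̄_air)_Q / (D_w / D̄_air)_Q0 — the ratio of
#' water-to-cavity-air dose ratios in the user quality Q and the
#' calibration quality Q0, following the Bragg–Gray reduction of the
#' TRS-398 quality-factor chain.
#'
#' @param dw_over_dair_q Ratio (D_w / D̄_air) at quality Q, > 0.
#' @param dw_over_dair_q0 Same ratio at the calibration quality Q0, > 0.
#' @return k_Q,Q0 (dimensionless).
#' @export
quality_factor <- function(dw_over_dair_q, dw_over_dair_q0) {
  if (!is.numeric(dw_over_dair_q) || dw_over_dair_q <= 0 ||
      !is.numeric(dw_over_dair_q0) || dw_over_dair_q0 <= 0)
    stop("quality_factor: ratios must be positive", call. = FALSE)
  dw_over_dair_q / dw_over_dair_q0
}

#' Full-scatter conversion factor F
#'
#' Converts ionization measured in the compact PMMA phantom directly to
#' absorbed dose to water in the full-scatter TG-43 reference geometry:
#' F = (D_w^full scatter / D̄_air^PMMA phantom)_Ir-192 / [s_w,air · p]_Co-60.
#' The denominator is the TRS-398 constant (not simulated) stored in
#' [trs398_constants()].
#'
#' @param dw_full_over_dair_pmma_ir192 Monte Carlo ratio of dose to water
#'   in full scatter to mean cavity-air dose in the PMMA phantom, for
#'   Ir-192; > 0.
#' @param constants A [trs398_constants()].
#' @return F (dimensionless).
#' @export
full_scatter_factor <- function(dw_full_over_dair_pmma_ir192,
                                constants = trs398_constants()) {
  stopifnot(inherits(constants, "trs398_constants"))
  if (!is.numeric(dw_full_over_dair_pmma_ir192) ||
      dw_full_over_dair_pmma_ir192 <= 0)
    stop("full_scatter_factor: ratio must be positive", call. = FALSE)
  dw_full_over_dair_pmma_ir192 / constants$sw_air_p_co60
}

#' Temperature/pressure-corrected chamber reading
#'
#' M = m_raw × ks × kpol × (273.15 + T)/(273.15 + T_ref) × P_ref / P.
#' Reference conditions default to 20 °C and 101.325 kPa.
#'
#' @param rdg A [chamber_reading()].
#' @param ref_temperature Reference temperature (°C).
#' @param ref_pressure Reference pressure (kPa).
#' @return Corrected reading M (nC).
#' @export
correct_reading <- function(rdg, ref_temperature = 20,
                            ref_pressure = 101.325) {
  stopifnot(inherits(rdg, "chamber_reading"))
  ktp <- (273.15 + rdg$temperature) / (273.15 + ref_temperature) *
    ref_pressure / rdg$pressure
  rdg$m_raw * rdg$ks * rdg$kpol * ktp
}

#' Absorbed dose to water in full-scatter geometry
#'
#' D_w^full scatter = N_D,w,Co-60 × M × F. With F = 1 this reduces to the
#' plain TRS-398 Co-60 dose equation.
#'
#' @param nd_w N_D,w,Co-60 in Gy/nC.
#' @param m Corrected chamber reading (nC), >= 0.
#' @param f Full-scatter factor F from [full_scatter_factor()].
#' @return Dose in Gy.
#' @export
dose_to_water_full_scatter <- function(nd_w, m, f) {
  stopifnot(is.numeric(nd_w), nd_w > 0, is.numeric(m), m >= 0,
            is.numeric(f), f > 0)
  nd_w * m * f
}

#' Water-equivalence gap of polystyrene
#'
#' Percent disagreement between the full-scatter/mini-phantom dose ratio
#' computed in water and in polystyrene:
#' 100 × |(D_w ratio)/(D_pol ratio) − 1|. Quantifies how far "polystyrene
#' is water equivalent" holds in the Ir-192 spectrum at the calibration
#' distance.
#'
#' @param dw_full_over_dw_pmma Water dose ratio (full scatter / PMMA
#'   phantom), > 0.
#' @param dpol_full_over_dpol_pmma Polystyrene dose ratio, > 0.
#' @return Percent gap (>= 0).
#' @export
water_equivalence_gap <- function(dw_full_over_dw_pmma,
                                  dpol_full_over_dpol_pmma) {
  stopifnot(dw_full_over_dw_pmma > 0, dpol_full_over_dpol_pmma > 0)
  100 * abs(dw_full_over_dw_pmma / dpol_full_over_dpol_pmma - 1)
}

#' Load the Monte Carlo dose-ratio fixture
#'
#' Reads the versioned JSON fixture of full-scatter/mini-phantom dose
#' ratios (with their k=1 relative uncertainties) shipped with the
#' package: water, polystyrene and cavity-air ratios, experimental
#' validation ratios, and the back-derived absolute ratio
#' (D_w^full / D̄_air^PMMA)_Ir-192 that the F computation needs (flagged
#' `derived` in the file since only F itself is a primary quantity).
#'
#' @param path Path to a ratio JSON file; defaults to the bundled fixture.
#' @return A named list of entries, each `list(value, u_rel, ...)`.
#' @export
load_mc_ratios <- function(path = system.file("extdata", "mc_ratios.json",
                                              package = "psdcal")) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- vapply(out$ratios, function(r) r$value, numeric(1))
  if (any(vals <= 0))
    stop("mc ratio fixture: non-positive ratio", call. = FALSE)
  out
}

#' Run the full calibration chain
#'
#' From the Monte Carlo ratio fixture, TRS-398 constants and (optionally)
#' a chamber reading: computes F, the quality-style factor
#' k_Ir-192^PMMA phantom, the polystyrene water-equivalence gap, the
#' combined relative uncertainty of F (MC ratio and TRS-398 constant
#' components in quadrature), and — when a reading and N_D,w are given —
#' the absorbed dose to water in full scatter.
#'
#' @param ratios Fixture list from [load_mc_ratios()].
#' @param constants A [trs398_constants()].
#' @param reading Optional [chamber_reading()].
#' @param ref_temperature,ref_pressure Reference conditions for the
#'   reading correction.
#' @return A list of class `calibration_result` with elements `f_factor`,
#'   `k_ir192_pmma`, `u_rel`, `water_equiv_gap_pct` and, when computable,
#'   `m_corrected` and `dw_full_scatter`.
#' @export
calibrate <- function(ratios, constants = trs398_constants(),
                      reading = NULL, ref_temperature = 20,
                      ref_pressure = 101.325) {
  rr <- ratios$ratios
  f <- full_scatter_factor(rr$dw_full_over_dair_pmma_ir192$value, constants)
  k <- quality_factor(rr$dw_full_over_dair_pmma_ir192$value,
                      constants$sw_air_p_co60)
  u_f <- combine_quadrature(c(
    rr$dw_full_over_dair_pmma_ir192$u_rel_pct,
    ratios$sw_air_p_u_rel_pct %||% 0))
  gap <- water_equivalence_gap(rr$dw_full_over_dw_pmma$value,
                               rr$dpol_full_over_dpol_pmma$value)
  res <- list(f_factor = f, k_ir192_pmma = k, u_rel = u_f,
              water_equiv_gap_pct = gap)
  if (!is.null(reading) && !is.na(constants$nd_w_co60)) {
    m <- correct_reading(reading, ref_temperature, ref_pressure)
    res$m_corrected <- m
    res$dw_full_scatter <-
      dose_to_water_full_scatter(constants$nd_w_co60, m, f)
  }
  structure(res, class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> F = %.4g +/- %.2g%% (k=1)\n",
              x$f_factor, x$u_rel))
  cat(sprintf("  k_Ir-192^PMMA = %.4g; polystyrene gap %.2f%%\n",
              x$k_ir192_pmma, x$water_equiv_gap_pct))
  if (!is.null(x$dw_full_scatter))
    cat(sprintf("  D_w (full scatter) = %.4g Gy (M = %.4g nC)\n",
                x$dw_full_scatter, x$m_corrected))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
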