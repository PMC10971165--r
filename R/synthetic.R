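# Seeded synthetic-data generator. Emulates what the physical set-ups
# produce — PSD and dummy-probe count-rate sessions over away-along
# grids, angular sweeps and temperature series, plus a toy reference
# table — with *known, injected* dependences so that every pipeline
# stage can be validated by round trip. It does not model scintillation
# physics, optical transport or Monte Carlo radiation transport.

#' Generator configuration
#'
#' @param seed Integer seed; every simulate_* call is deterministic
#'   given the config (seeds are explicit, never global state).
#' @param sensitivity Detector sensitivity in counts per 100 ms per
#'   (cGy·h⁻¹), > 0. The default puts count rates at O(10³) per 100 ms
#'   at clinical measurement distances from an HDR source.
#' @param temp_slope Injected relative temperature slope a (1/°C).
#' @param stem_coefficient Amplitude of the additive stem term, counts
#'   per 100 ms × cm (scales an inverse-square-weighted irradiated-fiber
#'   integral with units 1/cm).
#' @param fiber_length_cm Irradiated fiber length entering the stem
#'   proxy (cm).
#' @param energy_profile Function of radial distance r (cm) returning a
#'   multiplicative detector response perturbation; default identically 1.
#' @param angular_profile Function of angle (degrees) returning a
#'   multiplicative perturbation; default identically 1.
#' @param noise_model One of "poisson" (counting statistics on total
#'   counts), "gaussian" (relative sd `gaussian_sd_pct`), "none".
#' @param gaussian_sd_pct Relative Gaussian noise in percent.
#' @param temp_drift_c Maximum before/after water-temperature drift per
#'   irradiation set (°C), exercised by the uniform-interval rule.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             sensitivity = 1.0,
                             temp_slope = -0.0019,
                             stem_coefficient = 200,
                             fiber_length_cm = 20,
                             energy_profile = function(r) rep(1, length(r)),
                             angular_profile = function(a) rep(1, length(a)),
                             noise_model = c("poisson", "gaussian", "none"),
                             gaussian_sd_pct = 0.3,
                             temp_drift_c = 0.3) {
  stopifnot(sensitivity > 0, stem_coefficient >= 0, fiber_length_cm >= 0,
            is.function(energy_profile), is.function(angular_profile),
            gaussian_sd_pct >= 0, temp_drift_c >= 0)
  noise_model <- match.arg(noise_model)
  structure(list(seed = as.integer(seed), sensitivity = sensitivity,
                 temp_slope = temp_slope,
                 stem_coefficient = stem_coefficient,
                 fiber_length_cm = fiber_length_cm,
                 energy_profile = energy_profile,
                 angular_profile = angular_profile,
                 noise_model = noise_model,
                 gaussian_sd_pct = gaussian_sd_pct,
                 temp_drift_c = temp_drift_c),
            class = "generator_config")
}

# Evaluate code under a local seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Counting noise on a clean rate (counts per 100 ms) over duration_s.
apply_noise <- function(rate, duration_s, cfg) {
  nw <- duration_s * 10
  switch(cfg$noise_model,
    none = rate,
    poisson = stats::rpois(length(rate), rate * nw) / nw,
    gaussian = rate * (1 + stats::rnorm(length(rate), 0,
                                        cfg$gaussian_sd_pct / 100)))
}

# Inverse-square-weighted irradiated-fiber integral: the fiber occupies
# the probe axis from the detector (h = 0) to h = Lf; the source sits at
# perpendicular distance y and axial offset z from the detector.
# Integral of dh / (y^2 + (z - h)^2) in closed form; units 1/cm.
stem_proxy_away_along <- function(y, z, Lf) {
  (atan((Lf - z) / y) + atan(z / y)) / y
}

# Same proxy for the azimuthal plane: fiber from the detector outward
# along the 0-degree direction, source at radius R and angle phi.
stem_proxy_azimuthal <- function(phi_deg, R, Lf) {
  phi <- phi_deg * pi / 180
  s <- sin(phi); cphi <- R * cos(phi)
  ifelse(abs(s) < 1e-12,
         if (cos(phi) > 0) {
           # source on the fiber axis: guard (not reached for 30..330 sweeps)
           1 / abs(R - Lf) - 1 / R
         } else 1 / R - 1 / (R + Lf),
         (atan((Lf - cphi) / (R * abs(s))) + atan(cphi / (R * abs(s)))) /
           (R * abs(s)))
}

#' Toy away-along reference table
#'
#' Builds a deterministic stand-in for a consensus away-along table from
#' a line-source geometry function times an exponential attenuation
#' factor, normalized to `lambda` at (r = 1 cm, θ = 90°):
#' value(y, z) = lambda × G_L(r, θ)/G_L(1, 90°) × exp(−mu (r − 1)).
#' With a point source (`active_length` 0) and `mu = 0` the field is
#' exactly proportional to 1/r². This is a synthetic table: it mimics
#' the inverse-square structure and magnitude of published consensus
#' data but is not transcribed from any of them.
#'
#' @param source A [source_state()] (supplies the active length).
#' @param away Away distances y in cm (default 1–6 cm).
#' @param along Along distances z in cm (default −7…7 cm).
#' @param lambda Dose-rate constant analogue, cGy·h⁻¹·U⁻¹ at 1 cm.
#' @param mu Effective attenuation coefficient (1/cm).
#' @return An [away_along_table()].
#' @export
make_toy_away_along <- function(source, away = seq(1, 6, by = 0.5),
                                along = seq(-7, 7, by = 1),
                                lambda = 1.109, mu = 0.006) {
  stopifnot(inherits(source, "source_state"), lambda > 0, mu >= 0)
  L <- source$active_length
  g0 <- geometry_function_line(1, 90, L)
  vals <- outer(along, away, function(z, y) {
    r <- sqrt(y^2 + z^2)
    theta <- atan2(y, z) * 180 / pi
    g <- vapply(seq_along(r), function(i)
      geometry_function_line(r[i], theta[i], L), numeric(1))
    lambda * g / g0 * exp(-mu * (r - 1))
  })
  away_along_table(away, along, vals)
}

#' Simulate a paired away-along measurement session
#'
#' PSD rate = sensitivity × dose rate × energy_profile(r) + stem;
#' dummy rate = stem alone; noise per the config's noise model. The stem
#' term is the inverse-square-weighted irradiated-fiber integral, so it
#' grows as the source approaches the probe axis.
#'
#' @param cfg A [generator_config()].
#' @param table Reference [away_along_table()] the detector "sees".
#' @param grid Data frame of measurement nodes `y`, `z` (cm).
#' @param source A [source_state()] (supplies Sk and the session decay).
#' @param duration_s Acquisition duration per point (s).
#' @param start_time First acquisition timestamp.
#' @param spacing_s Time between consecutive acquisitions (s).
#' @return List with `psd` and `dummy` [measurement_session()]s.
#' @export
simulate_away_along_session <- function(cfg, table, grid, source,
                                        duration_s = 10,
                                        start_time = as.POSIXct(
                                          "2024-03-01 09:00:00", tz = "UTC"),
                                        spacing_s = 60) {
  stopifnot(inherits(cfg, "generator_config"),
            inherits(table, "away_along_table"),
            all(c("y", "z") %in% names(grid)),
            inherits(source, "source_state"))
  n <- nrow(grid)
  times <- start_time + spacing_s * (seq_len(n) - 1L)
  r <- sqrt(grid$y^2 + grid$z^2)
  with_seed(cfg$seed, {
    rate_psd <- rate_dummy <- numeric(n)
    for (i in seq_len(n)) {
      sk <- rakr_to_sk(decay_correct(source, times[i]))
      dose <- dose_rate_at(table, grid$y[i], grid$z[i], sk = sk)
      stem <- cfg$stem_coefficient *
        stem_proxy_away_along(grid$y[i], grid$z[i], cfg$fiber_length_cm)
      rate_psd[i] <- cfg$sensitivity * dose * cfg$energy_profile(r[i]) + stem
      rate_dummy[i] <- stem
    }
    rate_psd <- apply_noise(rate_psd, duration_s, cfg)
    rate_dummy <- apply_noise(rate_dummy, duration_s, cfg)
    mk <- function(rate, kind) measurement_session(data.frame(
      counts_per_100ms = rate, duration_s = duration_s,
      timestamp = times, y = grid$y, z = grid$z, probe_kind = kind))
    list(psd = mk(rate_psd, "psd"), dummy = mk(rate_dummy, "dummy"))
  })
}

#' Simulate a paired angular-sweep session
#'
#' Source steps around the detector at fixed radius, 30°–330° in 20°
#' steps by default. In the azimuthal plane the stem term peaks toward
#' the fiber-axis angles (near 0°/360°); in the axial plane the fiber is
#' perpendicular to the sweep plane and the stem is constant. The clean
#' detector response is inverse-square at the sweep radius times the
#' injected angular profile.
#'
#' @param cfg A [generator_config()].
#' @param plane "azimuthal" or "axial".
#' @param source A [source_state()].
#' @param radius_mm Sweep radius (mm), default 60.
#' @param angles Angles in degrees.
#' @param lambda Dose-rate constant analogue (cGy·h⁻¹·U⁻¹ at 1 cm).
#' @param duration_s,start_time,spacing_s Acquisition timing.
#' @return List with `psd` and `dummy` [measurement_session()]s.
#' @export
simulate_angular_session <- function(cfg, plane = c("azimuthal", "axial"),
                                     source, radius_mm = 60,
                                     angles = seq(30, 330, by = 20),
                                     lambda = 1.109, duration_s = 10,
                                     start_time = as.POSIXct(
                                       "2024-03-02 09:00:00", tz = "UTC"),
                                     spacing_s = 60) {
  stopifnot(inherits(cfg, "generator_config"),
            inherits(source, "source_state"), radius_mm > 0)
  plane <- match.arg(plane)
  n <- length(angles)
  times <- start_time + spacing_s * (seq_len(n) - 1L)
  R <- mm_to_cm(radius_mm)
  with_seed(cfg$seed + 1L, {
    rate_psd <- rate_dummy <- numeric(n)
    for (i in seq_len(n)) {
      sk <- rakr_to_sk(decay_correct(source, times[i]))
      dose <- sk * lambda / R^2
      stem <- cfg$stem_coefficient * switch(plane,
        azimuthal = stem_proxy_azimuthal(angles[i], R, cfg$fiber_length_cm),
        axial = atan(cfg$fiber_length_cm / R) / R)
      rate_psd[i] <- cfg$sensitivity * dose *
        cfg$angular_profile(angles[i]) + stem
      rate_dummy[i] <- stem
    }
    rate_psd <- apply_noise(rate_psd, duration_s, cfg)
    rate_dummy <- apply_noise(rate_dummy, duration_s, cfg)
    mk <- function(rate, kind) measurement_session(data.frame(
      counts_per_100ms = rate, duration_s = duration_s,
      timestamp = times, angle = angles, probe_kind = kind),
      radius_mm = radius_mm, plane = plane)
    list(psd = mk(rate_psd, "psd"), dummy = mk(rate_dummy, "dummy"))
  })
}

#' Simulate a temperature-dependence session
#'
#' Sets of repeated irradiations at each water temperature; the clean
#' rate is s0 × (1 + temp_slope × (T − 25)). The water temperature
#' drifts by up to `temp_drift_c` between the before/after readings of a
#' set, so each set carries `t_initial`/`t_final` for the
#' uniform-interval uncertainty rule; the recorded set temperature is
#' their mean and is the temperature the signal is generated at.
#'
#' @param cfg A [generator_config()].
#' @param temps Target set temperatures (°C), default 15–40 °C in 5 °C
#'   steps.
#' @param n_repeats Irradiations per set (default 5).
#' @param s0 Clean rate at 25 °C (counts per 100 ms).
#' @param duration_s,start_time,spacing_s Acquisition timing.
#' @return A [measurement_session()] with per-acquisition `set`,
#'   `temperature`, `t_initial`, `t_final` columns.
#' @export
simulate_temperature_session <- function(cfg, temps = seq(15, 40, by = 5),
                                         n_repeats = 5, s0 = 2000,
                                         duration_s = 10,
                                         start_time = as.POSIXct(
                                           "2024-03-03 09:00:00", tz = "UTC"),
                                         spacing_s = 60) {
  stopifnot(inherits(cfg, "generator_config"), n_repeats >= 1, s0 > 0)
  n_sets <- length(temps)
  with_seed(cfg$seed + 2L, {
    drift <- stats::runif(n_sets, 0, cfg$temp_drift_c) *
      sample(c(-1, 1), n_sets, replace = TRUE)
    t_initial <- temps - drift / 2
    t_final <- temps + drift / 2
    t_set <- (t_initial + t_final) / 2
    rows <- do.call(rbind, lapply(seq_len(n_sets), function(i) {
      clean <- s0 * (1 + cfg$temp_slope * (t_set[i] - 25))
      rate <- apply_noise(rep(clean, n_repeats), duration_s, cfg)
      data.frame(set = i, temperature = t_set[i],
                 t_initial = t_initial[i], t_final = t_final[i],
                 counts_per_100ms = rate, duration_s = duration_s,
                 probe_kind = "psd")
    }))
    rows$timestamp <- start_time + spacing_s * (seq_len(nrow(rows)) - 1L)
    measurement_session(rows)
  })
}
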