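# Signal processing for PSD / dummy-probe sessions: stem-effect
# subtraction, source-decay normalization, and normalization of a
# measured grid to a reference away-along table.

#' Measurement session container
#'
#' A session is a data frame of acquisitions: count rate per 100 ms,
#' acquisition duration, timestamp, geometry (either an away-along point
#' `y`/`z` in cm or an `angle` in degrees with a `radius_mm` attribute),
#' probe kind ("psd" or "dummy") and optionally the water temperature.
#'
#' @param df Data frame with at least `counts_per_100ms`, `duration_s`,
#'   `timestamp` and `probe_kind` columns; `y`/`z` and/or `angle` as
#'   geometry.
#' @param radius_mm Optional source-to-detector radius for angular
#'   sessions (mm).
#' @param plane Optional plane label for angular sessions
#'   ("axial"/"azimuthal").
#' @return The data frame with class `measurement_session`.
#' @export
measurement_session <- function(df, radius_mm = NULL, plane = NULL) {
  need <- c("counts_per_100ms", "duration_s", "timestamp", "probe_kind")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("measurement_session: missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$counts_per_100ms < 0))
    stop("measurement_session: negative count rate", call. = FALSE)
  if (any(df$duration_s <= 0))
    stop("measurement_session: non-positive duration", call. = FALSE)
  if (!all(df$probe_kind %in% c("psd", "dummy")))
    stop("measurement_session: probe_kind must be 'psd' or 'dummy'",
         call. = FALSE)
  attr(df, "radius_mm") <- radius_mm
  attr(df, "plane") <- plane
  class(df) <- c("measurement_session", class(df))
  df
}

#' Write / read a session as JSON
#'
#' Sessions are exchanged as a JSON array of acquisition records with
#' ISO-8601 UTC timestamps.
#'
#' @param session A [measurement_session()].
#' @param path File path.
#' @return `path` invisibly / the session.
#' @export
write_session <- function(session, path) {
  df <- as.data.frame(session)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%OS3Z",
                         tz = "UTC")
  payload <- list(radius_mm = attr(session, "radius_mm"),
                  plane = attr(session, "plane"),
                  acquisitions = df)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- payload$acquisitions
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%OSZ")
  measurement_session(df, radius_mm = payload$radius_mm,
                      plane = payload$plane)
}

# Poisson (Type A) absolute uncertainty of a count rate per 100 ms:
# sqrt(N)/t with N the total counts over the acquisition.
rate_u_abs <- function(rate_per_100ms, duration_s) {
  n_windows <- duration_s * 10
  total <- rate_per_100ms * n_windows
  ifelse(total > 0, sqrt(total) / n_windows, 0)
}

#' Stem-effect subtraction
#'
#' Subtracts a dummy-probe (scintillator-free, stem-only) session from
#' the matching PSD session acquisition by acquisition. Rows are paired
#' by geometry: away-along points within `tol_mm` (default 0.1 mm) or
#' angles within `tol_deg` (default 0.5°). Poisson Type A uncertainties
#' of the two rates combine in quadrature. Net rates more than 3σ below
#' zero are kept (clamping would bias means of repeated low-signal
#' acquisitions) but flagged.
#'
#' @param psd,dummy [measurement_session()]s with `probe_kind` "psd" and
#'   "dummy" respectively, on the same geometry set.
#' @param tol_mm,tol_deg Pairing tolerances.
#' @return Data frame of class `corrected_signals` with the geometry
#'   columns, `net_rate`, `u_abs`, `u_rel`, `timestamp` and a
#'   `negative_flag`.
#' @export
subtract_stem <- function(psd, dummy, tol_mm = 0.1, tol_deg = 0.5) {
  stopifnot(inherits(psd, "measurement_session"),
            inherits(dummy, "measurement_session"))
  if (nrow(psd) != nrow(dummy))
    stop("subtract_stem: sessions have different numbers of acquisitions",
         call. = FALSE)
  angular <- "angle" %in% names(psd) && !all(is.na(psd$angle))
  if (angular) {
    d <- abs(psd$angle - dummy$angle)
    if (any(d > tol_deg))
      stop(sprintf(
        "subtract_stem: angle mismatch up to %.3g deg exceeds tolerance %g deg",
        max(d), tol_deg), call. = FALSE)
    geom <- psd[, "angle", drop = FALSE]
  } else {
    d_cm <- sqrt((psd$y - dummy$y)^2 + (psd$z - dummy$z)^2)
    if (any(cm_to_mm(d_cm) > tol_mm))
      stop(sprintf(
        "subtract_stem: geometry mismatch up to %.3g mm exceeds tolerance %g mm",
        max(cm_to_mm(d_cm)), tol_mm), call. = FALSE)
    geom <- psd[, c("y", "z"), drop = FALSE]
  }
  net <- psd$counts_per_100ms - dummy$counts_per_100ms
  u_abs <- sqrt(rate_u_abs(psd$counts_per_100ms, psd$duration_s)^2 +
                rate_u_abs(dummy$counts_per_100ms, dummy$duration_s)^2)
  out <- cbind(geom, data.frame(
    net_rate = net,
    u_abs = u_abs,
    u_rel = ifelse(net != 0, abs(u_abs / net), NA_real_),
    timestamp = psd$timestamp,
    negative_flag = net < -3 * u_abs))
  attr(out, "radius_mm") <- attr(psd, "radius_mm")
  attr(out, "plane") <- attr(psd, "plane")
  class(out) <- c("corrected_signals", class(out))
  out
}

#' Source-decay normalization
#'
#' Divides each net rate by RAKR(t)/RAKR(ref_time) so all acquisitions
#' refer to the source strength at the reference time. When the maximum
#' decay variation across the session is below `threshold_pct`
#' (default 0.2%), the correction is skipped and the signals returned
#' unchanged, mirroring routine practice for short sessions on a
#' 73.83 d half-life source.
#'
#' @param signals A `corrected_signals` frame from [subtract_stem()].
#' @param source A [source_state()].
#' @param threshold_pct Skip threshold on the peak-to-peak decay
#'   variation, percent.
#' @return `signals` with `net_rate` (and `u_abs`) rescaled; attribute
#'   `decay_correction_applied` records whether anything was done.
#' @export
decay_normalize <- function(signals, source, threshold_pct = 0.2) {
  stopifnot(inherits(signals, "corrected_signals"),
            inherits(source, "source_state"))
  factor <- vapply(seq_len(nrow(signals)), function(i)
    decay_correct(source, signals$timestamp[i]) / source$rakr, numeric(1))
  variation_pct <- 100 * (max(factor) - min(factor)) / min(factor)
  applied <- variation_pct >= threshold_pct
  if (applied) {
    signals$net_rate <- signals$net_rate / factor
    signals$u_abs <- signals$u_abs / factor
  }
  attr(signals, "decay_correction_applied") <- applied
  attr(signals, "decay_variation_pct") <- variation_pct
  signals
}

#' Normalize a measured grid to a reference away-along table
#'
#' Rescales a grid of stem-corrected, decay-normalized net rates so that
#' its value at the normalization point equals the reference dose rate
#' there (per unit Sk). The measured grid then lives in the reference
#' table's units and can be compared node by node.
#'
#' @param signals `corrected_signals` frame with `y`/`z` columns (cm).
#' @param reference An [away_along_table()].
#' @param y0,z0 Normalization point in cm (default the 4 cm transverse
#'   point in the source plane).
#' @param tol_mm Tolerance for locating the normalization node.
#' @return List with `grid` (signals plus a `dose_rate` column in
#'   cGy·h⁻¹·U⁻¹) and the positive `scale` factor applied.
#' @export
normalize_to_reference <- function(signals, reference, y0 = 4, z0 = 0,
                                   tol_mm = 0.1) {
  stopifnot(inherits(signals, "corrected_signals"),
            inherits(reference, "away_along_table"))
  if (!all(c("y", "z") %in% names(signals)))
    stop("normalize_to_reference: signals carry no (y, z) geometry",
         call. = FALSE)
  d_mm <- cm_to_mm(sqrt((signals$y - y0)^2 + (signals$z - z0)^2))
  at <- which(d_mm <= tol_mm)
  if (!length(at))
    stop(sprintf(
      "normalize_to_reference: no measured point at (y=%g, z=%g) cm", y0, z0),
      call. = FALSE)
  meas0 <- mean(signals$net_rate[at])
  if (meas0 <= 0)
    stop("normalize_to_reference: non-positive rate at the normalization point",
         call. = FALSE)
  ref0 <- dose_rate_at(reference, y0, z0, sk = 1)
  scale <- ref0 / meas0
  # rescale the rates themselves (idempotent: re-normalizing gives scale 1)
  signals$net_rate <- signals$net_rate * scale
  signals$u_abs <- signals$u_abs * scale
  signals$dose_rate <- signals$net_rate
  list(grid = signals, scale = scale)
}
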