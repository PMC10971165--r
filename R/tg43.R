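#' Source state for an HDR Ir-192 source
#'
#' Bundles the reference air-kerma rate (RAKR) of the source with its
#' reference timestamp, half-life and active length. The RAKR at any other
#' time follows from exponential decay; the active length feeds the
#' line-source geometry function (0 means a point source).
#'
#' @param rakr Reference air-kerma rate in mGy·m²·h⁻¹ (numerically equal to
#'   air-kerma strength in U = µGy·m²·h⁻¹ when expressed at 1 m).
#' @param ref_time `POSIXct` timestamp at which `rakr` was stated.
#' @param half_life Half-life in days. Defaults to 73.83 d for Ir-192.
#' @param active_length Active source length in cm; 0 for a point source.
#' @return An object of class `source_state`.
#' @examples
#' src <- source_state(38.3, as.POSIXct("2024-01-01", tz = "UTC"))
#' decay_correct(src, src$ref_time + 86400 * 73.83)  # one half-life
#' @export
source_state <- function(rakr, ref_time, half_life = 73.83,
                         active_length = 0) {
  stopifnot(is.numeric(rakr), length(rakr) == 1L, rakr > 0)
  stopifnot(inherits(ref_time, "POSIXct"))
  stopifnot(is.numeric(half_life), half_life > 0)
  stopifnot(is.numeric(active_length), active_length >= 0)
  structure(
    list(rakr = rakr, ref_time = ref_time, half_life = half_life,
         active_length = active_length),
    class = "source_state"
  )
}

#' @export
print.source_state <- function(x, ...) {
  cat(sprintf(
    "<source_state> RAKR %.3g mGy.m2/h at %s, T1/2 %.2f d, L %.2f cm\n",
    x$rakr, format(x$ref_time, "%Y-%m-%d %H:%M %Z"), x$half_life,
    x$active_length))
  invisible(x)
}

#' Away-along dose-rate table
#'
#' Constructs a validated 2D away-along table: absorbed dose rate to water
#' per unit air-kerma strength (cGy·h⁻¹·U⁻¹) on a rectangular grid of
#' perpendicular ("away", y) and signed axial ("along", z) distances in cm.
#' The convention is z along the source axis (positive toward the cable)
#' and y perpendicular to it.
#'
#' @param away Strictly increasing away distances y in cm, all > 0.
#' @param along Strictly increasing signed along distances z in cm.
#' @param values Numeric matrix, `length(along)` rows by `length(away)`
#'   columns, of dose rate per unit Sk; all entries finite and > 0.
#' @return An object of class `away_along_table`.
#' @seealso [load_away_along()], [dose_rate_at()], [make_toy_away_along()]
#' @export
away_along_table <- function(away, along, values) {
  away <- as.numeric(away); along <- as.numeric(along)
  values <- as.matrix(values)
  if (length(away) < 2L || length(along) < 2L)
    stop("away_along_table: need at least a 2x2 grid", call. = FALSE)
  if (any(!is.finite(away)) || any(diff(away) <= 0))
    stop("away axis must be finite and strictly increasing", call. = FALSE)
  if (any(away <= 0))
    stop("away distances must be > 0", call. = FALSE)
  if (any(!is.finite(along)) || any(diff(along) <= 0))
    stop("along axis must be finite and strictly increasing", call. = FALSE)
  if (nrow(values) != length(along) || ncol(values) != length(away))
    stop(sprintf(
      "values must be %d rows (along) x %d cols (away), got %d x %d",
      length(along), length(away), nrow(values), ncol(values)),
      call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("table values must be finite and > 0", call. = FALSE)
  dimnames(values) <- list(along = format(along), away = format(away))
  structure(list(away = away, along = along, values = values),
            class = "away_along_table")
}

#' @export
print.away_along_table <- function(x, ...) {
  cat(sprintf(
    "<away_along_table> y: %g..%g cm (%d), z: %g..%g cm (%d), cGy/h/U\n",
    min(x$away), max(x$away), length(x$away),
    min(x$along), max(x$along), length(x$along)))
  invisible(x)
}

#' Read an away-along table from CSV
#'
#' Expects the layout used throughout this package: a header row whose
#' first cell is `z\\y` followed by the away distances (cm), then one row
#' per along distance with the along value in the first column and
#' dose-rate values (cGy·h⁻¹·U⁻¹) in the body.
#'
#' @param path Path to the CSV file.
#' @return An [away_along_table()].
#' @export
load_away_along <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (nrow(raw) < 3L || ncol(raw) < 3L)
    stop("away-along CSV: need a header row plus a >=2x2 grid",
         call. = FALSE)
  away <- suppressWarnings(as.numeric(raw[1, -1]))
  if (any(is.na(away)))
    stop(sprintf("away-along CSV: non-numeric away distance in header column %d",
                 which(is.na(away))[1] + 1L), call. = FALSE)
  along <- suppressWarnings(as.numeric(raw[-1, 1]))
  if (any(is.na(along)))
    stop(sprintf("away-along CSV: non-numeric along distance at row %d",
                 which(is.na(along))[1] + 1L), call. = FALSE)
  body <- raw[-1, -1, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  vals <- matrix(as.numeric(vals), nrow = nrow(body))
  if (any(is.na(vals) | !nzchar(as.matrix(body)))) {
    bad <- which(is.na(vals) | !nzchar(as.matrix(body)), arr.ind = TRUE)[1, ]
    stop(sprintf("away-along CSV: missing or non-numeric value at row %d, column %d",
                 bad[1] + 1L, bad[2] + 1L), call. = FALSE)
  }
  away_along_table(away, along, vals)
}

#' Write an away-along table to CSV
#'
#' Inverse of [load_away_along()]; the header cell is `z\\y` and axes are
#' written at full precision so a write/read round trip is exact.
#'
#' @param table An [away_along_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_away_along <- function(table, path) {
  stopifnot(inherits(table, "away_along_table"))
  fmt <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  header <- paste(c("z\\y", fmt(table$away)), collapse = ",")
  rows <- vapply(seq_along(table$along), function(i) {
    paste(c(fmt(table$along[i]), fmt(table$values[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Dose rate at a point from an away-along table
#'
#' Evaluates the absorbed dose rate (cGy·h⁻¹) at a point (y, z) for a
#' source of air-kerma strength `sk`. At a grid node the stored value is
#' returned exactly. Between nodes, values are first multiplied by r² at
#' their node (flattening out the inverse-square gradient that dominates
#' near the source), interpolated bilinearly, and divided by r² at the
#' query point. Queries outside the grid are an error — no extrapolation.
#'
#' @param table An [away_along_table()].
#' @param y,z Query point in cm; (y, z) must not be the origin.
#' @param sk Air-kerma strength in U (µGy·m²·h⁻¹).
#' @return Dose rate in cGy·h⁻¹.
#' @export
dose_rate_at <- function(table, y, z, sk = 1) {
  stopifnot(inherits(table, "away_along_table"))
  stopifnot(is.numeric(y), is.numeric(z), length(y) == 1L, length(z) == 1L)
  stopifnot(is.numeric(sk), sk >= 0)
  if (y == 0 && z == 0)
    stop("dose_rate_at: query at the source origin", call. = FALSE)
  ay <- table$away; az <- table$along
  if (y < ay[1] || y > ay[length(ay)] || z < az[1] || z > az[length(az)])
    stop(sprintf(
      "dose_rate_at: (y=%g, z=%g) outside table range y [%g, %g], z [%g, %g]",
      y, z, ay[1], ay[length(ay)], az[1], az[length(az)]), call. = FALSE)
  iy <- findInterval(y, ay, rightmost.closed = TRUE)
  iz <- findInterval(z, az, rightmost.closed = TRUE)
  iy <- min(iy, length(ay) - 1L); iz <- min(iz, length(az) - 1L)
  y0 <- ay[iy]; y1 <- ay[iy + 1L]; z0 <- az[iz]; z1 <- az[iz + 1L]
  ty <- (y - y0) / (y1 - y0); tz <- (z - z0) / (z1 - z0)
  r2 <- function(yy, zz) yy^2 + zz^2
  # corner values pre-multiplied by r^2 at their own node
  f00 <- table$values[iz,      iy     ] * r2(y0, z0)
  f01 <- table$values[iz,      iy + 1L] * r2(y1, z0)
  f10 <- table$values[iz + 1L, iy     ] * r2(y0, z1)
  f11 <- table$values[iz + 1L, iy + 1L] * r2(y1, z1)
  flat <- (1 - tz) * ((1 - ty) * f00 + ty * f01) +
          tz       * ((1 - ty) * f10 + ty * f11)
  sk * flat / r2(y, z)
}

#' TG-43 line-source geometry function
#'
#' G_L(r, theta) = beta / (L · r · sin(theta)) where beta is the angle
#' subtended by the active length L at the point; reduces to the
#' point-source 1/r² when L = 0, and to the on-axis limit
#' 1 / (r² − L²/4) when sin(theta) = 0.
#'
#' @param r Distance from the source centre in cm, > 0.
#' @param theta Polar angle in degrees from the source axis (+z).
#' @param L Active length in cm, >= 0.
#' @return Geometry function value in cm⁻².
#' @export
geometry_function_line <- function(r, theta, L = 0) {
  stopifnot(is.numeric(r), length(r) == 1L)
  if (r <= 0) stop("geometry_function_line: r must be > 0", call. = FALSE)
  stopifnot(is.numeric(L), L >= 0)
  if (L == 0) return(1 / r^2)
  th <- theta * pi / 180
  s <- sin(th)
  if (abs(s) < 1e-12) {
    if (r <= L / 2)
      stop("geometry_function_line: on-axis point inside the active length",
           call. = FALSE)
    return(1 / (r^2 - L^2 / 4))
  }
  y <- r * s           # perpendicular offset
  z <- r * cos(th)     # axial offset from source centre
  beta <- atan2(z + L / 2, y) - atan2(z - L / 2, y)
  beta / (L * r * s)
}

#' Decay-corrected RAKR
#'
#' RAKR at time `t`: rakr × 2^(−Δt / half_life) with Δt = t − ref_time in
#' days; Δt may be negative (back-correction).
#'
#' @param source A [source_state()].
#' @param t `POSIXct` time at which the RAKR is wanted.
#' @return RAKR at `t`, same units as `source$rakr`.
#' @export
decay_correct <- function(source, t) {
  stopifnot(inherits(source, "source_state"), inherits(t, "POSIXct"))
  dt_days <- as.numeric(difftime(t, source$ref_time, units = "days"))
  source$rakr * 2^(-dt_days / source$half_life)
}

#' Signal sensitivity to longitudinal source displacement
#'
#' Percent change of an inverse-square signal when the source is displaced
#' longitudinally by `delta_long` at perpendicular distance `d_perp`:
#' 100 × (1 − d²/(d² + δ²)). Used to bound the effect of source-positioning
#' accuracy on angular-dependence measurements.
#'
#' @param d_perp Perpendicular source–detector distance in mm, > 0.
#' @param delta_long Longitudinal displacement in mm.
#' @return Percent signal change (>= 0).
#' @export
displacement_sensitivity <- function(d_perp, delta_long) {
  stopifnot(is.numeric(d_perp), d_perp > 0, is.numeric(delta_long))
  100 * (1 - d_perp^2 / (d_perp^2 + delta_long^2))
}

#' Millimetre / centimetre conversion helpers
#'
#' Table axes and geometry functions in this package work in cm; probe and
#' displacement geometry is usually quoted in mm. These helpers make the
#' conversion explicit at API boundaries.
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @export
mm_to_cm <- function(x) x / 10

#' @rdname mm_to_cm
#' @export
cm_to_mm <- function(x) x * 10

#' Air-kerma strength from RAKR
#'
#' RAKR is quoted in mGy·m²·h⁻¹; away-along tables are per unit
#' air-kerma strength U = µGy·m²·h⁻¹, so Sk = 1000 × RAKR.
#'
#' @param rakr RAKR in mGy·m²·h⁻¹.
#' @return Air-kerma strength in U.
#' @export
rakr_to_sk <- function(rakr) rakr * 1000
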