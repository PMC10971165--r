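# Shared fixtures: a reference source, toy tables, and generator configs.

ref_time <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

ir192_source <- function(rakr = 38.3, active_length = 0.35)
  source_state(rakr, ref_time, half_life = 73.83,
               active_length = active_length)

point_source <- function(rakr = 38.3)
  source_state(rakr, ref_time, active_length = 0)

# Exact inverse-square table: value(y, z) = 1 / (y^2 + z^2).
inverse_square_table <- function(away = 1:6, along = -5:5) {
  vals <- outer(along, away, function(z, y) 1 / (y^2 + z^2))
  away_along_table(away, along, vals)
}

# Arbitrary positive table for bound checks (deterministic).
lumpy_table <- function() {
  away <- c(1, 2, 3.5, 5)
  along <- c(-2, 0, 1, 4)
  vals <- outer(along, away, function(z, y)
    1 / (y^2 + z^2) * (1 + 0.2 * sin(3 * y) * cos(2 * z)))
  away_along_table(away, along, vals)
}

quiet_config <- function(seed = 1L, ...)
  generator_config(seed = seed, noise_model = "none", ...)
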