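# Stem subtraction, decay normalization and reference normalization.

make_pair <- function(psd_rates, dummy_rates, y = NULL, z = NULL,
                      angle = NULL, times = NULL) {
  n <- length(psd_rates)
  if (is.null(times)) times <- ref_time + 60 * seq_len(n)
  base <- data.frame(duration_s = 10, timestamp = times)
  if (!is.null(angle)) base$angle <- angle else { base$y <- y; base$z <- z }
  psd <- measurement_session(cbind(base, data.frame(
    counts_per_100ms = psd_rates, probe_kind = "psd")))
  dummy <- measurement_session(cbind(base, data.frame(
    counts_per_100ms = dummy_rates, probe_kind = "dummy")))
  list(psd = psd, dummy = dummy)
}

test_that("stem subtraction removes the dummy signal and flags misfits", {
  p <- make_pair(c(1000, 500), c(100, 50), y = c(2, 4), z = c(0, 0))
  cs <- subtract_stem(p$psd, p$dummy)
  expect_equal(cs$net_rate, c(900, 450))
  # dummy at zero is the identity on rates
  p0 <- make_pair(c(1000, 500), c(0, 0), y = c(2, 4), z = c(0, 0))
  expect_equal(subtract_stem(p0$psd, p0$dummy)$net_rate, c(1000, 500))
  # antisymmetric in the two probes' rates
  rev <- subtract_stem(p$dummy, p$psd)
  expect_equal(rev$net_rate, -cs$net_rate)
  # quadrature of Poisson uncertainties
  u_each <- function(rate) sqrt(rate * 100) / 100
  expect_equal(cs$u_abs[1], sqrt(u_each(1000)^2 + u_each(100)^2))
  expect_false(any(cs$negative_flag))
})

test_that("geometry pairing is enforced within tolerance", {
  p <- make_pair(1000, 100, y = 2, z = 0)
  bad <- p$dummy; bad$y <- 2.05   # 0.5 mm off
  expect_error(subtract_stem(p$psd, bad), "mismatch")
  ok <- p$dummy; ok$y <- 2.005    # 0.05 mm, inside 0.1 mm default
  expect_silent(subtract_stem(p$psd, ok))
  pa <- make_pair(1000, 100, angle = 90)
  bad_a <- pa$dummy; bad_a$angle <- 91
  expect_error(subtract_stem(pa$psd, bad_a), "mismatch")
})

test_that("net rates far below zero are flagged, not clamped", {
  p <- make_pair(100, 200, y = 2, z = 0)
  cs <- subtract_stem(p$psd, p$dummy)
  expect_lt(cs$net_rate, 0)
  expect_true(cs$negative_flag)
})

test_that("decay normalization rescales, skips below threshold, shifts", {
  src <- point_source()
  day <- 86400
  # all at the reference time: unchanged even with threshold 0
  p <- make_pair(c(1000, 1000), c(0, 0), y = c(2, 4), z = c(0, 0),
                 times = rep(ref_time, 2))
  out <- decay_normalize(subtract_stem(p$psd, p$dummy), src,
                         threshold_pct = 0)
  expect_equal(out$net_rate, c(1000, 1000))

  # one half-life later the rate doubles after normalization
  p2 <- make_pair(c(1000, 1000), c(0, 0), y = c(2, 4), z = c(0, 0),
                  times = c(ref_time, ref_time + 73.83 * day))
  out2 <- decay_normalize(subtract_stem(p2$psd, p2$dummy), src,
                          threshold_pct = 0)
  expect_equal(out2$net_rate, c(1000, 2000))
  expect_true(attr(out2, "decay_correction_applied"))

  # a 2 h session on a 73.83 d half-life source varies < 0.1%: identity
  p3 <- make_pair(c(1000, 1000), c(0, 0), y = c(2, 4), z = c(0, 0),
                  times = c(ref_time, ref_time + 2 * 3600))
  cs3 <- subtract_stem(p3$psd, p3$dummy)
  out3 <- decay_normalize(cs3, src)
  expect_lt(attr(out3, "decay_variation_pct"), 0.1)
  expect_false(attr(out3, "decay_correction_applied"))
  expect_identical(out3$net_rate, cs3$net_rate)

  # time-translation invariance: shift timestamps and reference together
  shift <- 37 * day
  p4 <- make_pair(c(1000, 1000), c(0, 0), y = c(2, 4), z = c(0, 0),
                  times = c(ref_time, ref_time + 73.83 * day) + shift)
  src4 <- source_state(src$rakr, ref_time + shift, half_life = src$half_life)
  out4 <- decay_normalize(subtract_stem(p4$psd, p4$dummy), src4,
                          threshold_pct = 0)
  expect_equal(out4$net_rate, out2$net_rate)
})

test_that("normalization to the reference table anchors at 4 cm", {
  tab <- inverse_square_table()
  grid <- expand.grid(y = 1:6, z = -2:2)
  rates <- 321.7 * mapply(function(y, z) dose_rate_at(tab, y, z),
                          grid$y, grid$z)
  p <- make_pair(rates, rep(0, nrow(grid)), y = grid$y, z = grid$z)
  cs <- subtract_stem(p$psd, p$dummy)
  nz <- normalize_to_reference(cs, tab)
  expect_gt(nz$scale, 0)
  ref <- mapply(function(y, z) dose_rate_at(tab, y, z), grid$y, grid$z)
  # proportional field collapses onto the reference exactly
  expect_equal(nz$grid$dose_rate, ref, tolerance = 1e-12)
  # idempotent
  nz2 <- normalize_to_reference(nz$grid, tab)
  expect_equal(nz2$scale, 1, tolerance = 1e-12)
  expect_equal(nz2$grid$dose_rate, nz$grid$dose_rate, tolerance = 1e-12)
  # missing anchor
  off <- expand.grid(y = c(1, 2), z = c(1, 2))
  p_off <- make_pair(c(1, 1, 1, 1), rep(0, 4), y = off$y, z = off$z)
  expect_error(normalize_to_reference(subtract_stem(p_off$psd, p_off$dummy),
                                      tab), "no measured point")
})

test_that("a single perturbed node survives normalization unchanged elsewhere", {
  tab <- inverse_square_table()
  grid <- expand.grid(y = 1:6, z = 0)
  rates <- 10 * mapply(function(y, z) dose_rate_at(tab, y, z),
                       grid$y, grid$z)
  bump_at <- grid$y == 2
  rates[bump_at] <- rates[bump_at] * 1.03
  p <- make_pair(rates, rep(0, nrow(grid)), y = grid$y, z = grid$z)
  nz <- normalize_to_reference(subtract_stem(p$psd, p$dummy), tab)
  ref <- mapply(function(y, z) dose_rate_at(tab, y, z), grid$y, grid$z)
  pct <- 100 * (nz$grid$dose_rate - ref) / ref
  expect_equal(pct[bump_at], 3, tolerance = 1e-9)
  expect_equal(pct[!bump_at], rep(0, sum(!bump_at)), tolerance = 1e-9)
})

test_that("sessions survive a JSON round trip", {
  src <- point_source()
  cfg <- quiet_config()
  tab <- inverse_square_table()
  s <- simulate_away_along_session(cfg, tab, expand.grid(y = 2:3, z = 0:1),
                                   src)
  path <- withr::local_tempfile(fileext = ".json")
  write_session(s$psd, path)
  back <- read_session(path)
  expect_equal(back$counts_per_100ms, s$psd$counts_per_100ms)
  expect_equal(back$y, s$psd$y)
  expect_equal(as.numeric(back$timestamp), as.numeric(s$psd$timestamp))
})
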