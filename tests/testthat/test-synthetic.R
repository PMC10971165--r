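# The generator: determinism, toy-table structure, injected-dependence
# round trips and the sanity of the noise models.

test_that("identical config and seed reproduce sessions bit for bit", {
  src <- ir192_source()
  tab <- make_toy_away_along(src)
  grid <- expand.grid(y = c(2, 4), z = c(-1, 0, 1))
  for (mk in list(
    function(cfg) simulate_away_along_session(cfg, tab, grid, src),
    function(cfg) simulate_angular_session(cfg, "azimuthal", src),
    function(cfg) simulate_temperature_session(cfg))) {
    a <- mk(generator_config(seed = 99))
    b <- mk(generator_config(seed = 99))
    expect_identical(a, b)
    c <- mk(generator_config(seed = 100))
    expect_false(identical(a, c))
  }
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123); before <- runif(3)
  set.seed(123)
  invisible(simulate_temperature_session(generator_config(seed = 5)))
  expect_identical(runif(3), before)
})

test_that("the toy table reduces to inverse square for a point source", {
  tab <- make_toy_away_along(point_source(), mu = 0)
  grid <- expand.grid(z = tab$along, y = tab$away)
  vals <- mapply(function(y, z) tab$values[which(tab$along == z),
                                           which(tab$away == y)],
                 grid$y, grid$z)
  expect_equal(vals, 1.109 / (grid$y^2 + grid$z^2), tolerance = 1e-12)
})

test_that("the toy table is symmetric in +/-z and nests under refinement", {
  src <- ir192_source()
  tab <- make_toy_away_along(src, along = seq(-7, 7, by = 1))
  n <- length(tab$along)
  expect_equal(unname(tab$values[n:1, ]), unname(tab$values),
               tolerance = 1e-12)
  # refining the grid leaves common nodes unchanged
  coarse <- make_toy_away_along(src, away = c(1, 2, 4, 6),
                                along = c(-4, 0, 4))
  fine <- make_toy_away_along(src, away = seq(1, 6, by = 0.5),
                              along = seq(-4, 4, by = 1))
  for (y in coarse$away)
    for (z in coarse$along)
      expect_equal(coarse$values[which(coarse$along == z),
                                 which(coarse$away == y)],
                   fine$values[which(fine$along == z),
                               which(fine$away == y)],
                   tolerance = 1e-12)
})

test_that("zero-noise away-along round trip recovers injected dependences", {
  src <- ir192_source()
  tab <- make_toy_away_along(src)
  grid <- expand.grid(y = 1:6, z = -3:3)

  # flat detector: comparison statistics collapse to zero
  cfg <- quiet_config()
  s <- simulate_away_along_session(cfg, tab, grid, src)
  cs <- decay_normalize(subtract_stem(s$psd, s$dummy), src,
                        threshold_pct = 0)
  cmp <- away_along_comparison(normalize_to_reference(cs, tab), tab,
                               exclude_anchor = c(4, 0))
  expect_lt(cmp$max_abs_pct, 1e-9)

  # +3% energy-dependence shelf at r = 2 cm reads back as +3% there
  eps <- function(r) 1 + 0.03 * (abs(r - 2) < 1e-9)
  cfg2 <- quiet_config(energy_profile = eps)
  s2 <- simulate_away_along_session(cfg2, tab, grid, src)
  cs2 <- decay_normalize(subtract_stem(s2$psd, s2$dummy), src,
                         threshold_pct = 0)
  cmp2 <- away_along_comparison(normalize_to_reference(cs2, tab), tab,
                                exclude_anchor = c(4, 0))
  r <- sqrt(cmp2$per_point$y^2 + cmp2$per_point$z^2)
  expect_equal(cmp2$per_point$pct[abs(r - 2) < 1e-9],
               rep(3, sum(abs(r - 2) < 1e-9)), tolerance = 1e-6)
  expect_equal(cmp2$per_point$pct[abs(r - 2) >= 1e-9 &
                                    !(cmp2$per_point$y == 4 &
                                        cmp2$per_point$z == 0)],
               rep(0, sum(abs(r - 2) >= 1e-9) - 1), tolerance = 1e-6)
})

test_that("zero-noise angular round trip isolates the injected profile", {
  src <- ir192_source()
  # flat detector: after stem subtraction the sweep is flat (dwell
  # positions visited back to back, so no decay across the sweep)
  s <- simulate_angular_session(quiet_config(), "azimuthal", src,
                                spacing_s = 0)
  flat <- angular_summary(subtract_stem(s$psd, s$dummy))
  expect_lt(flat$max_abs_pct, 1e-9)
  # without the stem correction the sweep is visibly not flat
  raw <- angular_summary(s$psd$angle, s$psd$counts_per_100ms)
  expect_gt(raw$max_abs_pct, 0.5)

  # -5% dip at 90 degrees
  dip <- function(a) 1 - 0.05 * (abs(a - 90) < 1e-9)
  s2 <- simulate_angular_session(quiet_config(angular_profile = dip),
                                 "azimuthal", src, spacing_s = 0)
  sum2 <- angular_summary(subtract_stem(s2$psd, s2$dummy))
  at90 <- sum2$per_point$angle == 90
  # relative to the sweep mean the dip sits ~5% below the other angles
  expect_equal(sum2$per_point$pct[at90] -
                 mean(sum2$per_point$pct[!at90]), -5, tolerance = 0.01)

  # axial stem is constant so subtraction leaves the clean signal
  s3 <- simulate_angular_session(quiet_config(), "axial", src)
  expect_equal(diff(range(s3$dummy$counts_per_100ms)), 0)
})

test_that("azimuthal stem peaks at the angle nearest the fiber axis", {
  src <- ir192_source()
  s <- simulate_angular_session(quiet_config(), "azimuthal", src)
  dummy <- s$dummy
  axis_dist <- pmin(dummy$angle, 360 - dummy$angle)
  expect_equal(which.max(dummy$counts_per_100ms), which.min(axis_dist))
  # and decreases monotonically moving away from the axis on each side
  expect_true(all(diff(dummy$counts_per_100ms[dummy$angle <= 180]) < 0))
  expect_true(all(diff(dummy$counts_per_100ms[dummy$angle >= 180]) > 0))
})

test_that("zero-noise temperature sessions return the injected slope", {
  s <- simulate_temperature_session(quiet_config(temp_slope = -0.0019))
  m <- fit_temperature_model(s$temperature, s$counts_per_100ms)
  expect_equal(m$a, -0.0019, tolerance = 1e-12)
  # zero slope: all set means equal
  s0 <- simulate_temperature_session(quiet_config(temp_slope = 0))
  expect_equal(diff(range(tapply(s0$counts_per_100ms, s0$set, mean))), 0)
  # before/after drift feeds the uniform-interval rule
  expect_true(any(s$t_initial != s$t_final))
  u <- uniform_interval_u(temperature_reading(s$t_initial[1], s$t_final[1],
                                              u_cal = 0))
  expect_equal(u, abs(s$t_initial[1] - s$t_final[1]) / sqrt(12))
})

test_that("poisson noise has counting-statistics variance", {
  cfg <- generator_config(seed = 31, noise_model = "poisson")
  s <- simulate_temperature_session(cfg, temps = c(15, 25, 35),
                                    n_repeats = 1000, s0 = 500,
                                    duration_s = 1)
  one_set <- s[s$set == 2, ]
  total_counts <- one_set$counts_per_100ms * one_set$duration_s * 10
  expect_lt(abs(stats::var(total_counts) / mean(total_counts) - 1), 0.2)
})
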