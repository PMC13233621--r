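two_year_fields <- function(map1, map2) {
  # hydro years 2000 and 2001 with uniform months summing to the given MAPs
  months <- c(rep(map1 / 12, 12), rep(map2 / 12, 12))
  p <- tibble::tibble(cell_id = 0L,
                      year = c(rep(2000L, 3), rep(2001L, 12), rep(2002L, 9)),
                      month = c(10:12, 1:12, 1:9),
                      value = months)
  e <- dplyr::mutate(p, value = 0)
  list(p = p, e = e)
}

test_that("adaptation statistics are the per-hydro-year mean and s.d.", {
  f <- two_year_fields(1900, 2100)
  fit <- fit_adaptation(f$p, f$e, window = 2000:2001)
  expect_equal(fit$mu_map, 2000)
  expect_equal(fit$delta_map, 100)  # population s.d. by default
  fit_s <- fit_adaptation(f$p, f$e, window = 2000:2001, sd_type = "sample")
  expect_equal(fit_s$delta_map, 141.42, tolerance = 1e-4)

  # constant climate: zero adaptive capacity
  g <- make_grid(2, 2, 10000)
  clim <- simulate_climate(g, climate_params(seasonal_amplitude = 0,
                                             interannual_sd = 0,
                                             dry_interannual_sd = 0), 1990:1995)
  fit0 <- fit_adaptation(clim$precip, clim$evap, window = 1990:1994)
  expect_true(all(fit0$delta_map == 0))
  expect_true(all(fit0$delta_mcwd == 0))

  expect_error(fit_adaptation(f$p, f$e, window = 2000),
               class = "raincascade_input_error")
})

test_that("only in-window hydro years enter the fit", {
  g <- make_grid(1, 1, 10000)
  clim <- simulate_climate(g, climate_params(seed = 8), 1990:2010)
  fit_all <- fit_adaptation(clim$precip, clim$evap, window = 1990:2009)
  fit_sub <- fit_adaptation(clim$precip, clim$evap, window = 1995:2000)
  expect_equal(fit_sub$n_years, 6)
  expect_false(isTRUE(all.equal(fit_all$mu_map, fit_sub$mu_map)))
})

test_that("sigma draws respect their bounds and modes", {
  g <- make_grid(10, 10, 10000)
  s <- sample_sigma(g, seed = 1)
  expect_true(all(s$sigma >= 0.75 & s$sigma <= 1.25))
  s2 <- sample_sigma(g, bounds = c(0.5, 1), seed = 2)
  expect_true(all(s2$sigma >= 0.5 & s2$sigma <= 1))
  expect_identical(sample_sigma(g, seed = 3), sample_sigma(g, seed = 3))
  expect_false(identical(sample_sigma(g, seed = 3)$sigma,
                         sample_sigma(g, seed = 4)$sigma))

  g2 <- make_grid(2, 1, 10000)
  mr <- tibble::tibble(cell_id = 0:1, map = c(1000, 3000))
  hi <- sample_sigma(g2, mode = "wet_high", map_reference = mr)
  expect_equal(hi$sigma, c(0.75, 1.25))
  lo <- sample_sigma(g2, mode = "wet_low", map_reference = mr)
  expect_equal(lo$sigma, c(1.25, 0.75))
  expect_error(sample_sigma(g2, mode = "wet_high"),
               class = "raincascade_input_error")
})

test_that("thresholds follow the safety-margin formulas", {
  prof <- tibble::tibble(cell_id = 0:1,
                         mu_map = c(2000, 2000), delta_map = c(200, 200),
                         mu_mcwd = c(150, 150), delta_mcwd = c(80, 80))
  th <- compute_thresholds(prof, tibble::tibble(cell_id = 0:1, sigma = c(1, 1.25)))
  expect_equal(th$map_crit, c(1800, 1750))
  expect_equal(th$mcwd_crit, c(230, 250))
  expect_true(all(th$tippable))

  # degenerate margin: crit collapses onto the mean, cell flagged
  expect_warning(
    th0 <- compute_thresholds(prof, tibble::tibble(cell_id = 0:1, sigma = c(0, 1))),
    "non-tippable")
  expect_equal(th0$map_crit[1], 2000)
  expect_false(th0$tippable[1])
})

test_that("raising sigma widens the safety margin monotonically", {
  prof <- tibble::tibble(cell_id = 0L, mu_map = 2000, delta_map = 150,
                         mu_mcwd = 100, delta_mcwd = 40)
  sig <- seq(0.75, 1.25, by = 0.1)
  th <- lapply(sig, function(s) compute_thresholds(prof, s))
  mc <- sapply(th, function(x) x$map_crit)
  wc <- sapply(th, function(x) x$mcwd_crit)
  expect_true(all(diff(mc) < 0))
  expect_true(all(diff(wc) > 0))
})

test_that("absolute guard boundaries mask the right cells", {
  expect_true(guard_mask(2000, 200))
  expect_false(guard_mask(1700, 400))
  expect_false(guard_mask(2000, 400))          # AND: MCWD fails
  expect_true(guard_mask(2000, 400, combine = "or"))
  expect_equal(guard_mask(c(2000, 1700), c(200, 200)), c(TRUE, FALSE))
})
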