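test_that("hydrological years are complete October-September blocks", {
  f <- one_cell_field(rep(1, 24), start_year = 2000) # Jan 2000 - Dec 2001
  hy <- hydrological_years(f)
  expect_equal(unique(hy$hydro_year), 2000)
  expect_equal(nrow(hy), 12)
  expect_equal(hy$month, c(10:12, 1:9))

  # an exact Oct-Sep span survives as one block
  f2 <- tibble::tibble(cell_id = 0L,
                       year = c(rep(1950L, 3), rep(1951L, 9)),
                       month = c(10:12, 1:9), value = 1)
  hy2 <- hydrological_years(f2)
  expect_equal(unique(hy2$hydro_year), 1950)
  expect_equal(nrow(hy2), 12)

  # calendar-year accounting via start_month = 1
  hy3 <- hydrological_years(one_cell_field(rep(1, 24)), start_month = 1)
  expect_equal(sort(unique(hy3$hydro_year)), c(2000, 2001))

  expect_warning(hydrological_years(f2[1:3, ]), "no complete hydrological year")
})

test_that("MAP is the 12-month precipitation sum", {
  expect_equal(compute_map(rep(100, 12)), 1200)
  expect_equal(compute_map(1:12), 78)
  expect_equal(compute_map(rep(0, 12)), 0)
  expect_error(compute_map(c(-1, rep(1, 11))), class = "raincascade_input_error")
  expect_error(compute_map(rep(1, 11)), class = "raincascade_input_error")
})

test_that("MCWD follows the capped deficit recursion", {
  expect_equal(as.numeric(compute_mcwd(rep(120, 12), rep(100, 12))), 0)
  expect_equal(as.numeric(compute_mcwd(rep(100, 12), rep(110, 12))), 120)
  # hand-worked block: deepest deficit -80 reached in month 5 (and again in 8)
  d <- c(50, 20, -30, -40, -10, 100, -60, -20, 80, 10, -5, 30)
  expect_equal(as.numeric(compute_mcwd(d + 100, rep(100, 12))), 80)
  expect_error(compute_mcwd(rep(1, 11), rep(1, 11)), class = "raincascade_input_error")
})

test_that("MCWD matches the step-by-step oracle on random blocks", {
  set.seed(42)
  for (i in 1:1000) {
    p <- runif(12, 0, 300)
    e <- runif(12, 0, 200)
    expect_identical(as.numeric(compute_mcwd(p, e)), mcwd_oracle(p, e))
  }
})

test_that("adding surplus never deepens MCWD, and zero-deficit months are inert", {
  set.seed(7)
  for (i in 1:200) {
    p <- runif(12, 0, 250)
    e <- runif(12, 50, 150)
    base <- as.numeric(compute_mcwd(p, e))
    s <- runif(1, 0, 50)
    expect_lte(as.numeric(compute_mcwd(p + s, e)), base)
  }
  # raising precipitation in a month whose CWD is zero before and after
  # leaves MCWD untouched
  p <- c(500, 500, 50, 50, 50, 500, 500, 500, 500, 500, 500, 500)
  e <- rep(100, 12)
  m1 <- as.numeric(compute_mcwd(p, e))
  p[1] <- 900
  expect_equal(as.numeric(compute_mcwd(p, e)), m1)
})

test_that("windowed means follow the labelling convention", {
  s <- tibble::tibble(hydro_year = 2021:2030, map = 1:10)
  w <- windowed_means(s, window = 10)
  expect_equal(nrow(w), 1)
  expect_equal(w$hydro_year, 2026)
  expect_equal(w$map, 5.5)

  s2 <- tibble::tibble(hydro_year = 2000:2009, map = rep(3, 10))
  expect_equal(unique(windowed_means(s2, 4)$map), 3)
  expect_identical(windowed_means(s2, 1)$map, s2$map)
  expect_warning(w0 <- windowed_means(s2, 11), "window longer")
  expect_equal(nrow(w0), 0)
})

test_that("constant evapotranspiration transform is total and idempotent", {
  e <- one_cell_field(runif(12, 50, 150))
  e100 <- constant_et_transform(e)
  expect_true(all(e100$value == 100))
  expect_identical(constant_et_transform(e100), e100)
  # zero evaporation means no deficit is possible downstream
  p <- one_cell_field(runif(12, 0, 50))
  hs <- hydro_series(p, constant_et_transform(e, 0), start_month = 1)
  expect_equal(hs$mcwd, 0)
  expect_error(constant_et_transform(e, -5), class = "raincascade_input_error")
})

test_that("hydro_series computes per-cell per-year MAP and MCWD", {
  # two cells, one calendar year, start_month = 1 for directness
  p <- field_from_matrix(rbind(rep(100, 12), rep(50, 12)), years = 2000)
  e <- field_from_matrix(rbind(rep(90, 12), rep(60, 12)), years = 2000)
  hs <- hydro_series(p, e, start_month = 1)
  expect_equal(hs$map, c(1200, 600))
  expect_equal(hs$mcwd, c(0, 120))
})

test_that("deficits can be carried across hydrological years behind the flag", {
  # year 1 ends in deficit; year 2 starts in deficit too
  v <- c(rep(200, 6), rep(50, 6), rep(50, 3), rep(200, 9))
  p <- one_cell_field(v)
  e <- one_cell_field(rep(100, 24))
  reset <- hydro_series(p, e, start_month = 1)
  carry <- hydro_series(p, e, start_month = 1, carry_deficit = TRUE)
  expect_equal(reset$mcwd, c(300, 150))
  # carried: year 2 starts at -300, deepens to -450
  expect_equal(carry$mcwd, c(300, 450))
})
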