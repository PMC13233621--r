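flat_profile <- function(n) {
  tibble::tibble(cell_id = seq_len(n) - 1L,
                 mu_map = 2000, delta_map = 300,
                 mu_mcwd = 150, delta_mcwd = 100, sigma = 1,
                 map_crit = 1700, mcwd_crit = 250, tippable = TRUE)
}
no_links <- structure(tibble::tibble(source = integer(), target = integer(),
                                     delta_map = numeric(), delta_mcwd = numeric()),
                      class = c("link_effects", "tbl_df", "tbl", "data.frame"))

test_that("historical-mean conditions commit no transitions", {
  prof <- flat_profile(9)
  hydro <- tibble::tibble(cell_id = 0:8, map = 2000, mcwd = 150)
  snap <- run_snapshot(hydro, no_links, prof)
  expect_false(any(snap$transitioned))
  expect_true(all(snap$reason == "none"))
})

test_that("forcing every cell beyond its threshold transitions everything", {
  prof <- flat_profile(9)
  hydro <- tibble::tibble(cell_id = 0:8, map = 1600, mcwd = 150)
  snap <- run_snapshot(hydro, no_links, prof)
  expect_true(all(snap$transitioned))
  expect_true(all(snap$reason == "map"))
})

test_that("downwind cells transition through the network and say so", {
  prof <- flat_profile(3)
  # cell 0 pushed over directly; strong links 0->1->2; cells 1,2 neutral
  hydro <- tibble::tibble(cell_id = 0:2, map = c(1550, 2000, 2000), mcwd = 150)
  eff <- structure(tibble::tibble(source = c(0L, 1L), target = c(1L, 2L),
                                  delta_map = c(320, 320), delta_mcwd = 0),
                   class = class(no_links))
  snap <- run_snapshot(hydro, eff, prof)
  expect_true(all(snap$transitioned))
  expect_equal(snap$reason, c("map", "network", "network"))
  # agreement with the discrete oracle on identical inputs
  f <- forcing_components(hydro, prof)
  cm <- coupling_matrix(eff, prof)
  expect_setequal(as.integer(discrete_cascade(f, cm)), 0:2)
})

test_that("deforested cells are held transitioned and excluded from the shares", {
  prof <- flat_profile(4)
  hydro <- tibble::tibble(cell_id = 0:3, map = c(1550, 2000, 2000, 2000), mcwd = 150)
  lu <- tibble::tibble(cell_id = 0:3, fraction = c(0, 1, 0.6, 0.2))
  snap <- run_snapshot(hydro, no_links, prof, landuse = lu)
  expect_equal(snap$reason, c("map", "deforested", "deforested", "none"))
  sh <- attribution_shares(snap)
  expect_equal(sum(sh$n), 1)
  expect_equal(sh$share_pct[sh$reason == "map"], 100)
})

test_that("single-driver runs never attribute to the silenced driver", {
  res <- tiny_scenario("strong_drying", nx = 6, ny = 6, seed = 9)
  cfg <- model_config(dt = 0.2, t_max = 1200, n_members = 2,
                      driver_mode = "map_only")
  res_map <- run_scenario(scenario_preset("strong_drying", seed = 9),
                          nx = 6, ny = 6, config = cfg, master_seed = 9,
                          snapshot_starts = c(2050, 2090))
  expect_equal(res_map$attribution$n[res_map$attribution$reason == "mcwd"], 0L)
  expect_true(sum(res$attribution$n) > 0)
})

test_that("attribution accounting is conserved on full scenario runs", {
  res <- tiny_scenario("strong_drying_deforestation", nx = 6, ny = 6, seed = 4)
  st <- res$states
  n_attr <- sum(st$transitioned & !st$forced)
  expect_equal(sum(res$attribution$n), n_attr)
  expect_equal(sum(res$attribution$share_pct), 100, tolerance = 1e-9)
  expect_true(all(res$risk$risk >= 0 & res$risk$risk <= 1))
  expect_true(all(res$area$area_mean_pct <= 100 + 1e-9))
  expect_true(all(res$area$deforested_pct > 0))
})

test_that("ensembles are reproducible and degenerate bounds collapse the spread", {
  res1 <- tiny_scenario("moderate_drying", nx = 5, ny = 5, seed = 2,
                        snapshot_starts = c(2050, 2090))
  res2 <- tiny_scenario("moderate_drying", nx = 5, ny = 5, seed = 2,
                        snapshot_starts = c(2050, 2090))
  expect_identical(res1$risk, res2$risk)
  expect_identical(res1$area, res2$area)
  expect_identical(res1$states, res2$states)

  cfg1 <- model_config(dt = 0.2, t_max = 1200, n_members = 1)
  r1 <- run_scenario(scenario_preset("strong_drying", seed = 2), nx = 5, ny = 5,
                     config = cfg1, master_seed = 2, snapshot_starts = 2090)
  expect_true(all(r1$risk$risk %in% c(0, 1)))

  cfg0 <- model_config(dt = 0.2, t_max = 1200, n_members = 3,
                       sigma_bounds = c(1, 1))
  r0 <- run_scenario(scenario_preset("strong_drying", seed = 2), nx = 5, ny = 5,
                     config = cfg0, master_seed = 2, snapshot_starts = 2090)
  expect_equal(r0$area$area_sd_pct, 0)
})

test_that("the risk plane flags the 10% transitioned-area rule inclusively", {
  tbl <- tibble::tibble(map = c(2000, 1900, 1800), mcwd = c(150, 200, 250),
                        area_pct = c(5, 10, 40))
  rp <- risk_plane(tbl)
  expect_equal(rp$high_risk, c(FALSE, TRUE, TRUE))
  expect_error(risk_plane(tbl[0, ]), class = "raincascade_input_error")
})

test_that("guard boundaries forbid transitions in the robustness mode", {
  prof <- flat_profile(2)
  hydro <- tibble::tibble(cell_id = 0:1, map = c(1600, 1900), mcwd = c(150, 400))
  cfg <- model_config(guard = TRUE)
  snap <- run_snapshot(hydro, no_links, prof, config = cfg)
  # cell 0: MAP 1600 < 1850 guard fails on MAP... but MCWD 150 < 350: AND fails -> tippable
  expect_true(snap$transitioned[1])
  # a guarded cell (MAP 2000 > 1850, MCWD 300 < 350) is forbidden to tip even
  # though its drought forcing alone is far beyond critical
  snap_g <- run_snapshot(tibble::tibble(cell_id = 0:1, map = c(2000, 1600),
                                        mcwd = c(300, 150)),
                         no_links, prof, config = cfg)
  expect_false(snap_g$transitioned[1])
  expect_true(snap_g$transitioned[2])
  # without the guard the same cell tips
  snap_ng <- run_snapshot(tibble::tibble(cell_id = 0:1, map = c(2000, 1600),
                                         mcwd = c(300, 150)),
                          no_links, prof)
  expect_true(snap_ng$transitioned[1])
})
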