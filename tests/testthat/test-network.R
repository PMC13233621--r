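calm_fields <- function(g, years = 2000:2004) {
  simulate_climate(g, climate_params(seasonal_amplitude = 0, interannual_sd = 0,
                                     dry_interannual_sd = 0), years)
}

test_that("zero recycling target yields an empty network", {
  g <- make_grid(4, 4, 10000)
  clim <- calm_fields(g)
  net <- build_network(g, network_params(recycling_target = 0),
                       clim$precip, clim$evap)
  expect_equal(nrow(net), 0)
})

test_that("incoming link mass never exceeds precipitation and respects the recycling target", {
  g <- make_grid(6, 6, 10000)
  clim <- simulate_climate(g, climate_params(seed = 9), 2000:2009)
  net <- build_network(g, network_params(), clim$precip, clim$evap)
  p_clim <- attr(net, "p_clim")
  incoming <- tibble::as_tibble(net) |>
    dplyr::group_by(.data$target, .data$month) |>
    dplyr::summarise(inflow = sum(.data$flow), .groups = "drop")
  p_at <- p_clim[cbind(match(as.character(incoming$target), rownames(p_clim)),
                       incoming$month)]
  expect_true(all(incoming$inflow <= p_at + 1e-9))
  rec <- attr(annual_link_map(net), "recycling")
  expect_true(all(rec$recycling_fraction <= 0.5 + 1e-9))
  expect_gt(max(rec$recycling_fraction), 0.3) # interior approaches the target
})

test_that("link mass is biased downwind of the source", {
  g <- make_grid(7, 7, 10000)
  clim <- calm_fields(g)
  net <- build_network(g, network_params(wind_vector = c(1, 0)),
                       clim$precip, clim$evap)
  centre <- g$cell_id[g$x == 3 & g$y == 3]
  down <- g$cell_id[g$x == 4 & g$y == 3]
  up <- g$cell_id[g$x == 2 & g$y == 3]
  e <- tibble::as_tibble(net) |> dplyr::filter(.data$source == centre, .data$month == 1)
  expect_gt(e$flow[e$target == down], e$flow[e$target == up])
})

test_that("network generation is deterministic and errors on mismatched grids", {
  g <- make_grid(5, 5, 10000)
  clim <- calm_fields(g)
  n1 <- build_network(g, network_params(), clim$precip, clim$evap)
  n2 <- build_network(g, network_params(), clim$precip, clim$evap)
  expect_identical(tibble::as_tibble(n1), tibble::as_tibble(n2))
  g2 <- make_grid(4, 4, 10000)
  expect_error(build_network(g2, network_params(), clim$precip, clim$evap),
               class = "raincascade_input_error")
})

test_that("land-use rescaling is exact, monotone and multiplicative", {
  g <- make_grid(4, 4, 10000)
  clim <- calm_fields(g)
  net <- build_network(g, network_params(), clim$precip, clim$evap)
  f <- tibble::tibble(cell_id = g$cell_id, fraction = 0)

  expect_identical(tibble::as_tibble(apply_landuse(net, f)),
                   tibble::as_tibble(net))

  f1 <- dplyr::mutate(f, fraction = ifelse(.data$cell_id == 5, 1, 0))
  cleared <- tibble::as_tibble(apply_landuse(net, f1))
  expect_true(all(cleared$flow[cleared$source == 5] == 0))
  expect_identical(cleared$flow[cleared$source != 5],
                   tibble::as_tibble(net)$flow[net$source != 5])

  fh <- dplyr::mutate(f, fraction = 0.5)
  scaled <- tibble::as_tibble(apply_landuse(net, fh, retention = 0.4))
  expect_equal(scaled$flow, tibble::as_tibble(net)$flow * 0.7, tolerance = 1e-12)

  # composition: f1 then f2 equals the combined multiplicative factor
  fa <- dplyr::mutate(f, fraction = 0.3)
  fb <- dplyr::mutate(f, fraction = 0.2)
  two_step <- tibble::as_tibble(apply_landuse(apply_landuse(net, fa), fb))
  expect_equal(two_step$flow, tibble::as_tibble(net)$flow * 0.7 * 0.8,
               tolerance = 1e-12)

  # monotone: larger fractions never increase a link
  fbig <- dplyr::mutate(f, fraction = 0.9)
  expect_true(all(tibble::as_tibble(apply_landuse(net, fbig))$flow <=
                    tibble::as_tibble(apply_landuse(net, fa))$flow + 1e-12))

  expect_error(apply_landuse(net, dplyr::mutate(f, fraction = 1.2)),
               class = "raincascade_input_error")
  expect_error(apply_landuse(net, f, retention = -0.1),
               class = "raincascade_input_error")
})

test_that("annual link strengths sum the monthly flows", {
  # hand-built network carrying 10 mm in one month and 5 mm in all twelve
  edges <- tibble::tibble(
    source = c(0L, rep(1L, 12)),
    target = c(1L, rep(0L, 12)),
    month = c(3L, 1:12),
    flow = c(10, rep(5, 12))
  )
  net <- raincascade:::new_moisture_network(edges)
  alm <- annual_link_map(net)
  expect_equal(alm$delta_map[alm$source == 0], 10)
  expect_equal(alm$delta_map[alm$source == 1], 60)

  empty <- raincascade:::new_moisture_network(edges[0, ])
  expect_equal(nrow(annual_link_map(empty)), 0)
})
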