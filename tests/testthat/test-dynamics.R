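cs <- sqrt(4 / 27)

test_that("a coupling carrying the full adaptive range is tipping-equivalent", {
  prof <- tibble::tibble(cell_id = 0:1, mu_map = 2000, delta_map = 300,
                         mu_mcwd = 150, delta_mcwd = 100, sigma = 1,
                         map_crit = 1700, mcwd_crit = 250, tippable = TRUE)
  eff <- tibble::tibble(source = 0L, target = 1L, delta_map = 300, delta_mcwd = 0)
  cm <- coupling_matrix(eff, prof)
  expect_equal(cm$r, cs)

  # both compartments at the critical value: capped combination stays there
  eff2 <- tibble::tibble(source = 0L, target = 1L, delta_map = 300, delta_mcwd = 100)
  expect_equal(coupling_matrix(eff2, prof)$r, cs)

  # no moisture, no coupling
  eff0 <- tibble::tibble(source = 0L, target = 1L, delta_map = 0, delta_mcwd = 0)
  expect_equal(nrow(coupling_matrix(eff0, prof)), 0)

  effneg <- tibble::tibble(source = 0L, target = 1L, delta_map = -5, delta_mcwd = 0)
  expect_error(coupling_matrix(effneg, prof), class = "raincascade_input_error")
})

test_that("uncoupled cells settle on the fold's stable roots", {
  f <- toy_forcing(0)
  snap <- integrate_network(f, config = model_config())
  expect_equal(snap$x_final, -1, tolerance = 1e-6)
  expect_false(snap$transitioned)

  # beyond the bifurcation only the positive root survives
  f2 <- toy_forcing(0.5)
  snap2 <- integrate_network(f2, config = model_config())
  root <- max(cubic_roots_oracle(0.5))
  expect_equal(snap2$x_final, 1.1915, tolerance = 1e-4)
  expect_equal(snap2$x_final, root, tolerance = 1e-6)
  expect_true(snap2$transitioned)
})

test_that("integration brackets the bifurcation at sqrt(4/27)", {
  below <- integrate_network(toy_forcing(cs - 0.01), config = model_config())
  above <- integrate_network(toy_forcing(cs + 0.01), config = model_config())
  expect_lt(below$x_final, 0)
  expect_gt(above$x_final, 0)
})

test_that("a two-cell cascade matches the hand calculation and the oracle", {
  f <- toy_forcing(c(0.40, 0.25))
  cm <- toy_coupling(0L, 1L, 0.20)
  snap <- integrate_network(f, cm, config = model_config())
  expect_true(all(snap$transitioned)) # 0.40 > c*; 0.25 + 0.20 > c*
  tip <- discrete_cascade(f, cm)
  expect_setequal(as.integer(tip), c(0L, 1L))
})

test_that("the discrete cascade iterates hand-checkable chains", {
  f <- toy_forcing(c(0.40, 0.30, 0.30))
  chain <- toy_coupling(c(0L, 1L), c(1L, 2L), c(0.15, 0.15))
  expect_setequal(as.integer(discrete_cascade(f, chain)), 0:2)

  f2 <- toy_forcing(c(0.3, 0.35))
  expect_length(discrete_cascade(f2, NULL), 0)

  f3 <- toy_forcing(c(0.40, 0.30))
  expect_equal(as.integer(discrete_cascade(f3, NULL)), 0L)
})

test_that("states classify against the threshold and guards hold", {
  expect_false(classify_states(-1))
  expect_true(classify_states(1))
  expect_true(classify_states(1.1915))

  f <- toy_forcing(c(0.5, 0.5))
  snap <- integrate_network(f, config = model_config(),
                            guarded = c(TRUE, FALSE))
  expect_equal(snap$transitioned, c(FALSE, TRUE))
  snap2 <- integrate_network(toy_forcing(c(0, 0)), config = model_config(),
                             forced_tipped = c(TRUE, FALSE))
  expect_equal(snap2$transitioned, c(TRUE, FALSE))
  expect_equal(snap2$x_final[1], 1)
})

test_that("every steady state is a root of its effective cubic", {
  set.seed(31)
  for (i in 1:20) {
    inst <- random_cascade_instance(i + 500)
    snap <- integrate_network(inst$forcing, inst$coupling,
                              config = model_config(t_max = 5000))
    # effective forcing under the saturated zero-baseline weight
    n <- nrow(snap)
    w <- pmin(1, pmax(0, (snap$x_final + 1) / 2))
    boost <- rep(0, n)
    for (k in seq_len(nrow(inst$coupling))) {
      boost[inst$coupling$target[k] + 1] <-
        boost[inst$coupling$target[k] + 1] + inst$coupling$r[k] * w[inst$coupling$source[k] + 1]
    }
    resid <- -snap$x_final^3 + snap$x_final + snap$c_crit + boost
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("cascades are monotone in the seed set and in the couplings", {
  set.seed(13)
  for (i in 1:40) {
    inst <- random_cascade_instance(i + 900)
    base <- as.integer(discrete_cascade(inst$forcing, inst$coupling))
    # adding a seed can only grow the tipped set
    seeded <- as.integer(discrete_cascade(inst$forcing, inst$coupling,
                                          seed_tipped = 0L))
    expect_true(all(base %in% seeded))
    # strengthening a coupling can only grow it too
    cm2 <- inst$coupling
    if (nrow(cm2) > 0) {
      j <- sample(nrow(cm2), 1)
      cm2$r[j] <- cm2$r[j] + 0.3
      grown <- as.integer(discrete_cascade(inst$forcing, cm2))
      expect_true(all(base %in% grown))
    }
  }
})

test_that("non-convergence is flagged, not silent", {
  f <- toy_forcing(0.5)
  expect_warning(
    snap <- integrate_network(f, config = model_config(t_max = 0.05)),
    "did not converge")
  expect_false(attr(snap, "converged"))
})
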