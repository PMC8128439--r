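test_that("node inhibition follows the xi closed form and its identity", {
  meki <- drug_preset("meki")
  expect_equal(node_inhibition(meki, 0, inflow = 0.2), 0)

  # dose solving xi = 0.30 for MEKi on the default N1 inflow 0.2
  xstar <- max_dose_for_cap(meki, inflow = 0.2, cap = 0.3)
  expect_equal(xstar, 0.3 / (2 - 0.4 * 0.3), tolerance = 1e-12)
  expect_equal(xstar, 0.1595745, tolerance = 1e-6)
  expect_equal(node_inhibition(meki, xstar, inflow = 0.2), 0.3,
               tolerance = 1e-12)

  # identity xi * Y = K x / (1 + K x) for random (K, Y, x)
  withr::with_seed(11, {
    for (i in 1:50) {
      K <- stats::runif(1, 0, 5)
      y <- stats::runif(1, 0.05, 1)
      x <- stats::runif(1)
      d <- drug_spec("p38i", 8L, K)
      xi <- suppressWarnings(node_inhibition(d, x, inflow = y))
      expect_equal(xi * y, K * x / (1 + K * x), tolerance = 1e-12)
    }
  })

  expect_error(node_inhibition(meki, 0.5, inflow = 0), "positive")
  expect_warning(node_inhibition(drug_preset("meki"), 1, inflow = 0.2),
                 "coherence")
})

test_that("max_dose_for_cap round-trips and flags unreachable caps", {
  withr::with_seed(12, {
    for (i in 1:25) {
      K <- stats::runif(1, 0.1, 3)
      y <- stats::runif(1, 0.5, 1)   # Delta = K/y modest, caps reachable
      cap <- stats::runif(1, 0.05, 0.6)
      d <- drug_spec("MEKi", 3L, K)
      if (K / y > K * cap) {
        xs <- max_dose_for_cap(d, inflow = y, cap = cap)
        if (xs <= 1) {
          expect_equal(suppressWarnings(node_inhibition(d, xs, inflow = y)),
                       cap, tolerance = 1e-10)
        }
      }
    }
  })
  expect_equal(max_dose_for_cap(drug_preset("meki"), 0.2, 0), 0)
  # Delta <= K*cap only when inflow exceeds 1/cap; the guard still fires
  expect_error(max_dose_for_cap(drug_spec("MEKi", 3L, 2), inflow = 4, cap = 0.9),
               "unreachable")
})

test_that("hyperbolic output matches its closed form at anchor doses", {
  expect_equal(bach1_hyperbolic(2, 0), 1)
  expect_equal(bach1_hyperbolic(2, 1), 1 / 3)
  expect_equal(bach1_hyperbolic(0.4, 1), 1 / 1.4)
  expect_equal(bach1_hyperbolic(0.4, 1), 0.7142857, tolerance = 1e-6)
  # K -> 0 recovers the no-drug limit uniformly
  expect_equal(bach1_hyperbolic(0, seq(0, 1, 0.1)), rep(1, 11))
})

test_that("JNK inflow attenuates hyperbolically and rebalances under MLKi", {
  n1 <- build_n1()
  y60 <- jnk_inflow(n1, 0)
  expect_equal(y60, propagate(n1)$inflow[6])
  K3 <- mapk_constants()$K3
  expect_equal(jnk_inflow(n1, 1), y60 / (1 + K3), tolerance = 1e-12)
  # strictly decreasing in dose
  grid <- seq(0, 1, 0.05)
  expect_true(all(diff(jnk_inflow(n1, grid)) < 0))

  # MLKi co-treatment shrinks only the MLK-derived contribution
  K4 <- mapk_constants()$K4
  x <- 0.6
  with_mlki <- jnk_inflow(n1, x, mlki_active = TRUE)
  expect_lt(with_mlki, jnk_inflow(n1, x))
  # independent closed form: alpha2 -> alpha2/(1+K4 x) inside Y6(0)
  s <- n1$splits
  a2 <- s$alpha2 / (1 + K4 * x)
  y6_manual <- (a2 * s$alpha3 + s$A12 * s$alpha4 +
                  (s$alpha1 + (a2 * s$A3 + s$A12 * s$A4) * s$A5) * s$A6) /
    (1 + K3 * x)
  expect_equal(with_mlki, y6_manual, tolerance = 1e-12)
})

test_that("Hill redirection has the right limits and midpoint", {
  expect_equal(hill_redirection(1.5, 0), 1)
  expect_equal(hill_redirection(2, 0.5), 0.5)   # gamma * y6 = 1
  g3 <- mapk_constants()$gamma3
  n1 <- build_n1()
  g_treated <- hill_redirection(g3, jnk_inflow(n1, 1))
  g_untreated <- hill_redirection(g3, jnk_inflow(n1, 0))
  expect_gt(g_treated, g_untreated)
  expect_lt(g_treated, 1)
})

test_that("single-agent JNKi suppresses mildly via redirection", {
  n1 <- build_n1()
  grid <- seq(0, 1, 0.05)
  phi <- bach1_jnki(n1, grid)
  expect_equal(phi[1], 1)
  expect_true(all(diff(phi) <= 1e-12))
  # phi + eps6 = 1 by definition
  eps6 <- surplus_node6(n1, grid)
  expect_equal(phi + eps6, rep(1, length(grid)), tolerance = 1e-12)
  # redirection bounds the escape below one third
  expect_true(all(eps6 < 1 / 3))
  # suppression is minimal relative to p38i
  expect_lt(1 - phi[length(phi)], 1 - bach1_hyperbolic(2, 1))
})

test_that("additive combination matches the sum of absorbed-signal losses", {
  n1 <- build_n1()
  four <- scenario_preset("4d_mapki")
  expect_equal(bach1_combo(n1, four, 0), 1)
  ks <- c(2, 0.4, 0.475628, 0.1)
  expected <- 1 - sum(ks * 0.3 / (1 + ks * 0.3))
  expect_equal(bach1_combo(n1, four, 0.3), expected, tolerance = 1e-12)
  expect_equal(bach1_combo(n1, four, 0.3), 0.364, tolerance = 1e-3)
  # clamped at zero once the additive losses exceed the input
  expect_equal(bach1_combo(n1, four, 1), 0)
  # empty scenario is the untreated limit
  expect_equal(bach1_combo(n1, scenario(list(), name = "none"), c(0, 0.5, 1)),
               rep(1, 3))
  # combo suppresses at least as much as each constituent at the same dose
  for (x in c(0.1, 0.3, 0.6)) {
    singles <- c(bach1_hyperbolic(2, x), bach1_hyperbolic(0.4, x),
                 bach1_jnki(n1, x), bach1_hyperbolic(0.1, x))
    expect_true(all(bach1_combo(n1, four, x) <= singles + 1e-12))
  }
})

test_that("scenarios with duplicate targets are rejected", {
  expect_error(scenario(list(drug_preset("meki"), drug_preset("meki"))),
               "distinct nodes")
  expect_error(scenario_preset("nosuch"), "unknown scenario")
  expect_error(drug_spec("p38i", 8, -1), "nonnegative")
  expect_error(drug_spec("JNKi", 6, 0.5, "hyperbolic"), "jnk_redirection")
})

test_that("dose_response dispatches the right model per scenario", {
  n1 <- build_n1()
  n2 <- build_n2()
  grid <- c(0, 0.5, 1)

  p38_curve <- dose_response(n1, "p38i", grid)
  expect_s3_class(p38_curve, "dose_response_curve")
  expect_equal(p38_curve$phi_bach1, c(1, 0.5, 1 / 3))
  expect_equal(p38_curve$suppression_pct, 100 * (1 - c(1, 0.5, 1 / 3)))

  # hyperbolic scenarios are crosstalk-independent: identical on N1 and N2
  for (nm in c("p38i", "meki", "mlki")) {
    expect_equal(dose_response(n1, nm, grid)$phi_bach1,
                 dose_response(n2, nm, grid)$phi_bach1)
  }

  # JNKi uses redirection on N1, pure branch loss on N2
  K3 <- mapk_constants()$K3
  expect_equal(dose_response(n1, "jnki", grid)$phi_bach1, bach1_jnki(n1, grid))
  expect_equal(dose_response(n2, "jnki", grid)$phi_bach1,
               1 - K3 * grid / (1 + K3 * grid))

  expect_error(dose_response(n1, "p38i", c(0.5, 0.1)), "sorted")
  expect_error(dose_response(n1, "p38i", c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("phi starts at 1 and is non-increasing for every scenario-topology pair", {
  grid <- seq(0, 1, 0.01)
  for (topo in list(build_n1(), build_n2())) {
    for (nm in c("p38i", "meki", "jnki", "mlki", "4d_mapki")) {
      phi <- dose_response(topo, nm, grid)$phi_bach1
      expect_equal(phi[1], 1)
      expect_true(all(diff(phi) <= 1e-12),
                  label = paste("monotone", topo$name, nm))
      expect_true(all(phi >= 0 & phi <= 1))
    }
  }
})
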