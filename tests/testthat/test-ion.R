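test_that("Nernst potential: symmetry, valence, physiological K+ value", {
  expect_identical(nernst(1, 10, 10), 0)
  ## K+ 140 in / 4 out at 310 K, computed independently
  phi <- 8.31446261815324 * 310 / 96485.33212 * 1000
  expect_equal(nernst(1, 140, 4), phi * log(4 / 140))
  expect_equal(nernst(1, 140, 4), -95.0, tolerance = 0.001)
  expect_equal(nernst(-1, 140, 4), -nernst(1, 140, 4))
  expect_error(nernst(1, 0, 4), "positive")
  expect_error(nernst(1, 140, -1), "positive")
})

test_that("pump current: arrest, monotonicity, saturation", {
  p <- sd_params()
  expect_identical(pump_current(25, 4, 0, p), 0)
  Na <- seq(5, 80, by = 5)
  Ip <- pump_current(Na, 6, 1, p)
  expect_true(all(diff(Ip) > 0))
  Ke <- seq(1, 30, by = 1)
  Ip2 <- pump_current(25, Ke, 1, p)
  expect_true(all(diff(Ip2) > 0))
  ## within 1% of the maximum at 10x the half-activation points
  expect_gt(pump_current(10 * p$pump_Na_half, 10 * p$pump_K_half, 1, p),
            0.99 * p$rho_p)
  ## scaling is linear
  expect_equal(pump_current(25, 6, 0.5, p), 0.5 * pump_current(25, 6, 1, p))
})

test_that("glial and bath fluxes are difference-driven and vanish at
          equilibrium", {
  p <- sd_model()$params   # needs the derived fields
  eq0 <- glial_bath_fluxes(p$K_e0, p$Cl_e0, 0, p$K_e0, 1, p)
  expect_equal(unname(eq0["J_glia"]), 0)
  expect_equal(unname(eq0["J_bath"]), 0)
  expect_equal(unname(eq0["J_bath_Cl"]),
               p$lambda_bath * p$morph$omega_e0 * (p$Cl_e0 - p$Cl_e0) / 1000)
  ## raising bath K+ pushes K+ into the ECS
  step <- glial_bath_fluxes(p$K_e0, p$Cl_e0, 0, 15, 1, p)
  expect_gt(unname(step["J_bath"]), 0)
  ## elevated ECS K+ drives glial uptake
  up <- glial_bath_fluxes(12, p$Cl_e0, 0, p$K_e0, 1, p)
  expect_gt(unname(up["J_glia"]), 0)
  ## a full buffer releases K+ back at resting K_e
  rel <- glial_bath_fluxes(p$K_e0, p$Cl_e0, 100, p$K_e0, 1, p)
  expect_lt(unname(rel["J_glia"]), 0)
  ## OGD: all fluxes cease at scale 0
  off <- glial_bath_fluxes(12, p$Cl_e0, 0, 15, 0, p)
  expect_true(all(off == 0))
})

test_that("osmotic volume change vanishes at isotonic balance and points
          down the osmotic gradient", {
  p <- sd_model()$params
  v0 <- volume_rhs(304, 304, 304, 22500, 22500, p)
  expect_true(all(v0 == 0))
  v1 <- volume_rhs(310, 304, 304, 22500, 22500, p)
  expect_gt(v1[["domega_n"]], 0)   # hypertonic neuron swells
  expect_identical(v1[["domega_g"]], 0)
  v2 <- volume_rhs(304, 304, 320, 22500, 22500, p)
  expect_lt(v2[["domega_n"]], 0)   # hypertonic ECS shrinks both cells
  expect_lt(v2[["domega_g"]], 0)
})

test_that("HH steady-state gates are probabilities with correct voltage
          trends", {
  V <- seq(-100, 40, by = 5)
  g <- vapply(V, hh_inf, numeric(3))
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(diff(g["m", ]) > 0))   # activation increases with V
  expect_true(all(diff(g["n", ]) > 0))
  expect_true(all(diff(g["h", ]) < 0))   # inactivation deepens with V
})
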