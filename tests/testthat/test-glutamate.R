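test_that("release law: threshold, midpoint, pool scaling, continuity", {
  p <- sd_params()
  expect_identical(release_flux(p$V_cr - 10, p$N_max, p), 0)
  expect_equal(release_flux((p$V_cr + p$V_hi) / 2, p$N_max, p),
               p$R_max / 4)
  ## linear in the pool filling
  expect_equal(release_flux(0, p$N_max / 2, p),
               release_flux(0, p$N_max, p) / 2)
  ## continuous at V_cr
  expect_lt(release_flux(p$V_cr + 1e-9, p$N_max, p), 1e-15)
  ## unclamped by default above V_hi; clamp option bounds the factor
  expect_gt(release_flux(p$V_hi + 30, p$N_max, p), p$R_max)
  pc <- sd_params(clamp_release = TRUE)
  expect_equal(release_flux(p$V_hi + 30, p$N_max, pc), p$R_max)
})

test_that("receptor gate kinetics and fixed points", {
  expect_identical(receptor_gate_rhs(0, 0, 1.1, 0.19), 0)
  expect_equal(receptor_gate_rhs(0, 1, 1.1, 0.19), -0.19)
  ## balance point: G*alpha = beta -> r_inf = 1/2
  G <- 0.19 / 1.1
  r_inf <- G * 1.1 / (G * 1.1 + 0.19)
  expect_equal(r_inf, 0.5)
  expect_equal(receptor_gate_rhs(G, 0.5, 1.1, 0.19), 0)
  ## fixed point formula to 1e-12 for random rates
  set.seed(42)
  for (i in 1:25) {
    a <- runif(1, 0.01, 2); b <- runif(1, 0.001, 1)
    G <- runif(1, 0, 2)
    r_inf <- G * a / (G * a + b)
    expect_lt(abs(receptor_gate_rhs(G, r_inf, a, b)), 1e-12)
  }
})

test_that("magnesium block matches the printed form", {
  ## V = 0, Mg = 1 mM: denominator 1 + 0.33*exp(-0.7)
  expect_equal(1 / mg_block(0, 1), 1 + 0.33 * exp(-0.7))
  expect_equal(1 / mg_block(0, 1), 1.1639, tolerance = 1e-4)
  ## block releases with depolarization
  expect_gt(mg_block(0, 1), mg_block(-80, 1))
})

test_that("receptor currents vanish at closed gates and reversal", {
  p <- sd_params()
  rc <- receptor_currents(-65, 0, 0, 50, -90, p)
  expect_true(all(rc == 0))
  rc2 <- receptor_currents(50, 0.5, 0.5, 50, -90, p)  # V = E_Na
  expect_identical(rc2[["I_Na_AMPA"]], 0)
  expect_identical(rc2[["I_Na_NMDA"]], 0)
  expect_gt(rc2[["I_K_AMPA"]], 0)
})

test_that("diffusive flux is antisymmetric, linear and correctly signed", {
  m <- cleft_geometry(0.100825, 0.02)
  expect_identical(diffusion_flux(1.5, 1.5, m, 0.3, 2), 0)
  j1 <- diffusion_flux(2, 1, m, 0.3, 2)
  j2 <- diffusion_flux(3, 1, m, 0.3, 2)
  expect_equal(j2, 2 * j1)
  expect_equal(diffusion_flux(1, 2, m, 0.3, 2), -j1)
  expect_lt(j1, 0)   # transmitter leaves the cleft when G_c > G_e
  expect_error(diffusion_flux(1, 0, m, 0.3, 0), "dx")
})

test_that("uptake velocity is Michaelis-Menten", {
  expect_identical(uptake_velocity(0, 0.03, 0.02), 0)
  expect_equal(uptake_velocity(0.02, 0.03, 0.02), 0.015)
  expect_equal(uptake_velocity(1e4 * 0.02, 0.03, 0.02), 0.03,
               tolerance = 1e-4)
  G <- seq(0, 5, by = 0.1)
  v <- uptake_velocity(G, 0.03, 0.02)
  expect_true(all(diff(v) > 0))
  expect_true(all(v <= 0.03))
})

test_that("uptake velocity agrees with the brute-force quasi-steady-state
          of the binding scheme", {
  ## reaction scheme G + B <=> GB -> G_up + B at fixed total binding
  ## sites: solve the GB steady state numerically and compare the implied
  ## velocity k_r*GB with v_max*G/(G+k_m)
  set.seed(7)
  for (i in 1:100) {
    k1 <- runif(1, 0.1, 10); km1 <- runif(1, 0.01, 5)
    kr <- runif(1, 0.01, 5); B_tot <- runif(1, 0.1, 2)
    G <- runif(1, 0, 3)
    ## dGB/dt = k1*G*(B_tot - GB) - (km1 + kr)*GB = 0, solved by uniroot
    f <- function(GB) k1 * G * (B_tot - GB) - (km1 + kr) * GB
    GB <- if (G == 0) 0 else
      uniroot(f, c(0, B_tot), tol = 1e-14)$root
    v_oracle <- kr * GB
    k_m <- (km1 + kr) / k1
    expect_equal(uptake_velocity(G, kr * B_tot, k_m), v_oracle,
                 tolerance = 1e-10)
  }
})

test_that("effective uptake velocities keep the fixed pathway ratios", {
  m <- cleft_geometry(0.100825, 0.02)
  vm <- effective_vmaxes(0.03, m$omega_e0, m)
  expect_equal(vm[["v_cg"]] / vm[["v_cn"]], 4)
  expect_equal(vm[["v_en"]], 0.12 * 0.03)
  expect_equal(vm[["v_eg"]], 0.24 * vm[["v_cg"]])
  ## the factor 4 from transporter density and contact areas:
  ## rho_g = 8 rho_n on A_cg = 4 pi r^2 vs rho_n on A_cn = 8 pi r^2
  expect_equal((8 * m$A_up_cg) / (1 * m$A_up_cn), 4)
  ## ECS shrinkage doubles the ECS-pathway velocities
  vm2 <- effective_vmaxes(0.03, m$omega_e0 / 2, m)
  expect_equal(vm2[["v_en"]], 2 * vm[["v_en"]])
  expect_equal(vm2[["v_eg"]], 2 * vm[["v_eg"]])
  expect_equal(vm2[["v_cn"]], vm[["v_cn"]])   # cleft pathways unaffected
  expect_error(effective_vmaxes(0.03, -1, m), "positive")
})

test_that("glutamate pool dynamics conserve the weighted total", {
  p <- sd_params()
  m <- p$morph
  set.seed(11)
  for (i in 1:200) {
    pools <- list(N_i = runif(1, 0, 0.02), N_c = runif(1, 0, 1e-4),
                  N_e = runif(1, 0, 50), N_up = runif(1, 0, 50))
    V <- runif(1, -80, 30)
    w_e <- runif(1, 2000, 7500)
    g <- glutamate_rhs(pools, V, w_e, p,
                       uptake_scale = runif(1), uptake_fraction = runif(1))
    dT <- (m$N_syn / 2) * (g$deriv[["N_i"]] + g$deriv[["N_c"]]) +
      g$deriv[["N_e"]] + g$deriv[["N_up"]]
    scale <- max(abs(g$deriv))
    expect_lt(abs(dT), 1e-12 * max(scale, 1e-9))
  }
})

test_that("literal recycling reproduces the non-conservative form", {
  p <- sd_params(literal_recycling = TRUE)
  pools <- list(N_i = 0.01, N_c = 1e-5, N_e = 5, N_up = 10)
  g <- glutamate_rhs(pools, -70, 7500, p)
  ## below threshold: dN_i/dt = k_rec * N_up (whole amount per synapse)
  expect_equal(g$deriv[["N_i"]], p$k_rec * 10)
  dT <- (p$morph$N_syn / 2) * (g$deriv[["N_i"]] + g$deriv[["N_c"]]) +
    g$deriv[["N_e"]] + g$deriv[["N_up"]]
  expect_gt(abs(dT), 1e-6)   # the printed form does not conserve mass
})

test_that("quiescent empty pools are a fixed point of the glutamate
          subsystem", {
  p <- sd_params()
  g <- glutamate_rhs(list(N_i = 0, N_c = 0, N_e = 0, N_up = 0),
                     p$V_cr - 5, 7500, p)
  expect_true(all(g$deriv == 0))
  expect_true(all(g$uptake == 0))
})
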