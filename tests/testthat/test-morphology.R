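test_that("cleft geometry satisfies the fixed envelope/area relations", {
  m <- cleft_geometry(0.2, 0.005)
  expect_equal(m$omega_c, 2 * pi * 0.2^2 * 0.005)   # 1.256637e-3 um^3
  expect_equal(m$omega_c, 1.256637e-3, tolerance = 1e-6)
  expect_equal(m$omega_en, 3.769911e-3, tolerance = 1e-6)
  expect_identical(m$omega_en / m$omega_c, 3)
  expect_identical(m$A_sigma, 0.05 * 4 * pi * 0.2^2)
  expect_identical(m$A_up_cn / m$A_up_cg, 2)

  ## relations hold for arbitrary (r, h)
  for (r in c(0.05, 0.1, 0.3)) for (h in c(0.01, 0.02)) {
    mm <- cleft_geometry(r, h)
    expect_equal(mm$omega_en / mm$omega_c, 3)
    expect_gt(mm$omega_c, 0)
    expect_gt(mm$A_sigma, 0)
  }
})

test_that("degenerate height gives zero volumes but finite areas", {
  m <- cleft_geometry(0.2, 0)
  expect_identical(m$omega_c, 0)
  expect_identical(m$omega_en, 0)
  expect_equal(m$A_sigma, 0.008 * pi)
})

test_that("thin-shell approximation differs from the exact shell by O(h^2)", {
  r <- 0.2
  for (h in c(0.02, 0.01, 0.005, 0.0025)) {
    exact <- 0.5 * (4 / 3) * pi * ((r + h)^3 - r^3)
    approx <- cleft_geometry(r, h)$omega_c
    err <- abs(exact - approx)
    ## second-order term of the expansion: 0.5*(4/3)*pi*3*r*h^2 = 2*pi*r*h^2
    expect_lt(err, 1.2 * (2 * pi * r * h^2 + (2 / 3) * pi * h^3))
    expect_gt(err, 0.8 * 2 * pi * r * h^2)
  }
})

test_that("invalid radii are rejected", {
  expect_error(cleft_geometry(-0.1, 0.02), "positive")
  expect_error(cleft_geometry(0, 0.02), "positive")
  expect_error(cleft_geometry(0.1, -0.01), "non-negative")
})

test_that("receptor conductance bounds reproduce the printed ranges", {
  ## NMDA per-AP conductance range 1e-8..6e-7 mS
  nmda <- receptor_density_bounds(c(1e-8, 6e-7)) * 20  # per N_syn_AP
  expect_equal(nmda[2], 16.7, tolerance = 0.005)
  expect_equal(nmda[1], 0.2778, tolerance = 0.005)
  ## AMPA 3.5e-7..1e-6 mS
  ampa <- receptor_density_bounds(c(3.5e-7, 1e-6)) * 20
  expect_equal(ampa[1], 9.7, tolerance = 0.005)
  expect_equal(ampa[2], 27.8, tolerance = 0.005)
  ## identity scaling
  expect_identical(receptor_density_bounds(2e-7, N_post = 20, A_m = 1,
                                           N_syn_AP = 20), 2e-7)
})
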