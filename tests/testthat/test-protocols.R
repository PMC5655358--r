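test_that("perfusion protocol steps bath K+ and nothing else", {
  pr <- perfusion_protocol(15, t_on = 1000)
  expect_equal(pr$K_bath(999), 4)
  expect_equal(pr$K_bath(1000), 15)
  expect_equal(pr$K_bath(1e6), 15)
  for (t in c(0, 999, 1001, 5e5)) {
    expect_equal(pr$pump_scale(t), 1)
    expect_equal(pr$glia_scale(t), 1)
    expect_equal(pr$uptake_scale(t), 1)
  }
  ## null perturbation
  pr0 <- perfusion_protocol(K_high = 4)
  expect_equal(pr0$K_bath(12345), 4)
})

test_that("OGD protocol ramps all activities 1 -> 0 -> 1", {
  pr <- ogd_protocol(t_start = 10000, ramp = 15000, hold = 40000)
  expect_equal(pr$pump_scale(0), 1)
  expect_equal(pr$pump_scale(10000 + 7500), 0.5)       # ramp midpoint
  expect_equal(pr$pump_scale(seq(25000, 65000, 1000)),
               rep(0, 41))                             # hold window
  expect_equal(pr$pump_scale(65000 + 7500), 0.5)
  expect_equal(pr$pump_scale(90000), 1)
  ## uptake is interrupted alongside pump and glia
  expect_equal(pr$uptake_scale(40000), 0)
  expect_equal(pr$K_bath(40000), 4)                    # bath K+ untouched
  ## cosine variant is smooth and monotone on the ramps
  prc <- ogd_protocol(t_start = 0, ramp = 1000, hold = 1000,
                      shape = "cosine")
  s <- prc$pump_scale(seq(0, 1000, 50))
  expect_true(all(diff(s) <= 0))
  expect_equal(prc$pump_scale(500), 0.5)
})

test_that("impaired uptake multiplies only the uptake fraction", {
  base <- perfusion_protocol(15)
  expect_identical(impaired_uptake(base, 1)$uptake_fraction, 1)
  mod <- impaired_uptake(base, 0.2)
  expect_equal(mod$uptake_fraction, 0.2)
  expect_equal(mod$K_bath(0), base$K_bath(0))
  expect_equal(mod$pump_scale(0), 1)
  expect_error(impaired_uptake(base, 1.3), "\\[0,1\\]")
  expect_error(impaired_uptake(base, -0.1), "\\[0,1\\]")
})

test_that("protocol evaluation is pure and deterministic", {
  pr <- ogd_protocol(t_start = 5000)
  t <- seq(0, 90000, 100)
  expect_identical(pr$pump_scale(t), pr$pump_scale(t))
  expect_identical(pr$K_bath(t), pr$K_bath(t))
})
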