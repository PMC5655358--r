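test_that("the calibrated resting state is an exact fixed point", {
  mod <- sd_test_model()
  r <- full_rhs(0, mod$state0, mod, perfusion_protocol(K_high = 4))
  expect_lt(max(abs(r[[1]])), 1e-12)
})

test_that("rest is electroneutral and isotonic in every compartment", {
  mod <- sd_test_model()
  p <- mod$params
  s <- mod$state0
  m <- p$morph
  ## net charge (cations - anions - impermeants), fmol
  q_n <- s[["Na_n"]] + s[["K_n"]] - s[["Cl_n"]] - p$A_n
  q_e <- s[["Na_e"]] + s[["K_e"]] - s[["Cl_e"]] - p$A_e
  q_g <- s[["Na_g"]] + s[["K_g"]] - s[["Cl_g"]] - p$A_g
  expect_lt(abs(q_n), 1e-9)
  expect_lt(abs(q_e), 1e-9)
  expect_lt(abs(q_g), 1e-9)
  osm <- function(Na, K, Cl, A, w) 1000 * (Na + K + Cl + A) / w
  o_n <- osm(s[["Na_n"]], s[["K_n"]], s[["Cl_n"]], p$A_n, m$omega_n0)
  o_e <- osm(s[["Na_e"]], s[["K_e"]], s[["Cl_e"]], p$A_e, m$omega_e0)
  o_g <- osm(s[["Na_g"]], s[["K_g"]], s[["Cl_g"]], p$A_g, m$omega_g0)
  expect_equal(o_n, o_e, tolerance = 1e-10)
  expect_equal(o_g, o_e, tolerance = 1e-10)
})

test_that("the resting state is stable (fast-subsystem spectrum in the
          left half plane)", {
  mod <- sd_test_model()
  cl <- list(dNK_glia = 0, dNK_bath = 0, G_c = 0, dNCl_bath = 0)
  fps <- find_fixed_points(mod, cl,
                           seeds = list(mod$state0[c("V", "n", "h", "rA",
                                                     "rN", "Na_n", "K_n",
                                                     "Cl_n", "w_n",
                                                     "w_g")]))
  expect_length(fps, 1)
  expect_true(fps[[1]]$stable)
  expect_lt(max(Re(fps[[1]]$eig)), 0)
})

test_that("compiled and reference right-hand sides agree on random
          states", {
  mod <- sd_test_model()
  pr <- perfusion_protocol(15)
  cp <- sdglu:::sd_c_parms(mod, pr)
  states <- random_states(25, seed = 3, model = mod)
  for (y in states) {
    rR <- full_rhs(37, y, mod, pr)[[1]]
    rC <- .Call("sd_rhs_eval", 37, as.numeric(y), cp,
                PACKAGE = "sdglu")[seq_along(rR)]
    expect_lt(max(abs(rR - rC) / pmax(abs(rR), 1e-10)), 1e-12)
  }
  ## and for the OGD protocol inside the ramp
  pro <- ogd_protocol(t_start = 1000, ramp = 4000, hold = 4000)
  cpo <- sdglu:::sd_c_parms(mod, pro)
  y <- states[[1]]
  rR <- full_rhs(3000, y, mod, pro)[[1]]
  rC <- .Call("sd_rhs_eval", 3000, as.numeric(y), cpo,
              PACKAGE = "sdglu")[seq_along(rR)]
  expect_lt(max(abs(rR - rC) / pmax(abs(rR), 1e-10)), 1e-12)
})

test_that("non-finite states raise a numerical-state error naming the
          offending variable", {
  mod <- sd_test_model()
  y <- mod$state0
  y["Na_e"] <- -y[["Na_e"]]   # negative ECS Na+ -> log() domain
  expect_error(full_rhs(0, y, mod, perfusion_protocol(15)),
               "positive|non-finite")
})

test_that("closed-system accounting holds along an integrated
          trajectory", {
  mod <- sd_test_model()
  traj <- simulate(mod, protocol = perfusion_protocol(15), t_end = 10000,
                   dt = 50)
  audit <- conservation_audit(traj)
  expect_lt(audit$ions, 1e-6)
  expect_lt(audit$glutamate, 1e-6)
  expect_lt(audit$volume, 1e-9)
  ## derived ECS volume is the exact complement
  m <- mod$params$morph
  expect_equal(traj$omega_e, m$omega_tot - traj$w_n - traj$w_g,
               tolerance = 1e-12)
})

test_that("the combined slow K+ export is the slowest state group at
          rest and during SD", {
  mod <- sd_test_model()
  traj <- simulate(mod, protocol = perfusion_protocol(15),
                   t_end = 120000, dt = 500)
  p <- mod$params
  pr <- perfusion_protocol(15)
  dNK <- (traj$K_g - p$K_g_rest) + traj$dNK_bath
  rng <- function(x) diff(range(x))
  ## instantaneous rates from the right-hand side at sampled states,
  ## normalized by each variable's range over the run
  idx <- seq_len(nrow(traj))   # include the fast transitions
  rates <- sapply(idx, function(i) {
    y <- as.numeric(traj[i, sd_state_names()])
    dy <- full_rhs(traj$time[i], y, mod, pr)[[1]]
    c(V = abs(dy[["V"]]) / rng(traj$V),
      Na_n = abs(dy[["Na_n"]]) / rng(traj$Na_n),
      K_n = abs(dy[["K_n"]]) / rng(traj$K_n),
      n_gate = abs(dy[["n"]]) / rng(traj$n),
      slow = abs(dy[["K_g"]] + dy[["dNK_bath"]]) / rng(dNK))
  })
  ## volumes are excluded: they relax in ~250 ms but move quasi-statically
  ## slaved to the slow drift, so their apparent trajectory rate matches
  ## the slow variable by construction
  r <- apply(rates, 1, max)
  expect_lt(r[["slow"]], r[["V"]])
  expect_lt(r[["slow"]], r[["Na_n"]])
  expect_lt(r[["slow"]], r[["K_n"]])
  expect_lt(r[["slow"]], r[["n_gate"]])
})
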