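## Release-rate calibration.
##
## The continuous release law is anchored to the experimental quantum:
## one action potential releases about 3,000 glutamate molecules per
## synapse.  R_max is fixed so that the time-integral of the release law
## over one simulated action-potential waveform (membrane subsystem at
## resting ion concentrations, driven by a brief current pulse) equals
## that quantum when the releasable pool is full.

#' Simulate a single action-potential waveform
#'
#' Integrates the membrane subsystem (V, n, h with instantaneous m) at
#' fixed resting ion concentrations, driven by a rectangular stimulus
#' current.  Used by \code{\link{calibrate_release}} and available for
#' inspection.
#'
#' @param model An `sd_model`.
#' @param I_stim Stimulus amplitude (uA/cm^2).
#' @param t_stim Stimulus duration (ms).
#' @param t_end Total simulated time (ms).
#' @param dt Output step (ms).
#' @return data.frame with `time` (ms) and `V` (mV).
#' @export
ap_waveform <- function(model, I_stim = 10, t_stim = 1, t_end = 20,
                        dt = 0.01) {
  p <- model$params
  E_Na <- nernst(1, p$Na_n0, p$Na_e0)
  E_K <- nernst(1, p$K_n0, p$K_e0)
  E_Cl <- p$V_rest             # Cl- rests at its Nernst equilibrium
  g0 <- hh_inf(p$V_rest)
  rhs <- function(t, y, parms) {
    V <- y[1]; n <- y[2]; h <- y[3]
    m_inf <- alpha_m(V) / (alpha_m(V) + beta_m(V))
    I_p <- pump_current(p$Na_n0, p$K_e0, 1, p)
    I_Na <- p$g_Na * m_inf^3 * h * (V - E_Na) + p$g_Na_l * (V - E_Na) +
      3 * I_p
    I_K <- p$g_K * n^4 * (V - E_K) + p$g_K_l * (V - E_K) - 2 * I_p
    I_Cl <- p$g_Cl_l * (V - E_Cl)
    I_app <- if (t <= t_stim) I_stim else 0
    list(c(-(I_Na + I_K + I_Cl - I_app) / p$C_m,
           p$phi_gate * (alpha_n(V) * (1 - n) - beta_n(V) * n),
           p$phi_gate * (alpha_h(V) * (1 - h) - beta_h(V) * h)))
  }
  out <- deSolve::ode(c(p$V_rest, g0[["n"]], g0[["h"]]),
                      seq(0, t_end, dt), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  data.frame(time = out[, 1], V = out[, 2])
}

#' Calibrate the maximal release rate
#'
#' Computes R_max such that the release law integrated over one simulated
#' action potential (full releasable pool) yields `molecules` glutamate
#' molecules: `R_max = quantum / integral(q(V(t)) dt)` with
#' `q(V) = ((V - V_cr)/(V_hi - V_cr))^2` above threshold.
#'
#' @param model An `sd_model`.
#' @param molecules Target release per synapse per AP (default 3000).
#' @param ... Passed to \code{\link{ap_waveform}}.
#' @return List with `R_max` (fmol/ms), the dimensionless `q_integral`
#'   (ms), and the waveform used.
#' @export
calibrate_release <- function(model, molecules = 3000, ...) {
  wf <- ap_waveform(model, ...)
  p <- model$params
  q <- pmax((wf$V - p$V_cr) / (p$V_hi - p$V_cr), 0)^2
  dt <- diff(wf$time)
  q_int <- sum((q[-1] + q[-length(q)]) / 2 * dt)   # trapezoid rule
  quantum <- molecules / sd_constants()$N_A * 1e15 # fmol
  list(R_max = quantum / q_int, q_integral = q_int, waveform = wf)
}
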