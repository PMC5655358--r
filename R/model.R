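## Model assembly: resting-state calibration and the full right-hand side.
##
## The 25 state variables are, in order:
##   V, n, h, rA, rN                        membrane and receptor gates
##   Na_n, K_n, Cl_n                        neuron ion amounts (fmol)
##   Na_e, K_e, Cl_e                        ECS ion amounts (fmol)
##   Na_g, K_g, Cl_g                        glia ion amounts (fmol)
##   dNK_bath                               cumulative K+ exported to bath
##   w_n, w_g                               neuron/glia volumes (um^3)
##   Ni, Nc                                 per-synapse glutamate (fmol)
##   Ne, Nup                                total ECS/buffered glutamate
##   U_cn, U_cg, U_en, U_eg                 cumulative uptake by pathway
##   dNCl_bath                              cumulative Cl- exported to bath
##
## omega_e = omega_tot - w_n - w_g and dNK_glia = K_g - K_g0 are derived.

.state_names <- c("V", "n", "h", "rA", "rN",
                  "Na_n", "K_n", "Cl_n",
                  "Na_e", "K_e", "Cl_e",
                  "Na_g", "K_g", "Cl_g",
                  "dNK_bath", "w_n", "w_g",
                  "Ni", "Nc", "Ne", "Nup",
                  "U_cn", "U_cg", "U_en", "U_eg", "dNCl_bath")

#' State variable names of the full model
#' @return Character vector of the 26 state names, in integration order.
#' @export
sd_state_names <- function() .state_names

#' Build the SD model
#'
#' Assembles the model object: stores the parameter set and calibrates the
#' resting state.  Calibration solves, in closed form, for the quantities
#' the parameter set leaves free so that the resting state is an exact
#' fixed point: intracellular Cl- sits at its Nernst equilibrium
#' (`E_Cl = V_rest`), Na+ and K+ leak conductances balance the gated and
#' pump fluxes at rest, and impermeant anion amounts enforce per-compartment
#' electroneutrality (which, with equal cation sums, also gives isotonic
#' rest).
#'
#' @param params An `sd_params` parameter set.
#' @return An object of class `sd_model` with elements `params` (augmented
#'   with derived `g_Na_l`, `g_K_l`, `Cl_n0`, anion amounts `A_n`, `A_g`,
#'   `A_e`, ion totals, and resting gate values) and `state0` (named
#'   resting state vector).
#' @export
sd_model <- function(params = sd_params()) {
  p <- params
  k <- sd_constants()
  m <- p$morph

  ## Cl- rests at its Nernst equilibrium so the (leak-only) Cl current is 0
  p$Cl_n0 <- p$Cl_e0 * exp(p$V_rest / k$phi)

  ## gates at steady state
  g0 <- hh_inf(p$V_rest)
  E_Na <- nernst(1, p$Na_n0, p$Na_e0)
  E_K <- nernst(1, p$K_n0, p$K_e0)

  I_p0 <- pump_current(p$Na_n0, p$K_e0, 1, p)
  I_Na_gated <- p$g_Na * g0[["m"]]^3 * g0[["h"]] * (p$V_rest - E_Na)
  I_K_gated <- p$g_K * g0[["n"]]^4 * (p$V_rest - E_K)

  ## leak conductances that make rest a fixed point of the ion fluxes
  p$g_Na_l <- -(I_Na_gated + 3 * I_p0) / (p$V_rest - E_Na)
  p$g_K_l <- (2 * I_p0 - I_K_gated) / (p$V_rest - E_K)
  if (p$g_Na_l <= 0 || p$g_K_l <= 0)
    stop("resting-state calibration failed: negative leak conductance; ",
         "check rho_p and resting concentrations", call. = FALSE)

  ## impermeant anions: electroneutrality of each compartment at rest
  p$A_n <- (p$Na_n0 + p$K_n0 - p$Cl_n0) * m$omega_n0 / 1000
  p$A_g <- (p$Na_g0 + p$K_g0 - p$Cl_g0) * m$omega_g0 / 1000
  p$A_e <- (p$Na_e0 + p$K_e0 - p$Cl_e0) * m$omega_e0 / 1000
  if (p$A_e < 0)
    stop("resting-state calibration failed: ECS anion amount negative",
         call. = FALSE)

  state0 <- c(
    V = p$V_rest, n = unname(g0["n"]), h = unname(g0["h"]), rA = 0, rN = 0,
    Na_n = p$Na_n0 * m$omega_n0 / 1000,
    K_n = p$K_n0 * m$omega_n0 / 1000,
    Cl_n = p$Cl_n0 * m$omega_n0 / 1000,
    Na_e = p$Na_e0 * m$omega_e0 / 1000,
    K_e = p$K_e0 * m$omega_e0 / 1000,
    Cl_e = p$Cl_e0 * m$omega_e0 / 1000,
    Na_g = p$Na_g0 * m$omega_g0 / 1000,
    K_g = p$K_g0 * m$omega_g0 / 1000,
    Cl_g = p$Cl_g0 * m$omega_g0 / 1000,
    dNK_bath = 0,
    w_n = m$omega_n0, w_g = m$omega_g0,
    Ni = p$N_max, Nc = 0, Ne = 0, Nup = 0,
    U_cn = 0, U_cg = 0, U_en = 0, U_eg = 0, dNCl_bath = 0)
  names(state0) <- .state_names

  ## closed-system ion totals (fmol; bath exports tracked separately)
  p$tot_Na <- sum(state0[c("Na_n", "Na_e", "Na_g")])
  p$tot_K <- sum(state0[c("K_n", "K_e", "K_g")])
  p$tot_Cl <- sum(state0[c("Cl_n", "Cl_e", "Cl_g")])
  p$K_g_rest <- unname(state0["K_g"])

  mod <- list(params = p, state0 = state0, env = new.env(parent = emptyenv()))
  class(mod) <- "sd_model"
  mod
}

#' @export
print.sd_model <- function(x, ...) {
  p <- x$params
  cat("Spreading-depolarization model (neuron + glia + ECS + bath)\n")
  cat(sprintf("  resting V = %g mV; leak conductances (derived): g_Na_l = %.4g, g_K_l = %.4g mS/cm^2\n",
              p$V_rest, p$g_Na_l, p$g_K_l))
  cat(sprintf("  26 state variables; glutamate pools over %d synapses\n",
              p$morph$N_syn))
  invisible(x)
}

#' Full model right-hand side (reference implementation)
#'
#' Deterministic time derivative of the complete state.  Time dependence
#' enters only through the protocol.  A compiled version of the same
#' equations drives \code{\link{simulate.sd_model}}; this R implementation
#' is the reference used by the bifurcation toolkit and equivalence tests.
#'
#' @param t Time (ms).
#' @param y Named state vector (see \code{\link{sd_state_names}}).
#' @param model `sd_model`.
#' @param protocol `sd_protocol`.
#' @param clamp Optional named list to freeze parts of the dynamics (used
#'   by the fast-subsystem analysis): `dNK_glia`, `dNK_bath` (fmol) clamp
#'   the slow variables, `G_c` (mM) clamps cleft glutamate and disables
#'   glutamate pool dynamics.
#' @return List whose first element is the derivative vector; the `aux`
#'   attribute-style second element carries diagnostic quantities
#'   (Nernst potentials, concentrations, currents, G_c, G_e, omega_e).
#' @export
full_rhs <- function(t, y, model, protocol, clamp = NULL) {
  p <- model$params
  k <- sd_constants()
  m <- p$morph
  y <- setNames(as.numeric(y), .state_names)
  yl <- as.list(y)

  w_n <- unname(yl$w_n); w_g <- unname(yl$w_g)
  w_e <- m$omega_tot - w_n - w_g
  if (!is.finite(w_e) || w_e <= 0.05 * m$omega_e0)
    stop("volume collapse: omega_e <= 5% of its resting value at t = ", t,
         call. = FALSE)

  clamped_slow <- !is.null(clamp) &&
    (!is.null(clamp$dNK_glia) || !is.null(clamp$dNK_bath))
  clamped_glu <- !is.null(clamp) && !is.null(clamp$G_c)

  ## concentrations (mM)
  cc <- function(amount, vol) unname(1000 * amount / vol)
  Na_n <- cc(yl$Na_n, w_n); K_n <- cc(yl$K_n, w_n)
  Cl_n <- cc(yl$Cl_n, w_n)
  Na_e <- cc(yl$Na_e, w_e); K_e <- cc(yl$K_e, w_e)
  Cl_e <- cc(yl$Cl_e, w_e)
  Na_g <- cc(yl$Na_g, w_g); K_g <- cc(yl$K_g, w_g)
  Cl_g <- cc(yl$Cl_g, w_g)

  E_Na <- nernst(1, Na_n, Na_e)
  E_K <- nernst(1, K_n, K_e)
  E_Cl <- nernst(-1, Cl_n, Cl_e)

  ## protocol
  pump_sc <- protocol$pump_scale(t)
  glia_sc <- protocol$glia_scale(t)
  upt_sc <- protocol$uptake_scale(t)
  K_bath <- protocol$K_bath(t)

  ## glutamate
  G_c <- if (clamped_glu) clamp$G_c else 1000 * yl$Nc / m$omega_en
  glu <- glutamate_rhs(list(N_i = yl$Ni,
                            N_c = if (clamped_glu) G_c * m$omega_en / 1000
                                  else yl$Nc,
                            N_e = yl$Ne, N_up = yl$Nup),
                       V = yl$V, omega_e = w_e, p = p,
                       uptake_scale = upt_sc,
                       uptake_fraction = protocol$uptake_fraction)
  G_e <- glu$G_e

  ## membrane currents (uA/cm^2)
  V <- yl$V
  m_inf <- alpha_m(V) / (alpha_m(V) + beta_m(V))
  I_p <- pump_current(Na_n, K_e, pump_sc, p)
  rec <- receptor_currents(V, yl$rN, yl$rA, E_Na, E_K, p)

  ## neuronal glutamate-uptake cotransport: 3 Na+ in per glutamate
  U_n <- glu$uptake[["cn"]] + glu$uptake[["en"]]      # fmol/ms
  gamma_n <- m$A_m_n * k$flux_per_current              # fmol/ms per uA/cm^2
  I_co <- -3 * U_n / gamma_n                           # inward current

  I_Na <- p$g_Na * m_inf^3 * yl$h * (V - E_Na) + p$g_Na_l * (V - E_Na) +
    3 * I_p + rec[["I_Na_AMPA"]] + rec[["I_Na_NMDA"]] + I_co
  I_K <- p$g_K * yl$n^4 * (V - E_K) + p$g_K_l * (V - E_K) -
    2 * I_p + rec[["I_K_AMPA"]] + rec[["I_K_NMDA"]]
  I_Cl <- p$g_Cl_l * (V - E_Cl)

  dV <- -(I_Na + I_K + I_Cl) / p$C_m
  dn <- p$phi_gate * (alpha_n(V) * (1 - yl$n) - beta_n(V) * yl$n)
  dh <- p$phi_gate * (alpha_h(V) * (1 - yl$h) - beta_h(V) * yl$h)
  drA <- receptor_gate_rhs(G_c, yl$rA, p$alpha_AMPA, p$beta_AMPA)
  drN <- receptor_gate_rhs(G_c, yl$rN, p$alpha_NMDA, p$beta_NMDA)

  ## transmembrane amount fluxes (fmol/ms); cations: dN = -gamma*I
  dNa_n <- -gamma_n * I_Na
  dK_n <- -gamma_n * I_K
  dCl_n <- gamma_n * I_Cl

  ## glia / bath K+ handling (KCl co-movement)
  dNK_glia_now <- yl$K_g - p$K_g_rest
  if (clamped_slow) {
    J_glia <- 0; J_bath <- 0; J_bath_Cl <- 0
  } else {
    gb <- glial_bath_fluxes(K_e, Cl_e, dNK_glia_now, K_bath, glia_sc, p)
    J_glia <- gb[["J_glia"]]; J_bath <- gb[["J_bath"]]
    J_bath_Cl <- gb[["J_bath_Cl"]]
  }

  dNa_e <- -dNa_n
  dK_e <- -dK_n - J_glia + J_bath
  dCl_e <- -dCl_n - J_glia + J_bath_Cl
  dNa_g <- 0
  dK_g <- J_glia
  dCl_g <- J_glia
  ddNK_bath <- -J_bath

  ## osmosis (impermeant anion amounts fixed)
  osm_n <- Na_n + K_n + Cl_n + cc(p$A_n, w_n)
  osm_g <- Na_g + K_g + Cl_g + cc(p$A_g, w_g)
  osm_e <- Na_e + K_e + Cl_e + cc(p$A_e, w_e)
  dvol <- volume_rhs(osm_n, osm_g, osm_e, w_n, w_g, p)

  dy <- c(dV, dn, dh, drA, drN,
          dNa_n, dK_n, dCl_n,
          dNa_e, dK_e, dCl_e,
          dNa_g, dK_g, dCl_g,
          ddNK_bath, dvol[["domega_n"]], dvol[["domega_g"]],
          glu$deriv[["N_i"]], glu$deriv[["N_c"]],
          glu$deriv[["N_e"]], glu$deriv[["N_up"]],
          glu$uptake[["cn"]], glu$uptake[["cg"]],
          glu$uptake[["en"]], glu$uptake[["eg"]], -J_bath_Cl)
  if (clamped_glu) dy[18:21] <- 0
  if (clamped_slow) { dy[15] <- 0; dy[26] <- 0 }
  names(dy) <- .state_names

  if (any(!is.finite(dy))) {
    bad <- .state_names[!is.finite(dy)]
    stop("numerical state error: non-finite derivative for ",
         paste(bad, collapse = ", "), " at t = ", t, call. = FALSE)
  }

  list(dy, c(G_c = unname(G_c), G_e = unname(G_e), E_Na = unname(E_Na),
             E_K = unname(E_K), E_Cl = unname(E_Cl), I_p = unname(I_p),
             omega_e = unname(w_e), K_e_conc = unname(K_e),
             Na_e_conc = unname(Na_e),
             dNK_glia = unname(dNK_glia_now),
             dNK = unname(dNK_glia_now + yl$dNK_bath)))
}
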