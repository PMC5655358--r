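## Glutamate subsystem: continuous release, receptor gating and currents,
## cleft-ECS diffusion, Michaelis-Menten uptake, and the four-pool
## bookkeeping (per-synapse releasable pool N_i and cleft pool N_c, total
## ECS pool N_e, total buffered pool N_up).
##
## Amounts are fmol; concentrations mM; G_c = 1000*N_c/omega_en,
## G_e = 1000*N_e/omega_e.  Cross-terms between concentration-velocity
## (mM/ms) and amount fluxes carry the 1/1000 conversion.

#' Continuous glutamate release flux
#'
#' Release grows quadratically with depolarization beyond the critical
#' potential `V_cr`, reaching the maximal rate `R_max` at `V_hi`, and
#' scales linearly with the filling of the releasable pool `N_i/N_max`.
#' Below `V_cr` release is zero; the function is continuous at `V_cr`.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param N_i Per-synapse releasable glutamate (fmol), non-negative.
#' @param p Parameter list with `R_max`, `V_cr`, `V_hi`, `N_max`, and
#'   logical `clamp_release` (clamp the quadratic factor at 1).
#' @return Release flux per synapse (fmol/ms).
#' @export
release_flux <- function(V, N_i, p) {
  q <- pmax((V - p$V_cr) / (p$V_hi - p$V_cr), 0)^2
  if (isTRUE(p$clamp_release)) q <- pmin(q, 1)
  p$R_max * q * (N_i / p$N_max)
}

#' Receptor gate kinetics
#'
#' First-order HH-like opening driven by the cleft glutamate concentration:
#' `dr/dt = G_c*alpha*(1-r) - beta*r`, with fixed point
#' `r_inf = G_c*alpha/(G_c*alpha + beta)`.
#'
#' @param G_c Cleft glutamate concentration (mM).
#' @param r_gate Gate open probability in [0,1].
#' @param alpha Forward rate (1/(mM ms)).
#' @param beta Closing rate (1/ms).
#' @return Time derivative of the gate (1/ms).
#' @export
receptor_gate_rhs <- function(G_c, r_gate, alpha, beta) {
  G_c * alpha * (1 - r_gate) - beta * r_gate
}

#' Magnesium block factor of the NMDA receptor
#'
#' `1 / (1 + 0.33*Mg*exp(-0.07*V - 0.7))`.
#'
#' @param V Membrane potential (mV).
#' @param Mg Extracellular magnesium (mM).
#' @return Unblocked fraction in (0, 1].
#' @export
mg_block <- function(V, Mg) {
  1 / (1 + 0.33 * Mg * exp(-0.07 * V - 0.7))
}

#' NMDA and AMPA receptor currents
#'
#' AMPA is ohmic in both its Na+ and K+ components; NMDA carries the
#' voltage-dependent magnesium block.
#'
#' @param V Membrane potential (mV).
#' @param r_NMDA,r_AMPA Gate open probabilities in [0,1].
#' @param E_Na,E_K Reversal potentials (mV).
#' @param p Parameter list with `g_NMDA`, `g_AMPA`, `Mg`.
#' @return Named vector of current densities (uA/cm^2):
#'   `I_Na_AMPA`, `I_K_AMPA`, `I_Na_NMDA`, `I_K_NMDA`.
#' @export
receptor_currents <- function(V, r_NMDA, r_AMPA, E_Na, E_K, p) {
  blk <- mg_block(V, p$Mg)
  c(I_Na_AMPA = p$g_AMPA * r_AMPA * (V - E_Na),
    I_K_AMPA  = p$g_AMPA * r_AMPA * (V - E_K),
    I_Na_NMDA = p$g_NMDA * r_NMDA * blk * (V - E_Na),
    I_K_NMDA  = p$g_NMDA * r_NMDA * blk * (V - E_K))
}

#' Diffusive glutamate flux out of one synaptic cleft
#'
#' `J_diff = -(A_sigma * D_G / dx) * (G_c - G_e)` converted to an amount
#' flux (fmol/ms); negative values mean transmitter leaving the cleft.
#'
#' @param G_c,G_e Cleft and ECS glutamate concentrations (mM).
#' @param morph `sd_morphology` (supplies `A_sigma`).
#' @param D_G Diffusion coefficient (um^2/ms).
#' @param dx Cutoff distance (um), must be positive.
#' @return Signed amount flux per synapse (fmol/ms).
#' @export
diffusion_flux <- function(G_c, G_e, morph, D_G, dx) {
  if (!is.finite(dx) || dx <= 0)
    stop("invalid parameter: dx must be positive", call. = FALSE)
  -(morph$A_sigma * D_G / dx) * (G_c - G_e) / 1000
}

#' Michaelis-Menten uptake velocity
#'
#' Quasi-steady-state velocity of the transporter scheme
#' G + B <-> GB -> G_up + B at fixed total binding sites:
#' `v = v_max * G / (G + k_m)`.
#'
#' @param G Glutamate concentration (mM), non-negative.
#' @param v_max Maximal velocity (mM/ms).
#' @param k_m Half-saturation constant (mM).
#' @return Uptake velocity (mM/ms), bounded by `v_max`.
#' @export
uptake_velocity <- function(G, v_max, k_m) {
  v_max * G / (G + k_m)
}

#' Right-hand side of the four glutamate pools
#'
#' Implements the release / diffusion / uptake / recycling balance of the
#' four pools.  Only half of the transmitter that leaves the `N_syn`
#' synaptic clefts enters the ECS of the model unit (factor `N_syn/2`),
#' and the recycling return is divided among the synapses
#' (`(2/N_syn)*k_rec*N_up` per synapse) so that the weighted total
#' `T = (N_syn/2)*(N_i + N_c) + N_e + N_up` is exactly conserved.  Setting
#' `p$literal_recycling = TRUE` instead returns the whole recycled amount
#' to every synapse (the non-conservative textbook form).
#'
#' @param pools Named numeric vector/list with `N_i`, `N_c` (fmol per
#'   synapse), `N_e`, `N_up` (fmol total).
#' @param V Membrane potential (mV).
#' @param omega_e Current ECS volume (um^3).
#' @param p `sd_params`.
#' @param uptake_scale Protocol uptake activity in [0,1].
#' @param uptake_fraction Constant transporter-impairment multiplier in
#'   [0,1].
#' @return List with `deriv` (named derivatives of the four pools,
#'   fmol/ms) and `uptake` (named per-pathway total uptake fluxes
#'   `c(cn, cg, en, eg)`, fmol/ms; `cn`/`en` are the neuronal ones).
#' @export
glutamate_rhs <- function(pools, V, omega_e, p, uptake_scale = 1,
                          uptake_fraction = 1) {
  pools <- lapply(as.list(pools), unname)
  tot <- glutamate_total(pools, p$morph)
  if (any(!is.finite(unlist(pools))) ||
      any(unlist(pools) < -1e-3 * max(tot, 1e-12)))
    stop("state validity: glutamate pools must be non-negative",
         call. = FALSE)
  m <- p$morph
  ## rate laws are evaluated at non-negative concentrations so that tiny
  ## negative solver excursions are pushed back instead of erroring out
  G_c <- max(1000 * pools$N_c / m$omega_en, 0)
  G_e <- max(1000 * pools$N_e / omega_e, 0)

  v_base <- uptake_scale * uptake_fraction * p$v_cn_max
  vm <- effective_vmaxes(v_base, omega_e, m)
  v_cn <- uptake_velocity(G_c, vm[["v_cn"]], p$k_m)
  v_cg <- uptake_velocity(G_c, vm[["v_cg"]], p$k_m)
  v_en <- uptake_velocity(G_e, vm[["v_en"]], p$k_m)
  v_eg <- uptake_velocity(G_e, vm[["v_eg"]], p$k_m)

  J_rel <- release_flux(V, max(pools$N_i, 0), p)
  J_diff <- diffusion_flux(G_c, G_e, m, p$D_G, p$dx)

  half <- m$N_syn / 2
  up_cn <- half * m$omega_en * v_cn / 1000   # fmol/ms, all clefts
  up_cg <- half * m$omega_en * v_cg / 1000
  up_en <- omega_e * v_en / 1000
  up_eg <- omega_e * v_eg / 1000

  rec_per_syn <- if (isTRUE(p$literal_recycling)) p$k_rec * pools$N_up
                 else (2 / m$N_syn) * p$k_rec * pools$N_up

  deriv <- c(
    N_i  = -J_rel + rec_per_syn,
    N_c  = J_rel + J_diff - m$omega_en * (v_cn + v_cg) / 1000,
    N_e  = -half * J_diff - (up_en + up_eg),
    N_up = up_cn + up_cg + up_en + up_eg - p$k_rec * pools$N_up
  )
  list(deriv = deriv,
       uptake = c(cn = up_cn, cg = up_cg, en = up_en, eg = up_eg),
       G_c = G_c, G_e = G_e)
}

#' Total glutamate of the model unit
#'
#' `T = (N_syn/2) * (N_i + N_c) + N_e + N_up` (fmol); conserved by
#' \code{\link{glutamate_rhs}} under conservative recycling.
#'
#' @param pools Named vector/list with `N_i`, `N_c`, `N_e`, `N_up`.
#' @param morph `sd_morphology`.
#' @return Total glutamate (fmol).
#' @export
glutamate_total <- function(pools, morph) {
  pools <- as.list(pools)
  (morph$N_syn / 2) * (pools$N_i + pools$N_c) + pools$N_e + pools$N_up
}
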