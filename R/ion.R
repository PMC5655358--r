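## Ion-dynamics backbone: HH gating, Na/K pump, glial K+ buffering, bath
## exchange, and osmotic volume dynamics.  Functional forms follow the
## established ion-homeostasis lineage (HH rate functions with
## instantaneous m, product-of-sigmoids pump, first-order saturable glial
## buffer, linear diffusive bath coupling with Cl- co-movement).

## HH rate functions (V in mV, rates in 1/ms)
alpha_n <- function(V) {
  x <- V + 34
  ifelse(abs(x) < 1e-7, 0.1, 0.01 * x / (1 - exp(-0.1 * x)))
}
beta_n <- function(V) 0.125 * exp(-(V + 44) / 80)
alpha_m <- function(V) {
  x <- V + 30
  ifelse(abs(x) < 1e-7, 1, 0.1 * x / (1 - exp(-0.1 * x)))
}
beta_m <- function(V) 4 * exp(-(V + 55) / 18)
alpha_h <- function(V) 0.07 * exp(-(V + 44) / 20)
beta_h <- function(V) 1 / (1 + exp(-0.1 * (V + 14)))

#' Steady-state HH activation values
#'
#' `m` is treated as instantaneous (`m = m_inf(V)`); `n_inf`/`h_inf` give
#' the resting initialization of the slower gates.
#'
#' @param V Membrane potential (mV).
#' @return Named vector `c(m, n, h)`.
#' @export
hh_inf <- function(V) {
  c(m = alpha_m(V) / (alpha_m(V) + beta_m(V)),
    n = alpha_n(V) / (alpha_n(V) + beta_n(V)),
    h = alpha_h(V) / (alpha_h(V) + beta_h(V)))
}

#' Na/K pump current
#'
#' Electrogenic 3Na+/2K+ ATPase current, a product of sigmoids in
#' intracellular Na+ and extracellular K+ scaled by the maximal density
#' `rho_p` and the protocol activity `scale`; `scale = 0` is complete pump
#' failure (OGD core).
#'
#' @param Na_i Intracellular Na+ (mM).
#' @param K_e Extracellular K+ (mM).
#' @param scale Activity in [0,1].
#' @param p Parameter list with `rho_p`, `pump_Na_half`, `pump_Na_slope`,
#'   `pump_K_half`, `pump_K_slope`.
#' @return Pump current density (uA/cm^2).
#' @export
pump_current <- function(Na_i, K_e, scale, p) {
  scale * p$rho_p /
    ((1 + exp((p$pump_Na_half - Na_i) / p$pump_Na_slope)) *
     (1 + exp((p$pump_K_half - K_e) / p$pump_K_slope)))
}

#' Glial buffering and bath exchange K+ fluxes
#'
#' Both slow processes are difference-driven.  The glial buffer relaxes at
#' rate `lambda_glia` toward a saturable sigmoidal equilibrium content
#' `B_glia * (S(K_e) - S(K_e0))` with
#' `S(K) = 1/(1 + exp((glia_K_half - K)/glia_K_slope))`, which is zero at
#' resting K_e.  The bath is an effectively infinite perfusion reservoir:
#' K+ and Cl- each couple diffusively toward the bath composition,
#' `lambda_bath * omega_e0 * (c_bath - c_e)` into the ECS (high-K+
#' perfusion replaces Na+ by K+ at constant Cl-, so the bath Cl- stays at
#' the resting ECS value).  All fluxes scale with the protocol glia
#' activity.  The glial buffer moves Cl- along with K+ (electroneutral
#' KCl uptake, which is what makes glia swell osmotically).
#'
#' @param K_e Extracellular K+ (mM).
#' @param Cl_e Extracellular Cl- (mM).
#' @param dN_glia_K Current glial buffer content above rest (fmol).
#' @param K_bath Bath K+ (mM).
#' @param scale Glia/vasculature activity in [0,1].
#' @param p `sd_params`.
#' @return Named vector: `J_glia` (fmol/ms of KCl into glia), `J_bath`
#'   (fmol/ms of K+ into the ECS from the bath), `J_bath_Cl` (fmol/ms of
#'   Cl- into the ECS from the bath).
#' @export
glial_bath_fluxes <- function(K_e, Cl_e, dN_glia_K, K_bath, scale, p) {
  S <- function(K) 1 / (1 + exp((p$glia_K_half - K) / p$glia_K_slope))
  eq <- p$B_glia * (S(K_e) - S(p$K_e0))
  J_glia <- scale * p$lambda_glia * (eq - dN_glia_K)
  J_bath <- scale * p$lambda_bath * p$morph$omega_e0 * (K_bath - K_e) / 1000
  J_bath_Cl <- scale * p$lambda_bath * p$morph$omega_e0 *
    (p$Cl_e0 - Cl_e) / 1000
  c(J_glia = J_glia, J_bath = J_bath, J_bath_Cl = J_bath_Cl)
}

#' Osmotic volume dynamics
#'
#' Each cell's volume relaxes toward osmotic balance with the ECS:
#' `domega/dt = L * (osm_in - osm_out)` with `L = omega0/(osm0*tau_osm)`,
#' osmolarity being the sum of all ion concentrations plus the impermeant
#' anions.  The ECS volume is `omega_tot - omega_n - omega_g`, so total
#' volume is conserved exactly.
#'
#' @param osm_n,osm_g,osm_e Compartment osmolarities (mM).
#' @param omega_n,omega_g Current cell volumes (um^3, positive).
#' @param p `sd_params`.
#' @return Named vector `c(domega_n, domega_g)` (um^3/ms).
#' @export
volume_rhs <- function(osm_n, osm_g, osm_e, omega_n, omega_g, p) {
  m <- p$morph
  osm0 <- 2 * (p$Na_n0 + p$K_n0)  # resting osmolarity (isotonic init)
  L_n <- m$omega_n0 / (osm0 * p$tau_osm)
  L_g <- m$omega_g0 / (osm0 * p$tau_osm)
  c(domega_n = L_n * (osm_n - osm_e),
    domega_g = L_g * (osm_g - osm_e))
}
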