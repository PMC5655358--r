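## Default parameter set.
##
## Kinetic and biophysical constants for the glutamate subsystem (release,
## receptors, diffusion, uptake, recycling) and the ion-dynamics backbone
## (HH conductances, Na/K pump, glial K+ buffering, bath exchange,
## osmosis).  Receptor rate constants follow the first-order kinetic fits
## of Destexhe and colleagues; pump/glia/bath functional forms follow the
## established ion-homeostasis model lineage.  Leak conductances and
## impermeant anion amounts are not listed here: they are derived at
## initialization so that the resting state is an exact electroneutral,
## isotonic fixed point (see sd_rest_state()).

#' Default model parameters
#'
#' Returns the full parameter set of the model as a named list.  Any field
#' can be overridden through `...`; unknown names are rejected.
#'
#' @param morph An `sd_morphology` object, by default `cleft_geometry()`
#'   with the packaged defaults (r chosen so that a 3,000-molecule release
#'   raises the envelope concentration by 1.3 mM).
#' @param ... Named overrides of individual parameters.
#' @return An object of class `sd_params` (named list).
#'
#' @section Glutamate parameters:
#' \describe{
#'   \item{R_max}{maximal release rate per synapse (fmol/ms); calibrated so
#'     one action potential releases ~3,000 molecules (see
#'     \code{\link{calibrate_release}}).}
#'   \item{V_cr, V_hi}{critical and high potential of the release law (mV).}
#'   \item{N_max}{releasable glutamate pool per synapse (fmol).}
#'   \item{k_rec}{vesicle recycling rate (1/ms).}
#'   \item{g_NMDA, g_AMPA}{maximal receptor conductance densities (mS/cm^2),
#'     derived from per-AP conductances 1e-7 and 3.5e-7 mS.}
#'   \item{alpha_NMDA, beta_NMDA, alpha_AMPA, beta_AMPA}{receptor gate rate
#'     constants (1/(mM ms), 1/ms).}
#'   \item{Mg}{extracellular magnesium (mM).}
#'   \item{v_cn_max}{base maximal cleft-to-neuron uptake velocity (mM/ms);
#'     all other uptake velocities are implied (x4 glial, x0.12/x0.24 ECS).}
#'   \item{k_m}{transporter half-saturation constant (mM).}
#'   \item{D_G, dx}{glutamate diffusion coefficient (um^2/ms) and cutoff
#'     distance (um).}
#' }
#' @export
sd_params <- function(morph = cleft_geometry(0.100825, 0.02), ...) {
  p <- list(
    morph = morph,

    ## --- glutamate release (continuous power-law release function) ---
    R_max = 9.643e-6,   # fmol/ms per synapse; calibrate_release() result
    V_cr = -50,         # mV
    V_hi = 40,          # mV
    N_max = 0.015,      # fmol per synapse (~9e6 molecules releasable store)
    k_rec = 2e-5,       # 1/ms  (vesicle recycling, tau = 50 s)
    literal_recycling = FALSE, # TRUE reproduces the non-conservative form
    clamp_release = FALSE,     # TRUE clamps the quadratic factor at 1

    ## --- NMDA/AMPA receptors (first-order kinetics) ---
    g_NMDA = 1e-7 * 5000 / (20 * 1.8e-4),   # 0.1389 mS/cm^2
    g_AMPA = 3.5e-7 * 5000 / (20 * 1.8e-4), # 0.4861 mS/cm^2
    alpha_NMDA = 0.072, beta_NMDA = 0.0066,      # 1/(mM ms), 1/ms
    alpha_AMPA = 1.1,   beta_AMPA = 0.19,
    Mg = 1.0,                                    # mM

    ## --- diffusion and uptake ---
    D_G = 0.3,          # um^2/ms
    dx = 3.0,           # um
    v_cn_max = 0.03,    # mM/ms (normal value; the key perturbation knob)
    k_m = 0.02,         # mM

    ## --- HH membrane ---
    C_m = 1,            # uF/cm^2
    g_Na = 100,         # mS/cm^2 (gated, m^3 h with instantaneous m)
    g_K = 40,           # mS/cm^2 (gated, n^4)
    g_Cl_l = 0.02,      # mS/cm^2 (Cl- is leak-only)
    phi_gate = 3,       # gating rate scale

    ## --- Na/K pump (product of sigmoids in Na_i and K_e) ---
    rho_p = 5.25,       # uA/cm^2 maximal pump current
    pump_Na_half = 25.5, pump_Na_slope = 3,  # mM
    pump_K_half = 5.5,  pump_K_slope = 1,    # mM

    ## --- glial K+ buffering (saturable, difference-driven) ---
    lambda_glia = 1e-5, # 1/ms relaxation toward buffering equilibrium
    B_glia = 350,       # fmol buffering capacity
    glia_K_half = 18,   # mM half-activation of the equilibrium curve
    glia_K_slope = 2.5, # mM

    ## --- bath (vascular) coupling, K+ with Cl- co-movement ---
    lambda_bath = 3.5e-5, # 1/ms
    K_bath0 = 4,          # mM baseline bath K+

    ## --- osmosis ---
    tau_osm = 250,      # ms relaxation time of osmotic volume changes

    ## --- resting state targets (concentrations, mM; potential, mV) ---
    V_rest = -68,
    Na_n0 = 25, K_n0 = 127,          # Cl_n0 implied by E_Cl = V_rest
    Na_e0 = 148, K_e0 = 4, Cl_e0 = 130,
    Na_g0 = 22, K_g0 = 130, Cl_g0 = 8
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    p[names(dots)] <- dots
  }
  class(p) <- "sd_params"
  p
}

#' @export
print.sd_params <- function(x, ...) {
  cat("sdglu parameter set\n")
  cat(sprintf("  release: R_max = %.3g fmol/ms, V_cr = %g mV, V_hi = %g mV, N_max = %.3g fmol\n",
              x$R_max, x$V_cr, x$V_hi, x$N_max))
  cat(sprintf("  receptors: g_NMDA = %.3g, g_AMPA = %.3g mS/cm^2, Mg = %g mM\n",
              x$g_NMDA, x$g_AMPA, x$Mg))
  cat(sprintf("  uptake: v_cn_max = %g mM/ms, k_m = %g mM; D_G = %g um^2/ms\n",
              x$v_cn_max, x$k_m, x$D_G))
  cat(sprintf("  pump rho_p = %g uA/cm^2; glia lambda = %g/ms, B = %g fmol; bath lambda = %g/ms\n",
              x$rho_p, x$lambda_glia, x$B_glia, x$lambda_bath))
  invisible(x)
}

#' Effective maximal uptake velocities for the four clearance pathways
#'
#' The glial cleft uptake is four times the neuronal one (eight-fold
#' transporter density on half the contact area), and the ECS pathways
#' carry the fixed resting-geometry coefficients 0.12 and 0.24 rescaled by
#' the instantaneous ECS shrinkage `omega_e0/omega_e`.
#'
#' @param v_cn_max Base maximal cleft-to-neuron uptake velocity (mM/ms).
#' @param omega_e Current ECS volume (um^3), must be positive.
#' @param morph `sd_morphology` (supplies `omega_e0`).
#' @return Named numeric vector `c(v_cn, v_cg, v_en, v_eg)` of maximal
#'   velocities (mM/ms).
#' @export
effective_vmaxes <- function(v_cn_max, omega_e, morph) {
  if (!is.finite(omega_e) || omega_e <= 0)
    stop("invalid state: omega_e must be positive", call. = FALSE)
  v_cg_max <- 4 * v_cn_max
  c(v_cn = v_cn_max,
    v_cg = v_cg_max,
    v_en = 0.12 * v_cn_max * morph$omega_e0 / omega_e,
    v_eg = 0.24 * v_cg_max * morph$omega_e0 / omega_e)
}
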