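## Synapse and compartment geometry.
##
## The synaptic cleft is modelled as a thin half-spherical shell of radius r
## and height h; glia wrap the cleft in an "envelope" whose volume is three
## times the cleft volume, and released transmitter is assumed to
## equilibrate over the envelope instantly.  Diffusion out of the cleft runs
## through 5% of the outer spherical surface (the rest is glial sheath).
## Neuronal cleft-uptake area is twice the glial one (inner sphere plus the
## two half-spherical faces above and below the cleft).

#' Synapse and compartment morphology
#'
#' Builds the geometric constants of the model unit from the synapse radius
#' and cleft height: cleft volume `omega_c = 2*pi*r^2*h`, glial-envelope
#' volume `omega_en = 3*omega_c`, cleft-to-ECS diffusion cross-section
#' `A_sigma = 0.05 * 4*pi*r^2`, and cleft-uptake contact areas
#' `A_up_cn = 8*pi*r^2` (neuron) and `A_up_cg = 4*pi*r^2` (glia).
#'
#' The thin-shell approximation drops terms of order h^2: the exact shell
#' volume `0.5*(4/3)*pi*((r+h)^3 - r^3)` differs from `omega_c` only by
#' O(h^2) terms.
#'
#' @param r Synapse radius (micrometre), must be positive.
#' @param h Cleft height (micrometre), non-negative; assumed small
#'   compared to `r`.
#' @param A_m_n,A_m_g Neuron / glia total membrane areas (cm^2), used as
#'   the ECS-uptake contact areas.
#' @param N_syn Total synapse count of the model neuron.
#' @param N_syn_AP Synapses active during a single normal action potential.
#' @param omega_n0,omega_g0,omega_e0 Resting volumes of neuron, glia and
#'   ECS (micrometre^3).
#' @return An object of class `sd_morphology`: a named list with the fields
#'   above plus derived `omega_c`, `omega_en`, `A_sigma`, `A_up_cn`,
#'   `A_up_cg`, and `omega_tot`.
#' @examples
#' m <- cleft_geometry(0.1008, 0.02)
#' m$omega_en / m$omega_c   # exactly 3
#' @export
cleft_geometry <- function(r, h, A_m_n = 6e-4, A_m_g = 6e-4,
                           N_syn = 10000, N_syn_AP = 20,
                           omega_n0 = 22500, omega_g0 = 22500,
                           omega_e0 = 7500) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("invalid morphology: synapse radius r must be a positive number",
         call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h < 0)
    stop("invalid morphology: cleft height h must be non-negative",
         call. = FALSE)
  omega_c <- 2 * pi * r^2 * h
  m <- list(
    r = r, h = h,
    omega_c = omega_c,
    omega_en = 3 * omega_c,
    A_sigma = 0.05 * 4 * pi * r^2,
    A_up_cn = 8 * pi * r^2,
    A_up_cg = 4 * pi * r^2,
    A_m_n = A_m_n, A_m_g = A_m_g,
    N_syn = N_syn, N_syn_AP = N_syn_AP,
    omega_n0 = omega_n0, omega_g0 = omega_g0, omega_e0 = omega_e0,
    omega_tot = omega_n0 + omega_g0 + omega_e0
  )
  class(m) <- "sd_morphology"
  m
}

#' @export
print.sd_morphology <- function(x, ...) {
  cat("Synapse/compartment morphology\n")
  cat(sprintf("  r = %.4g um, h = %.4g um\n", x$r, x$h))
  cat(sprintf("  cleft volume  %.4g um^3, envelope %.4g um^3 (x3)\n",
              x$omega_c, x$omega_en))
  cat(sprintf("  diffusion cross-section %.4g um^2\n", x$A_sigma))
  cat(sprintf("  synapses: %d total, %d per AP\n", x$N_syn, x$N_syn_AP))
  cat(sprintf("  resting volumes (um^3): neuron %g, glia %g, ECS %g\n",
              x$omega_n0, x$omega_g0, x$omega_e0))
  invisible(x)
}

#' Receptor conductance density bounds
#'
#' Scales a per-synapse, per-AP receptor conductance (mS) to a whole-cell
#' SD-relevant conductance density (mS/cm^2): during SD all postsynaptic
#' synapses (`N_post`) are active simultaneously rather than the `N_syn_AP`
#' of a normal action potential, so the per-event conductance is multiplied
#' by `N_post / (N_syn_AP * A_m)`.
#'
#' @param g Per-event receptor conductance (mS); may be a vector (e.g. a
#'   low/high range).
#' @param N_post Number of postsynaptic synapses active in SD (default
#'   5000, i.e. half of 10,000 synapses).
#' @param A_m Membrane area (cm^2).
#' @param N_syn_AP Synapses active in one normal AP.
#' @return Conductance density (mS/cm^2), same length as `g`.
#' @examples
#' # NMDA per-AP conductance range 1e-8..6e-7 mS
#' receptor_density_bounds(c(1e-8, 6e-7)) * 20  # 0.28..16.7 mS/cm^2 at N_syn_AP = 20
#' @export
receptor_density_bounds <- function(g, N_post = 5000, A_m = 1.8e-4,
                                    N_syn_AP = 20) {
  g * N_post / (N_syn_AP * A_m)
}
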