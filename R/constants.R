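## Physical constants and the package-wide unit system.
##
## Internal units: mV, ms, mM, micrometre^3 (volumes), fmol (amounts),
## microA/cm^2 (current densities), mS/cm^2 (conductance densities).
## Conversions all route through the constants below; nothing else in the
## package hard-codes a unit change.

#' Physical constants used by the model
#'
#' A named list with Avogadro's number (`N_A`, 1/mol), the Faraday constant
#' (`F`, C/mol), the thermal voltage `RT/F` at 310 K (`phi`, mV), and the
#' amount/concentration conversion `conc_per_amount` such that
#' concentration in mM equals `conc_per_amount * amount_fmol / volume_um3`.
#'
#' @return Named list of constants.
#' @export
sd_constants <- function() {
  list(
    N_A = 6.02214076e23,         # 1/mol
    F = 96485.33212,             # C/mol
    T = 310,                     # K
    phi = 8.31446261815324 * 310 / 96485.33212 * 1000, # RT/F in mV, 26.712
    conc_per_amount = 1000,      # mM per (fmol/um^3)
    # current density -> amount flux: fmol/ms per (uA/cm^2 * cm^2)
    flux_per_current = 1e6 / 96485.33212
  )
}

#' Nernst reversal potential
#'
#' @param z Ion valence (+1 for Na+/K+, -1 for Cl-).
#' @param c_in Intracellular concentration (mM), must be positive.
#' @param c_out Extracellular concentration (mM), must be positive.
#' @param T_K Temperature in Kelvin (default 310).
#' @return Reversal potential in mV.
#' @examples
#' nernst(1, 140, 4)   # K+ at rest, about -95 mV
#' @export
nernst <- function(z, c_in, c_out, T_K = 310) {
  if (any(c_in <= 0) || any(c_out <= 0))
    stop("nernst(): concentrations must be positive", call. = FALSE)
  phi <- 8.31446261815324 * T_K / 96485.33212 * 1000
  (phi / z) * log(c_out / c_in)
}
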