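## Experimental protocols: time-dependent bath K+ and activity scales.
##
## A protocol is a pure object: evaluating it at a time t yields bath K+
## (mM) and pump/glia/uptake activity scales in [0,1]; `uptake_fraction`
## is a constant transporter-impairment multiplier on v_cn_max.

new_protocol <- function(type, K_bath, pump_scale, glia_scale, uptake_scale,
                         uptake_fraction, cpar) {
  pr <- list(type = type, K_bath = K_bath, pump_scale = pump_scale,
             glia_scale = glia_scale, uptake_scale = uptake_scale,
             uptake_fraction = uptake_fraction, cpar = cpar)
  class(pr) <- "sd_protocol"
  pr
}

#' High-K+ perfusion protocol
#'
#' Bath K+ steps from 4 mM to `K_high` at `t_on` and stays elevated; all
#' activity scales remain 1.
#'
#' @param K_high Elevated bath K+ (mM), default 15.
#' @param t_on Step time (ms), default 0.
#' @param K_base Baseline bath K+ (mM), default 4.
#' @return An `sd_protocol` object.
#' @export
perfusion_protocol <- function(K_high = 15, t_on = 0, K_base = 4) {
  if (!is.finite(K_high) || K_high <= 0)
    stop("K_high must be positive", call. = FALSE)
  one <- function(t) rep(1, length(t))
  new_protocol(
    type = "perfusion",
    K_bath = function(t) ifelse(t < t_on, K_base, K_high),
    pump_scale = one, glia_scale = one, uptake_scale = one,
    uptake_fraction = 1,
    cpar = c(code = 1, K_base = K_base, K_high = K_high, t_on = t_on,
             ramp = 0, hold = 0, shape = 0, uptake_fraction = 1))
}

#' Oxygen-glucose deprivation protocol
#'
#' Pump, glial and uptake activities ramp smoothly from 1 to 0 over
#' `[t_start, t_start + ramp]`, stay 0 for `hold`, then ramp back to 1 over
#' the final `ramp`; bath K+ stays at baseline.
#'
#' @param t_start Onset (ms), default 10000.
#' @param ramp Cessation/reactivation ramp duration (ms), default 15000.
#' @param hold Full-interruption duration (ms), default 40000.
#' @param shape Ramp shape, `"linear"` (default) or `"cosine"`.
#' @param K_base Bath K+ (mM), default 4.
#' @return An `sd_protocol` object.
#' @export
ogd_protocol <- function(t_start = 10000, ramp = 15000, hold = 40000,
                         shape = c("linear", "cosine"), K_base = 4) {
  shape <- match.arg(shape)
  if (ramp <= 0 || hold <= 0) stop("ramp and hold must be positive",
                                   call. = FALSE)
  sc <- function(t) ogd_scale(t, t_start, ramp, hold, shape)
  new_protocol(
    type = "ogd",
    K_bath = function(t) rep(K_base, length(t)),
    pump_scale = sc, glia_scale = sc, uptake_scale = sc,
    uptake_fraction = 1,
    cpar = c(code = 2, K_base = K_base, K_high = K_base, t_on = t_start,
             ramp = ramp, hold = hold,
             shape = if (shape == "linear") 0 else 1, uptake_fraction = 1))
}

## activity scale of the OGD protocol: 1 -> 0 -> 0 -> 1
ogd_scale <- function(t, t_start, ramp, hold, shape) {
  x <- numeric(length(t))
  t1 <- t_start; t2 <- t_start + ramp
  t3 <- t2 + hold; t4 <- t3 + ramp
  down <- (t2 - t) / ramp     # 1 -> 0 over the first ramp
  up <- (t - t3) / ramp       # 0 -> 1 over the second ramp
  s <- ifelse(t < t1, 1,
       ifelse(t < t2, down,
       ifelse(t < t3, 0,
       ifelse(t < t4, up, 1))))
  if (shape == "cosine") s <- (1 - cos(pi * s)) / 2
  s
}

#' Impaired-uptake modification of a protocol
#'
#' Multiplies the base maximal uptake velocity `v_cn_max` by `fraction`
#' (all four pathway velocities follow through the fixed ratios); leaves
#' everything else untouched.
#'
#' @param base An `sd_protocol`.
#' @param fraction Uptake fraction in [0,1].
#' @return The modified `sd_protocol`.
#' @export
impaired_uptake <- function(base, fraction) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be in [0,1]", call. = FALSE)
  base$uptake_fraction <- fraction
  base$cpar[["uptake_fraction"]] <- fraction
  base
}

#' @export
print.sd_protocol <- function(x, ...) {
  cat(sprintf("sd_protocol <%s>", x$type))
  if (x$type == "perfusion")
    cat(sprintf(": K_bath %g -> %g mM at t = %g ms",
                x$cpar[["K_base"]], x$cpar[["K_high"]], x$cpar[["t_on"]]))
  if (x$type == "ogd")
    cat(sprintf(": ramps %g ms, hold %g ms from t = %g ms",
                x$cpar[["ramp"]], x$cpar[["hold"]], x$cpar[["t_on"]]))
  if (x$uptake_fraction != 1)
    cat(sprintf("; uptake fraction %.3g", x$uptake_fraction))
  cat("\n")
  invisible(x)
}
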