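## Stiff integration of the full model, SD event detection, and scans.

## Pack model + protocol into the flat parameter vector consumed by the
## compiled RHS (src/sdglu.c).  Order must match the #defines there.
sd_c_parms <- function(model, protocol) {
  p <- model$params
  m <- p$morph
  osm0 <- 2 * (p$Na_n0 + p$K_n0)
  c(C_m = p$C_m, g_Na = p$g_Na, g_K = p$g_K, g_Cl_l = p$g_Cl_l,
    g_Na_l = p$g_Na_l, g_K_l = p$g_K_l, phi_gate = p$phi_gate,
    rho_p = p$rho_p, pNa_half = p$pump_Na_half, pNa_slope = p$pump_Na_slope,
    pK_half = p$pump_K_half, pK_slope = p$pump_K_slope,
    lam_glia = p$lambda_glia, B_glia = p$B_glia,
    glia_K_half = p$glia_K_half, glia_K_slope = p$glia_K_slope,
    K_e_rest = p$K_e0, lam_bath = p$lambda_bath,
    L_n = m$omega_n0 / (osm0 * p$tau_osm),
    L_g = m$omega_g0 / (osm0 * p$tau_osm),
    A_n = p$A_n, A_g = p$A_g, A_e = p$A_e,
    omega_tot = m$omega_tot, omega_e0 = m$omega_e0, omega_en = m$omega_en,
    diff_coef = m$A_sigma * p$D_G / p$dx,
    N_half = m$N_syn / 2,
    gamma_n = m$A_m_n * sd_constants()$flux_per_current,
    R_max = p$R_max, V_cr = p$V_cr, V_hi = p$V_hi, N_max = p$N_max,
    k_rec = p$k_rec,
    literal_rec = as.numeric(isTRUE(p$literal_recycling)),
    clamp_rel = as.numeric(isTRUE(p$clamp_release)),
    g_NMDA = p$g_NMDA, g_AMPA = p$g_AMPA,
    aN = p$alpha_NMDA, bN = p$beta_NMDA,
    aA = p$alpha_AMPA, bA = p$beta_AMPA, Mg = p$Mg,
    v_cn_max = p$v_cn_max, k_m = p$k_m,
    K_g_rest = p$K_g_rest, phi = sd_constants()$phi,
    protocol$cpar, Cl_bath0 = p$Cl_e0)
}

.aux_names <- c("G_c", "G_e", "E_Na", "E_K", "E_Cl", "I_p", "omega_e",
                "dNK")

#' Simulate the SD model
#'
#' Adaptive stiff integration (deSolve, lsoda) of the full model under a
#' protocol, using the compiled right-hand side.  The integration is
#' deterministic: identical inputs give identical trajectories.
#'
#' @param object An `sd_model`.
#' @param nsim Unused (simulate generic signature).
#' @param seed Unused (the model is deterministic); kept for the generic.
#' @param protocol An `sd_protocol` (default: high-K+ perfusion).
#' @param t_end End time (ms).
#' @param dt Output sampling interval (ms), decoupled from solver steps.
#' @param initial Optional initial state (default: the calibrated rest).
#' @param rtol,atol Solver tolerances.
#' @param hmax Maximal internal step (ms).  Fixed by default so that the
#'   solution does not depend on the output sampling grid (lsoda
#'   otherwise caps its step at the output interval).
#' @param use_compiled Integrate the compiled RHS (default) or the R
#'   reference implementation (slow; used for cross-checks).
#' @param ... Passed on to [deSolve::ode()].
#' @return An object of class `sd_trajectory`: a data.frame with time
#'   (ms), all state variables, and derived series (G_c, G_e, Nernst
#'   potentials, pump current, omega_e, dNK), with the model and protocol
#'   attached as attributes.
#' @export
simulate.sd_model <- function(object, nsim = 1, seed = NULL,
                              protocol = perfusion_protocol(),
                              t_end = 300000, dt = 10,
                              initial = NULL, rtol = 1e-10, atol = 1e-10,
                              hmax = 100, use_compiled = TRUE, ...) {
  model <- object
  y0 <- if (is.null(initial)) model$state0 else initial
  stopifnot(length(y0) == length(.state_names))
  names(y0) <- .state_names
  times <- seq(0, t_end, by = dt)

  if (use_compiled) {
    out <- deSolve::ode(y0, times, func = "sd_derivs",
                        parms = sd_c_parms(model, protocol),
                        dllname = "sdglu", initfunc = "sd_initmod",
                        nout = length(.aux_names), outnames = .aux_names,
                        method = "lsoda", rtol = rtol, atol = atol,
                        hmax = hmax, maxsteps = 500000, ...)
  } else {
    out <- deSolve::ode(y0, times,
                        func = function(t, y, parms) full_rhs(t, y, model,
                                                              protocol),
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol, hmax = hmax,
                        maxsteps = 500000, ...)
    aux <- t(vapply(seq_len(nrow(out)), function(i)
      full_rhs(out[i, 1], out[i, -1][seq_along(.state_names)], model,
               protocol)[[2]][.aux_names],
      numeric(length(.aux_names))))
    out <- cbind(out[, seq_len(length(.state_names) + 1)], aux)
  }

  d <- as.data.frame(out)
  names(d)[1] <- "time"
  m <- model$params$morph
  if (any(d$omega_e <= 0.05 * m$omega_e0))
    warning("volume collapse: omega_e fell below 5% of its resting value",
            call. = FALSE)
  ## completeness check: lsoda returns early on failure
  if (abs(d$time[nrow(d)] - t_end) > dt)
    warning(sprintf("integration stopped early at t = %g ms",
                    d$time[nrow(d)]), call. = FALSE)
  attr(d, "model") <- model
  attr(d, "protocol") <- protocol
  class(d) <- c("sd_trajectory", "data.frame")
  d
}

#' @export
print.sd_trajectory <- function(x, ...) {
  cat(sprintf("sd_trajectory: %d samples, t = %g..%g ms (%s protocol)\n",
              nrow(x), x$time[1], x$time[nrow(x)],
              attr(x, "protocol")$type))
  cat(sprintf("  V in [%.1f, %.1f] mV; K_e up to %.1f mM; G_c up to %.3g mM\n",
              min(x$V), max(x$V), max(1000 * x$K_e / x$omega_e),
              max(x$G_c)))
  invisible(x)
}

#' @export
summary.sd_trajectory <- function(object, ...) {
  ev <- detect_sd_events(object)
  audit <- conservation_audit(object)
  out <- list(events = ev, audit = audit,
              protocol = attr(object, "protocol")$type)
  class(out) <- "summary.sd_trajectory"
  out
}

#' @export
print.summary.sd_trajectory <- function(x, ...) {
  ev <- x$events
  cat(sprintf("SD simulation summary (%s protocol)\n", x$protocol))
  if (is.na(ev$t_depol)) {
    cat("  no SD event detected\n")
  } else {
    cat(sprintf("  depolarization at %.1f s", ev$t_depol / 1000))
    if (ev$recovered)
      cat(sprintf(", repolarization at %.1f s (duration %.1f s)\n",
                  ev$t_repol / 1000, ev$duration / 1000))
    else cat(", no recovery before end of run\n")
  }
  cat(sprintf("  conservation drift (relative): ions %.2e, glutamate %.2e, volume %.2e\n",
              x$audit$ions, x$audit$glutamate, x$audit$volume))
  invisible(x)
}

#' @export
plot.sd_trajectory <- function(x, which = c("V", "ions", "glutamate",
                                            "volumes"), ...) {
  which <- match.arg(which)
  t_s <- x$time / 1000
  if (which == "V") {
    plot(t_s, x$V, type = "l", xlab = "time (s)",
         ylab = "membrane potential (mV)", ...)
  } else if (which == "ions") {
    Ke <- 1000 * x$K_e / x$omega_e
    Nae <- 1000 * x$Na_e / x$omega_e
    matplot(t_s, cbind(Ke, Nae), type = "l", lty = 1,
            xlab = "time (s)", ylab = "ECS concentration (mM)", ...)
    legend("topright", c("K+", "Na+"), lty = 1, col = 1:2, bty = "n")
  } else if (which == "glutamate") {
    matplot(t_s, cbind(x$G_c, x$G_e), type = "l", lty = 1,
            xlab = "time (s)", ylab = "glutamate (mM)", ...)
    legend("topright", c("cleft", "ECS"), lty = 1, col = 1:2, bty = "n")
  } else {
    m <- attr(x, "model")$params$morph
    matplot(t_s, cbind(x$w_n, x$w_g, x$omega_e), type = "l", lty = 1,
            xlab = "time (s)", ylab = "volume (um^3)", ...)
    legend("right", c("neuron", "glia", "ECS"), lty = 1, col = 1:3,
           bty = "n")
  }
  invisible(x)
}

#' Conservation audit of a trajectory
#'
#' Maximal relative drift, over the whole trajectory, of the per-ion
#' closed-system totals (compartments plus bath exports), the weighted
#' glutamate total, and the total volume.
#'
#' @param traj An `sd_trajectory`.
#' @return List with elements `ions`, `glutamate`, `volume` (maximal
#'   relative drift of each audited total).
#' @export
conservation_audit <- function(traj) {
  model <- attr(traj, "model")
  p <- model$params
  m <- p$morph
  rel_drift <- function(series) {
    ref <- series[1]
    max(abs(series - ref)) / abs(ref)
  }
  tot_Na <- traj$Na_n + traj$Na_e + traj$Na_g
  tot_K <- traj$K_n + traj$K_e + traj$K_g + traj$dNK_bath
  tot_Cl <- traj$Cl_n + traj$Cl_e + traj$Cl_g + traj$dNCl_bath
  glu <- (m$N_syn / 2) * (traj$Ni + traj$Nc) + traj$Ne + traj$Nup
  vol <- traj$w_n + traj$w_g + traj$omega_e
  list(ions = max(rel_drift(tot_Na), rel_drift(tot_K), rel_drift(tot_Cl)),
       glutamate = rel_drift(glu),
       volume = rel_drift(vol))
}

#' Detect SD onset and recovery in a voltage trace
#'
#' Depolarization onset is the first time V crosses `depol_threshold` and
#' stays above it for at least `persistence`; repolarization is the first
#' later time V returns within `repol_tol` of the pre-SD baseline (the
#' mean V over `baseline_window` before onset) and stays there for
#' `persistence`.
#'
#' @param traj An `sd_trajectory` (or data.frame with `time` and `V`).
#' @param baseline_window Baseline estimation window before onset (ms).
#' @param depol_threshold Sustained-depolarization threshold (mV).
#' @param persistence Minimal time above threshold to count as sustained
#'   depolarization (ms).
#' @param repol_tol Return tolerance around the baseline (mV).
#' @return List of class `sd_events`: `t_depol`, `t_repol`, `duration`
#'   (ms; NA when absent), `recovered` flag, and `baseline` (mV).
#' @export
detect_sd_events <- function(traj, baseline_window = 5000,
                             depol_threshold = -30, persistence = 5000,
                             repol_tol = 2) {
  t <- traj$time; V <- traj$V
  if (t[length(t)] - t[1] <= baseline_window)
    stop("trajectory shorter than the baseline window", call. = FALSE)
  dt <- stats::median(diff(t))
  need <- max(1L, ceiling(persistence / dt))
  above <- V > depol_threshold
  ## first index where `above` holds for `need` consecutive samples
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  cand <- which(run$values & run$lengths >= need)
  ev <- list(t_depol = NA_real_, t_repol = NA_real_,
             duration = NA_real_, recovered = TRUE, baseline = NA_real_)
  class(ev) <- "sd_events"
  if (!length(cand)) return(ev)           # no SD: trivially recovered
  i0 <- starts[cand[1]]
  ev$t_depol <- t[i0]
  base_idx <- t >= t[i0] - baseline_window & t < t[i0]
  if (!any(base_idx)) base_idx <- seq_len(max(i0 - 1, 1))
  ev$baseline <- mean(V[base_idx])
  ## repolarization: first time V has come back down to the baseline
  ## level (the abrupt drop can cross the +-tol band between samples, so
  ## the criterion is a downward crossing, not a sample inside the band)
  back <- which(V <= ev$baseline + repol_tol &
                  seq_along(V) > ends[cand[1]])
  if (!length(back)) {
    ev$recovered <- FALSE
    return(ev)
  }
  ev$t_repol <- t[back[1]]
  ev$duration <- ev$t_repol - ev$t_depol
  ev$recovered <- TRUE
  ev
}

#' @export
print.sd_events <- function(x, ...) {
  if (is.na(x$t_depol)) {
    cat("no SD event\n")
  } else if (x$recovered) {
    cat(sprintf("SD: depol %.1f s, repol %.1f s, duration %.1f s\n",
                x$t_depol / 1000, x$t_repol / 1000, x$duration / 1000))
  } else {
    cat(sprintf("SD: depol %.1f s, no recovery\n", x$t_depol / 1000))
  }
  invisible(x)
}

#' Scan SD duration against transporter impairment
#'
#' Runs one simulation per uptake fraction (multiplying `v_cn_max`; all
#' four pathway velocities follow) and reports the detected SD duration
#' and recovery flag for each.
#'
#' @param fractions Uptake fractions in [0,1], scanned as given.
#' @param model An `sd_model`.
#' @param protocol Base protocol (default high-K+ perfusion).
#' @param t_end Simulation length per run (ms).
#' @param ... Passed to [simulate.sd_model()].
#' @return data.frame with columns `fraction`, `t_depol`, `t_repol`,
#'   `duration` (ms), `recovered`, `error` (NA or the error message of a
#'   failed run).
#' @export
scan_uptake <- function(fractions, model = sd_model(),
                        protocol = perfusion_protocol(),
                        t_end = 900000, dt = 100, ...) {
  rows <- lapply(fractions, function(fr) {
    res <- tryCatch({
      traj <- simulate(model, protocol = impaired_uptake(protocol, fr),
                       t_end = t_end, dt = dt, ...)
      ev <- detect_sd_events(traj)
      data.frame(fraction = fr, t_depol = ev$t_depol,
                 t_repol = ev$t_repol, duration = ev$duration,
                 recovered = ev$recovered, error = NA_character_)
    }, error = function(e)
      data.frame(fraction = fr, t_depol = NA, t_repol = NA,
                 duration = NA, recovered = NA,
                 error = conditionMessage(e)))
    res
  })
  do.call(rbind, rows)
}

#' Cumulative glutamate uptake decomposed by pathway
#'
#' The four clearance pathways (cleft-to-neuron, cleft-to-glia,
#' ECS-to-neuron, ECS-to-glia) are integrated alongside the state, so the
#' decomposition is exact: the pathway sum minus the recycled amount
#' equals the buffered pool at every sample.
#'
#' @param traj An `sd_trajectory`.
#' @return data.frame with `time` and the four non-decreasing cumulative
#'   series `cleft_neuron`, `cleft_glia`, `ecs_neuron`, `ecs_glia` (fmol).
#' @export
uptake_decomposition <- function(traj) {
  data.frame(time = traj$time,
             cleft_neuron = traj$U_cn, cleft_glia = traj$U_cg,
             ecs_neuron = traj$U_en, ecs_glia = traj$U_eg)
}

#' Slow potassium variable along a trajectory
#'
#' The slow variable is the combined K+ amount removed from the
#' neuron+ECS system by glial buffering and bath exchange,
#' `dNK = dNK_glia + dNK_bath`.  Reports its series and its values at the
#' detected de- and repolarization times against the cycle extrema.
#'
#' @param traj An `sd_trajectory`.
#' @param events Optional precomputed `sd_events`.
#' @return List with `series` (data.frame time, dNK_glia, dNK_bath, dNK),
#'   `at_depol`, `at_repol`, `min`, `max` (fmol; NA without events).
#' @export
slow_variable_series <- function(traj, events = NULL) {
  model <- attr(traj, "model")
  dNK_glia <- traj$K_g - model$params$K_g_rest
  ser <- data.frame(time = traj$time, dNK_glia = dNK_glia,
                    dNK_bath = traj$dNK_bath,
                    dNK = dNK_glia + traj$dNK_bath)
  if (is.null(events)) events <- detect_sd_events(traj)
  res <- list(series = ser, at_depol = NA_real_, at_repol = NA_real_,
              min = NA_real_, max = NA_real_)
  if (!is.na(events$t_depol)) {
    i1 <- which.min(abs(traj$time - events$t_depol))
    res$at_depol <- ser$dNK[i1]
    if (!is.na(events$t_repol)) {
      i2 <- which.min(abs(traj$time - events$t_repol))
      res$at_repol <- ser$dNK[i2]
      cyc <- ser$dNK[traj$time >= events$t_depol - 20000 &
                     traj$time <= events$t_repol + 5000]
      res$min <- min(cyc); res$max <- max(cyc)
    }
  }
  res
}
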