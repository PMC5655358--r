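## Slow-fast phase-space toolkit.
##
## The two slowest processes are glial K+ buffering and bath K+ exchange;
## their combined export dNK = dNK_glia + dNK_bath is the slow variable.
## Freezing the slow variables (and treating cleft glutamate as a
## parameter) defines the fast "transmembrane" subsystem whose fixed-point
## structure guides depolarization and repolarization in the full model.
## Fixed points are found by damped Newton iteration, followed in dNK by
## pseudo-arclength continuation with eigenvalue-based Hopf/fold test
## functions, all on the R reference right-hand side.

## fast-subsystem state: 10 of the full state variables
.fast_idx <- c(1, 2, 3, 4, 5, 6, 7, 8, 16, 17)  # V n h rA rN Na_n K_n Cl_n w_n w_g
.fast_names <- c("V", "n", "h", "rA", "rN", "Na_n", "K_n", "Cl_n",
                 "w_n", "w_g")

## Membrane potential and the neuron's net ionic charge are redundant:
## C_m dV/dt equals the net charge flux, so along any trajectory
## V = V_rest + (dNa_n + dK_n - dCl_n)/(gamma_n C_m) exactly.  Root
## finding and continuation therefore work on the 9 remaining variables
## with V derived (otherwise the Jacobian is structurally singular).
.red_names <- c("n", "h", "rA", "rN", "Na_n", "K_n", "Cl_n", "w_n", "w_g")

.gamma_n <- function(model)
  model$params$morph$A_m_n * sd_constants()$flux_per_current

## V from neuron ion amounts via the charge relation
.v_from_amounts <- function(model, Na_n, K_n, Cl_n) {
  p <- model$params
  s0 <- model$state0
  q <- (Na_n - s0[["Na_n"]]) + (K_n - s0[["K_n"]]) - (Cl_n - s0[["Cl_n"]])
  p$V_rest + q / (.gamma_n(model) * p$C_m)
}

.red_to_fast <- function(x9, model) {
  x9 <- setNames(as.numeric(x9), .red_names)
  c(V = .v_from_amounts(model, x9[["Na_n"]], x9[["K_n"]], x9[["Cl_n"]]),
    x9)
}

## characteristic scales for Newton damping / finite differences.
## Amount scales are deliberately small: through the charge relation a
## 1 fmol net change moves V by ~160 mV.
.red_scales <- function(model) {
  c(n = 1, h = 1, rA = 1, rN = 1,
    Na_n = 10, K_n = 10, Cl_n = 10,
    w_n = unname(model$state0["w_n"]) / 50,
    w_g = unname(model$state0["w_g"]) / 50)
}

## reduced 9-dim RHS (V eliminated).  The compiled RHS is used directly:
## none of the 10 fast components involves the glial/bath fluxes that the
## clamp disables, so the raw derivatives on the assembled state equal the
## clamped reference values (asserted in the test suite).
.red_rhs <- function(x9, model, clamp) {
  y <- fast_to_full(.red_to_fast(x9, model), model, clamp)
  cp <- .bif_parms(model)
  dy <- .Call("sd_rhs_eval", 0.0, as.numeric(y), cp, PACKAGE = "sdglu")
  setNames(dy[.fast_idx][-1], .red_names)
}

## cached C parameter vector for clamped evaluations (null protocol)
.bif_parms <- function(model) {
  env <- model$env
  if (is.null(env)) return(sd_c_parms(model, .null_protocol()))
  if (is.null(env$bif_parms))
    env$bif_parms <- sd_c_parms(model, .null_protocol())
  env$bif_parms
}

.red_jacobian <- function(x9, model, clamp, sc = .red_scales(model)) {
  n <- length(x9)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hstep <- 1e-7 * sc[j]
    xp <- x9; xm <- x9
    xp[j] <- xp[j] + hstep
    xm[j] <- xm[j] - hstep
    J[, j] <- (.red_rhs(xp, model, clamp) -
                 .red_rhs(xm, model, clamp)) / (2 * hstep)
  }
  dimnames(J) <- list(.red_names, .red_names)
  J
}

#' Assemble a full model state from a fast-subsystem state and clamps
#'
#' ECS ion amounts are derived from the closed-system totals given the
#' clamped slow exports; glial K+/Cl- carry the clamped buffer content;
#' cleft glutamate is fixed at the clamped concentration with the other
#' glutamate pools empty.
#'
#' @param fast Named numeric vector of the 10 fast variables (`V`, `n`,
#'   `h`, `rA`, `rN`, `Na_n`, `K_n`, `Cl_n`, `w_n`, `w_g`).
#' @param model `sd_model`.
#' @param clamp List with `dNK_glia`, `dNK_bath` (fmol), `G_c` (mM), and
#'   optionally `dNCl_bath` (fmol, default 0: no net Cl- exchanged with
#'   the bath).
#' @return Full named state vector.
#' @export
fast_to_full <- function(fast, model, clamp) {
  p <- model$params
  s <- model$state0
  fast <- setNames(as.numeric(fast), .fast_names)
  dNCl_bath <- if (is.null(clamp$dNCl_bath)) 0 else clamp$dNCl_bath
  s[.fast_names] <- fast
  s["K_g"] <- p$K_g_rest + clamp$dNK_glia
  s["Cl_g"] <- model$state0["Cl_g"] + clamp$dNK_glia
  s["Na_g"] <- model$state0["Na_g"]
  s["dNK_bath"] <- clamp$dNK_bath
  s["Na_e"] <- p$tot_Na - fast["Na_n"] - s["Na_g"]
  s["K_e"] <- p$tot_K - fast["K_n"] - s["K_g"] - clamp$dNK_bath
  s["Cl_e"] <- p$tot_Cl - fast["Cl_n"] - s["Cl_g"] - dNCl_bath
  s["dNCl_bath"] <- dNCl_bath
  s["Nc"] <- clamp$G_c * p$morph$omega_en / 1000
  s["Ni"] <- 0; s["Ne"] <- 0; s["Nup"] <- 0
  s[c("U_cn", "U_cg", "U_en", "U_eg")] <- 0
  s
}

#' Fast-subsystem right-hand side
#'
#' Time derivative of the 10 fast variables with the slow K+ exports and
#' cleft glutamate frozen: identical to the full model with glial/bath
#' fluxes and glutamate pool dynamics disabled.
#'
#' @param fast Named fast-state vector (see \code{\link{fast_to_full}}).
#' @param model `sd_model`.
#' @param clamp Clamp list (`dNK_glia`, `dNK_bath`, `G_c`, optional
#'   `dNCl_bath`).
#' @return Named derivative vector of the fast variables (per ms).
#' @export
fast_subsystem_rhs <- function(fast, model, clamp) {
  y <- fast_to_full(fast, model, clamp)
  dy <- full_rhs(0, y, model, .null_protocol(), clamp = clamp)[[1]]
  dy[.fast_idx]
}

## baseline protocol used for clamped evaluations (all scales 1, K_bath
## at rest; glia/bath fluxes are disabled by the clamp anyway)
.null_protocol <- function() perfusion_protocol(K_high = 4)

#' Find fixed points of the fast subsystem
#'
#' Damped Newton iteration from each seed on the charge-reduced
#' subsystem, with central-difference Jacobians on scaled variables;
#' converged roots are deduplicated and classified by the eigenvalue
#' spectrum.
#'
#' @param model `sd_model`.
#' @param clamp Clamp list (see \code{\link{fast_subsystem_rhs}}).
#' @param seeds List of named fast-state vectors (10 variables; the `V`
#'   entry is recomputed from the charge relation).  Defaults to
#'   \code{\link{default_seeds}}.
#' @param tol Residual tolerance (scaled units).
#' @param max_iter Newton iteration cap.
#' @return List of fixed points, each a list with `state` (named
#'   10-variable fast vector including the derived V), `eig` (eigenvalues
#'   of the reduced Jacobian), `stable`, `residual`.  Empty (with a
#'   warning) if no seed converges.
#' @export
find_fixed_points <- function(model, clamp, seeds = default_seeds(model),
                              tol = 1e-9, max_iter = 60) {
  sc <- .red_scales(model)
  roots <- list()
  for (sd0 in seeds) {
    x9 <- setNames(as.numeric(sd0)[match(.red_names, names(sd0))],
                   .red_names)
    r <- .newton_red(x9, model, clamp, sc, tol, max_iter)
    if (is.null(r)) next
    dup <- any(vapply(roots, function(z)
      max(abs(z$state[.red_names] - r$state[.red_names]) / sc) < 1e-5,
      logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  if (!length(roots))
    warning("no fixed point converged from the given seeds", call. = FALSE)
  roots
}

## damped Newton on the reduced subsystem; returns NULL on failure
.newton_red <- function(x9, model, clamp, sc, tol, max_iter) {
  f <- function(z) tryCatch(.red_rhs(z, model, clamp),
                            error = function(e) rep(NA_real_, length(z)))
  fx <- f(x9)
  if (any(!is.finite(fx))) return(NULL)
  for (it in seq_len(max_iter)) {
    res <- max(abs(fx) / sc)
    if (res < tol) {
      J <- .red_jacobian(x9, model, clamp, sc)
      ev <- eigen(J, only.values = TRUE)$values
      return(list(state = .red_to_fast(x9, model), eig = ev,
                  stable = max(Re(ev)) < 0, residual = res))
    }
    J <- .red_jacobian(x9, model, clamp, sc)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      xn <- x9 + lam * step
      xn[1:4] <- pmin(pmax(xn[1:4], -0.2), 1.2)  # gate box
      fn <- f(xn)
      if (all(is.finite(fn)) &&
          max(abs(fn) / sc) < max(abs(fx) / sc) * (1 - 1e-4 * lam)) break
      lam <- lam / 2
      if (lam < 1e-7) return(NULL)
    }
    x9 <- xn; fx <- fn
  }
  NULL
}

#' Default Newton seeds spanning polarized and depolarized states
#'
#' The polarized seed is the calibrated resting state.  The depolarized
#' seed reproduces the collapsed-gradient composition SD trajectories
#' visit (most K+ out of, Na+ and water into the neuron), with the
#' chloride amount adjusted so the charge relation puts V near -5 mV.
#'
#' @param model `sd_model`.
#' @param V_dep Target potential of the depolarized seed (mV).
#' @return Named list of fast-state vectors (`polarized`,
#'   `depolarized`).
#' @export
default_seeds <- function(model, V_dep = -5) {
  s0 <- model$state0[.fast_names]
  p <- model$params
  dep <- s0
  dNa <- unname(s0["Na_n"]) * 1.8
  dK <- -unname(s0["K_n"]) * 0.43
  dCl <- dNa + dK - .gamma_n(model) * p$C_m * (V_dep - p$V_rest)
  dep["Na_n"] <- s0["Na_n"] + dNa
  dep["K_n"] <- s0["K_n"] + dK
  dep["Cl_n"] <- max(unname(s0["Cl_n"]) + dCl, 1)
  ## recompute the actually implied V (Cl floor may bind)
  dep["V"] <- .v_from_amounts(model, dep[["Na_n"]], dep[["K_n"]],
                              dep[["Cl_n"]])
  g <- hh_inf(dep[["V"]])
  dep["n"] <- 0.8; dep["h"] <- g[["h"]]
  dep["rA"] <- 0; dep["rN"] <- 0
  dep["w_n"] <- unname(s0["w_n"]) * 1.05
  list(polarized = s0, depolarized = dep)
}

#' Continue a fixed-point branch in the slow variable
#'
#' Pseudo-arclength continuation of a fast-subsystem fixed point as
#' `dNK = dNK_glia + dNK_bath` varies (the glial share stays at its
#' clamped value; the bath share absorbs the parameter change).  At each
#' accepted point the reduced Jacobian spectrum is recorded; a marker is
#' placed where the leading eigenvalue crosses the imaginary axis,
#' refined by bisection and classified as Hopf (complex pair) or fold
#' (real eigenvalue).
#'
#' @param start_fp A converged fixed point from
#'   \code{\link{find_fixed_points}}.
#' @param model `sd_model`.
#' @param clamp Clamp list giving `dNK_glia`, `G_c`, optional
#'   `dNCl_bath`.
#' @param dNK_start Slow-variable value at `start_fp`
#'   (`clamp$dNK_glia + clamp$dNK_bath`).
#' @param dNK_range Numeric length-2: interval to cover; continuation
#'   starts toward `dNK_range[2]`.
#' @param ds Initial arclength step (scaled units).
#' @param ds_max,ds_min Step bounds.
#' @param max_points Cap on accepted branch points.
#' @return Object of class `sd_branch`: data.frame `points` (dNK, V, the
#'   fast variables, max_re_eig, stable) ordered along the branch, and
#'   list `markers` (type, dNK, V).
#' @export
continue_branch <- function(start_fp, model, clamp, dNK_start,
                            dNK_range, ds = 2, ds_max = 10, ds_min = 1e-5,
                            max_points = 600) {
  sc <- .red_scales(model)
  p_sc <- 25                      # dNK scale, fmol
  nf <- length(.red_names)
  scl <- c(sc, p_sc)

  make_clamp <- function(dNK) {
    cl <- clamp
    cl$dNK_bath <- dNK - clamp$dNK_glia
    cl
  }
  F <- function(x, dNK) .red_rhs(x, model, make_clamp(dNK))
  spec <- function(x, dNK)
    eigen(.red_jacobian(x, model, make_clamp(dNK), sc),
          only.values = TRUE)$values

  solve_point <- function(xg, dNKg, xref, dNKref, tang, ds) {
    x <- xg; dNK <- dNKg
    for (it in 1:30) {
      fx <- tryCatch(F(x, dNK), error = function(e) NULL)
      if (is.null(fx) || any(!is.finite(fx))) return(NULL)
      arc <- sum((c(x, dNK) - c(xref, dNKref)) / scl * tang) - ds
      if (max(abs(fx) / sc) < 1e-11 && abs(arc) < 1e-7)
        return(list(x = x, dNK = dNK))
      J <- .red_jacobian(x, model, make_clamp(dNK), sc)
      hp <- 0.25
      dFdp <- (F(x, dNK + hp) - F(x, dNK - hp)) / (2 * hp)
      A <- rbind(cbind(J, dFdp), tang / scl)
      step <- tryCatch(solve(A, -c(fx, arc)), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) return(NULL)
      x <- x + step[seq_len(nf)]
      dNK <- dNK + step[nf + 1]
      if (max(abs(step[seq_len(nf)] / sc)) > 50) return(NULL)
    }
    NULL
  }

  x <- setNames(as.numeric(start_fp$state[.red_names]), .red_names)
  dNK <- dNK_start
  ev <- spec(x, dNK)
  pts <- list(list(x = x, dNK = dNK, eig = ev))
  markers <- list()

  dirn <- sign(dNK_range[2] - dNK_start)
  if (dirn == 0) dirn <- 1
  tang <- c(rep(0, nf), dirn)

  for (k in seq_len(max_points)) {
    ok <- NULL
    dstry <- ds
    while (is.null(ok) && dstry >= ds_min) {
      xg <- x + tang[seq_len(nf)] * dstry * sc
      dg <- dNK + tang[nf + 1] * dstry * p_sc
      ok <- solve_point(xg, dg, x, dNK, tang, dstry)
      if (is.null(ok)) dstry <- dstry / 2
    }
    if (is.null(ok)) break               # step collapse: truncate branch
    ds <- dstry
    ev_new <- spec(ok$x, ok$dNK)
    re_old <- max(Re(ev)); re_new <- max(Re(ev_new))
    if (is.finite(re_old) && is.finite(re_new) &&
        sign(re_old) != sign(re_new)) {
      mk <- .refine_marker(solve_point, spec, list(x = x, dNK = dNK),
                           list(x = ok$x, dNK = ok$dNK), tang, ds, sc,
                           model)
      if (!is.null(mk)) markers[[length(markers) + 1L]] <- mk
    }
    tang_new <- (c(ok$x, ok$dNK) - c(x, dNK)) / scl
    nrm <- sqrt(sum(tang_new^2))
    if (nrm > 0) tang <- tang_new / nrm
    x <- ok$x; dNK <- ok$dNK; ev <- ev_new
    pts[[length(pts) + 1L]] <- list(x = x, dNK = dNK, eig = ev)
    ds <- min(ds * 1.4, ds_max)
    if (dNK > max(dNK_range) || dNK < min(dNK_range)) break
  }

  df <- do.call(rbind, lapply(pts, function(z) {
    data.frame(dNK = z$dNK,
               V = .v_from_amounts(model, z$x[["Na_n"]], z$x[["K_n"]],
                                   z$x[["Cl_n"]]),
               t(z$x), max_re_eig = max(Re(z$eig)),
               stable = max(Re(z$eig)) < 0)
  }))
  br <- list(points = df, markers = markers, clamp = clamp,
             dNK_range = dNK_range)
  class(br) <- "sd_branch"
  br
}

## bisection refinement of a stability-change marker between consecutive
## accepted branch points a (old sign) and b (new sign)
.refine_marker <- function(solve_point, spec, a, b, tang, ds, sc, model) {
  ev_a <- spec(a$x, a$dNK)
  sgn_a <- sign(max(Re(ev_a)))
  for (i in 1:30) {
    m <- solve_point((a$x + b$x) / 2, (a$dNK + b$dNK) / 2,
                     a$x, a$dNK, tang, ds / 2)
    if (is.null(m)) break
    ev_m <- spec(m$x, m$dNK)
    if (sign(max(Re(ev_m))) == sgn_a) a <- m else b <- m
    ds <- ds / 2
    if (abs(b$dNK - a$dNK) < 1e-7) break
  }
  ev_b <- spec(b$x, b$dNK)
  i <- which.max(Re(ev_b))
  list(type = if (abs(Im(ev_b[i])) > 1e-10) "hopf" else "fold",
       dNK = (a$dNK + b$dNK) / 2,
       V = .v_from_amounts(model, b$x[["Na_n"]], b$x[["K_n"]],
                           b$x[["Cl_n"]]))
}

#' @export
print.sd_branch <- function(x, ...) {
  df <- x$points
  cat(sprintf("sd_branch: %d points, dNK in [%.1f, %.1f] fmol\n",
              nrow(df), min(df$dNK), max(df$dNK)))
  cat(sprintf("  V in [%.1f, %.1f] mV; %d/%d stable points\n",
              min(df$V), max(df$V), sum(df$stable), nrow(df)))
  for (m in x$markers)
    cat(sprintf("  %s marker at dNK = %.2f fmol (V = %.2f mV)\n",
                m$type, m$dNK, m$V))
  invisible(x)
}

#' Ends of the stable depolarized and polarized branches at one G_c
#'
#' Finds the depolarized branch from a settled depolarized state at low
#' dNK and follows it upward to the stability loss that terminates it;
#' finds the polarized branch at high dNK and follows it downward to the
#' stability loss that marks its beginning.
#'
#' @param model `sd_model`.
#' @param G_c Cleft glutamate clamp (mM).
#' @param dNK_glia Clamped glial share of the slow variable (fmol).
#' @param dNK_range Continuation range (fmol).
#' @param dNCl_bath Clamped bath Cl- export (fmol).
#' @param seeds_at List with `polarized` and `depolarized` starting dNK
#'   values (fmol).
#' @return List `depol_end`, `polar_start` (fmol; NA when the branch or
#'   its stability change is not found), plus the two branches.
#' @export
branch_ends <- function(model, G_c, dNK_glia = 200,
                        dNK_range = c(-150, 1200), dNCl_bath = 0,
                        seeds_at = list(polarized = 900,
                                        depolarized = 100)) {
  res <- list(depol_end = NA_real_, polar_start = NA_real_,
              depol_branch = NULL, polar_branch = NULL)

  cl_dep <- list(dNK_glia = dNK_glia,
                 dNK_bath = seeds_at$depolarized - dNK_glia,
                 G_c = G_c, dNCl_bath = dNCl_bath)
  fp_dep <- settled_fixed_point(model, cl_dep, depolarized = TRUE)
  if (!is.null(fp_dep) && fp_dep$stable) {
    br <- continue_branch(fp_dep, model, cl_dep,
                          dNK_start = seeds_at$depolarized,
                          dNK_range = c(min(dNK_range), max(dNK_range)))
    res$depol_branch <- br
    mks <- br$markers
    vs <- vapply(mks, function(m) m$V, numeric(1))
    dep <- which(vs >= -45)
    res$depol_end <- if (length(dep)) mks[[dep[1]]]$dNK else
      .stability_change(br)
  }

  cl_pol <- list(dNK_glia = dNK_glia,
                 dNK_bath = seeds_at$polarized - dNK_glia,
                 G_c = G_c, dNCl_bath = dNCl_bath)
  fp_pol <- settled_fixed_point(model, cl_pol, depolarized = FALSE)
  if (!is.null(fp_pol) && fp_pol$stable) {
    br <- continue_branch(fp_pol, model, cl_pol,
                          dNK_start = seeds_at$polarized,
                          dNK_range = c(max(dNK_range), min(dNK_range)))
    res$polar_branch <- br
    res$polar_start <- .stability_change(br)
  }
  res
}

## dNK of the first stability change along a branch (marker if refined,
## else the last stable point before the first unstable one)
.stability_change <- function(br) {
  if (length(br$markers)) return(br$markers[[1]]$dNK)
  df <- br$points
  if (all(df$stable) || !df$stable[1]) return(NA_real_)
  i <- which(!df$stable)[1]
  df$dNK[i - 1]
}

#' Settle the fast subsystem to a fixed point by integration + Newton
#'
#' Integrates the charge-reduced fast subsystem from the polarized or
#' depolarized default seed until transients die out, then polishes with
#' Newton.  Returns NULL when no fixed point of the requested kind is
#' found (e.g. the branch does not exist at these clamps).
#'
#' @param model `sd_model`.
#' @param clamp Clamp list.
#' @param depolarized Seek the depolarized (TRUE) or polarized state.
#' @param t_settle Integration time (ms).
#' @return A fixed point (as in \code{\link{find_fixed_points}}) or NULL.
#' @export
settled_fixed_point <- function(model, clamp, depolarized,
                                t_settle = 30000) {
  seeds <- default_seeds(model)
  x0 <- if (depolarized) seeds$depolarized else seeds$polarized
  x9 <- setNames(as.numeric(x0)[match(.red_names, names(x0))], .red_names)
  ## large clamped exports must come out of the neuron: exchange neuronal
  ## K+ for ECS Na+ (charge- and osmotically neutral) until the implied
  ## ECS K+ amount is positive
  full <- fast_to_full(.red_to_fast(x9, model), model, clamp)
  w_e <- model$params$morph$omega_tot - full[["w_n"]] - full[["w_g"]]
  deficit <- 2 * w_e / 1000 - full[["K_e"]]   # keep K_e above ~2 mM
  if (deficit > 0) {
    move <- min(deficit, x9[["K_n"]] * 0.8, full[["Na_e"]] * 0.8)
    x9[["K_n"]] <- x9[["K_n"]] - move
    x9[["Na_n"]] <- x9[["Na_n"]] + move
  }
  rhs <- function(t, z, parms)
    list(as.numeric(.red_rhs(setNames(z, .red_names), model, clamp)))
  out <- tryCatch(
    deSolve::ode(unname(x9), c(0, t_settle), rhs, NULL, method = "lsoda",
                 rtol = 1e-8, atol = 1e-6, maxsteps = 100000),
    error = function(e) NULL)
  if (!is.null(out) && nrow(out) == 2)
    x9 <- setNames(as.numeric(out[2, -1]), .red_names)
  fps <- suppressWarnings(
    find_fixed_points(model, clamp, seeds = list(.red_to_fast(x9, model)),
                      tol = 1e-12))
  if (!length(fps)) return(NULL)
  fp <- fps[[1]]
  if (depolarized && fp$state[["V"]] < -40) return(NULL)
  if (!depolarized && fp$state[["V"]] > -40) return(NULL)
  fp
}

#' Hopf loci of the two branches over a grid of cleft glutamate levels
#'
#' Scans G_c, recording where the stable depolarized branch ends and the
#' stable polarized branch begins.  Repolarization requires overlap
#' (depolarized end beyond polarized start); the critical G_c where the
#' overlap vanishes is refined by the secant method on the overlap gap.
#'
#' @inheritParams branch_ends
#' @param G_c_grid Cleft glutamate levels (mM).
#' @return List with `loci` (data.frame: G_c, dNK_depol_end,
#'   dNK_polar_start, overlap) and `critical_G_c` (mM; NA if the overlap
#'   never changes sign on the grid).
#' @export
hopf_loci <- function(model, G_c_grid = c(0.0001, 0.005, 0.01, 0.02,
                                          0.035, 0.05, 0.1),
                      dNK_glia = 200, dNK_range = c(-150, 1200),
                      dNCl_bath = 0,
                      seeds_at = list(polarized = 900,
                                      depolarized = 100)) {
  one <- function(gc) {
    e <- branch_ends(model, gc, dNK_glia, dNK_range, dNCl_bath, seeds_at)
    c(e$depol_end, e$polar_start)
  }
  rows <- t(vapply(G_c_grid, one, numeric(2)))
  loci <- data.frame(G_c = G_c_grid, dNK_depol_end = rows[, 1],
                     dNK_polar_start = rows[, 2])
  ## three-valued overlap: TRUE (both branch ends found, depolarized end
  ## beyond polarized start, or polarized branch stable over the whole
  ## range), FALSE (both found, no overlap), NA (a branch could not be
  ## resolved at this G_c)
  status <- function(de, ps) {
    if (!is.finite(de) && !identical(ps, -Inf)) return(NA)
    if (is.na(ps)) return(NA)
    isTRUE(de > ps) || identical(ps, -Inf)
  }
  has_overlap <- mapply(status, rows[, 1], rows[, 2])
  loci$overlap <- has_overlap
  crit <- NA_real_
  yes <- which(has_overlap %in% TRUE)
  no <- which(has_overlap %in% FALSE)
  if (length(yes) && length(no) && max(yes) < min(no)) {
    g1 <- G_c_grid[max(yes)]      # overlap present
    g2 <- G_c_grid[min(no)]       # overlap gone
    for (k in 1:10) {
      gm <- (g1 + g2) / 2
      em <- one(gm)
      ov <- status(em[1], em[2])
      if (is.na(ov)) {            # unresolved probe: nudge and retry
        em <- one(g1 + 0.45 * (g2 - g1))
        ov <- status(em[1], em[2])
        if (is.na(ov)) break
      }
      if (isTRUE(ov)) g1 <- gm else g2 <- gm
      if (g2 - g1 < 5e-4) break
    }
    crit <- (g1 + g2) / 2
  }
  list(loci = loci, critical_G_c = crit)
}

#' Fixed points of the membrane-only subsystem
#'
#' With all ion concentrations (hence reversal potentials and the pump
#' current) held as parameters, the membrane model reduces to (V, gates);
#' at a fixed point the gates sit at their steady-state values, so roots
#' are located by a dense scan + bisection of the scalar total-current
#' balance in V.  Stability comes from the 5x5 Jacobian of (V, n, h, rA,
#' rN).  Also reports whether a stable fixed point below E_K (pump-driven
#' hyperpolarization) exists, and the residual of the leak-only balance
#' at that point.
#'
#' @param ion_config Named list/vector with concentrations `Na_n`, `K_n`,
#'   `Cl_n`, `Na_e`, `K_e`, `Cl_e` (mM).
#' @param G_c Cleft glutamate (mM).
#' @param model `sd_model` (supplies conductances and pump parameters).
#' @param V_range Scan interval (mV).
#' @param n_grid Scan resolution.
#' @return List with `fixed_points` (data.frame V, stable, below_E_K),
#'   `E_K`, `has_hyperpolarized` flag, and `leak_residual_rel` (residual
#'   of the leak+pump-only current balance at the most polarized stable
#'   fixed point, relative to the total current scale).
#' @export
membrane_fixed_points <- function(ion_config, G_c, model,
                                  V_range = c(-200, 20), n_grid = 2000) {
  p <- model$params
  ic <- as.list(ion_config)
  E_Na <- nernst(1, ic$Na_n, ic$Na_e)
  E_K <- nernst(1, ic$K_n, ic$K_e)
  E_Cl <- nernst(-1, ic$Cl_n, ic$Cl_e)
  I_p <- pump_current(ic$Na_n, ic$K_e, 1, p)
  rA_inf <- G_c * p$alpha_AMPA / (G_c * p$alpha_AMPA + p$beta_AMPA)
  rN_inf <- G_c * p$alpha_NMDA / (G_c * p$alpha_NMDA + p$beta_NMDA)

  I_total <- function(V) {
    g <- hh_inf(V)
    rec <- receptor_currents(V, rN_inf, rA_inf, E_Na, E_K, p)
    p$g_Na * g[["m"]]^3 * g[["h"]] * (V - E_Na) + p$g_Na_l * (V - E_Na) +
      3 * I_p + rec[["I_Na_AMPA"]] + rec[["I_Na_NMDA"]] +
      p$g_K * g[["n"]]^4 * (V - E_K) + p$g_K_l * (V - E_K) - 2 * I_p +
      rec[["I_K_AMPA"]] + rec[["I_K_NMDA"]] +
      p$g_Cl_l * (V - E_Cl)
  }
  Vs <- seq(V_range[1], V_range[2], length.out = n_grid)
  Is <- vapply(Vs, I_total, numeric(1))
  sgn <- sign(Is)
  roots <- c()
  for (i in which(diff(sgn) != 0)) {
    r <- stats::uniroot(I_total, c(Vs[i], Vs[i + 1]), tol = 1e-10)
    roots <- c(roots, r$root)
  }
  if (!length(roots))
    return(list(fixed_points = data.frame(V = numeric(0),
                                          stable = logical(0),
                                          below_E_K = logical(0)),
                E_K = E_K, has_hyperpolarized = FALSE,
                leak_residual_rel = NA_real_))

  ## stability via the (V, n, h, rA, rN) Jacobian
  memb_rhs <- function(y) {
    V <- y[1]; n <- y[2]; h <- y[3]; rA <- y[4]; rN <- y[5]
    m_inf <- alpha_m(V) / (alpha_m(V) + beta_m(V))
    rec <- receptor_currents(V, rN, rA, E_Na, E_K, p)
    I_Na <- p$g_Na * m_inf^3 * h * (V - E_Na) + p$g_Na_l * (V - E_Na) +
      3 * I_p + rec[["I_Na_AMPA"]] + rec[["I_Na_NMDA"]]
    I_K <- p$g_K * n^4 * (V - E_K) + p$g_K_l * (V - E_K) - 2 * I_p +
      rec[["I_K_AMPA"]] + rec[["I_K_NMDA"]]
    I_Cl <- p$g_Cl_l * (V - E_Cl)
    c(-(I_Na + I_K + I_Cl) / p$C_m,
      p$phi_gate * (alpha_n(V) * (1 - n) - beta_n(V) * n),
      p$phi_gate * (alpha_h(V) * (1 - h) - beta_h(V) * h),
      receptor_gate_rhs(G_c, rA, p$alpha_AMPA, p$beta_AMPA),
      receptor_gate_rhs(G_c, rN, p$alpha_NMDA, p$beta_NMDA))
  }
  stab <- vapply(roots, function(V) {
    g <- hh_inf(V)
    y0 <- c(V, g[["n"]], g[["h"]], rA_inf, rN_inf)
    J <- matrix(0, 5, 5)
    hstep <- c(1e-4, 1e-7, 1e-7, 1e-7, 1e-7)
    for (j in 1:5) {
      yp <- y0; ym <- y0
      yp[j] <- yp[j] + hstep[j]; ym[j] <- ym[j] - hstep[j]
      J[, j] <- (memb_rhs(yp) - memb_rhs(ym)) / (2 * hstep[j])
    }
    max(Re(eigen(J, only.values = TRUE)$values)) < 0
  }, logical(1))

  fp <- data.frame(V = roots, stable = stab, below_E_K = roots < E_K)
  hyp <- fp$stable & fp$below_E_K
  leak_res <- NA_real_
  if (any(fp$stable)) {
    Vh <- min(fp$V[fp$stable])
    leak_only <- p$g_K_l * (Vh - E_K) + p$g_Na_l * (Vh - E_Na) +
      p$g_Cl_l * (Vh - E_Cl) + I_p
    scale <- abs(p$g_K_l * (Vh - E_K)) + abs(p$g_Na_l * (Vh - E_Na)) +
      abs(p$g_Cl_l * (Vh - E_Cl)) + abs(I_p)
    leak_res <- abs(leak_only) / scale
  }
  list(fixed_points = fp, E_K = E_K, has_hyperpolarized = any(hyp),
       leak_residual_rel = leak_res)
}

#' Critical G_c for the membrane-only hyperpolarized state
#'
#' Bisection in G_c for the level beyond which the membrane model (at
#' the supplied ion configuration) loses its stable fixed point below
#' E_K.
#'
#' @param ion_config As in \code{\link{membrane_fixed_points}}.
#' @param model `sd_model`.
#' @param G_range Bracketing interval (mM).
#' @param tol Bisection tolerance (mM).
#' @return Critical G_c (mM), or NA if the state exists on the whole
#'   interval or at neither end.
#' @export
membrane_critical_gc <- function(ion_config, model,
                                 G_range = c(1e-4, 0.5), tol = 5e-4) {
  has <- function(gc) membrane_fixed_points(ion_config, gc,
                                            model)$has_hyperpolarized
  lo <- G_range[1]; hi <- G_range[2]
  if (!has(lo) || has(hi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
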