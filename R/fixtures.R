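## Deterministic test fixtures: synthetic voltage traces with known event
## times, a two-dimensional system with an analytic Hopf bifurcation, and
## batches of random valid model states for conservation audits.

#' Generate test fixtures
#'
#' @param kind One of `"trapezoid_trace"` (synthetic voltage trace:
#'   baseline, linear ramp up, depolarized plateau, ramp down),
#'   `"toy_hopf_system"` (2-D normal form with eigenvalues `mu +- i`),
#'   `"random_states"` (valid random perturbations of the resting state).
#' @param ... Kind-specific arguments, see Details.
#' @return See Details.
#'
#' @details
#' `trapezoid_trace(baseline = -70, plateau_V = -10, plateau_ms = 80000,
#' ramp_ms = 2000, t_end = 200000, dt = 10, t_on = 50000)` returns a
#' data.frame (`time`, `V`) whose true depolarization onset is the upward
#' crossing of any threshold between baseline and plateau during
#' `[t_on, t_on + ramp_ms]` and whose return to baseline is at
#' `t_on + ramp_ms + plateau_ms + ramp_ms`.
#'
#' `toy_hopf_system(mu)` returns a list with `rhs(t, y)` implementing
#' `dx = mu*x - y - x*(x^2+y^2)`, `dy = x + mu*y - y*(x^2+y^2)` (scaled
#' supercritical Hopf normal form; the origin's Jacobian eigenvalues are
#' exactly `mu +- i`) and `jacobian(y)`.
#'
#' `random_states(n = 100, seed = 1, model = sd_model())` returns a list
#' of `n` valid full state vectors: multiplicative log-uniform
#' perturbations of the resting state with gates resampled in [0,1].
#' @export
make_fixtures <- function(kind = c("trapezoid_trace", "toy_hopf_system",
                                   "random_states"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         trapezoid_trace = trapezoid_trace(...),
         toy_hopf_system = toy_hopf_system(...),
         random_states = random_states(...))
}

#' @rdname make_fixtures
#' @param baseline,plateau_V,plateau_ms,ramp_ms,t_end,dt,t_on Trapezoid
#'   trace geometry (mV / ms).
#' @export
trapezoid_trace <- function(baseline = -70, plateau_V = -10,
                            plateau_ms = 80000, ramp_ms = 2000,
                            t_end = 200000, dt = 10, t_on = 50000) {
  t <- seq(0, t_end, dt)
  t1 <- t_on; t2 <- t_on + ramp_ms
  t3 <- t2 + plateau_ms; t4 <- t3 + ramp_ms
  up <- baseline + (plateau_V - baseline) * (t - t1) / ramp_ms
  dn <- plateau_V + (baseline - plateau_V) * (t - t3) / ramp_ms
  V <- ifelse(t < t1, baseline,
       ifelse(t < t2, up,
       ifelse(t < t3, plateau_V,
       ifelse(t < t4, dn, baseline))))
  structure(data.frame(time = t, V = V),
            events = list(t_up = t1, t_plateau = t2, t_down = t3,
                          t_back = t4))
}

#' @rdname make_fixtures
#' @param mu Bifurcation parameter of the toy system.
#' @export
toy_hopf_system <- function(mu = 0) {
  list(
    mu = mu,
    rhs = function(t, y) {
      r2 <- sum(y^2)
      c(mu * y[1] - y[2] - y[1] * r2,
        y[1] + mu * y[2] - y[2] * r2)
    },
    jacobian = function(y = c(0, 0)) {
      r2 <- sum(y^2)
      matrix(c(mu - 3 * y[1]^2 - y[2]^2, 1 - 2 * y[1] * y[2],
               -1 - 2 * y[1] * y[2], mu - y[1]^2 - 3 * y[2]^2),
             2, 2)
    })
}

#' @rdname make_fixtures
#' @param n Number of random states.
#' @param seed RNG seed (fixed for reproducibility).
#' @param model `sd_model` providing the reference resting state.
#' @param spread Log-uniform half-width of the multiplicative
#'   perturbation.
#' @export
random_states <- function(n = 100, seed = 1, model = sd_model(),
                          spread = 0.15) {
  set.seed(seed)
  s0 <- model$state0
  lapply(seq_len(n), function(i) {
    y <- s0 * exp(stats::runif(length(s0), -spread, spread))
    y["V"] <- stats::runif(1, -90, 20)
    y[c("n", "h", "rA", "rN")] <- stats::runif(4)
    y["dNK_bath"] <- stats::runif(1, -50, 300)
    y[c("U_cn", "U_cg", "U_en", "U_eg", "dNCl_bath")] <- 0
    y
  })
}

#' Locate an eigenvalue crossing of the imaginary axis by bisection
#'
#' Generic helper used for Hopf detection on parametrized systems: given
#' a function returning the Jacobian spectrum at a parameter value,
#' bisects the sign change of the leading real part.
#'
#' @param spec_fun Function of the scalar parameter returning a vector of
#'   (complex) eigenvalues.
#' @param lo,hi Bracketing parameter values (leading real parts must
#'   differ in sign).
#' @param tol Bisection tolerance on the parameter.
#' @return List with `value` (parameter at the crossing), `type`
#'   (`"hopf"` if the leading eigenvalue pair is complex, else
#'   `"fold"`).
#' @export
locate_eig_crossing <- function(spec_fun, lo, hi, tol = 1e-10) {
  f <- function(p) max(Re(spec_fun(p)))
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi))
    stop("leading eigenvalue real part does not change sign on [lo, hi]",
         call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(flo)) lo <- mid else hi <- mid
  }
  p <- (lo + hi) / 2
  ev <- spec_fun(p)
  i <- which.max(Re(ev))
  list(value = p, type = if (abs(Im(ev[i])) > 1e-12) "hopf" else "fold")
}
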