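## Configuration files: flat key-value text with [section] headers.
##
## Keys carry explicit units in their names (_mM, _ms, _um, _mV, ...).
## A packaged defaults file (inst/extdata/defaults.cfg) reproduces the
## model's reference configuration.

#' Read a model configuration file
#'
#' Parses the INI-style key-value format ([morphology], [release],
#' [receptors], [uptake], [ion_dynamics], [protocol], [solver],
#' [events] sections), merges it over the packaged defaults, validates
#' ranges, and returns the assembled objects.
#'
#' @param path Path to a config file; `NULL` loads the packaged defaults.
#' @return List of class `sd_config` with elements `params`
#'   (`sd_params`), `protocol` (`sd_protocol`), `solver` (rtol, atol,
#'   dt_ms, t_end_ms), `events` (detection settings), and `raw` (the
#'   merged key-value list).
#' @export
load_config <- function(path = NULL) {
  defaults <- .parse_cfg(system.file("extdata", "defaults.cfg",
                                     package = "sdglu", mustWork = TRUE))
  raw <- defaults
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("config file not found: ", path, call. = FALSE)
    user <- .parse_cfg(path)
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    raw[names(user)] <- user
  }
  .validate_cfg(raw)
  cfg <- .assemble_cfg(raw)
  cfg$raw <- raw
  class(cfg) <- "sd_config"
  cfg
}

#' Write a configuration file
#'
#' Serializes a merged key-value configuration back to the flat text
#' format; `load_config(write_config(cfg, f))` round-trips losslessly.
#'
#' @param config An `sd_config` (or its `raw` element).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- if (inherits(config, "sd_config")) config$raw else config
  secs <- split(names(raw), vapply(strsplit(names(raw), "\\."), `[`,
                                   "", 1))
  lines <- character(0)
  for (s in names(secs)) {
    lines <- c(lines, sprintf("[%s]", s))
    for (k in secs[[s]]) {
      key <- sub(paste0("^", s, "\\."), "", k)
      v <- raw[[k]]
      lines <- c(lines, sprintf("%s = %s", key,
                                format(v, digits = 17, scientific = NA)))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

.parse_cfg <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sec <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("\\[|\\]", "", ln)
    } else if (grepl("=", ln)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      out[[paste(sec, key, sep = ".")]] <- if (is.na(num)) val else num
    } else {
      stop("cannot parse config line: ", ln, call. = FALSE)
    }
  }
  out
}

.validate_cfg <- function(raw) {
  chk <- function(key, lo = -Inf, hi = Inf, positive = FALSE) {
    v <- raw[[key]]
    if (is.null(v)) stop("missing config key: ", key, call. = FALSE)
    if (!is.numeric(v))
      stop("config key ", key, " must be numeric", call. = FALSE)
    if (positive && v <= 0)
      stop("config key ", key, " must be positive (got ", v, ")",
           call. = FALSE)
    if (v < lo || v > hi)
      stop("config key ", key, " out of range [", lo, ", ", hi,
           "] (got ", v, ")", call. = FALSE)
  }
  chk("morphology.r_um", positive = TRUE)
  chk("morphology.h_um", 0)
  chk("release.R_max_fmol_per_ms", positive = TRUE)
  chk("release.N_max_fmol", positive = TRUE)
  chk("uptake.v_cn_max_mM_per_ms", positive = TRUE)
  chk("uptake.k_m_mM", positive = TRUE)
  chk("protocol.uptake_fraction", 0, 1)
  chk("ion_dynamics.rho_p_uA_per_cm2", positive = TRUE)
  if (!raw[["protocol.type"]] %in% c("perfusion", "ogd"))
    stop("protocol.type must be 'perfusion' or 'ogd'", call. = FALSE)
  if (raw[["release.V_hi_mV"]] <= raw[["release.V_cr_mV"]])
    stop("release.V_hi_mV must exceed release.V_cr_mV", call. = FALSE)
  invisible(TRUE)
}

.assemble_cfg <- function(raw) {
  g <- function(k) raw[[k]]
  morph <- cleft_geometry(
    r = g("morphology.r_um"), h = g("morphology.h_um"),
    A_m_n = g("morphology.A_m_n_cm2"), A_m_g = g("morphology.A_m_g_cm2"),
    N_syn = g("morphology.N_syn"), N_syn_AP = g("morphology.N_syn_AP"),
    omega_n0 = g("morphology.omega_n0_um3"),
    omega_g0 = g("morphology.omega_g0_um3"),
    omega_e0 = g("morphology.omega_e0_um3"))
  params <- sd_params(
    morph = morph,
    R_max = g("release.R_max_fmol_per_ms"),
    V_cr = g("release.V_cr_mV"), V_hi = g("release.V_hi_mV"),
    N_max = g("release.N_max_fmol"), k_rec = g("release.k_rec_per_ms"),
    g_NMDA = g("receptors.g_NMDA_mS_per_cm2"),
    g_AMPA = g("receptors.g_AMPA_mS_per_cm2"),
    alpha_NMDA = g("receptors.alpha_NMDA_per_mM_ms"),
    beta_NMDA = g("receptors.beta_NMDA_per_ms"),
    alpha_AMPA = g("receptors.alpha_AMPA_per_mM_ms"),
    beta_AMPA = g("receptors.beta_AMPA_per_ms"),
    Mg = g("receptors.Mg_mM"),
    D_G = g("uptake.D_G_um2_per_ms"), dx = g("uptake.dx_um"),
    v_cn_max = g("uptake.v_cn_max_mM_per_ms"), k_m = g("uptake.k_m_mM"),
    rho_p = g("ion_dynamics.rho_p_uA_per_cm2"),
    lambda_glia = g("ion_dynamics.lambda_glia_per_ms"),
    B_glia = g("ion_dynamics.B_glia_fmol"),
    glia_K_half = g("ion_dynamics.glia_K_half_mM"),
    glia_K_slope = g("ion_dynamics.glia_K_slope_mM"),
    lambda_bath = g("ion_dynamics.lambda_bath_per_ms"),
    tau_osm = g("ion_dynamics.tau_osm_ms"))
  protocol <- if (g("protocol.type") == "perfusion") {
    perfusion_protocol(K_high = g("protocol.K_high_mM"),
                       t_on = g("protocol.t_on_ms"))
  } else {
    ogd_protocol(t_start = g("protocol.t_on_ms"),
                 ramp = g("protocol.ramp_ms"),
                 hold = g("protocol.hold_ms"))
  }
  protocol <- impaired_uptake(protocol, g("protocol.uptake_fraction"))
  list(params = params, protocol = protocol,
       solver = list(rtol = g("solver.rtol"), atol = g("solver.atol"),
                     dt_ms = g("solver.dt_ms"),
                     t_end_ms = g("solver.t_end_ms")),
       events = list(depol_threshold = g("events.depol_threshold_mV"),
                     persistence = g("events.persistence_ms"),
                     repol_tol = g("events.repol_tol_mV"),
                     baseline_window = g("events.baseline_window_ms")))
}

#' @export
print.sd_config <- function(x, ...) {
  cat("sd_config:", length(x$raw), "keys;", x$protocol$type, "protocol\n")
  invisible(x)
}
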