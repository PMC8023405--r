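#' Reference parameter bundle
#'
#' The standard parameter set for an elongating dicot shoot (radius
#' 0.5 mm, growth zone a few cm, growth time tens of hours, 12-minute
#' tropic memory/reaction times, lignification over days). All values in
#' SI units; the endogenous sensitivity `alpha` is left free (0 by
#' default).
#'
#' @return named list of all model parameters.
#' @export
preset_table1 <- function() {
  list(alpha = 0, beta = 0.8, eta = 20,
       tau_a = 120,          # statolith avalanche time: 2 min
       tau_e = 1200,         # endogenous period: 20 min
       tau_m = 720, tau_r = 720,    # gravitropic memory/reaction: 12 min
       tau_bm = 720, tau_br = 720,  # proprioceptive memory/reaction: 12 min
       tau_g = 72000,        # growth time: 20 h
       tau_l = 6 * 86400,    # lignification time: 6 d
       r = 5e-4,             # radius: 0.5 mm
       l_g = 0.07,           # growth zone: 7 cm (observed range 4-7 cm)
       nu_poisson = 0.5, rho = 1000,
       E0 = 1e7, E1 = 2e9,   # stiffening ratio 200
       g_accel = 9.81,
       shear_modulus_convention = "standard",
       endo_sign = 1, endo_phase = 0)
}

#' Parse a quantity with units to SI
#'
#' Accepts bare numbers or strings like "20 h", "0.5 mm", "10 MPa".
#' Supported units: s, min, h, d; m, cm, mm; Pa, kPa, MPa, GPa;
#' kg/m^3; m/s^2 (factor 1 for the already-SI units).
#'
#' @param x numeric, or character "value unit".
#' @return numeric value in SI units.
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  units <- c(s = 1, sec = 1, min = 60, h = 3600, d = 86400,
             m = 1, cm = 1e-2, mm = 1e-3,
             Pa = 1, kPa = 1e3, MPa = 1e6, GPa = 1e9,
             "kg/m^3" = 1, "m/s^2" = 1)
  out <- vapply(as.character(x), function(xi) {
    parts <- strsplit(trimws(xi), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(v)) stop("cannot parse quantity: '", xi, "'")
    if (length(parts) == 1) return(v)
    if (!parts[2] %in% names(units))
      stop("unknown unit '", parts[2], "' in '", xi, "'")
    v * units[[parts[2]]]
  }, numeric(1))
  unname(out)
}

config_key_schema <- function() {
  list(numeric = c("alpha", "beta", "eta", "tau_a", "tau_e", "tau_m",
                   "tau_r", "tau_bm", "tau_br", "tau_g", "tau_l", "r",
                   "l_g", "nu_poisson", "rho", "E0", "E1", "g_accel",
                   "endo_phase", "l", "l0", "t_end", "dt", "horizon",
                   "kick_amplitude", "out_every"),
       other = c("preset", "scenario", "shear_modulus_convention",
                 "endo_sign", "n_nodes", "seed", "spin",
                 "fast_statoliths", "freeze_growth"))
}

#' Load and validate a structured configuration file
#'
#' YAML key-value file; values may carry units ("20 h" is parsed to
#' seconds). Keys default from [preset_table1()] (or the preset named by
#' the `preset` key); unknown keys are rejected with a field-level
#' message. Required scenario-specific keys are checked by the consumers
#' ([reduced_config()], [simulation_config()]).
#'
#' @param path configuration file path.
#' @return named list of validated SI-unit parameters, with unmodified
#'   control keys (`scenario`, `n_nodes`, ...).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a key-value mapping")
  sch <- config_key_schema()
  unknown <- setdiff(names(raw), c(sch$numeric, sch$other))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$preset)) {
    if (!identical(raw$preset, "table1"))
      stop("unknown preset '", raw$preset, "'")
    raw$preset <- NULL
  }
  cfg <- utils::modifyList(preset_table1(), raw)
  for (k in intersect(names(cfg), sch$numeric)) cfg[[k]] <- parse_quantity(cfg[[k]])
  if (!is.null(cfg$nu_poisson) &&
      (cfg$nu_poisson < 0 || cfg$nu_poisson > 0.5))
    stop("nu_poisson must lie in [0, 0.5]")
  bad <- intersect(names(cfg),
                   c("tau_a", "tau_e", "tau_m", "tau_bm", "tau_g", "tau_l",
                     "r", "rho", "E0", "E1"))
  neg <- bad[vapply(bad, function(k) cfg[[k]] <= 0, logical(1))]
  if (length(neg)) stop("parameter(s) must be positive: ",
                        paste(neg, collapse = ", "))
  cfg
}

#' Build a stimulus/elastic parameter pair from a flat config
#'
#' Helper mapping a [load_config()]/[preset_table1()] list onto the typed
#' parameter objects used by the simulators.
#'
#' @param cfg flat named list of SI parameters.
#' @param E Young's modulus for the elastic bundle (default `cfg$E0`).
#' @return list with `stimulus` and `elastic`.
#' @export
params_from_config <- function(cfg, E = cfg$E0) {
  list(stimulus = stimulus_params(alpha = cfg$alpha, beta = cfg$beta,
                                  eta = cfg$eta, tau_e = cfg$tau_e,
                                  tau_m = cfg$tau_m, tau_r = cfg$tau_r,
                                  tau_bm = cfg$tau_bm, tau_br = cfg$tau_br,
                                  tau_a = cfg$tau_a, r = cfg$r,
                                  endo_sign = cfg$endo_sign,
                                  endo_phase = cfg$endo_phase),
       elastic = elastic_params(E = E, r = cfg$r,
                                nu_poisson = cfg$nu_poisson, rho = cfg$rho,
                                g_accel = cfg$g_accel,
                                shear_modulus_convention =
                                  cfg$shear_modulus_convention))
}

#' Dump a configuration back to YAML
#' @param cfg named list.
#' @param path output file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
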