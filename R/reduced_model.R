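#' Configuration of the constant-length reduced model
#'
#' For processes much faster than growth the shoot length and stiffness are
#' frozen (l ~ l0 <= lg, E ~ E0), material and current arc length coincide,
#' the whole rod grows at epsdot = 1/tau_g, and the statolith transient is
#' skipped (h = -g at all times). The scenario switch zeroes parameters
#' consistently: `"graviceptive"` (alpha = eta = 0), `"microgravity"`
#' (alpha = beta = 0, q = 0), `"proprio_graviceptive"` (alpha = 0) and
#' `"with_endogenous"` (all three active).
#'
#' @param l fixed shoot length \[m\].
#' @param tau_g characteristic growth time \[s\].
#' @param scenario one of the four scenario labels.
#' @param stimulus `stimulus_params`.
#' @param elastic `elastic_params`.
#' @param horizon simulated time \[s\].
#' @param n_nodes grid nodes.
#' @param dt time step \[s\]; default `min(tau_m, tau_bm, tau_e)/40`,
#'   snapped so it divides the reaction delays exactly.
#' @param perturb list: `amplitude` (intrinsic-curvature kick \[1/m\],
#'   default 1e-4/l), `spin` (+1/-1 rotating kick selecting the chirality,
#'   0 planar kick), `cycles` (duration of the rotating kick in periods of
#'   the proprioceptive Hopf frequency).
#' @param out_every output cadence in steps.
#' @param eq_ctrl equilibrium-solver controls: `relax` (under-relaxation,
#'   default 0.5), `tol_tip` \[m\], `max_iter`. Lengths close to the
#'   self-buckling length need more iterations (the fixed point loses
#'   contraction near the fold).
#' @return object of class `reduced_config`.
#' @export
reduced_config <- function(l, tau_g,
                           scenario = c("proprio_graviceptive", "graviceptive",
                                        "microgravity", "with_endogenous"),
                           stimulus = stimulus_params(),
                           elastic = elastic_params(),
                           horizon = NULL, n_nodes = 100, dt = NULL,
                           perturb = list(), out_every = 4,
                           eq_ctrl = list()) {
  scenario <- match.arg(scenario)
  stopifnot(l > 0, tau_g > 0)
  if (scenario == "graviceptive") { stimulus$alpha <- 0; stimulus$eta <- 0 }
  if (scenario == "microgravity") { stimulus$alpha <- 0; stimulus$beta <- 0 }
  if (scenario == "proprio_graviceptive") stimulus$alpha <- 0
  q <- if (scenario == "microgravity") 0 else gravity_load(elastic)
  per <- utils::modifyList(list(amplitude = 1e-4 / l, spin = 0, cycles = 1),
                           perturb)
  if (is.null(dt)) dt <- min(stimulus$tau_m, stimulus$tau_bm, stimulus$tau_e) / 40
  dt <- snap_dt(dt, c(stimulus$tau_r, stimulus$tau_br))
  if (is.null(horizon)) {
    Tref <- 2 * pi / hopf_reference_frequency(stimulus)
    horizon <- 30 * Tref
  }
  eqc <- utils::modifyList(list(relax = 0.5, tol_tip = 1e-9,
                                max_iter = 200), eq_ctrl)
  structure(list(l = l, tau_g = tau_g, scenario = scenario,
                 stimulus = stimulus, elastic = elastic, q = q,
                 horizon = horizon, n_nodes = n_nodes, dt = dt,
                 perturb = per, out_every = out_every, eq_ctrl = eqc),
            class = "reduced_config")
}

# largest dt' <= dt such that both reaction delays are integer multiples
snap_dt <- function(dt, delays) {
  delays <- delays[delays > 0]
  if (!length(delays)) return(dt)
  for (d in delays) dt <- d / ceiling(d / dt)
  # re-check the first delay after snapping to the second
  for (d in delays) if (abs(d / dt - round(d / dt)) > 1e-9)
    dt <- d / ceiling(d / dt)
  dt
}

# angular frequency of the delayed-feedback oscillation used to size
# horizons and kicks: root of tan(x) = tau_r/(x tau_m), x = omega tau_r
hopf_reference_frequency <- function(stimulus) {
  tm <- if (stimulus$eta > 0) stimulus$tau_bm else stimulus$tau_m
  tr <- if (stimulus$eta > 0) stimulus$tau_br else stimulus$tau_r
  if (tr <= 0) return(2 * pi / (20 * tm))
  f <- function(x) x * sin(x) * tm - tr * cos(x)
  x <- stats::uniroot(f, c(1e-9, pi / 2 - 1e-9), tol = 1e-12)$root
  x / tr
}

#' Time-step the reduced model
#'
#' Perturbs the upright state and advances the constant-length rod:
#' spontaneous-strain rates from the active stimuli with epsdot = 1/tau_g
#' everywhere, h = -g (fast statoliths), and a quasi-static elastic
#' equilibrium solve every step.
#'
#' @param config a `reduced_config`.
#' @return object of class `rod_simulation`: `trajectory` (data.frame t,
#'   x, y, z, l), `state` (final `rod_state`), `internals` (solver state
#'   for diagnostics/restart), `config`.
#' @export
simulate_reduced <- function(config) {
  stopifnot(inherits(config, "reduced_config"))
  st <- config$stimulus
  n <- config$n_nodes
  s <- seq(0, config$l, length.out = n)
  Kst <- stiffnesses(config$elastic)
  pars <- list(alpha = st$alpha, beta = st$beta, eta = st$eta, r = st$r,
               tau_e = st$tau_e, tau_m = st$tau_m, tau_r = st$tau_r,
               tau_bm = st$tau_bm, tau_br = st$tau_br, tau_a = st$tau_a,
               endo_sign = st$endo_sign, endo_phase = st$endo_phase)
  dt <- config$dt
  n_steps <- ceiling(config$horizon / dt)
  ustar0 <- matrix(0, n, 2)
  kick <- list(amp = 0, omega = 1, spin = 0, t_end = -1)
  om <- hopf_reference_frequency(st)
  if (config$perturb$spin == 0) {
    ustar0[, 1] <- config$perturb$amplitude
  } else {
    kick <- list(amp = config$perturb$amplitude * om,
                 omega = om, spin = config$perturb$spin,
                 t_end = config$perturb$cycles * 2 * pi / om)
  }
  Lg <- round(st$tau_r / dt)
  Lp <- round(st$tau_br / dt)
  zeros <- function(m) matrix(0, m + 1, n)
  res <- cpp_simulate(
    s_t = matrix(s, 1), eps_t = matrix(1 / config$tau_g, 1, n),
    K1_t = matrix(rep_len(Kst$K1, n), 1), K3_t = matrix(rep_len(Kst$K3, n), 1),
    q = config$q, g_dir = c(0, 0, -1), R0 = unclass(frame_identity()),
    p0 = c(0, 0, 0),
    ustar0 = ustar0, u0 = cbind(ustar0, 0),
    hb0 = cbind(matrix(0, n, 2), 1),
    bufH1 = zeros(Lg), bufH2 = zeros(Lg), bufU1 = zeros(Lp), bufU2 = zeros(Lp),
    Ig1_0 = numeric(n), Ig2_0 = numeric(n),
    Ip1_0 = numeric(n), Ip2_0 = numeric(n),
    dt = dt, n_steps = n_steps, t0 = 0, k0 = 0,
    pars = pars, kick = kick, fast_stat = TRUE,
    eq_ctrl = config$eq_ctrl,
    out_every = config$out_every)
  if (res$fail_step >= 0)
    stop(structure(class = c("morphorod_equilibrium_failure", "error",
                             "condition"),
                   list(message = paste0("equilibrium failure at t = ",
                                         res$fail_step * dt, " s"),
                        call = sys.call())))
  traj <- data.frame(t = res$times, x = res$tip[, 1], y = res$tip[, 2],
                     z = res$tip[, 3], l = res$length)
  grid <- as_rod_grid(s)
  state <- new_rod_state(grid, res$state$p, res$state$d1, res$state$d2,
                         res$state$d3, res$state$u)
  structure(list(trajectory = traj, state = state, internals = res$state,
                 config = config, dt = dt,
                 max_eq_iterations = res$max_eq_iterations),
            class = "rod_simulation")
}

#' Leading exponential rate of the tip oscillation
#'
#' Fits the late-time envelope of the horizontal tip deflection
#' |x + i y|: rolling-maximum envelope over one reference period, then a
#' linear fit of its logarithm. Also reports the envelope growth factor
#' over the window, more robust than the slope once the motion saturates
#' on a limit cycle.
#'
#' @param t,x,y tip trajectory samples.
#' @param period reference oscillation period \[s\] for the envelope.
#' @param window fraction of the record (from the end) used for the fit.
#' @return list `rate` \[1/s\], `growth_factor`, `amplitude` (final).
#' @export
fit_leading_rate <- function(t, x, y, period, window = 0.4) {
  r <- sqrt(x^2 + y^2)
  i0 <- max(1, floor(length(t) * (1 - window)))
  tt <- t[i0:length(t)]
  rr <- r[i0:length(t)]
  dt <- stats::median(diff(tt))
  w <- max(3, ceiling(period / dt))
  env <- rolling_max(rr, w)
  keep <- env > 0 & seq_along(env) > w & seq_along(env) <= length(env) - 1
  if (sum(keep) < 5)
    return(list(rate = NA_real_, growth_factor = NA_real_,
                amplitude = max(rr)))
  fit <- stats::lm(log(env[keep]) ~ tt[keep])
  ek <- env[keep]
  list(rate = unname(stats::coef(fit)[2]),
       growth_factor = ek[length(ek)] / ek[1],
       amplitude = ek[length(ek)])
}

rolling_max <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- max(x[max(1, i - w + 1):i])
  out
}

# stability probe at a single length: TRUE if the perturbation grows
probe_unstable <- function(l, tau_g, scenario, stimulus, elastic, n_nodes,
                           horizon_periods = 30, eq_ctrl = list()) {
  om <- hopf_reference_frequency(stimulus)
  Tref <- 2 * pi / om
  cfg <- reduced_config(l, tau_g, scenario = scenario, stimulus = stimulus,
                        elastic = elastic, n_nodes = n_nodes,
                        horizon = horizon_periods * Tref, out_every = 4,
                        eq_ctrl = eq_ctrl)
  sim <- simulate_reduced(cfg)
  tr <- sim$trajectory
  fit <- fit_leading_rate(tr$t, tr$x, tr$y, period = Tref)
  gf <- fit$growth_factor
  if (!is.na(gf) && gf > 1.5) return(list(unstable = TRUE, fit = fit))
  if (!is.na(gf) && gf < 1 / 1.5) return(list(unstable = FALSE, fit = fit))
  list(unstable = !is.na(fit$rate) && fit$rate > 0, fit = fit)
}

#' Critical shoot length of the reduced model
#'
#' Bisects the fixed length l for the onset of spontaneous oscillations:
#' at each trial the rod is released from a small planar
#' intrinsic-curvature kick (1e-4/l) and the leading rate is estimated
#' from the late-time tip envelope. The bracket is narrowed to 0.01 cm.
#'
#' @param tau_g growth time \[s\].
#' @param scenario `"proprio_graviceptive"` or `"graviceptive"`.
#' @param stimulus `stimulus_params`.
#' @param elastic `elastic_params`.
#' @param bracket initial length bracket \[m\].
#' @param n_nodes grid nodes per trial (100 keeps the bisection fast; the
#'   threshold moves by well under the bracket tolerance on refinement).
#' @param horizon_periods trial horizon in reference oscillation periods.
#' @param tol_l bracket tolerance \[m\] (default 1e-4 m = 0.01 cm).
#' @param eq_ctrl equilibrium-solver controls (see [reduced_config()]);
#'   raise `max_iter` when probing lengths close to the self-buckling
#'   length.
#' @return object of class `stability_result`: `critical_value` \[m\],
#'   `leading_rate` and `leading_frequency` \[1/s\] near threshold,
#'   `scenario`, `classification`, the final `bracket`.
#' @export
critical_length <- function(tau_g, scenario = c("proprio_graviceptive",
                                                "graviceptive"),
                            stimulus = stimulus_params(),
                            elastic = elastic_params(),
                            bracket = c(0.05, 0.08), n_nodes = 100,
                            horizon_periods = 30, tol_l = 1e-4,
                            eq_ctrl = list()) {
  scenario <- match.arg(scenario)
  lo <- bracket[1]; hi <- bracket[2]
  p_lo <- probe_unstable(lo, tau_g, scenario, stimulus, elastic, n_nodes,
                         horizon_periods, eq_ctrl)
  p_hi <- probe_unstable(hi, tau_g, scenario, stimulus, elastic, n_nodes,
                         horizon_periods, eq_ctrl)
  if (p_lo$unstable || !p_hi$unstable)
    stop("no stability change in the scanned bracket [",
         lo, ", ", hi, "] m: lower ",
         ifelse(p_lo$unstable, "unstable", "stable"), ", upper ",
         ifelse(p_hi$unstable, "unstable", "stable"))
  last_fit <- p_hi$fit
  while (hi - lo > tol_l) {
    mid <- (lo + hi) / 2
    pm <- probe_unstable(mid, tau_g, scenario, stimulus, elastic, n_nodes,
                         horizon_periods, eq_ctrl)
    if (pm$unstable) { hi <- mid; last_fit <- pm$fit } else lo <- mid
  }
  om <- hopf_reference_frequency(stimulus)
  structure(list(critical_value = (lo + hi) / 2,
                 leading_rate = last_fit$rate,
                 leading_frequency = om / (2 * pi),
                 scenario = scenario,
                 classification = "hopf_onset",
                 bracket = c(lo, hi)),
            class = "stability_result")
}

# scalar time-domain probe of the proprioception-only (microgravity) law:
# du/dt = -(eta/tau_g) I(t), dI/dt = (u(t - tau_br) - I)/tau_bm
proprio_scalar_rate <- function(tau_g, eta, tau_bm, tau_br,
                                horizon = NULL, dt = NULL) {
  om <- hopf_reference_frequency(stimulus_params(eta = eta, tau_bm = tau_bm,
                                                 tau_br = tau_br))
  if (is.null(horizon)) horizon <- 30 * 2 * pi / om
  if (is.null(dt)) dt <- tau_bm / 100
  dt <- snap_dt(dt, tau_br)
  L <- round(tau_br / dt)
  nst <- ceiling(horizon / dt)
  a <- dt / tau_bm; mu <- exp(-a)
  c1 <- (a - 1 + mu) / a; c0 <- (1 - mu * (1 + a)) / a
  g <- eta / tau_g
  if (L < 1) stop("dt must be smaller than the reaction delay")
  M <- L + 1
  slot <- function(m) ((m %% M) + M) %% M + 1
  u <- numeric(nst + 1)
  u[1] <- 1
  buf <- rep(1, M)   # primed with the initial condition
  I <- 1             # converged integral of the constant pre-history
  for (k in seq_len(nst)) {
    f_old <- buf[slot(k - 1 - L)]
    f_new <- buf[slot(k - L)]
    I_new <- mu * I + c0 * f_old + c1 * f_new
    u[k + 1] <- u[k] - dt * g * (I + I_new) / 2
    buf[slot(k)] <- u[k + 1]
    I <- I_new
  }
  tt <- seq(0, by = dt, length.out = nst + 1)
  fit <- fit_leading_rate(tt, u, 0 * u, period = 2 * pi / om, window = 0.5)
  fit
}

#' Critical growth time in microgravity (proprioception only)
#'
#' With alpha = beta = 0 and q = 0 the proprioceptive law is spatially
#' local and linear, and the straight state loses stability through a
#' Hopf bifurcation at a critical tau_g independent of the shoot length.
#' The characteristic relation of the exponential-kernel/discrete-delay
#' linearization, i lambda (1 + lambda tau_bm) = -(eta/tau_g)
#' exp(-lambda tau_br) at lambda = i omega, reduces to
#' tan(omega tau_br) = 1/(omega tau_bm) and
#' tau_g_crit = eta tau_br sin(x)/x with x = omega tau_br.
#' The `"bisection"` method brackets the same threshold by time-domain
#' simulation of the scalar delay law (decay vs sustained growth).
#'
#' @param eta proprioceptive sensitivity.
#' @param tau_bm,tau_br proprioceptive memory and reaction times \[s\].
#' @param method `"linearized"` (default) or `"bisection"`.
#' @param bracket tau_g bracket \[s\] for the bisection method.
#' @param tol_rel relative bracket tolerance for the bisection.
#' @return `stability_result` with `critical_value` = tau_g \[s\] and
#'   `leading_frequency` \[1/s\] at threshold.
#' @export
critical_growth_time_microgravity <- function(eta = 20, tau_bm = 720,
                                              tau_br = 720,
                                              method = c("linearized",
                                                         "bisection"),
                                              bracket = NULL,
                                              tol_rel = 5e-3) {
  method <- match.arg(method)
  stopifnot(eta > 0, tau_bm > 0, tau_br > 0)
  f <- function(x) x * sin(x) * tau_bm - tau_br * cos(x)
  x <- stats::uniroot(f, c(1e-9, pi / 2 - 1e-9), tol = 1e-12)$root
  omega <- x / tau_br
  tg_lin <- eta * tau_br * sin(x) / x
  val <- tg_lin
  if (method == "bisection") {
    if (is.null(bracket)) bracket <- tg_lin * c(0.5, 2)
    lo <- bracket[1]; hi <- bracket[2]
    # larger tau_g = weaker gain = stable
    while ((hi - lo) / lo > tol_rel) {
      mid <- sqrt(lo * hi)
      fit <- proprio_scalar_rate(mid, eta, tau_bm, tau_br)
      if (!is.na(fit$rate) && fit$rate > 0) lo <- mid else hi <- mid
    }
    val <- sqrt(lo * hi)
  }
  structure(list(critical_value = val, leading_rate = 0,
                 leading_frequency = omega / (2 * pi),
                 scenario = "microgravity", classification = "hopf_onset"),
            class = "stability_result")
}

#' Stability boundary over a grid of growth times
#'
#' Maps [critical_length()] (or the length-independent microgravity
#' threshold) over `tau_g_grid`. Lengths are reported raw and normalized
#' by the self-buckling length; per-point bracket failures are recorded
#' as flags, not aborts.
#'
#' @param scenario scenario label.
#' @param tau_g_grid growth times \[s\].
#' @param stimulus,elastic parameter bundles.
#' @param ... passed to [critical_length()].
#' @return data.frame with tau_g, l_star \[m\], l_star_over_lc, frequency
#'   \[1/s\], flag.
#' @export
stability_boundary <- function(scenario, tau_g_grid,
                               stimulus = stimulus_params(),
                               elastic = elastic_params(), ...) {
  stopifnot(all(tau_g_grid > 0))
  lc <- self_buckling_length(elastic)
  if (scenario == "microgravity") {
    res <- critical_growth_time_microgravity(eta = stimulus$eta,
                                             tau_bm = stimulus$tau_bm,
                                             tau_br = stimulus$tau_br)
    return(data.frame(tau_g = tau_g_grid,
                      tau_g_crit = res$critical_value,
                      l_star = NA_real_, l_star_over_lc = NA_real_,
                      frequency = res$leading_frequency,
                      flag = "length_independent"))
  }
  rows <- lapply(tau_g_grid, function(tg) {
    out <- tryCatch(critical_length(tg, scenario = scenario,
                                    stimulus = stimulus, elastic = elastic,
                                    ...),
                    error = function(e) e)
    if (inherits(out, "error"))
      return(data.frame(tau_g = tg, tau_g_crit = NA_real_, l_star = NA_real_,
                        l_star_over_lc = NA_real_, frequency = NA_real_,
                        flag = conditionMessage(out)))
    data.frame(tau_g = tg, tau_g_crit = NA_real_,
               l_star = out$critical_value,
               l_star_over_lc = out$critical_value / lc,
               frequency = out$leading_frequency, flag = "ok")
  })
  do.call(rbind, rows)
}
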