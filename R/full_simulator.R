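#' Configuration of the full growing-shoot simulation
#'
#' Couples subapical growth (analytic material-to-current map),
#' lignification of the Young's modulus, statolith avalanche dynamics,
#' the three differential-growth stimuli, and the quasi-static elastic
#' equilibrium. Spontaneous strains live on the fixed material grid
#' (strains are material properties); the equilibrium is solved on the
#' material nodes' current arc-length positions.
#'
#' @param growth `growth_params`.
#' @param lign `lignification_params`.
#' @param stimulus `stimulus_params`.
#' @param elastic `elastic_params` (E0 is taken from `lign`).
#' @param t_end simulated horizon \[s\].
#' @param dt time step \[s\]; default `min(tau_a, tau_m, tau_bm, tau_e)/20`,
#'   snapped to divide the reaction delays.
#' @param n_nodes material nodes.
#' @param out_every output cadence in steps.
#' @param perturb list(`amplitude` \[1/m\], `spin`, `cycles`) as in
#'   [reduced_config()]; default a small planar kick of 1e-4/l0.
#' @param fast_statoliths if TRUE assume h = -g (skip the avalanche
#'   transient).
#' @param freeze_growth if TRUE pin the grid and modulus at their t = 0
#'   values while keeping epsdot from the REGR profile (used for
#'   consistency checks against the reduced model).
#' @param seed integer seed controlling any randomized perturbation (the
#'   physics itself is deterministic).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(growth, lign = lignification_params(),
                              stimulus = stimulus_params(),
                              elastic = elastic_params(E = lign$E0),
                              t_end, dt = NULL, n_nodes = 100,
                              out_every = 10, perturb = list(),
                              fast_statoliths = FALSE,
                              freeze_growth = FALSE, seed = 1L) {
  stopifnot(inherits(growth, "growth_params"), t_end > 0)
  if (is.null(dt))
    dt <- min(stimulus$tau_a, stimulus$tau_m, stimulus$tau_bm,
              stimulus$tau_e) / 20
  dt <- snap_dt(dt, c(stimulus$tau_r, stimulus$tau_br))
  per <- utils::modifyList(list(amplitude = 1e-4 / growth$l0, spin = 0,
                                cycles = 1), perturb)
  structure(list(growth = growth, lign = lign, stimulus = stimulus,
                 elastic = elastic, t_end = t_end, dt = dt,
                 n_nodes = n_nodes, out_every = out_every, perturb = per,
                 fast_statoliths = fast_statoliths,
                 freeze_growth = freeze_growth, seed = as.integer(seed)),
            class = "simulation_config")
}

# per-step field matrices (rows = local steps k0..k0+n_steps) for the C++ loop
build_field_matrices <- function(config, k0, n_steps) {
  gp <- config$growth
  n <- config$n_nodes
  S <- seq(0, gp$l0, length.out = n)
  t_star <- exit_time(gp, S)
  if (config$freeze_growth) {
    cm <- growth_map_closed(gp, S, 0)
    l <- growth_length(gp, 0)
    eps <- regr_profile(cm$s, l, gp)
    E <- young_modulus(t_star, 0, config$lign)
    pars <- config$elastic
    pars$E <- E
    K <- stiffnesses(pars)
    return(list(s = matrix(cm$s, 1), eps = matrix(eps, 1),
                K1 = matrix(K$K1, 1), K3 = matrix(K$K3, 1), S = S))
  }
  nt <- n_steps + 1
  s_t <- eps_t <- K1_t <- K3_t <- matrix(0, nt, n)
  for (j in seq_len(nt)) {
    t <- (k0 + j - 1) * config$dt
    cm <- growth_map_closed(gp, S, t)
    l <- cm$s[n]
    s_t[j, ] <- cm$s
    eps_t[j, ] <- regr_profile(cm$s, l, gp)
    pars <- config$elastic
    pars$E <- young_modulus(t_star, t, config$lign)
    K <- stiffnesses(pars)
    K1_t[j, ] <- K$K1
    K3_t[j, ] <- K$K3
  }
  list(s = s_t, eps = eps_t, K1 = K1_t, K3 = K3_t, S = S)
}

#' Run the full growing-shoot simulation
#'
#' Per step, in order: the growth map and modulus are advanced
#' analytically; the statolith normals relax toward -g (unless
#' `fast_statoliths`); the spontaneous-strain rates (endogenous +
#' gravitropic + proprioceptive, each carrying the local REGR factor) are
#' accumulated; the elastic equilibrium is re-solved on the grown grid;
#' histories and outputs are appended. An equilibrium failure (mechanical
#' collapse/fold) terminates the run with the partial record.
#'
#' @param config a `simulation_config`.
#' @param .internal_state resume state (used by [restart_simulation()]).
#' @param .k0 absolute step offset for resumes.
#' @return object of class `rod_simulation` (see [simulate_reduced()]);
#'   `trajectory` additionally carries the shoot length l(t); if the run
#'   terminated early, `failed_at` holds the failure time \[s\].
#' @export
run_simulation <- function(config, .internal_state = NULL, .k0 = 0) {
  stopifnot(inherits(config, "simulation_config"))
  st <- config$stimulus
  n <- config$n_nodes
  dt <- config$dt
  n_steps <- ceiling(config$t_end / dt) - .k0
  if (n_steps < 1) stop("t_end already reached")
  fm <- build_field_matrices(config, .k0, n_steps)
  pars <- list(alpha = st$alpha, beta = st$beta, eta = st$eta, r = st$r,
               tau_e = st$tau_e, tau_m = st$tau_m, tau_r = st$tau_r,
               tau_bm = st$tau_bm, tau_br = st$tau_br, tau_a = st$tau_a,
               endo_sign = st$endo_sign, endo_phase = st$endo_phase)
  Lg <- round(st$tau_r / dt)
  Lp <- round(st$tau_br / dt)
  if (is.null(.internal_state)) {
    set.seed(config$seed)
    ustar0 <- matrix(0, n, 2)
    kick <- list(amp = 0, omega = 1, spin = 0, t_end = -1)
    if (config$perturb$spin == 0) {
      ustar0[, 1] <- config$perturb$amplitude
    } else {
      om <- hopf_reference_frequency(st)
      kick <- list(amp = config$perturb$amplitude * om, omega = om,
                   spin = config$perturb$spin,
                   t_end = config$perturb$cycles * 2 * pi / om)
    }
    init <- list(ustar0 = ustar0, u0 = cbind(ustar0, 0),
                 hb0 = cbind(matrix(0, n, 2), 1),
                 bufH1 = matrix(0, Lg + 1, n), bufH2 = matrix(0, Lg + 1, n),
                 bufU1 = matrix(0, Lp + 1, n), bufU2 = matrix(0, Lp + 1, n),
                 Ig1 = numeric(n), Ig2 = numeric(n),
                 Ip1 = numeric(n), Ip2 = numeric(n), kick = kick)
  } else {
    ist <- .internal_state
    init <- list(ustar0 = ist$u_star, u0 = ist$u, hb0 = ist$h_body,
                 bufH1 = ist$bufH1, bufH2 = ist$bufH2,
                 bufU1 = ist$bufU1, bufU2 = ist$bufU2,
                 Ig1 = ist$Ig1, Ig2 = ist$Ig2, Ip1 = ist$Ip1, Ip2 = ist$Ip2,
                 kick = ist$kick)
  }
  res <- cpp_simulate(
    s_t = fm$s, eps_t = fm$eps, K1_t = fm$K1, K3_t = fm$K3,
    q = gravity_load(config$elastic), g_dir = c(0, 0, -1),
    R0 = unclass(frame_identity()), p0 = c(0, 0, 0),
    ustar0 = init$ustar0, u0 = init$u0, hb0 = init$hb0,
    bufH1 = init$bufH1, bufH2 = init$bufH2,
    bufU1 = init$bufU1, bufU2 = init$bufU2,
    Ig1_0 = init$Ig1, Ig2_0 = init$Ig2, Ip1_0 = init$Ip1, Ip2_0 = init$Ip2,
    dt = dt, n_steps = n_steps, t0 = .k0 * dt, k0 = .k0,
    pars = pars, kick = init$kick, fast_stat = config$fast_statoliths,
    eq_ctrl = list(relax = 0.5, tol_tip = 1e-9, max_iter = 200),
    out_every = config$out_every)
  traj <- data.frame(t = res$times, x = res$tip[, 1], y = res$tip[, 2],
                     z = res$tip[, 3], l = res$length)
  ns <- if (res$fail_step >= 0) res$fail_step else n_steps
  s_last <- if (nrow(fm$s) == 1) fm$s[1, ] else fm$s[ns + 1, ]
  state <- new_rod_state(as_rod_grid(s_last), res$state$p, res$state$d1,
                         res$state$d2, res$state$d3, res$state$u)
  internals <- res$state
  internals$kick <- init$kick
  structure(list(trajectory = traj, state = state, internals = internals,
                 config = config, dt = dt,
                 failed_at = if (res$fail_step >= 0) res$fail_step * dt else NULL,
                 max_eq_iterations = res$max_eq_iterations),
            class = "rod_simulation")
}

CHECKPOINT_VERSION <- 1L

#' Checkpoint and restart a simulation
#'
#' `save_checkpoint()` stores the complete solver state; resuming with
#' `restart_simulation()` reproduces the uninterrupted run bit-for-bit
#' (the stepper is deterministic and the delay buffers, kernel integrals
#' and absolute step index are all preserved).
#'
#' @param sim a `rod_simulation` from [run_simulation()].
#' @param path checkpoint file.
#' @export
save_checkpoint <- function(sim, path) {
  stopifnot(inherits(sim, "rod_simulation"),
            inherits(sim$config, "simulation_config"))
  saveRDS(list(version = CHECKPOINT_VERSION, config = sim$config,
               internals = sim$internals, trajectory = sim$trajectory),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param t_end new horizon \[s\] (must exceed the checkpoint time).
#' @param config_override optional function applied to the stored config
#'   (e.g. to change a sensitivity after the restart point).
#' @return the completed `rod_simulation`, with the pre-checkpoint
#'   trajectory prepended.
#' @export
restart_simulation <- function(path, t_end = NULL, config_override = NULL) {
  ck <- tryCatch(readRDS(path),
                 error = function(e) stop("unreadable checkpoint: ",
                                          conditionMessage(e)))
  if (!is.list(ck) || !identical(ck$version, CHECKPOINT_VERSION))
    stop("checkpoint version mismatch; refusing to resume")
  config <- ck$config
  if (!is.null(config_override)) config <- config_override(config)
  if (!is.null(t_end)) config$t_end <- t_end
  k0 <- ck$internals$k_abs
  sim <- run_simulation(config, .internal_state = ck$internals, .k0 = k0)
  pre <- ck$trajectory
  sim$trajectory <- rbind(pre[pre$t < sim$trajectory$t[1], ], sim$trajectory)
  rownames(sim$trajectory) <- NULL
  sim
}
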