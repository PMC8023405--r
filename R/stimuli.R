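#' Stimulus parameters
#'
#' Sensitivities and characteristic times of the three drivers of
#' differential growth: the endogenous oscillator (alpha, tau_e), the
#' delayed gravitropic response fed by statolith dynamics (beta, tau_m,
#' tau_r, tau_a) and delayed proprioception (eta, tau_bm, tau_br). Defaults
#' follow the reference parameter bundle (`preset_table1()`).
#'
#' @param alpha endogenous sensitivity \[-\].
#' @param beta gravitropic sensitivity \[-\].
#' @param eta proprioceptive sensitivity \[-\].
#' @param tau_e endogenous period \[s\].
#' @param tau_m,tau_r gravitropic memory and reaction times \[s\].
#' @param tau_bm,tau_br proprioceptive memory and reaction times \[s\].
#' @param tau_a statolith avalanche time \[s\].
#' @param r organ radius \[m\].
#' @param endo_sign +1/-1, rotation direction of the endogenous oscillator.
#' @param endo_phase initial phase \[rad\] of the endogenous oscillator.
#' @return object of class `stimulus_params`.
#' @export
stimulus_params <- function(alpha = 0, beta = 0.8, eta = 20,
                            tau_e = 1200, tau_m = 720, tau_r = 720,
                            tau_bm = 720, tau_br = 720, tau_a = 120,
                            r = 5e-4, endo_sign = 1, endo_phase = 0) {
  stopifnot(alpha >= 0, beta >= 0, eta >= 0, tau_m > 0, tau_bm > 0,
            tau_e > 0, tau_r >= 0, tau_br >= 0, tau_a > 0, r > 0,
            endo_sign %in% c(-1, 1))
  structure(as.list(environment()), class = "stimulus_params")
}

#' Advance the statolith free-surface normal
#'
#' The perceived-gravity vector h (components in the local director basis)
#' relaxes viscously toward -g: sum_j hdot_j d_j = (1/tau_a) h x (h x g).
#' The rates are taken in the current local basis (corotational law); one
#' RK4 step is applied with the frames held fixed, then |h| is
#' renormalized to 1.
#'
#' @param h n x 3 matrix of body components of h, |h| = 1 per node.
#' @param frames a `rod_state` (or list with `d1`, `d2`, `d3` matrices).
#' @param g_dir unit gravity direction (world frame).
#' @param tau_a avalanche time \[s\].
#' @param dt time step \[s\] (> 0).
#' @return updated n x 3 matrix of unit body components.
#' @export
step_statoliths <- function(h, frames, g_dir, tau_a, dt) {
  h <- as.matrix(h)
  stopifnot(dt > 0, abs(sum(g_dir^2) - 1) < 1e-9)
  nh <- sqrt(rowSums(h^2))
  if (any(nh < 1e-12)) stop("zero-norm statolith normal")
  # gravity components in each node's local basis
  gb <- cbind(frames$d1 %*% g_dir, frames$d2 %*% g_dir, frames$d3 %*% g_dir)
  rate <- function(hh) {
    t1 <- cbind(hh[, 2] * gb[, 3] - hh[, 3] * gb[, 2],
                hh[, 3] * gb[, 1] - hh[, 1] * gb[, 3],
                hh[, 1] * gb[, 2] - hh[, 2] * gb[, 1])
    t2 <- cbind(hh[, 2] * t1[, 3] - hh[, 3] * t1[, 2],
                hh[, 3] * t1[, 1] - hh[, 1] * t1[, 3],
                hh[, 1] * t1[, 2] - hh[, 2] * t1[, 1])
    t2 / tau_a
  }
  k1 <- rate(h)
  k2 <- rate(h + dt / 2 * k1)
  k3 <- rate(h + dt / 2 * k2)
  k4 <- rate(h + dt * k3)
  hn <- h + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  hn / sqrt(rowSums(hn^2))
}

#' Endogenous oscillator rates
#'
#' Spatially uniform time-harmonic driver of the spontaneous strains:
#' du1*/dt = alpha epsdot / r cos(2 pi t / tau_e),
#' du2*/dt = alpha epsdot / r sin(2 pi t / tau_e)
#' (the sine term carries `endo_sign`, selecting the rotation direction).
#'
#' @param epsdot true-strain rate (REGR) \[1/s\], >= 0.
#' @param t time \[s\].
#' @param params `stimulus_params`.
#' @return matrix with columns du1, du2 \[1/(m s)\].
#' @export
endogenous_rate <- function(epsdot, t, params) {
  stopifnot(all(epsdot >= 0))
  if (params$r <= 0) stop("organ radius must be positive")
  ph <- 2 * pi * t / params$tau_e + params$endo_phase
  cbind(du1 = params$alpha * epsdot / params$r * cos(ph),
        du2 = params$endo_sign * params$alpha * epsdot / params$r * sin(ph))
}

#' Time-stamped stimulus history
#'
#' Per-node past samples of the perceived-gravity components (h1, h2) and
#' of the visible strains (u1, u2), feeding the distributed-delay
#' integrals. Signals are matrices (time x node); before the earliest
#' sample the signals are assumed constant at their first value (the
#' priming convention: the trivial upright state is an exact equilibrium).
#'
#' @param times strictly increasing sample times \[s\].
#' @param h1,h2,u1,u2 matrices (length(times) x n_nodes) or vectors.
#' @return object of class `stimulus_history`.
#' @export
stimulus_history <- function(times, h1, h2, u1, u2) {
  as_m <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1)
  h1 <- as_m(h1); h2 <- as_m(h2); u1 <- as_m(u1); u2 <- as_m(u2)
  if (any(diff(times) <= 0)) stop("history timestamps must be strictly increasing")
  stopifnot(nrow(h1) == length(times), nrow(h2) == length(times),
            nrow(u1) == length(times), nrow(u2) == length(times))
  structure(list(times = times, h1 = h1, h2 = h2, u1 = u1, u2 = u2),
            class = "stimulus_history")
}

#' Exponentially weighted delay integral
#'
#' Evaluates I(t) = (1/tau_m) int_-inf^(t - tau_r) exp(-(t - tau_r -
#' tau)/tau_m) f(tau) dtau for sampled signals. The kernel is integrated
#' exactly against the piecewise-linear interpolant of f (so for constant
#' f the kernel mass is exactly 1); before the earliest sample f is taken
#' constant at its first value.
#'
#' @param times sample times of f \[s\], strictly increasing.
#' @param f signal samples: vector, or matrix (time x node).
#' @param t evaluation time \[s\].
#' @param tau_r reaction (discrete) delay \[s\].
#' @param tau_m memory time \[s\].
#' @param span_factor required history span beyond the delay, in units of
#'   tau_m (precondition; default 10).
#' @return scalar or per-node vector.
#' @export
delay_integral <- function(times, f, t, tau_r, tau_m, span_factor = 10) {
  if (!is.matrix(f)) f <- matrix(f, ncol = 1)
  Tend <- t - tau_r
  if (times[1] > Tend - span_factor * tau_m + 1e-9)
    stop("insufficient history span: need samples back to t - tau_r - ",
         span_factor, " * tau_m")
  keep <- times <= Tend + 1e-12
  tt <- times[keep]
  ff <- f[keep, , drop = FALSE]
  if (tt[length(tt)] < Tend - 1e-12) {
    # interpolate the signal at the delayed evaluation time
    i <- length(tt)
    if (i < length(times)) {
      w <- (Tend - times[i]) / (times[i + 1] - times[i])
      ff <- rbind(ff, (1 - w) * f[i, ] + w * f[i + 1, ])
    } else {
      ff <- rbind(ff, f[i, ])
    }
    tt <- c(tt, Tend)
  }
  # fully converged tail before the first sample, then exact per-interval
  # exponential recurrence for kernel x linear interpolant
  I <- ff[1, ]
  if (length(tt) > 1) {
    for (i in seq_len(length(tt) - 1)) {
      a <- (tt[i + 1] - tt[i]) / tau_m
      mu <- exp(-a)
      c1 <- (a - 1 + mu) / a
      c0 <- (1 - mu * (1 + a)) / a
      I <- mu * I + c0 * ff[i, ] + c1 * ff[i + 1, ]
    }
  }
  drop(I)
}

#' Gravitropic spontaneous-strain rates
#'
#' Delayed, exponentially remembered reorientation toward the perceived
#' gravity vector:
#' du1*/dt = -(beta epsdot / r) I\[h2\], du2*/dt = +(beta epsdot / r) I\[h1\],
#' with I the [delay_integral()] over the history buffer.
#'
#' @param history a `stimulus_history`.
#' @param t evaluation time \[s\].
#' @param params `stimulus_params`.
#' @param epsdot per-node strain rate \[1/s\].
#' @return matrix with columns du1, du2 \[1/(m s)\].
#' @export
gravitropic_rate <- function(history, t, params, epsdot) {
  if (params$beta == 0)
    return(cbind(du1 = 0 * epsdot, du2 = 0 * epsdot))
  I2 <- delay_integral(history$times, history$h2, t, params$tau_r, params$tau_m)
  I1 <- delay_integral(history$times, history$h1, t, params$tau_r, params$tau_m)
  cbind(du1 = -params$beta * epsdot / params$r * I2,
        du2 = params$beta * epsdot / params$r * I1)
}

#' Proprioceptive spontaneous-strain rates
#'
#' Delayed curvature-driven straightening using the VISIBLE strains:
#' duj*/dt = -eta epsdot I\[u_j\], j = 1, 2.
#'
#' @inheritParams gravitropic_rate
#' @return matrix with columns du1, du2 \[1/(m s)\].
#' @export
proprioceptive_rate <- function(history, t, params, epsdot) {
  if (params$eta == 0)
    return(cbind(du1 = 0 * epsdot, du2 = 0 * epsdot))
  I1 <- delay_integral(history$times, history$u1, t, params$tau_br, params$tau_bm)
  I2 <- delay_integral(history$times, history$u2, t, params$tau_br, params$tau_bm)
  cbind(du1 = -params$eta * epsdot * I1,
        du2 = -params$eta * epsdot * I2)
}

#' Total spontaneous-strain rate
#'
#' Componentwise sum of the endogenous, gravitropic and proprioceptive
#' laws (separate signaling pathways, no cross-talk); the torsional
#' component is identically zero.
#'
#' @inheritParams gravitropic_rate
#' @return matrix with columns du1, du2, du3 (du3 = 0) \[1/(m s)\].
#' @export
total_spontaneous_rate <- function(history, t, params, epsdot) {
  e <- endogenous_rate(epsdot, t, params)
  g <- gravitropic_rate(history, t, params, epsdot)
  p <- proprioceptive_rate(history, t, params, epsdot)
  cbind(du1 = e[, 1] + g[, 1] + p[, 1],
        du2 = e[, 2] + g[, 2] + p[, 2],
        du3 = rep(0, length(epsdot)))
}
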