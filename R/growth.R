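#' Growth parameters
#'
#' Subapical growth with a piecewise-constant relative elemental growth
#' rate (REGR): zero below the growth zone, 1/tau_g inside it.
#'
#' @param l0 initial shoot length \[m\].
#' @param lg growth-zone length \[m\].
#' @param tau_g characteristic growth time \[s\].
#' @return object of class `growth_params`.
#' @export
growth_params <- function(l0, lg, tau_g) {
  stopifnot(l0 > 0, lg > 0, tau_g > 0)
  structure(list(l0 = l0, lg = lg, tau_g = tau_g,
                 analytic = l0 <= lg), class = "growth_params")
}

#' Relative elemental growth rate profile
#'
#' REGR(s) = 0 for s <= l - lg (below the growth zone) and 1/tau_g above it;
#' the apex always grows.
#'
#' @param s current arc length(s) \[m\], in \[0, l\].
#' @param l current shoot length \[m\].
#' @param params `growth_params`.
#' @return rate(s) \[1/s\].
#' @export
regr_profile <- function(s, l, params) {
  if (any(s < -1e-12) || any(s > l + 1e-12))
    stop("s must lie in [0, l]")
  ifelse(s > l - params$lg, 1 / params$tau_g, 0)
}

#' Shoot length over time
#'
#' Exponential elongation l(t) = l0 exp(t/tau_g) while l <= lg, then
#' constant-rate elongation dl/dt = lg/tau_g.
#' @param params `growth_params`.
#' @param t time(s) \[s\].
#' @return length(s) \[m\].
#' @export
growth_length <- function(params, t) {
  if (!params$analytic) {
    return(vapply(t, function(ti)
      growth_numeric(params, n_material = 64, t_end = ti)$l, numeric(1)))
  }
  t1 <- params$tau_g * log(params$lg / params$l0)
  ifelse(t <= t1,
         params$l0 * exp(t / params$tau_g),
         params$lg + params$lg / params$tau_g * (t - t1))
}

#' Exit time from the growth zone
#'
#' The time t*(S) at which material point S first satisfies
#' s(S, t) <= l(t) - lg. Inf for the apex (S = l0), which never exits.
#' @param params `growth_params`.
#' @param S material coordinate(s) in \[0, l0\] \[m\].
#' @return time(s) \[s\].
#' @export
exit_time <- function(params, S) {
  if (!params$analytic) stop("exit_time closed form requires l0 <= lg")
  t1 <- params$tau_g * log(params$lg / params$l0)
  out <- t1 + params$tau_g * log(params$l0 / (params$l0 - S))
  out[S >= params$l0] <- Inf
  out
}

# closed-form material-to-current map for l0 <= lg (vectorized in S)
growth_map_closed <- function(params, S, t) {
  l0 <- params$l0; lg <- params$lg; tg <- params$tau_g
  t1 <- tg * log(lg / l0)
  if (t <= t1) {
    g <- exp(t / tg)
    return(list(s = S * g, gamma = rep(g, length(S))))
  }
  b <- lg / tg * (t - t1)
  w0 <- S * lg / l0
  te <- exit_time(params, S)
  grow <- t < te
  s <- gamma <- numeric(length(S))
  s[grow] <- b + lg - (lg - w0[grow]) * exp((t - t1) / tg)
  gamma[grow] <- (lg / l0) * exp((t - t1) / tg)
  s[!grow] <- lg * log(l0 / (l0 - S[!grow]))
  gamma[!grow] <- lg / (l0 - S[!grow])
  list(s = s, gamma = gamma)
}

#' Initialize a material-to-current growth map
#'
#' The material grid S in \[0, l0\] is fixed (Lagrangian parameterization);
#' `advance_growth()` evaluates the map s(S, t), the stretch gamma, exit
#' times and the lignifying Young's modulus at later times.
#'
#' @param params `growth_params`.
#' @param n_material number of material nodes.
#' @param lign optional `lignification_params` used to fill the modulus
#'   field `E`.
#' @return object of class `growth_map` with fields `S`, `s`, `gamma`,
#'   `t_star`, `t`, `E`.
#' @export
growth_map <- function(params, n_material = 200, lign = NULL) {
  S <- seq(0, params$l0, length.out = n_material)
  t_star <- if (params$analytic) exit_time(params, S) else rep(NA_real_, n_material)
  E <- if (is.null(lign)) rep(NA_real_, n_material)
       else young_modulus(t_star, 0, lign)
  structure(list(S = S, s = S, gamma = rep(1, n_material), t_star = t_star,
                 t = 0, l = params$l0, E = E, params = params, lign = lign),
            class = "growth_map")
}

#' Advance the growth map to time t
#'
#' Uses the analytic solution of the growth PDE (exponential branch while
#' l <= lg, then constant-rate elongation with the sub-basal region
#' frozen). Falls back to numerical integration when l0 > lg.
#'
#' @param map a `growth_map`.
#' @param t target time \[s\] (>= 0).
#' @return the map evaluated at time t.
#' @export
advance_growth <- function(map, t) {
  if (!inherits(map, "growth_map")) stop("map must be a growth_map")
  stopifnot(t >= 0)
  params <- map$params
  if (params$analytic) {
    cm <- growth_map_closed(params, map$S, t)
    map$s <- cm$s
    map$gamma <- cm$gamma
    map$l <- growth_length(params, t)
  } else {
    num <- growth_numeric(params, n_material = length(map$S), t_end = t,
                          S = map$S)
    map$s <- num$s
    map$gamma <- num$gamma
    map$l <- num$l
    map$t_star <- num$t_star
  }
  map$t <- t
  if (!is.null(map$lign)) map$E <- young_modulus(map$t_star, t, map$lign)
  map
}

# time-stepped integration of the growth PDE (used when l0 > lg, and as a
# total fallback); exponential update of gamma per step, trapezoid for s
growth_numeric <- function(params, n_material = 200, t_end, dt = NULL,
                           S = NULL) {
  if (is.null(S)) S <- seq(0, params$l0, length.out = n_material)
  if (is.null(dt)) dt <- params$tau_g / 2000
  gamma <- rep(1, length(S))
  t_star <- rep(Inf, length(S))
  mar_prev <- rep(1, length(S))  # s - (l - lg) margin, > 0 while growing
  t <- 0
  cum_s <- function(gamma) c(0, cumsum((gamma[-1] + gamma[-length(gamma)]) / 2 * diff(S)))
  s <- cum_s(gamma)
  while (t < t_end - 1e-12) {
    h <- min(dt, t_end - t)
    l <- s[length(s)]
    regr <- ifelse(s > l - params$lg, 1 / params$tau_g, 0)
    gamma <- gamma * exp(regr * h)
    t <- t + h
    s <- cum_s(gamma)
    l <- s[length(s)]
    mar <- s - (l - params$lg)
    crossed <- which(mar <= 0 & mar_prev > 0 & is.infinite(t_star))
    if (length(crossed)) {
      # linear interpolation of the crossing time between steps
      frac <- mar_prev[crossed] / (mar_prev[crossed] - mar[crossed])
      t_star[crossed] <- t - h + frac * h
    }
    mar_prev <- mar
  }
  list(S = S, s = s, gamma = gamma, l = s[length(s)], t_star = t_star)
}

#' Lignification parameters
#'
#' Exponential stiffening of tissue after it exits the growth zone.
#' @param E0 initial Young's modulus \[Pa\].
#' @param E1 asymptotic modulus \[Pa\] (>= E0).
#' @param tau_l lignification time \[s\].
#' @return object of class `lignification_params`.
#' @export
lignification_params <- function(E0 = 1e7, E1 = 200 * E0, tau_l = 6 * 86400) {
  stopifnot(E0 > 0, E1 >= E0, tau_l > 0)
  structure(list(E0 = E0, E1 = E1, tau_l = tau_l),
            class = "lignification_params")
}

#' Young's modulus under lignification
#'
#' E = E1 - (E1 - E0) exp(-max\{0, t - t*\}/tau_l): tissue stiffens only
#' after leaving the growth zone at its exit time t*.
#' @param t_star exit time(s) \[s\] (Inf for material that never exits).
#' @param t current time \[s\].
#' @param params `lignification_params`.
#' @return modulus \[Pa\].
#' @export
young_modulus <- function(t_star, t, params) {
  stopifnot(t >= 0)
  params$E1 - (params$E1 - params$E0) * exp(-pmax(0, t - t_star) / params$tau_l)
}

#' Export a growth curve table
#'
#' Delimited text with t, l(t) and the trajectories s(S_i, t) of a set of
#' material markers.
#' @param params `growth_params`.
#' @param times vector of times \[s\].
#' @param markers material coordinates \[m\] (default 9 equally spaced).
#' @param path optional file; if given, written as tab-separated text.
#' @return the data.frame, invisibly if written.
#' @export
growth_curve <- function(params, times, markers = NULL, path = NULL) {
  if (is.null(markers)) markers <- seq(0, params$l0, length.out = 9)
  rows <- lapply(times, function(t) {
    cm <- growth_map_closed(params, markers, t)
    c(t = t, l = growth_length(params, t), stats::setNames(cm$s, paste0("s", seq_along(markers))))
  })
  df <- as.data.frame(do.call(rbind, rows))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
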