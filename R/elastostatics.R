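#' Elastic and loading parameters
#'
#' @param E Young's modulus \[Pa\]: scalar or per-node vector.
#' @param r cross-section radius \[m\].
#' @param nu_poisson Poisson's ratio (0..0.5).
#' @param rho mass density \[kg/m^3\].
#' @param g_accel gravitational acceleration \[m/s^2\].
#' @param shear_modulus_convention `"standard"` uses the isotropic
#'   mu = E/(2(1+nu)); `"as_printed"` uses mu = 2E(1+nu), an alternative
#'   convention surfaced for sensitivity checks (it makes mu > E, which is
#'   unphysical for an isotropic material at nu = 0.5).
#' @return object of class `elastic_params`.
#' @export
elastic_params <- function(E = 1e7, r = 5e-4, nu_poisson = 0.5,
                           rho = 1000, g_accel = 9.81,
                           shear_modulus_convention = c("standard", "as_printed")) {
  shear_modulus_convention <- match.arg(shear_modulus_convention)
  stopifnot(all(E > 0), r > 0, nu_poisson >= 0, nu_poisson <= 0.5,
            rho > 0, g_accel >= 0)
  structure(list(E = E, r = r, nu_poisson = nu_poisson, rho = rho,
                 g_accel = g_accel,
                 shear_modulus_convention = shear_modulus_convention),
            class = "elastic_params")
}

#' Distributed gravity load per unit length
#' @param params `elastic_params`.
#' @return q = rho g A \[N/m\].
#' @export
gravity_load <- function(params) {
  params$rho * params$g_accel * pi * params$r^2
}

#' Bending and torsional stiffnesses
#'
#' K1 = K2 = E I with I = pi r^4 / 4; K3 = mu J with J = 2 I and mu per
#' the chosen shear-modulus convention.
#'
#' @param params `elastic_params`.
#' @return list with per-node (or scalar) `K1`, `K2`, `K3` \[N m^2\].
#' @export
stiffnesses <- function(params) {
  I <- pi * params$r^4 / 4
  K1 <- params$E * I
  mu <- if (params$shear_modulus_convention == "standard")
    params$E / (2 * (1 + params$nu_poisson))
  else 2 * params$E * (1 + params$nu_poisson)
  list(K1 = K1, K2 = K1, K3 = mu * 2 * I)
}

#' Contact force under distributed gravity
#'
#' n(s) = q (l - s) g_dir, the integral of the Kirchhoff force balance
#' with the free-tip condition n(l) = 0.
#'
#' @param s arc length(s) \[m\] in \[0, l\].
#' @param l shoot length \[m\].
#' @param q distributed load \[N/m\].
#' @param g_dir unit gravity direction.
#' @return matrix (length(s) x 3) \[N\].
#' @export
contact_force <- function(s, l, q, g_dir = c(0, 0, -1)) {
  outer(q * (l - s), g_dir)
}

#' Quasi-static Kirchhoff equilibrium of the rod
#'
#' Solves the coupled nonlinear system: visible strains u = u* + m_j/K_j,
#' moment balance dm/ds = q (l - s) g x d3 with m(l) = 0, and the frame
#' reconstruction, by an under-relaxed fixed point on the strain field.
#' Convergence is declared when successive tip positions differ by less
#' than `tol_tip`; non-convergence (proximity to a fold or buckling)
#' raises a `morphorod_equilibrium_failure` error.
#'
#' @param u_star n x 3 spontaneous strains on the grid \[1/m\] (third
#'   column must be zero).
#' @param grid `rod_grid` or arc-length vector.
#' @param params `elastic_params` (per-node E allowed).
#' @param base_frame base clamp frame (default upright).
#' @param g_dir unit gravity direction (default -z).
#' @param q distributed load \[N/m\]; default `gravity_load(params)`.
#' @param u_init initial guess for the visible strains (warm start).
#' @param relax under-relaxation factor (default 0.5).
#' @param tol_tip tip-displacement convergence tolerance \[m\].
#' @param max_iter maximum fixed-point iterations.
#' @return list with `state` (a `rod_state`), `m` (n x 3 contact couple,
#'   world components \[N m\]), `n` (n x 3 contact force \[N\]), `u_e`
#'   (n x 3 elastic strains \[1/m\]), `converged`, `iterations`.
#' @export
solve_equilibrium <- function(u_star, grid, params,
                              base_frame = frame_identity(),
                              g_dir = c(0, 0, -1), q = NULL,
                              u_init = NULL, relax = 0.5,
                              tol_tip = 1e-9, max_iter = 200) {
  grid <- as_rod_grid(grid)
  n <- grid$n_nodes
  u_star <- as.matrix(u_star)
  stopifnot(nrow(u_star) == n, ncol(u_star) == 3)
  if (max(abs(u_star[, 3])) > 1e-12)
    stop("spontaneous torsional strain must be zero (u3* == 0)")
  K <- stiffnesses(params)
  K1 <- rep_len(K$K1, n)
  K3 <- rep_len(K$K3, n)
  if (is.null(q)) q <- gravity_load(params)
  if (is.null(u_init)) u_init <- u_star
  if (!inherits(base_frame, "rod_frame"))
    base_frame <- rod_frame(base_frame[, 1], base_frame[, 2], base_frame[, 3])
  res <- cpp_solve_equilibrium(u_star, grid$s, K1, K3, q, g_dir,
                               unclass(base_frame), c(0, 0, 0),
                               as.matrix(u_init), relax, tol_tip, max_iter)
  if (!res$converged)
    stop(structure(class = c("morphorod_equilibrium_failure", "error",
                             "condition"),
                   list(message = paste0(
                          "equilibrium fixed point did not converge in ",
                          max_iter, " iterations (possible fold/buckling)"),
                        call = sys.call())))
  state <- new_rod_state(grid, res$p, res$d1, res$d2, res$d3, res$u)
  list(state = state, m = res$m,
       n = contact_force(grid$s, grid$length, q, g_dir),
       u_e = res$u - u_star,
       converged = res$converged, iterations = res$iterations)
}

.morphorod_cache <- new.env(parent = emptyenv())

#' Self-weight buckling coefficient of a clamped-free column
#'
#' The marginal eigenvalue alpha0 = q l^3 / (E I) at which a vertical
#' prismatic rod buckles under its own distributed weight. Computed from
#' the discretized linearized bending eigenproblem
#' -theta'' = lambda (1 - s) theta, theta(0) = 0, theta'(1) = 0
#' (cell-centered second-order finite differences, symmetric generalized
#' eigenvalue solve), or from the classical closed form
#' (9/4) j^2 with j the first positive zero of the Bessel function of
#' order -1/3.
#'
#' @param n number of cells for the eigenvalue solve.
#' @param method `"eigen"` (discretized eigenproblem, default) or
#'   `"bessel"` (closed form).
#' @return alpha0 (dimensionless, approximately 7.837).
#' @export
self_buckling_alpha0 <- function(n = 1000, method = c("eigen", "bessel")) {
  method <- match.arg(method)
  key <- paste0("alpha0_", method, "_", n)
  if (!is.null(.morphorod_cache[[key]])) return(.morphorod_cache[[key]])
  val <- if (method == "bessel") {
    j <- stats::uniroot(function(x) besselJ(x, -1 / 3), c(1.5, 2.2),
                        tol = 1e-13)$root
    2.25 * j^2
  } else {
    h <- 1 / n
    sm <- (seq_len(n) - 0.5) * h
    # A theta = lambda diag(1 - s) theta, A = -d^2/ds^2 with ghost-node BCs
    main <- rep(2, n) / h^2
    main[1] <- 3 / h^2   # Dirichlet at s = 0 (ghost reflection)
    main[n] <- 1 / h^2   # Neumann at s = 1
    off <- rep(-1 / h^2, n - 1)
    A <- diag(main)
    A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
    A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
    b <- 1 / sqrt(1 - sm)
    C <- A * outer(b, b)
    min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  }
  .morphorod_cache[[key]] <- val
  val
}

#' Self-buckling length
#'
#' l_c = (alpha0 E I / q)^(1/3), the length at which a vertical rod of
#' uniform stiffness buckles under its own weight. For q = 0 there is no
#' elastic limit and Inf is returned (flagged).
#'
#' @param params `elastic_params` (uniform E; if per-node, the first value
#'   is used as the pre-lignification reference).
#' @param q distributed load \[N/m\]; default `gravity_load(params)`.
#' @param alpha0 buckling coefficient; default the cached eigenvalue solve.
#' @return length \[m\], with attribute `no_elastic_limit = TRUE` when Inf.
#' @export
self_buckling_length <- function(params, q = NULL, alpha0 = NULL) {
  if (is.null(q)) q <- gravity_load(params)
  if (is.null(alpha0)) alpha0 <- self_buckling_alpha0()
  EI <- params$E[1] * pi * params$r^4 / 4
  if (q <= 0) {
    out <- Inf
    attr(out, "no_elastic_limit") <- TRUE
    return(out)
  }
  (alpha0 * EI / q)^(1 / 3)
}
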