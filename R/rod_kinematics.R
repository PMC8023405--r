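#' Arc-length grid for a rod
#'
#' Builds a uniform grid of arc-length samples from the clamped base
#' (`s = 0`) to the free apex (`s = l`). All lengths are in meters.
#'
#' @param l rod length \[m\].
#' @param n_nodes number of nodes (default 200; fields vary smoothly on a
#'   1--10 cm organ so a few hundred nodes suffice).
#' @return an object of class `rod_grid` with elements `s`, `n_nodes`,
#'   `length`.
#' @export
rod_grid <- function(l, n_nodes = 200) {
  stopifnot(is.numeric(l), length(l) == 1, l > 0, n_nodes >= 2)
  structure(list(s = seq(0, l, length.out = n_nodes),
                 n_nodes = as.integer(n_nodes), length = l),
            class = "rod_grid")
}

as_rod_grid <- function(x) {
  if (inherits(x, "rod_grid")) return(x)
  s <- as.numeric(x)
  if (length(s) < 2 || any(diff(s) <= 0))
    stop("grid arc lengths must be strictly increasing")
  if (abs(s[1]) > 1e-12) stop("grid must start at s = 0")
  structure(list(s = s, n_nodes = length(s), length = s[length(s)]),
            class = "rod_grid")
}

#' Orthonormal director frame
#'
#' A director frame \{d1, d2, d3\} with d3 = d1 x d2, the cross-section
#' normal and centerline tangent.
#'
#' @param d1,d2,d3 unit 3-vectors.
#' @param tol orthonormality tolerance.
#' @return object of class `rod_frame` (a 3x3 matrix with columns d1, d2, d3).
#' @export
rod_frame <- function(d1, d2, d3 = NULL, tol = 1e-9) {
  if (is.null(d3)) d3 <- c(d1[2] * d2[3] - d1[3] * d2[2],
                           d1[3] * d2[1] - d1[1] * d2[3],
                           d1[1] * d2[2] - d1[2] * d2[1])
  R <- cbind(d1, d2, d3, deparse.level = 0)
  G <- crossprod(R)
  if (max(abs(G - diag(3))) > tol)
    stop("frame is not orthonormal (deviation ",
         format(max(abs(G - diag(3)))), ")")
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  if (max(abs(cr - R[, 3])) > tol) stop("frame must satisfy d3 = d1 x d2")
  structure(R, class = "rod_frame")
}

#' Identity (upright) base frame
#'
#' The clamp of the trivial upright state: d3 points along +z (opposing
#' gravity when gravity is -z), d1 and d2 span the horizontal plane.
#' @return a `rod_frame`.
#' @export
frame_identity <- function() rod_frame(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

new_rod_state <- function(grid, p, d1, d2, d3, u) {
  structure(list(grid = grid, p = p, d1 = d1, d2 = d2, d3 = d3, u = u),
            class = "rod_state")
}

#' Reconstruct a rod from its strain field
#'
#' Integrates the frame equations d(d_j)/ds = u x d_j, d3 = dp/ds from the
#' base upward. Each grid interval applies the exact rotation generated by
#' the interval-midpoint strain vector (an exponential-map update), so the
#' director frame stays orthonormal by construction.
#'
#' @param u n x 3 matrix of strain components (u1, u2, u3) in the local
#'   director basis \[1/m\].
#' @param base_frame `rod_frame` at the clamped base.
#' @param grid `rod_grid` or numeric vector of arc lengths.
#' @param p0 base position (default origin).
#' @return a `rod_state`: grid, centerline `p` (n x 3), directors `d1`,
#'   `d2`, `d3` (n x 3), strains `u`.
#' @export
integrate_frame <- function(u, base_frame, grid, p0 = c(0, 0, 0)) {
  grid <- as_rod_grid(grid)
  u <- as.matrix(u)
  if (nrow(u) != grid$n_nodes || ncol(u) != 3)
    stop("u must be an n_nodes x 3 matrix")
  if (!inherits(base_frame, "rod_frame"))
    base_frame <- rod_frame(base_frame[, 1], base_frame[, 2], base_frame[, 3])
  res <- cpp_integrate_frame(u, grid$s, unclass(base_frame), p0)
  new_rod_state(grid, res$p, res$d1, res$d2, res$d3, u)
}

#' Geometric curvature and visible normal
#'
#' kappa = sqrt(u1^2 + u2^2); the visible normal is the unit vector
#' nu = kappa^-1 d(d3)/ds = (u2 d1 - u1 d2)/kappa, undefined where the rod
#' is locally straight.
#'
#' @param state a `rod_state`.
#' @param tol curvature below which the normal is flagged undefined
#'   (default 1e-8 1/m, the numerical floor of the straight state).
#' @return list with `kappa` (n), `normal` (n x 3, NA rows where
#'   undefined), `defined` (logical n).
#' @export
curvature_and_normal <- function(state, tol = 1e-8) {
  u <- state$u
  kappa <- sqrt(u[, 1]^2 + u[, 2]^2)
  defined <- kappa > tol
  normal <- (u[, 2] * state$d1 - u[, 1] * state$d2) / kappa
  normal[!defined, ] <- NA_real_
  list(kappa = kappa, normal = normal, defined = defined)
}

#' Tip position of a rod state
#' @param state a `rod_state`.
#' @return 3-vector, the centerline position at s = l \[m\].
#' @export
tip_position <- function(state) state$p[nrow(state$p), ]

#' Maximum deviation of the director frames from orthonormality
#' @param state a `rod_state`.
#' @return max over nodes of |Gram - I|.
#' @export
frame_gram_error <- function(state) {
  n <- nrow(state$p)
  err <- 0
  for (i in seq_len(n)) {
    R <- cbind(state$d1[i, ], state$d2[i, ], state$d3[i, ])
    err <- max(err, max(abs(crossprod(R) - diag(3))))
  }
  err
}

#' Write / read a rod shape snapshot
#'
#' Delimited text table with columns s, px, py, pz, d1x..d3z, u1, u2, u3
#' (SI units, header line).
#' @param state a `rod_state`.
#' @param path file path.
#' @export
write_rod_snapshot <- function(state, path) {
  df <- data.frame(s = state$grid$s,
                   px = state$p[, 1], py = state$p[, 2], pz = state$p[, 3],
                   d1x = state$d1[, 1], d1y = state$d1[, 2], d1z = state$d1[, 3],
                   d2x = state$d2[, 1], d2y = state$d2[, 2], d2z = state$d2[, 3],
                   d3x = state$d3[, 1], d3y = state$d3[, 2], d3z = state$d3[, 3],
                   u1 = state$u[, 1], u2 = state$u[, 2], u3 = state$u[, 3])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rod_snapshot
#' @export
read_rod_snapshot <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  grid <- as_rod_grid(df$s)
  new_rod_state(grid,
                as.matrix(df[, c("px", "py", "pz")]),
                as.matrix(df[, c("d1x", "d1y", "d1z")]),
                as.matrix(df[, c("d2x", "d2y", "d2z")]),
                as.matrix(df[, c("d3x", "d3y", "d3z")]),
                as.matrix(df[, c("u1", "u2", "u3")]))
}
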