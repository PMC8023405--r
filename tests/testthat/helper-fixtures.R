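# Shared fixtures: reference parameter bundles and small independent oracles.

table1_stimulus <- function(...) stimulus_params(...)
table1_elastic <- function(...) elastic_params(...)

# independent frame-integration oracle: dense first-order Euler stepping of
# d(d_j)/ds = u x d_j with re-orthonormalization, on a refined grid
euler_frame_oracle <- function(u_fun, l, n_fine = 20000) {
  s <- seq(0, l, length.out = n_fine)
  h <- s[2] - s[1]
  R <- diag(3)
  p <- c(0, 0, 0)
  for (i in seq_len(n_fine - 1)) {
    sm <- (s[i] + s[i + 1]) / 2
    ub <- u_fun(sm)
    uw <- R %*% ub                      # strain vector in world frame
    K <- matrix(c(0, uw[3], -uw[2], -uw[3], 0, uw[1], uw[2], -uw[1], 0), 3, 3)
    p <- p + h * R[, 3] + h^2 / 2 * (K %*% R[, 3])
    R <- R + h * (K %*% R)
    # re-orthonormalize
    q <- qr.Q(qr(R))
    R <- q %*% diag(sign(diag(crossprod(q, R))))
  }
  list(tip = p, R = R)
}

# closed-form statolith projection: cos(angle(h, g)) follows -tanh in time
statolith_projection_closed <- function(c0, t, tau_a) {
  t0 <- tau_a * atanh(c0)
  -tanh((t - t0) / tau_a)
}

run_probe <- function(l, tau_g, scenario, n_nodes = 60, periods = 20, ...) {
  morphorod:::probe_unstable(l, tau_g, scenario, table1_stimulus(...),
                             table1_elastic(), n_nodes = n_nodes,
                             horizon_periods = periods)
}
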