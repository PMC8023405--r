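upright_frames <- function(n) {
  list(d1 = matrix(rep(c(1, 0, 0), each = n), n, 3),
       d2 = matrix(rep(c(0, 1, 0), each = n), n, 3),
       d3 = matrix(rep(c(0, 0, 1), each = n), n, 3))
}

test_that("h = -g is a statolith equilibrium and |h| is preserved", {
  fr <- upright_frames(3)
  h <- matrix(rep(c(0, 0, 1), each = 3), 3, 3)  # -g in body components
  h2 <- step_statoliths(h, fr, c(0, 0, -1), tau_a = 120, dt = 10)
  expect_equal(h2, h, tolerance = 1e-14)
  set.seed(7)
  h <- matrix(stats::rnorm(9), 3, 3)
  h <- h / sqrt(rowSums(h^2))
  for (k in 1:100) h <- step_statoliths(h, fr, c(0, 0, -1), 120, 10)
  expect_equal(sqrt(rowSums(h^2)), rep(1, 3), tolerance = 1e-9)
  # all initial conditions relax to -g (h3 -> 1 in the upright frame)
  expect_true(all(h[, 3] > 0.97))
  expect_error(step_statoliths(matrix(0, 1, 3), upright_frames(1),
                               c(0, 0, -1), 120, 10), "zero-norm")
})

test_that("statolith projection follows the -tanh closed form", {
  fr <- upright_frames(1)
  phi0 <- 2.0  # initial angle to -g
  h <- matrix(c(sin(phi0), 0, cos(phi0)), 1, 3)
  tau_a <- 120
  dt <- tau_a / 100
  c0 <- -cos(phi0)  # projection on g = (0,0,-1) is -h3
  err <- 0
  for (k in 1:500) {
    h <- step_statoliths(h, fr, c(0, 0, -1), tau_a, dt)
    c_num <- -h[1, 3]
    c_ana <- statolith_projection_closed(c0, k * dt, tau_a)
    err <- max(err, abs(c_num - c_ana))
  }
  expect_lt(err, 1e-6)
})

test_that("endogenous oscillator phase and scaling", {
  p <- table1_stimulus(alpha = 0.5)
  ed <- 1 / p$tau_e
  r0 <- endogenous_rate(ed, 0, p)
  expect_equal(as.numeric(r0), c(0.5 * ed / p$r, 0))
  rq <- endogenous_rate(ed, p$tau_e / 4, p)
  expect_equal(as.numeric(rq), c(0, 0.5 * ed / p$r), tolerance = 1e-12)
  expect_equal(as.numeric(endogenous_rate(0, 123, p)), c(0, 0))
})

test_that("exponential kernel has unit mass and matches a closed form", {
  tau_m <- 720
  times <- seq(-10 * tau_m - 800, 0, by = tau_m / 20)
  ones <- rep(1, length(times))
  expect_equal(delay_integral(times, ones, 0, tau_r = 720, tau_m = tau_m), 1,
               tolerance = 1e-12)
  # exponentially decaying signal: I(T) = exp(lambda T)/(1 + lambda tau_m)
  lam <- 1 / 3000
  f <- exp(lam * times)
  Tend <- -720
  expect_equal(delay_integral(times, f, 0, 720, tau_m),
               exp(lam * Tend) / (1 + lam * tau_m), tolerance = 1e-4)
  expect_error(delay_integral(seq(-1000, 0, 10), rep(1, 101), 0, 720, 720),
               "insufficient history")
})

test_that("gravitropic law reproduces the constant-history limit", {
  p <- table1_stimulus()
  ed <- 1e-5
  times <- seq(-10 * p$tau_m - p$tau_r - 100, 0, by = 36)
  nt <- length(times)
  hist <- stimulus_history(times,
                           h1 = matrix(0.3, nt, 2), h2 = matrix(-0.1, nt, 2),
                           u1 = matrix(0, nt, 2), u2 = matrix(0, nt, 2))
  g <- gravitropic_rate(hist, 0, p, epsdot = c(ed, ed))
  expect_equal(g[, "du1"], rep(-p$beta * ed / p$r * (-0.1), 2),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(g[, "du2"], rep(p$beta * ed / p$r * 0.3, 2),
               tolerance = 1e-10, ignore_attr = TRUE)
  # upright rod: h1 = h2 = 0 -> no forcing; beta = 0 -> no forcing
  hist0 <- stimulus_history(times, h1 = matrix(0, nt, 1),
                            h2 = matrix(0, nt, 1),
                            u1 = matrix(0, nt, 1), u2 = matrix(0, nt, 1))
  expect_equal(as.numeric(gravitropic_rate(hist0, 0, p, ed)), c(0, 0))
  p0 <- table1_stimulus(beta = 0)
  expect_equal(as.numeric(gravitropic_rate(hist, 0, p0, c(ed, ed))),
               rep(0, 4))
})

test_that("proprioceptive law straightens against remembered visible strain", {
  p <- table1_stimulus()
  ed <- 1e-5
  times <- seq(-10 * p$tau_bm - p$tau_br - 100, 0, by = 36)
  nt <- length(times)
  hist <- stimulus_history(times, h1 = matrix(0, nt, 1), h2 = matrix(0, nt, 1),
                           u1 = matrix(2.5, nt, 1), u2 = matrix(0, nt, 1))
  pr <- proprioceptive_rate(hist, 0, p, ed)
  expect_equal(as.numeric(pr), c(-p$eta * ed * 2.5, 0), tolerance = 1e-10)
  p0 <- table1_stimulus(eta = 0)
  expect_equal(as.numeric(proprioceptive_rate(hist, 0, p0, ed)), c(0, 0))
})

test_that("total rate is the componentwise sum with zero torsion", {
  p <- table1_stimulus(alpha = 0.2)
  ed <- 2e-5
  times <- seq(-10 * 720 - 820, 0, by = 36)
  nt <- length(times)
  hist <- stimulus_history(times, h1 = matrix(0.1, nt, 1),
                           h2 = matrix(0.2, nt, 1),
                           u1 = matrix(1.0, nt, 1), u2 = matrix(-0.5, nt, 1))
  tot <- total_spontaneous_rate(hist, 0, p, ed)
  ref <- endogenous_rate(ed, 0, p) + gravitropic_rate(hist, 0, p, ed) +
    proprioceptive_rate(hist, 0, p, ed)
  expect_equal(tot[, 1:2], ref, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(as.numeric(tot[, 3]), 0)
  # alpha = beta = eta = 0 -> identically zero
  pz <- stimulus_params(alpha = 0, beta = 0, eta = 0)
  expect_equal(as.numeric(total_spontaneous_rate(hist, 0, pz, ed)), rep(0, 3))
})
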