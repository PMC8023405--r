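test_that("stiffnesses follow the circular-section formulas", {
  ep <- table1_elastic()
  K <- stiffnesses(ep)
  expect_equal(K$K1, 1e7 * pi * (5e-4)^4 / 4, tolerance = 1e-12)
  expect_equal(K$K1, 4.909e-7, tolerance = 1e-4)
  expect_equal(K$K1, K$K2)
  # r^4 scaling
  K2 <- stiffnesses(table1_elastic(r = 1e-3))
  expect_equal(K2$K1 / K$K1, 16, tolerance = 1e-12)
  # torsional stiffness under both shear-modulus conventions (nu = 0.5)
  expect_equal(K$K3 / K$K1, 2 / 3, tolerance = 1e-12)
  Kp <- stiffnesses(table1_elastic(shear_modulus_convention = "as_printed"))
  expect_equal(Kp$K3 / Kp$K1, 4 * 1.5, tolerance = 1e-12)
})

test_that("contact force integrates the distributed weight from the free tip", {
  n <- contact_force(c(0, 0.02, 0.05), l = 0.05, q = 2e-3)
  expect_equal(n[3, ], c(0, 0, 0))                     # n(l) = 0
  expect_equal(n[1, ], c(0, 0, -2e-3 * 0.05))          # base: ql downward
  expect_equal(contact_force(0.01, 0.05, 0), matrix(0, 1, 3))
})

test_that("without load the equilibrium is the intrinsic shape", {
  n <- 80
  g <- rod_grid(0.05, n)
  us <- cbind(10 * sin(g$s * 100), 5 * cos(g$s * 60), 0)
  eq <- solve_equilibrium(us, g, table1_elastic(), q = 0)
  expect_equal(eq$state$u, us, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(max(abs(eq$m)), 0)
  expect_equal(max(abs(eq$u_e)), 0)
})

test_that("small-load heavy cantilever matches q l^4 / (8 EI)", {
  ep <- table1_elastic()
  EI <- stiffnesses(ep)$K1
  l <- 0.05
  q <- 2e-5   # deflection ~ 3e-5 m << l: linear regime
  base <- rod_frame(c(0, 0, -1), c(0, 1, 0), c(1, 0, 0))  # horizontal rod
  eq <- solve_equilibrium(matrix(0, 200, 3), rod_grid(l, 200), ep,
                          base_frame = base, q = q)
  defl <- -tip_position(eq$state)[3]
  expect_equal(defl, q * l^4 / (8 * EI), tolerance = 0.01)
  # elastic strains scale linearly in q for small loads
  eq2 <- solve_equilibrium(matrix(0, 200, 3), rod_grid(l, 200), ep,
                           base_frame = base, q = 2 * q)
  expect_equal(max(abs(eq2$u_e)) / max(abs(eq$u_e)), 2, tolerance = 1e-3)
})

test_that("moment balance residual vanishes at convergence", {
  ep <- table1_elastic()
  n <- 150
  l <- 0.06
  g <- rod_grid(l, n)
  us <- cbind(rep(5, n), rep(2, n), 0)
  q <- gravity_load(ep)
  eq <- solve_equilibrium(us, g, ep, q = q)
  s <- g$s
  h <- s[2] - s[1]
  dm <- (eq$m[3:n, ] - eq$m[1:(n - 2), ]) / (2 * h)
  # g x d3 with g = (0, 0, -1) is (d3y, -d3x, 0)
  gxd3 <- cbind(eq$state$d3[2:(n - 1), 2], -eq$state$d3[2:(n - 1), 1], 0)
  rhs <- q * (l - s[2:(n - 1)]) * gxd3
  expect_lt(max(abs(dm - rhs)), 5e-3 * q * l)
  # boundary conditions hold exactly
  expect_equal(eq$m[n, ], c(0, 0, 0))
})

test_that("planar intrinsic shape with in-plane gravity stays planar", {
  ep <- table1_elastic()
  n <- 100
  g <- rod_grid(0.06, n)
  us <- cbind(0, rep(4, n), 0)  # bend in the x-z plane
  eq <- solve_equilibrium(us, g, ep)
  expect_lt(max(abs(eq$state$p[, 2])), 1e-12)
})

test_that("vertical rod is stable below and buckles above the critical length", {
  ep <- table1_elastic()
  lc <- self_buckling_length(ep)
  n <- 120
  ui <- matrix(0, n, 3); ui[, 1] <- 1e-3
  eq_lo <- solve_equilibrium(matrix(0, n, 3), rod_grid(0.9 * lc, n), ep,
                             u_init = ui, max_iter = 500)
  expect_lt(sqrt(sum(tip_position(eq_lo$state)[1:2]^2)), 1e-7)
  eq_hi <- solve_equilibrium(matrix(0, n, 3), rod_grid(1.1 * lc, n), ep,
                             u_init = ui, max_iter = 500)
  expect_gt(sqrt(sum(tip_position(eq_hi$state)[1:2]^2)), 0.01)
})

test_that("Greenhill coefficient: eigenvalue solve agrees with the Bessel zero", {
  a_b <- self_buckling_alpha0(method = "bessel")
  a_e <- self_buckling_alpha0(n = 1000)
  expect_equal(a_b, 7.837, tolerance = 1e-4)
  expect_equal(a_e / a_b, 1, tolerance = 1e-4)
  # discretization error shrinks under mesh refinement
  e400 <- abs(self_buckling_alpha0(n = 400) - a_b)
  e800 <- abs(self_buckling_alpha0(n = 800) - a_b)
  expect_lt(e800, e400)
})

test_that("self-buckling length: reference value, scaling and q = 0 flag", {
  ep <- table1_elastic()
  lc <- self_buckling_length(ep)
  expect_equal(lc, 0.0794, tolerance = 2e-3)
  expect_equal(0.0659 / lc, 0.83, tolerance = 0.01)
  lc8 <- self_buckling_length(table1_elastic(E = 8e7))
  expect_equal(lc8 / lc, 2, tolerance = 1e-9)
  lc0 <- self_buckling_length(ep, q = 0)
  expect_true(is.infinite(lc0))
  expect_true(attr(lc0, "no_elastic_limit"))
})

test_that("equilibrium failure is reported as a typed condition", {
  ep <- table1_elastic()
  n <- 80
  ui <- matrix(0, n, 3)
  ui[, 1] <- 1e-3
  expect_error(solve_equilibrium(matrix(0, n, 3), rod_grid(0.079, n), ep,
                                 u_init = ui, max_iter = 15),
               class = "morphorod_equilibrium_failure")
})
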