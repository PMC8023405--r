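fig7_config <- function(t_end, n_nodes = 40, ...) {
  gp <- growth_params(l0 = 0.05, lg = 0.07, tau_g = 72000)
  simulation_config(gp, stimulus = stimulus_params(alpha = 0.4),
                    t_end = t_end, n_nodes = n_nodes, ...)
}

test_that("without forcing a subcritical shoot stays upright while growing", {
  gp <- growth_params(l0 = 0.02, lg = 0.04, tau_g = 72000)
  cfg <- simulation_config(gp,
                           stimulus = stimulus_params(alpha = 0, beta = 0,
                                                      eta = 0),
                           t_end = 4 * 3600, n_nodes = 40,
                           perturb = list(amplitude = 0, spin = 0),
                           fast_statoliths = TRUE)
  sim <- run_simulation(cfg)
  tr <- sim$trajectory
  expect_lt(max(abs(tr$x), abs(tr$y)), 1e-12)
  # the tip height tracks the analytic shoot length
  expect_equal(tr$z, growth_length(gp, tr$t), tolerance = 1e-6)
  expect_true(all(diff(tr$l) >= 0))
})

test_that("tip stays within the shoot length and times are increasing", {
  cfg <- fig7_config(2 * 3600)
  sim <- run_simulation(cfg)
  tr <- sim$trajectory
  expect_true(all(diff(tr$t) > 0))
  expect_true(all(sqrt(tr$x^2 + tr$y^2 + tr$z^2) <= tr$l + 1e-9))
})

test_that("frozen growth and fast statoliths reproduce the reduced model", {
  l <- 0.06
  gp <- growth_params(l0 = l, lg = 0.07, tau_g = 72000)
  st <- stimulus_params(alpha = 0.4)
  cfgF <- simulation_config(gp, stimulus = st, t_end = 2 * 3600,
                            n_nodes = 50, out_every = 5,
                            fast_statoliths = TRUE, freeze_growth = TRUE,
                            perturb = list(amplitude = 1e-4 / l, spin = 0))
  cfgR <- reduced_config(l, 72000, scenario = "with_endogenous",
                         stimulus = st, n_nodes = 50,
                         horizon = 2 * 3600, dt = cfgF$dt, out_every = 5,
                         perturb = list(amplitude = 1e-4 / l, spin = 0))
  f <- run_simulation(cfgF)
  r <- simulate_reduced(cfgR)
  m <- merge(f$trajectory, r$trajectory, by = "t")
  expect_gt(nrow(m), 100)
  expect_lt(max(abs(m$x.x - m$x.y), abs(m$y.x - m$y.y), abs(m$z.x - m$z.y)),
            1e-12)
})

test_that("statolith transient vanishes as the avalanche time shrinks", {
  l <- 0.06
  gp <- growth_params(l0 = l, lg = 0.07, tau_g = 72000)
  mk <- function(tau_a, fast) {
    st <- stimulus_params(alpha = 0.4, tau_a = tau_a)
    simulation_config(gp, stimulus = st, t_end = 3600, n_nodes = 40,
                      out_every = 5, fast_statoliths = fast,
                      freeze_growth = TRUE, dt = 3,
                      perturb = list(amplitude = 1e-3 / l, spin = 0))
  }
  fast <- run_simulation(mk(120, TRUE))$trajectory
  slow <- run_simulation(mk(120, FALSE))$trajectory
  quick <- run_simulation(mk(12, FALSE))$trajectory
  d_slow <- max(abs(slow$x - fast$x), abs(slow$y - fast$y))
  d_quick <- max(abs(quick$x - fast$x), abs(quick$y - fast$y))
  expect_lt(d_quick, d_slow / 3)
})

test_that("halving the step changes the trajectory by little in the stable regime", {
  l <- 0.055
  gp <- growth_params(l0 = l, lg = 0.07, tau_g = 72000)
  st <- stimulus_params(alpha = 0.4)
  mk <- function(dt) {
    simulation_config(gp, stimulus = st, t_end = 3600 * 2, n_nodes = 40,
                      dt = dt, out_every = round(360 / dt),
                      fast_statoliths = TRUE,
                      perturb = list(amplitude = 1e-4 / l, spin = 0))
  }
  a <- run_simulation(mk(12))$trajectory
  b <- run_simulation(mk(6))$trajectory
  m <- merge(a, b, by = "t")
  amp <- max(sqrt(m$x.x^2 + m$y.x^2))
  expect_lt(max(abs(m$x.x - m$x.y), abs(m$y.x - m$y.y)), 0.05 * amp)
})

test_that("checkpoint restart is bit-for-bit and divergence starts at the restart", {
  cfg <- fig7_config(2 * 3600, out_every = 5)
  full <- run_simulation(cfg)
  cfg1 <- cfg
  cfg1$t_end <- 3600
  half <- run_simulation(cfg1)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(half, ck)
  resumed <- restart_simulation(ck, t_end = 2 * 3600)
  expect_identical(full$trajectory, resumed$trajectory)
  # altered sensitivity after the restart point: identical before, not after
  altered <- restart_simulation(ck, t_end = 2 * 3600,
                                config_override = function(cf) {
                                  cf$stimulus$alpha <- 0.9
                                  cf
                                })
  m <- merge(full$trajectory, altered$trajectory, by = "t")
  pre <- m$t <= 3600
  expect_identical(max(abs(m$x.x[pre] - m$x.y[pre])), 0)
  expect_gt(max(abs(m$x.x[!pre] - m$x.y[!pre])), 0)
})

test_that("corrupt or mismatched checkpoints are refused cleanly", {
  f <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a checkpoint", f)
  expect_error(restart_simulation(f), "unreadable checkpoint")
  saveRDS(list(version = 99L), f)
  expect_error(restart_simulation(f), "version mismatch")
})
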