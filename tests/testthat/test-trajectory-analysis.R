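test_that("a synthetic circle yields one tone with the right period and sign", {
  tk <- make_synthetic_track(A = 0.01, B = 0, omega1 = 2 * pi / 3600,
                             omega2 = 1, duration = 8 * 3600, dt = 30)
  p <- estimate_periods(tk)
  expect_equal(nrow(p), 1)
  expect_equal(p$period[1], 3600, tolerance = 1e-3)
  expect_gt(p$frequency[1], 0)
  expect_equal(p$amplitude[1], 0.01, tolerance = 0.05)
  rep <- classify_pattern(tk)
  expect_identical(rep$label, "circular")
  expect_identical(rep$rotation_sign, 1L)
})

test_that("two-tone tracks recover both periods and the trochoid labels", {
  mk <- function(sgn) make_synthetic_track(A = 0.01, B = 0.004,
                                           omega1 = 2 * pi / 5400,
                                           omega2 = 2 * pi / 1200,
                                           sign = sgn, duration = 12 * 3600,
                                           dt = 20)
  p <- estimate_periods(mk(1))
  expect_equal(sort(p$period), c(1200, 5400), tolerance = 1e-2)
  expect_identical(classify_pattern(mk(1))$label, "epitrochoid_like")
  expect_identical(classify_pattern(mk(-1))$label, "hypotrochoid_like")
})

test_that("a straight-segment oscillation is pendular", {
  t <- seq(0, 6 * 3600, by = 30)
  tk <- tip_track(t, 0.01 * sin(2 * pi * t / 1800), rep(0, length(t)),
                  provenance = "synthetic")
  rep <- classify_pattern(tk)
  expect_identical(rep$label, "pendular")
  expect_lt(rep$ellipticity, 0.05)
  # counter-rotating equal tones at one frequency degenerate to a line
  tk2 <- make_synthetic_track(A = 0.01, B = 0.01, omega1 = 2 * pi / 1800,
                              omega2 = 2 * pi / 1800, sign = -1,
                              duration = 6 * 3600, dt = 30)
  expect_identical(classify_pattern(tk2)$label, "pendular")
})

test_that("pure noise yields no significant tone and a flagged report", {
  set.seed(11)
  t <- seq(0, 3600, by = 10)
  tk <- tip_track(t, stats::rnorm(length(t), sd = 1e-4),
                  stats::rnorm(length(t), sd = 1e-4),
                  provenance = "synthetic")
  p <- estimate_periods(tk)
  expect_equal(nrow(p), 0)
  rep <- classify_pattern(tk)
  expect_true(is.na(rep$label))
  expect_identical(rep$flag, "no_significant_tone")
})

test_that("mirroring flips rotation sign and swaps trochoid labels", {
  tk <- make_synthetic_track(A = 0.01, B = 0.004, omega1 = 2 * pi / 5400,
                             omega2 = 2 * pi / 1200, sign = 1,
                             duration = 12 * 3600, dt = 20)
  mir <- tip_track(tk$times, tk$x, -tk$y, provenance = "synthetic")
  r1 <- classify_pattern(tk)
  r2 <- classify_pattern(mir)
  expect_identical(r1$label, "epitrochoid_like")
  expect_identical(r2$label, "epitrochoid_like")  # both flip: still concordant
  expect_identical(r2$rotation_sign, -r1$rotation_sign)
  # flipping only the second tone swaps epi <-> hypo
  tk3 <- make_synthetic_track(A = 0.01, B = 0.004, omega1 = 2 * pi / 5400,
                              omega2 = 2 * pi / 1200, sign = -1,
                              duration = 12 * 3600, dt = 20)
  expect_identical(classify_pattern(tk3)$label, "hypotrochoid_like")
})

test_that("classification is scale invariant", {
  tk <- make_synthetic_track(A = 0.01, B = 0.004, omega1 = 2 * pi / 5400,
                             omega2 = 2 * pi / 1200, sign = 1,
                             duration = 12 * 3600, dt = 20)
  sc <- tip_track(tk$times, 1e3 * tk$x, 1e3 * tk$y, provenance = "synthetic")
  expect_identical(classify_pattern(sc)$label, classify_pattern(tk)$label)
  expect_equal(classify_pattern(sc)$ellipticity, classify_pattern(tk)$ellipticity,
               tolerance = 1e-12)
})

test_that("the classifier round-trips on its own generator across a sweep", {
  set.seed(5)
  for (k in 1:6) {
    P1 <- stats::runif(1, 4000, 8000)
    P2 <- stats::runif(1, 900, 1600)
    sgn <- sample(c(-1, 1), 1)
    tk <- make_synthetic_track(A = 0.01, B = 0.003, omega1 = 2 * pi / P1,
                               omega2 = 2 * pi / P2, sign = sgn,
                               duration = 6 * P1, dt = P2 / 40,
                               noise = 1e-5)
    lab <- classify_pattern(tk)$label
    expect_identical(lab, if (sgn > 0) "epitrochoid_like" else "hypotrochoid_like")
  }
})

test_that("short tracks are rejected", {
  tk <- make_synthetic_track(A = 0.01, B = 0, omega1 = 2 * pi / 3600,
                             omega2 = 1, duration = 7000, dt = 30)
  expect_error(estimate_periods(tk), "4 estimated periods")
  expect_error(tip_track(c(0, 1, 1), 1:3, 1:3), "strictly increasing")
})

test_that("tip tracks round-trip through delimited text", {
  tk <- make_synthetic_track(A = 0.01, B = 0.002, omega1 = 2 * pi / 3600,
                             omega2 = 2 * pi / 900, duration = 4 * 3600,
                             dt = 60)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tip_track(tk, f)
  tk2 <- read_tip_track(f)
  expect_equal(tk2$x, tk$x, tolerance = 1e-12)
  expect_equal(tk2$times, tk$times, tolerance = 1e-12)
  expect_identical(tk2$provenance, "measured")
})
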