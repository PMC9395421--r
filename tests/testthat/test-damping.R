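# Forward damping model, its inversion, and the damping-vs-delay curve.

test_that("forward model evaluates the bracketed products", {
  expect_equal(unclass(forward_steps(equilibrium_constants(Inf, Inf, Inf))),
               c(d1 = 1, d2 = 1, d3 = 1))
  expect_equal(forward_steps(equilibrium_constants(1, Inf, Inf))[["d1"]],
               0.5)
  # wild-type Rvx constants, acceptor terms taken as 1
  s <- forward_steps(equilibrium_constants(9, 49, 3.7))
  expect_equal(unclass(s), c(d1 = 0.9, d2 = 0.9 * 49 / 50,
                             d3 = 0.9 * (49 / 50) * (3.7 / 4.7)),
               tolerance = 1e-12)
  expect_equal(s[["d3"]], 0.6943404, tolerance = 1e-6)
  expect_error(forward_steps(equilibrium_constants(-1, 1, 1)),
               "non-negative")
})

test_that("step ordering D3 <= D2 <= D1 <= 1 holds for random constants", {
  set.seed(7)
  for (i in 1:200) {
    K <- equilibrium_constants(10^stats::runif(1, -3, 3),
                               10^stats::runif(1, -3, 3),
                               10^stats::runif(1, -3, 3),
                               K_A1 = 10^stats::runif(1, -1, 4),
                               K_A2 = 10^stats::runif(1, -1, 4))
    s <- unclass(forward_steps(K))
    expect_true(s[3] <= s[2] + 1e-15 && s[2] <= s[1] + 1e-15 &&
                  s[1] <= 1)
  }
})

test_that("inversion reproduces the ratio formulas", {
  K <- invert_steps(step_heights(c(0.5, 0.25, 0.125)))
  expect_equal(c(K$K_D1, K$K_D2, K$K_D3), c(1, 1, 1))
  # printed wild-type constants from their step ratios
  expect_equal(invert_steps(step_heights(c(0.9, 0.9 * 0.98,
                                           0.9 * 0.98 * 3.7 / 4.7)))$K_D2,
               49, tolerance = 1e-9)
  expect_equal(invert_steps(step_heights(
    c(0.9, 0.9 * 0.98, 0.9 * 0.98 * (3.7 / 4.7))))$K_D3,
    3.7, tolerance = 1e-9)
})

test_that("round trip invert(forward(K)) is exact at infinite K_A", {
  set.seed(11)
  for (i in 1:500) {
    kd <- 10^stats::runif(3, -3, 3)
    K <- equilibrium_constants(kd[1], kd[2], kd[3])
    back <- invert_steps(forward_steps(K))
    expect_equal(c(back$K_D1, back$K_D2, back$K_D3), kd,
                 tolerance = 1e-9)
  }
})

test_that("finite acceptor constants are inverted exactly when supplied,
           and neglected inversion underestimates accordingly", {
  kd <- c(5, 2, 0.8); ka <- c(8, 3)
  s <- forward_steps(equilibrium_constants(kd[1], kd[2], kd[3],
                                           ka[1], ka[2]))
  exact <- invert_steps(s, K_A = ka)
  expect_equal(c(exact$K_D1, exact$K_D2, exact$K_D3), kd,
               tolerance = 1e-12)
  naive <- invert_steps(s)
  # neglecting K_A shrinks the apparent ratio by exactly K_A/(1+K_A)
  r2_naive <- naive$K_D2 / (1 + naive$K_D2)
  r2_true <- kd[2] / (1 + kd[2])
  expect_equal(r2_naive / r2_true, ka[1] / (1 + ka[1]),
               tolerance = 1e-12)
  expect_lt(naive$K_D2, kd[2])
})

test_that("unidentifiable ratios raise unless clipping is enabled", {
  expect_error(invert_steps(step_heights(c(0.5, 0.55, 0.2))),
               "no damping")
  expect_error(invert_steps(step_heights(c(0, 0, 0))), "undefined")
  clipped <- invert_steps(step_heights(c(0.5, 0.5005, 0.2)),
                          clip_tol = 0.01)
  expect_gt(clipped$K_D2, 1e6)
  expect_error(invert_steps(step_heights(c(0.5, 0.7, 0.2)),
                            clip_tol = 0.01), "no damping")
})

test_that("damping_vs_delay follows the re-opening law", {
  d <- c(2e-5, 5e-5, 1e-4, 2e-4, 1e-3)
  cv <- damping_vs_delay(1.2e4, 1e6, 1, d)
  expect_equal(cv$ratio[3], 0.6988, tolerance = 1e-4)
  expect_equal(cv$ratio, reopening_fraction(d, 1.2e4, 1e6))
  expect_true(all(diff(cv$ratio) > 0))
  cv2 <- damping_vs_delay(1e4, 1e4, 0.8, c(0.1, 1))
  expect_equal(cv2$ratio[2], 0.8, tolerance = 1e-6)   # -> R_inf
  expect_error(damping_vs_delay(1e4, 1e4, 0.8, c(0, 1e-4)), "positive")
  expect_error(damping_vs_delay(1e4, 1e4, 1.2, c(1e-4)), "R_inf")
})

test_that("damping curves round-trip through CSV", {
  cv <- damping_vs_delay(1e4, 1e5, 0.9, c(5e-5, 1e-4, 4e-4), pair = "3/2")
  f <- tempfile(fileext = ".csv")
  write_damping_curve(cv, f)
  back <- read_damping_curve(f)
  expect_equal(back$ratio, cv$ratio)
  expect_identical(attr(back, "pair"), "3/2")
})

test_that("titration series convert element-wise, preserving order", {
  df <- data.frame(t_inc = c(0, 600),
                   d1 = c(0.5, 0.4), d2 = c(0.25, 0.12),
                   d3 = c(0.125, 0.024))
  kd <- titration_to_kd(df)
  expect_equal(kd$t_inc, df$t_inc)
  expect_equal(kd$K_D1[1], 1)
  expect_true(all(diff(kd$K_D1) < 0) && all(diff(kd$K_D2) < 0))
  # monotone-decreasing steps map to monotone-decreasing constants
  set.seed(3)
  r <- sort(stats::runif(6, 0.05, 0.9), decreasing = TRUE)
  series <- data.frame(t_inc = 1:6, d1 = r, d2 = r * r, d3 = r * r * r)
  kk <- titration_to_kd(series)
  expect_true(all(diff(kk$K_D2) < 0))
  # empty input, empty output
  expect_equal(nrow(titration_to_kd(df[0, ])), 0)
  # errors are tagged with the incubation time
  bad <- data.frame(t_inc = 42, d1 = 0.5, d2 = 0.6, d3 = 0.1)
  expect_error(titration_to_kd(bad), "42")
})
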