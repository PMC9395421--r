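# Independent oracles and shared fixtures for the test suite.

# Brute-force ODE oracle for the two-branch re-opening scheme: after a
# flash the RC is closed on both sides; one irreversible step at k_A and
# one at k_D, proceeding independently, must both complete before the RC
# is open.  States: (neither done, A done, D done, both done).
oracle_reopening <- function(t, k_A, k_D) {
  derivs <- function(t, y, p) {
    list(c(-(p[1] + p[2]) * y[1],
           p[1] * y[1] - p[2] * y[2],
           p[2] * y[1] - p[1] * y[3],
           p[2] * y[2] + p[1] * y[3]))
  }
  out <- deSolve::ode(y = c(1, 0, 0, 0), times = c(0, t), func = derivs,
                      parms = c(k_A, k_D), method = "lsoda",
                      rtol = 1e-10, atol = 1e-14)
  out[-1, 5]
}

# exact three-phase piecewise-linear trace builder (continuous at breaks)
piecewise_three <- function(t, slopes, breaks) {
  y1 <- slopes[1] * pmin(t, breaks[1])
  y2 <- slopes[2] * (pmin(t, breaks[2]) - breaks[1]) * (t > breaks[1])
  y3 <- slopes[3] * (t - breaks[2]) * (t > breaks[2])
  y1 + y2 + y3
}

# fast rate set for light-limited continuous checks
fast_rates <- function(...) {
  rate_set(k_AB1 = 2e6, k_AB2 = 2e6, k_Qex = 2e6, k_bind = 5e6,
           k_unbind = 5e6, k_ET = 5e6, N_pool = 1e5, k_bc1 = 0, ...)
}

# presets are expensive to calibrate; memoised here so the whole suite
# pays at most once per preset
cached_preset <- local({
  store <- new.env(parent = emptyenv())
  function(name, ...) {
    key <- paste(name, ..., sep = "_")
    if (is.null(store[[key]])) store[[key]] <- strain_preset(name, ...)
    store[[key]]
  }
})
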