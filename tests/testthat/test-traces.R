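# Beer-Lambert conversion, step extraction, averaging, normalization and
# file round trips.

test_that("Beer-Lambert arithmetic and sign convention", {
  t <- seq(0, 1e-3, 5e-5)
  tr <- absorbance_trace(t, rep(-0.0211, length(t)))
  conc <- absorbance_to_concentration(tr)
  expect_equal(conc$conc_uM, rep(1, length(t)))         # 1 uM oxidized
  tr2 <- absorbance_trace(t, rep(-0.0211, length(t)), rc_uM = 0.5)
  expect_equal(absorbance_to_concentration(tr2)$per_rc,
               rep(2, length(t)))                        # 2 cyt3+/RC
  expect_equal(absorbance_to_concentration(
    absorbance_trace(t, rep(0, length(t))))$conc_uM, rep(0, length(t)))
  # oxidation is positive at both difference pairs
  trP <- absorbance_trace(t, rep(-0.07, length(t)),
                          wavelength_pair = "790-750", delta_eps = 70)
  expect_true(all(absorbance_to_concentration(trP)$conc_uM > 0))
})

test_that("trace construction validates the grid and metadata", {
  expect_error(absorbance_trace(c(0, 1e-5, 5e-5), c(0, 0, 0)), "uniform")
  expect_error(absorbance_trace(c(0, 1e-5), c(0, 0), delta_eps = 0),
               "delta_eps")
  expect_error(absorbance_trace(c(1e-5, 0), c(0, 0)), "increasing")
})

test_that("step extraction differences the plateaus", {
  pr <- default_flash_protocol()
  t <- seq(0, 1.6e-3, 5e-5)
  y <- 1.0 * (t >= 2e-4) + 0.8 * (t >= 6e-4) + 0.6 * (t >= 1e-3)
  s <- extract_steps(data.frame(time_s = t, per_rc = y), pr)
  expect_equal(unclass(s), c(d1 = 1.0, d2 = 0.8, d3 = 0.6))
  # no flashes -> error; oversized window -> error
  pr0 <- illumination_protocol("flash_train", 1e-3,
                               flash_times = numeric())
  expect_error(extract_steps(data.frame(time_s = t, per_rc = y), pr0),
               "no flashes")
  expect_error(extract_steps(data.frame(time_s = t, per_rc = y), pr,
                             window = c(1e-4, 5e-4)), "overlaps")
  expect_error(extract_steps(data.frame(time_s = t, per_rc = y),
                             illumination_protocol("continuous", 1e-3)),
               "flash_train")
})

test_that("averaging reduces white noise as 1/sqrt(n)", {
  set.seed(42)
  t <- seq(0, 1.6e-3, 5e-5)
  clean <- sin(2e3 * t) * 0.01
  sweeps <- lapply(1:32, function(i)
    absorbance_trace(t, clean + stats::rnorm(length(t), 0, 1e-3)))
  avg <- average_traces(sweeps)
  expect_equal(attr(avg, "n_averages"), 32L)
  expect_equal(stats::sd(avg$delta_A - clean), 1e-3 / sqrt(32),
               tolerance = 0.15)
  expect_identical(average_traces(sweeps[1]), sweeps[[1]])
  short <- absorbance_trace(t[1:10], clean[1:10])
  expect_error(average_traces(list(sweeps[[1]], short)), "grid")
})

test_that("reference normalization maps one turnover to unity", {
  df <- data.frame(time_s = 1:5, per_rc = c(2, 2, 2, 2, 2))
  out <- normalize_to_reference(df, 2)
  expect_equal(out$per_rc, rep(1, 5))
  expect_error(normalize_to_reference(df, 0), "positive")
  expect_error(normalize_to_reference(df, -1), "positive")
})

test_that("traces round-trip through CSV plus sidecar", {
  pr <- default_flash_protocol()
  t <- seq(0, 1.6e-3, 5e-5)
  tr <- absorbance_trace(t, -0.02 * (t >= 2e-4), rc_uM = 1,
                         protocol = pr, n_averages = 32L)
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(back$delta_A, tr$delta_A)
  expect_equal(attr(back, "delta_eps"), 21.1)
  expect_equal(attr(back, "protocol")$flash_times, pr$flash_times)
  expect_equal(attr(back, "n_averages"), 32L)
})
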