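# The synthetic spectrometer: determinism, noise statistics, and
# end-to-end recovery of the quantities it encodes.

test_that("noiseless traces are exact staircases from the simulator", {
  p <- cached_preset("rba_wt")
  ex <- generate_flash_experiment(p, noise = noise_model(sigma = 0))
  sim <- simulate_flash_train(p$rates, default_flash_protocol(),
                              pool_fraction = p$pool_fraction)
  expect_equal(ex$trace$delta_A, -21.1 * 1e-3 * sim$cyt3,
               tolerance = 1e-12)
  expect_true(all(ex$trace$delta_A <= 1e-9))  # oxidation is negative-going
})

test_that("identical seeds give identical experiments", {
  p <- cached_preset("rba_wt")
  e1 <- generate_flash_experiment(p, noise = noise_model(1e-3, 32, 7))
  e2 <- generate_flash_experiment(p, noise = noise_model(1e-3, 32, 7))
  expect_identical(e1$trace$delta_A, e2$trace$delta_A)
  e3 <- generate_flash_experiment(p, noise = noise_model(1e-3, 32, 8))
  expect_false(identical(e1$trace$delta_A, e3$trace$delta_A))
})

test_that("noise shrinks as one over the square root of the averages", {
  p <- cached_preset("rba_cycA")  # flat zero signal isolates the noise
  sds <- vapply(c(1, 8, 32), function(n) {
    ex <- generate_flash_experiment(p, noise = noise_model(1e-3, n, 11))
    stats::sd(ex$trace$delta_A)
  }, numeric(1))
  expect_equal(sds[1] / sds[2], sqrt(8), tolerance = 0.15)
  expect_equal(sds[1] / sds[3], sqrt(32), tolerance = 0.15)
})

test_that("extracted steps match ground truth within the noise level", {
  p <- cached_preset("rvx_wt")
  ex <- generate_flash_experiment(p, noise = noise_model(1e-3, 32, 5))
  conc <- absorbance_to_concentration(ex$trace)
  s <- extract_steps(conc, attr(ex$trace, "protocol"))
  sigma_step <- 2 * (1e-3 / sqrt(32)) / (21.1e-3) / sqrt(6)
  expect_true(all(abs(unclass(s) - unlist(ex$truth$steps)) <
                    3 * sigma_step))
})

test_that("the full pipeline recovers each preset's donor constants
           within ten percent at the default noise", {
  for (nm in c("rvx_wt", "rba_wt", "rvx_pufC")) {
    p <- cached_preset(nm)
    ex <- generate_flash_experiment(p, noise = noise_model(1e-4, 32, 23))
    conc <- absorbance_to_concentration(ex$trace)
    K <- invert_steps(extract_steps(conc, attr(ex$trace, "protocol")))
    expect_equal(K$K_D2, unname(p$implied_kd["K_D2"]), tolerance = 0.1)
    expect_equal(K$K_D3, unname(p$implied_kd["K_D3"]), tolerance = 0.1)
  }
})

test_that("continuous generation honours the design and treatments", {
  # no light: flat noise around zero
  ex0 <- generate_continuous_experiment("rvx_wt", duration = 5e-3,
                                        k_L = 0,
                                        noise = noise_model(1e-4, 32, 3))
  expect_lt(max(abs(ex0$trace$delta_A)), 1e-4)
  expect_gt(stats::sd(ex0$trace$delta_A), 0)
  # terbutryne saturates at a single turnover
  ext <- generate_continuous_experiment(
    strain_preset("rvx_wt", treatment = "terbutryne"),
    duration = 5e-3, noise = noise_model(sigma = 0))
  conc <- absorbance_to_concentration(ext$trace)
  expect_equal(max(conc$per_rc), 1, tolerance = 0.02)
  # the approach is a saturating rise: monotone up to noise, no phases
  expect_true(all(diff(conc$per_rc) > -1e-9))
})

test_that("ferricyanide titration yields monotone-declining constants", {
  p <- cached_preset("rvx_wt")
  series <- generate_ferricyanide_titration(
    p, t_inc = c(0, 1800, 3600, 5400, 7200),
    noise = noise_model(sigma = 0))
  expect_equal(series[[1]]$truth$pool_fraction, p$pool_fraction)
  kd <- t(vapply(series, function(el) unlist(el$truth$kd),
                 numeric(3)))
  expect_true(all(diff(kd[, "K_D1"]) < 0))
  expect_true(all(diff(kd[, "K_D2"]) < 0))
  expect_true(all(diff(kd[, "K_D3"]) < 0))
  # fully oxidized pool: steps vanish
  far <- generate_ferricyanide_titration(p, t_inc = 1e7,
                                         noise = noise_model(sigma = 0))
  expect_lt(max(unlist(far[[1]]$truth$steps)), 1e-3)
  expect_error(generate_ferricyanide_titration(p, 0, k_ox = -1),
               "non-negative")
})

test_that("experiments round-trip to disk with their ground truth", {
  p <- cached_preset("rba_wt")
  ex <- generate_flash_experiment(p, noise = noise_model(1e-4, 32, 9))
  f <- file.path(tempdir(), "exp.csv")
  write_experiment(ex, f)
  back <- read_trace(f)
  expect_equal(back$delta_A, ex$trace$delta_A)
  truth <- jsonlite::read_json(paste0(f, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 9)
  expect_equal(unlist(truth$steps), unlist(ex$truth$steps),
               tolerance = 1e-12)
})
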