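# Strain presets and their calibration back-solves.

test_that("unknown names and treatments are rejected informatively", {
  expect_error(strain_preset("rvx_mystery"), "valid names")
  expect_error(strain_preset("rvx_wt", treatment = "teaspoon"))
})

test_that("the cytochrome-less strain has no donor system", {
  p <- cached_preset("rba_cycA")
  expect_equal(p$rates$N_pool, 0)
  expect_equal(p$rates$k_ET, 0)
  sim <- simulate_flash_train(p$rates, default_flash_protocol())
  expect_lt(max(abs(sim$cyt3)), 1e-12)   # no cytochrome oxidation at all
  expect_gt(sim$pplus[length(sim$pplus)], 0.9)  # P+ persists instead
})

test_that("acceptor rates follow the strain and treatments modify them", {
  p <- cached_preset("rba_cycA")
  expect_equal(p$rates$k_AB1, 1.2e4)
  expect_equal(p$rates$k_AB2, 6e3)
  pt <- strain_preset("rba_cycA", treatment = "terbutryne")
  er <- rcflash:::effective_rates(pt$rates)
  expect_equal(er$k_AB1, 0)
  pd <- strain_preset("rba_cycA", treatment = "dithionite")
  expect_true(pd$rates$dithionite)
  pf <- strain_preset("rba_cycA", treatment = "ferrocene")
  expect_gt(pf$rates$k_ext, 0)
  pfe <- strain_preset("rba_cycA", treatment = "ferricyanide",
                       t_inc = 1800)
  expect_equal(pfe$pool_fraction, 0.5, tolerance = 1e-12)
})

test_that("donor calibration reproduces the implied constants through
           the noiseless pipeline", {
  for (nm in c("rvx_wt", "rba_wt", "rvx_pufC")) {
    p <- cached_preset(nm)
    steps <- rcflash:::measure_sim_steps(p$rates,
                                         default_flash_protocol(),
                                         pool_fraction = p$pool_fraction)
    K <- invert_steps(steps)
    expect_equal(K$K_D2, unname(p$implied_kd["K_D2"]), tolerance = 0.01)
    expect_equal(K$K_D3, unname(p$implied_kd["K_D3"]), tolerance = 0.01)
  }
})

test_that("damping severity orders the strains as published", {
  # larger K_D2 means weaker damping: Rvx WT > Rba WT > pufC
  k <- vapply(c("rvx_wt", "rba_wt", "rvx_pufC"), function(nm) {
    p <- cached_preset(nm)
    s <- rcflash:::measure_sim_steps(p$rates, default_flash_protocol(),
                                     pool_fraction = p$pool_fraction)
    s[["d2"]] / s[["d1"]]
  }, numeric(1))
  expect_true(k[["rvx_wt"]] > k[["rba_wt"]])
  expect_true(k[["rba_wt"]] > k[["rvx_pufC"]])
})

test_that("an external donor (ferrocene) accelerates P+ re-reduction", {
  pr <- default_flash_protocol()
  plain <- cached_preset("rba_cycA")
  fc <- strain_preset("rba_cycA", treatment = "ferrocene")
  s0 <- simulate_flash_train(plain$rates, pr)
  s1 <- simulate_flash_train(fc$rates, pr)
  n <- length(s0$time)
  expect_gt(s0$pplus[n], 0.9)       # no donor: P+ persists
  expect_lt(s1$pplus[n], 0.2)       # sub-ms collisional re-reduction
  # ferrocene reduces P+ without oxidizing cellular cytochromes
  expect_lt(max(abs(s1$cyt3)), 1e-9)
})
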