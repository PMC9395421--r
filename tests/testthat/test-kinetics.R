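# The chain-model simulator: conservation laws, saturation limits, the
# flash operator, and agreement with the closed-form re-opening law.

test_that("no light means no chemistry", {
  pr <- illumination_protocol("continuous", duration = 5e-3)
  sim <- simulate_continuous(rate_set(k_L = 0), pr)
  expect_equal(max(abs(sim$cyt3)), 0, tolerance = 1e-12)
  expect_equal(max(abs(sim$pplus)), 0, tolerance = 1e-12)
})

test_that("occupancies stay non-negative and sum to one", {
  pr <- illumination_protocol("continuous", duration = 10e-3)
  sim <- simulate_continuous(rate_set(), pr)
  expect_lt(max(abs(rowSums(sim$occupancy) - 1)), 1e-9)
  expect_gt(min(sim$occupancy), -1e-9)
  pr2 <- default_flash_protocol()
  sim2 <- simulate_flash_train(rate_set(), pr2)
  expect_lt(max(abs(rowSums(sim2$occupancy) - 1)), 1e-9)
})

test_that("terbutryne limits continuous photooxidation to one cytochrome", {
  pr <- illumination_protocol("continuous", duration = 20e-3)
  sim <- simulate_continuous(rate_set(terbutryne = TRUE), pr)
  expect_equal(sim$cyt3_cum[length(sim$cyt3_cum)], 1, tolerance = 1e-6)
  # and the limit is an asymptote, not an overshoot
  expect_true(all(sim$cyt3_cum <= 1 + 1e-9))
})

test_that("initial slope equals the excitation rate when light limits", {
  rs <- fast_rates(k_L = 1.5e4)
  pr <- illumination_protocol("continuous", duration = 5e-5,
                              sampling = 1e-6)
  sim <- simulate_continuous(rs, pr)
  sel <- sim$time >= 5e-6
  slope <- stats::coef(stats::lm(sim$cyt3_cum[sel] ~ sim$time[sel]))[[2]]
  expect_equal(slope, 1.5e4, tolerance = 0.02)
})

test_that("cumulative oxidation is monotone without bc1 resupply", {
  pr <- illumination_protocol("continuous", duration = 20e-3)
  sim <- simulate_continuous(rate_set(k_bc1 = 0), pr)
  expect_true(all(diff(sim$cyt3_cum) > -1e-10))
})

test_that("electron ledger balances exactly without resupply", {
  # net oxidized cytochrome = electrons now on the acceptor side plus
  # exported quinol electrons minus remaining P+ occupancy
  rs <- rate_set(k_bc1 = 0, N_pool = 50)
  for (sim in list(
    simulate_continuous(rs, illumination_protocol("continuous", 5e-3)),
    simulate_flash_train(rs, default_flash_protocol()))) {
    st <- sim$states
    i <- length(sim$time)
    acceptors <- sum(sim$occupancy[i, st$QA == 1]) +
      sum(sim$occupancy[i, st$QB == "QBm"]) +
      2 * sum(sim$occupancy[i, st$QB == "QBH2"]) + sim$exported[i]
    expect_equal(sim$cyt3_cum[i], acceptors - sim$pplus[i],
                 tolerance = 1e-8)
  }
})

test_that("the flash operator closes open states, conserves and is
           idempotent", {
  y <- rc_initial_state(rate_set())
  yf <- apply_flash(y)
  st <- rc_states()
  expect_equal(sum(yf), 1)
  expect_equal(sum(yf[st$P == "P" & st$QA == 0]), 0)
  expect_equal(apply_flash(yf), yf)            # idempotence
  # a fully closed population is untouched
  expect_equal(apply_flash(apply_flash(y)), apply_flash(y))
  # linearity: a 50/50 open/closed mixture ends fully closed
  y2 <- 0.5 * y + 0.5 * yf
  expect_equal(apply_flash(y2), yf, tolerance = 1e-12)
})

test_that("three flashes saturate at three electrons with the quinone
           gate closed to exchange", {
  rs <- rate_set(k_Qex = 0, N_pool = 100, k_bc1 = 0)
  pr <- illumination_protocol("flash_train", duration = 15e-3,
                              flash_times = c(1e-3, 5e-3, 9e-3))
  sim <- simulate_flash_train(rs, pr)
  expect_equal(sum(unclass(sim$steps)), 3, tolerance = 1e-5)
  expect_true(all(sim$cyt3_cum <= 3 + 1e-8))
})

test_that("terbutryne preserves the first flash step and removes the
           rest", {
  sim <- simulate_flash_train(rate_set(terbutryne = TRUE),
                              default_flash_protocol())
  s <- unname(unclass(sim$steps))
  # the first step saturates at one electron once docking completes; the
  # residual percent finishes early in the next interval
  expect_equal(s[1], 1, tolerance = 5e-3)
  expect_lt(s[2], 5e-3)
  expect_lt(s[3], 5e-4)
  expect_equal(sum(s), 1, tolerance = 1e-5)
})

test_that("zero flashes give a flat zero trace and close flashes error", {
  pr <- illumination_protocol("flash_train", duration = 1e-3,
                              flash_times = numeric())
  sim <- simulate_flash_train(rate_set(), pr)
  expect_equal(max(abs(sim$cyt3)), 0, tolerance = 1e-12)
  expect_null(sim$steps)
  pr2 <- illumination_protocol("flash_train", duration = 1e-3,
                               flash_times = c(2e-4, 2.2e-4),
                               sampling = 5e-5)
  expect_error(simulate_flash_train(rate_set(), pr2), "closer")
})

test_that("reopening law matches its definition and limits", {
  expect_equal(reopening_fraction(0, 1e4, 1e3), 0)
  # single-exponential half rise when the other branch is instantaneous
  kA <- 1.2e4
  expect_equal(reopening_fraction(log(2) / kA, kA, 1e12), 0.5,
               tolerance = 1e-9)
  expect_equal(reopening_fraction(1e-4, 1e4, 1e4), (1 - exp(-1))^2)
  # symmetry and saturation
  expect_equal(reopening_fraction(3e-4, 2e3, 5e4),
               reopening_fraction(3e-4, 5e4, 2e3))
  expect_equal(reopening_fraction(10, 1e4, 1e3), 1)
  expect_error(reopening_fraction(-1, 1e4, 1e4), "non-negative")
  expect_error(reopening_fraction(1e-4, -1, 1e4), "positive")
})

test_that("simulated single-flash reopening matches the closed form and
           the brute-force oracle", {
  tt <- seq(2e-5, 2e-3, by = 2e-5)
  for (k in list(c(1e4, 5e4), c(2e3, 2e3), c(1e5, 1e3))) {
    # chain model configured as the two-branch irreversible scheme:
    # donor ET at k_D from the bound cytochrome, acceptor at k_AB1 = k_A,
    # no further chemistry
    rs <- rate_set(k_AB1 = k[1], k_AB2 = 0, k_Qex = 0, k_bind = 0,
                   k_unbind = 0, k_ET = k[2], N_pool = 0, k_bc1 = 0)
    y0 <- rc_initial_state(rs)
    y0[] <- 0
    y0["P.QA0.QB.c2"] <- 1
    mod <- rcflash:::build_chain_model(rs, light_on = FALSE)
    y <- c(apply_flash(y0), r = 0, cyt = 0, resup = 0, exported = 0)
    out <- rcflash:::integrate_chain(mod, y, c(0, tt), rtol = 1e-10)
    st <- rc_states()
    open_idx <- 1L + which(st$P == "P" & st$QA == 0)
    open_sim <- rowSums(out[-1, open_idx, drop = FALSE])
    expect_lt(max(abs(open_sim - reopening_fraction(tt, k[1], k[2]))),
              1e-6)
    # independent oracle at a few points
    sub <- c(5L, 25L, 60L, 100L)
    expect_lt(max(abs(oracle_reopening(tt[sub], k[1], k[2]) -
                        reopening_fraction(tt[sub], k[1], k[2]))), 1e-6)
  }
})
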