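# Strain presets and the calibration back-solves that pin their donor-side
# parameters to the published generalized equilibrium constants.
#
# The microscopic donor parameters of intact cells are not observable
# directly; what is published are the interquinone rates and the per-flash
# donor equilibrium constants K_D.  Each preset therefore fixes the
# acceptor-side rates at the measured values and back-solves the donor
# poise after each flash (the per-interval reverse electron-transfer rate)
# so that a noiseless simulated three-flash staircase, measured exactly as
# the analysis pipeline measures it (plateau windows, step differences),
# reproduces the step heights implied by the preset's K_D triple.  The
# solve is deterministic and cached per session.

.rcflash_cache <- new.env(parent = emptyenv())

# mechanism = "poise": per-hole donor poise schedule at a fully reduced
# pool (strains whose cascade of constants outruns pool depletion);
# "pool": one donor equilibrium poised by a partially reduced, small pool
# (strains whose damping is carried by pool redox and depletion).
PRESET_BASE <- list(
  rvx_wt = list(k_AB1 = 1e4, k_AB2 = 7.2e3, N_pool = 8,
                mechanism = "poise",
                implied_kd = c(K_D1 = 99, K_D2 = 49, K_D3 = 3.7)),
  rba_wt = list(k_AB1 = 1.2e4, k_AB2 = 6e3, N_pool = 4,
                mechanism = "pool",
                implied_kd = c(K_D1 = 9, K_D2 = 3.5, K_D3 = 1.4)),
  rvx_pufC = list(k_AB1 = 1e4, k_AB2 = 7.2e3, N_pool = 4,
                  mechanism = "pool",
                  implied_kd = c(K_D1 = 1.5, K_D2 = 0.75, K_D3 = 0.3)),
  rba_cycA = list(k_AB1 = 1.2e4, k_AB2 = 6e3, N_pool = 0,
                  mechanism = "none",
                  implied_kd = c(K_D1 = 0, K_D2 = 0, K_D3 = 0))
)

PRESET_TREATMENTS <- c("none", "terbutryne", "myxothiazol", "dithionite",
                       "ferricyanide", "ferrocene")

#' Default three-flash protocol
#'
#' Three saturating flashes 400 us apart (the experimental spacing), the
#' first 200 us into the trace, sampled every 50 us over 1.6 ms.
#'
#' @return An [illumination_protocol()].
#' @export
default_flash_protocol <- function() {
  illumination_protocol("flash_train", duration = 1.6e-3,
                        flash_times = 2e-4 + 4e-4 * (0:2))
}

# measure the staircase exactly as the analysis pipeline does
measure_sim_steps <- function(rates, protocol, window = c(100e-6, 350e-6),
                              pool_fraction = 1) {
  sim <- simulate_flash_train(rates, protocol, pool_fraction = pool_fraction)
  extract_steps(data.frame(time_s = sim$time, per_rc = sim$cyt3),
                protocol, window = window)
}

# Back-solve the donor poise so the measured noiseless staircase
# reproduces forward_steps(K_D, K_A = Inf).  Exchange and forward electron
# transfer are fast and fixed; the free levers are the three per-interval
# reverse electron-transfer rates (the donor poise after each flash, the
# kinetic realization of the generalized K_Di).  Because the staircase is
# causal -- the i-th step depends only on poises 1..i -- the solve is
# three exact sequential bracketed 1-D roots on the full ODE staircase.
calibrate_donor <- function(base, kd, N_pool = 8,
                            protocol = default_flash_protocol()) {
  target <- unclass(forward_steps(equilibrium_constants(kd[1], kd[2],
                                                        kd[3])))
  k_ET <- 1e6
  mk <- function(k_ETr)
    rate_set(k_AB1 = base$k_AB1, k_AB2 = base$k_AB2, k_Qex = 0,
             k_bind = 2e5, k_unbind = 2e5, k_ET = k_ET, k_ETr = k_ETr,
             N_pool = N_pool, k_bc1 = 0)
  meas <- function(k_ETr)
    suppressWarnings(unclass(measure_sim_steps(mk(k_ETr), protocol)))
  kETr <- rep(1, 3)
  for (i in 1:3) {
    f <- function(lKe) {
      v <- kETr
      v[i] <- k_ET / 10^lKe
      meas(v)[i] - target[i]
    }
    kETr[i] <- k_ET /
      10^stats::uniroot(f, c(-2, 8), tol = 1e-9)$root
  }
  got <- meas(kETr)
  if (max(abs(got - target)) > 1e-4)
    warning(sprintf("donor calibration residual %.2g on step heights",
                    max(abs(got - target))))
  list(k_ET = k_ET, k_ETr = kETr, k_bind = 2e5, k_unbind = 2e5,
       r0 = 1, N_pool = N_pool, steps = got, target = target)
}

# Pool-equilibrium back-solve: one donor poise (k_ET/k_ETr) in detailed
# balance with a partially reduced pool; levers are the equilibrium
# constant, the dark reduced fraction r0 and the pool size.  A crude
# two-level model seeds a damped Newton iteration on the 3x3 system of
# measured-vs-target step heights.
calibrate_donor_pool <- function(base, kd,
                                 protocol = default_flash_protocol()) {
  target <- unclass(forward_steps(equilibrium_constants(kd[1], kd[2],
                                                        kd[3])))
  k_ET <- 1e6
  mk <- function(k_ETr, N_pool)
    rate_set(k_AB1 = base$k_AB1, k_AB2 = base$k_AB2, k_Qex = 0,
             k_bind = 2e5, k_unbind = 2e5, k_ET = k_ET, k_ETr = k_ETr,
             N_pool = N_pool, k_bc1 = 0)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  meas <- function(p) {
    k_ETr <- k_ET / 10^clamp(p[1], -2, 6)
    r0 <- stats::plogis(clamp(p[2], -12, 12))
    N_pool <- 10^clamp(p[3], -2, 4)
    suppressWarnings(
      tryCatch(unclass(measure_sim_steps(mk(k_ETr, N_pool), protocol,
                                         pool_fraction = r0)),
               error = function(e) rep(NA_real_, 3)))
  }
  resid <- function(p) meas(p) - target
  # seed: K_i = K_e * r_i/(1-r_i), r depleted by roughly D_i/N per flash
  seed <- function(lKe) {
    x <- kd / 10^lKe
    r <- x / (1 + x)
    if (any(diff(r) >= 0)) return(NULL)
    N <- mean(c(target[1] / (r[1] - r[2]), target[2] / (r[2] - r[3])))
    c(lKe, stats::qlogis(r[1]), log10(max(N, 0.5)))
  }
  starts <- Filter(Negate(is.null),
                   lapply(log10(kd[1]) + c(0, 0.5, 1, 1.5, 2), seed))
  if (!length(starts)) starts <- list(c(log10(kd[1]) + 1, 0, 0.5))
  newton <- function(p) {
    f <- resid(p)
    for (it in 1:15) {
      if (anyNA(f) || max(abs(f)) < 1e-3) break
      J <- matrix(0, 3, 3)
      for (j in 1:3) {
        dp <- p; dp[j] <- dp[j] + 1e-4
        J[, j] <- (resid(dp) - f) / 1e-4
      }
      step <- if (anyNA(J)) NULL else
        tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        pn <- p + lambda * step
        fn <- resid(pn)
        if (!anyNA(fn) && sum(fn^2) < sum(f^2)) break
        lambda <- lambda / 2
        if (lambda < 1e-4) { fn <- f; pn <- p; break }
      }
      if (identical(pn, p)) break
      p <- pn; f <- fn
    }
    list(p = p, err = if (anyNA(f)) Inf else max(abs(f)))
  }
  best <- list(err = Inf)
  for (p0 in starts) {
    cand <- newton(p0)
    if (cand$err < best$err) best <- cand
    if (best$err < 1e-3) break
  }
  p <- best$p
  r0 <- stats::plogis(clamp(p[2], -12, 12))
  N_pool <- 10^clamp(p[3], -2, 4)
  kETr <- rep(k_ET / 10^clamp(p[1], -2, 6), 3)
  if (best$err > 1e-8) {
    # zero the remaining residual exactly with small per-hole poise
    # corrections on top of the pool equilibrium (sequential, causal)
    measv <- function(v)
      suppressWarnings(unclass(measure_sim_steps(mk(v, N_pool), protocol,
                                                 pool_fraction = r0)))
    for (i in 1:3) {
      f <- function(lm) {
        v <- kETr
        v[i] <- kETr[i] / 10^lm
        measv(v)[i] - target[i]
      }
      if (f(-3) * f(3) < 0)
        kETr[i] <- kETr[i] /
          10^stats::uniroot(f, c(-3, 3), tol = 1e-9)$root
    }
  }
  got <- suppressWarnings(
    unclass(measure_sim_steps(mk(kETr, N_pool), protocol,
                              pool_fraction = r0)))
  if (max(abs(got - target)) > 1e-4)
    warning(sprintf("donor calibration residual %.2g on step heights",
                    max(abs(got - target))))
  list(k_ET = k_ET, k_ETr = kETr, k_bind = 2e5, k_unbind = 2e5,
       r0 = r0, N_pool = N_pool, steps = got, target = target)
}

#' Strain preset with calibrated chain-model parameters
#'
#' Returns the frozen rate set of a named strain, optionally with a
#' treatment applied. Acceptor-side rates are the measured interquinone
#' rates of each strain (Rvx. gelatinosus 1e4 and 7.2e3 s^-1, Rba.
#' sphaeroides 1.2e4 and 6e3 s^-1); the donor poise after each flash (the
#' per-interval reverse electron-transfer rate) is back-solved once per
#' session so that the simulated three-flash staircase reproduces the
#' strain's implied donor equilibrium constants (`rvx_wt`: K_D2 = 49,
#' K_D3 = 3.7; `rba_wt`: K_D2 = 3.5, K_D3 = 1.4; `rvx_pufC`: K_D2 = 0.75,
#' K_D3 = 0.3; K_D1 values are package choices consistent with the
#' observed first-step amplitudes). `rba_cycA` has no cytochrome donor at
#' all (`N_pool = 0`); it serves as the 1-turnover calibration strain.
#' Presets disable bc1 pool resupply, which is negligible on the
#' flash-train timescale.
#'
#' @param name One of `"rvx_wt"`, `"rba_wt"`, `"rvx_pufC"`, `"rba_cycA"`.
#' @param treatment One of `"none"`, `"terbutryne"`, `"myxothiazol"`,
#'   `"dithionite"`, `"ferricyanide"`, `"ferrocene"`.
#' @param t_inc Ferricyanide incubation time, s (used with
#'   `treatment = "ferricyanide"`): the reduced-pool fraction at time zero
#'   is `exp(-k_ox * t_inc)`.
#' @param k_ox Pool oxidation rate by ferricyanide, s^-1 (default a 30 min
#'   half-time).
#' @param k_ext Pseudo-first-order P+ re-reduction rate by ferrocene, s^-1
#'   (used with `treatment = "ferrocene"`).
#' @return An object of class `strain_preset`: `name`, `treatment`, `rates`
#'   (a [rate_set()]), `implied_kd`, `pool_fraction` and the calibration
#'   record.
#' @examples
#' \donttest{
#' p <- strain_preset("rba_cycA")
#' p$rates$N_pool  # 0: cytochrome electron transfer eliminated
#' }
#' @export
strain_preset <- function(name, treatment = "none", t_inc = 0,
                          k_ox = log(2) / 1800, k_ext = 5e3) {
  if (!name %in% names(PRESET_BASE))
    stop(sprintf("unknown strain preset '%s'; valid names: %s", name,
                 paste(names(PRESET_BASE), collapse = ", ")), call. = FALSE)
  treatment <- match.arg(treatment, PRESET_TREATMENTS)
  base <- PRESET_BASE[[name]]
  if (name == "rba_cycA") {
    rates <- rate_set(k_AB1 = base$k_AB1, k_AB2 = base$k_AB2, k_Qex = 0,
                      k_bind = 0, k_unbind = 5e4, k_ET = 0, N_pool = 0,
                      k_bc1 = 0)
    cal <- NULL
    pool_fraction <- 1
  } else {
    key <- paste0("donor_", name)
    cal <- .rcflash_cache[[key]]
    if (is.null(cal)) {
      cal <- if (identical(base$mechanism, "pool"))
        calibrate_donor_pool(base, base$implied_kd)
      else calibrate_donor(base, base$implied_kd, N_pool = base$N_pool)
      assign(key, cal, envir = .rcflash_cache)
    }
    rates <- rate_set(k_AB1 = base$k_AB1, k_AB2 = base$k_AB2, k_Qex = 0,
                      k_bind = cal$k_bind, k_unbind = cal$k_unbind,
                      k_ET = cal$k_ET, k_ETr = cal$k_ETr,
                      N_pool = cal$N_pool, k_bc1 = 0)
    pool_fraction <- cal$r0
  }
  if (treatment == "terbutryne") rates$terbutryne <- TRUE
  if (treatment == "myxothiazol") rates$myxothiazol <- TRUE
  if (treatment == "dithionite") rates$dithionite <- TRUE
  if (treatment == "ferrocene") rates$k_ext <- k_ext
  p <- structure(list(name = name, treatment = treatment, rates = rates,
                      mechanism = base$mechanism,
                      implied_kd = base$implied_kd,
                      pool_fraction = pool_fraction,
                      calibration = cal),
                 class = "strain_preset")
  if (treatment == "ferricyanide") {
    if (k_ox < 0) stop("oxidation rate must be non-negative", call. = FALSE)
    p <- apply_redox_poise(p, exp(-k_ox * t_inc))
  }
  p
}

#' Shift a preset's donor redox poise
#'
#' Progressive oxidation by an external oxidant (ferricyanide) raises the
#' ambient redox potential; by Nernst every donor equilibrium shifts by
#' the same factor. For pool-mechanism presets the pool reduced fraction
#' carries the poise (docking samples it), so it is scaled directly; for
#' poise-mechanism presets the equilibrium constants live in
#' `k_ET / k_ETr`, so the reverse rates are scaled up by the same factor.
#'
#' @param preset A [strain_preset()].
#' @param factor Multiplier on the donor availability in `[0, 1]`
#'   (`exp(-k_ox * t_inc)` for an incubation).
#' @return The shifted preset.
#' @export
apply_redox_poise <- function(preset, factor) {
  stopifnot(factor >= 0, factor <= 1)
  if (identical(preset$mechanism, "poise")) {
    if (factor > 0) preset$rates$k_ETr <- preset$rates$k_ETr / factor
    else preset$rates$k_ET <- 0
  } else {
    preset$pool_fraction <- preset$pool_fraction * factor
  }
  preset
}

#' @export
print.strain_preset <- function(x, ...) {
  cat(sprintf("Strain preset '%s' (treatment: %s)\n", x$name, x$treatment))
  cat(sprintf("  implied K_D = (%g, %g, %g)\n", x$implied_kd[1],
              x$implied_kd[2], x$implied_kd[3]))
  if (x$pool_fraction < 1)
    cat(sprintf("  reduced-pool fraction at t = 0: %.3g\n",
                x$pool_fraction))
  print(x$rates)
  invisible(x)
}

# ---- continuous-illumination design calibration -------------------------
#
# The three-phase continuous trace is parameterized by its observable design
# quantities: the light-limited initial slope, the turnover-limited
# stationary slope, and a slow pool-limited tail, with pool exhaustion near
# t_pool.  Downstream rates are fast so light is rate-limiting initially;
# quinol exchange is root-solved to set the stationary slope; pool size is
# set from the cumulative oxidation at t_pool; the docking rate is
# root-solved so the post-exhaustion creep matches the tail slope.

calibrate_continuous_design <- function(slopes = c(1.5e4, 3e3, 50),
                                        t_pool = 1e-2) {
  key <- sprintf("cont_%g_%g_%g_%g", slopes[1], slopes[2], slopes[3],
                 t_pool)
  hit <- .rcflash_cache[[key]]
  if (!is.null(hit)) return(hit)
  mk <- function(k_L, k_Qex, N_pool, k_bind)
    rate_set(k_L = k_L, k_AB1 = 1e5, k_AB2 = 1e5, k_Qex = k_Qex,
             k_bind = k_bind, k_unbind = 3e5, k_ET = 3e5,
             N_pool = N_pool, k_bc1 = 0)
  run <- function(rates, duration, sampling = 1e-4) {
    pr <- illumination_protocol("continuous", duration,
                                sampling = sampling)
    simulate_continuous(rates, pr)
  }
  slope_between <- function(sim, t0, t1) {
    c0 <- stats::approx(sim$time, sim$cyt3, t0)$y
    c1 <- stats::approx(sim$time, sim$cyt3, t1)$y
    (c1 - c0) / (t1 - t0)
  }
  fitted_slopes <- function(k_L, k_Qex, N_pool, k_bind) {
    sim <- run(mk(k_L, k_Qex, N_pool, k_bind), 30e-3, sampling = 5e-5)
    fit_three_phases(sim$time, sim$cyt3)$slopes
  }
  logroot <- function(f, lo, hi, tol = 1e-6) {
    if (f(lo) * f(hi) > 0) return(10^if (abs(f(lo)) < abs(f(hi))) lo
                                  else hi)
    10^stats::uniroot(function(p) f(p), c(lo, hi), tol = tol)$root
  }
  k_L <- slopes[1]; k_bind <- 6e5
  k_Qex <- slopes[2] / 2
  N_pool <- slopes[2] * t_pool
  # ballpark pass on direct slope measurements, then two refinement
  # passes in which each knob is root-solved against the slope the
  # segmented fit itself reports (the design slopes are observables of
  # the analysis, not raw parameters)
  k_Qex <- logroot(function(p)
    slope_between(run(mk(k_L, 10^p, 1e6, k_bind), 8e-3), 3e-3, 6e-3) -
      slopes[2], log10(slopes[2] / 2), log10(slopes[2] * 10), 1e-9)
  for (pass in 1:2) {
    sim_inf <- run(mk(k_L, k_Qex, 1e6, k_bind), t_pool * 1.2)
    N_pool <- stats::approx(sim_inf$time, sim_inf$cyt3, t_pool)$y - 1
    k_bind <- logroot(function(p)
      fitted_slopes(k_L, k_Qex, N_pool, 10^p)[3] - slopes[3],
      log10(3e3), log10(1e6))
    k_L <- logroot(function(p)
      fitted_slopes(10^p, k_Qex, N_pool, k_bind)[1] - slopes[1],
      log10(slopes[1]), log10(slopes[1] * 8), 1e-4)
    k_Qex <- logroot(function(p)
      fitted_slopes(k_L, 10^p, N_pool, k_bind)[2] - slopes[2],
      log10(slopes[2] / 2), log10(slopes[2] * 10), 1e-4)
  }
  out <- list(rates = mk(k_L, k_Qex, N_pool, k_bind), slopes = slopes,
              t_pool = t_pool,
              break1_est = 3 / (slopes[1] - slopes[2]))
  assign(key, out, envir = .rcflash_cache)
  out
}
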