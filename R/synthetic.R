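# Synthetic spectrometer: simulated experiments with the statistical
# structure the analysis assumes, plus a ground-truth record for every
# generated trace.

#' Measurement noise model
#'
#' Gaussian white noise per single sweep, reduced by sweep averaging; a
#' single integer seed makes every generated byte reproducible.
#'
#' @param sigma Absorbance noise SD per single sweep.
#' @param n_averages Number of averaged sweeps (noise SD scales as
#'   `1/sqrt(n)`).
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(sigma = 1e-3, n_averages = 32, seed = 1)
#' @export
noise_model <- function(sigma = 1e-4, n_averages = 32L, seed = NULL) {
  stopifnot(sigma >= 0, n_averages >= 1)
  structure(list(sigma = sigma, n_averages = as.integer(n_averages),
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(x, noise) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  x + stats::rnorm(length(x), 0, noise$sigma / sqrt(noise$n_averages))
}

per_rc_to_dA <- function(per_rc, rc_uM, delta_eps, path_cm, sign = -1) {
  # Beer-Lambert: dA = sign-convention * eps[mM^-1 cm^-1] * c[mM] * l[cm]
  sign * delta_eps * (per_rc * rc_uM * 1e-3) * path_cm
}

#' Generate a synthetic flash-train experiment
#'
#' Runs the chain model under a flash-train protocol for a strain preset,
#' converts the oxidized-cytochrome trajectory to a 551-540 nm
#' difference-absorbance trace (negative-going upon oxidation) and adds
#' averaged Gaussian noise. The returned ground truth holds the noiseless
#' step heights exactly as [extract_steps()] would measure them, the donor
#' equilibrium constants they imply, and the full parameterization.
#'
#' @param preset A [strain_preset()] (or preset name).
#' @param protocol Flash-train [illumination_protocol()]; default three
#'   flashes 400 us apart.
#' @param noise A [noise_model()].
#' @param rc_uM RC concentration, uM.
#' @param path_cm Optical path, cm.
#' @param delta_eps Cytochrome difference extinction coefficient,
#'   mM^-1 cm^-1 (21.1 by default; 20 is the alternative literature value).
#' @param window Plateau window used for the ground-truth step measurement.
#' @return A list with elements `trace` (an [absorbance_trace()]) and
#'   `truth` (steps, K_D, rates, protocol, seed).
#' @examples
#' \donttest{
#' ex <- generate_flash_experiment("rba_cycA", noise = noise_model(seed = 1))
#' range(ex$trace$delta_A)
#' }
#' @export
generate_flash_experiment <- function(preset,
                                      protocol = default_flash_protocol(),
                                      noise = noise_model(),
                                      rc_uM = 1, path_cm = 1,
                                      delta_eps = 21.1,
                                      window = c(100e-6, 350e-6)) {
  if (is.character(preset)) preset <- strain_preset(preset)
  stopifnot(inherits(preset, "strain_preset"))
  sim <- simulate_flash_train(preset$rates, protocol,
                              pool_fraction = preset$pool_fraction)
  steps_true <- extract_steps(
    data.frame(time_s = sim$time, per_rc = sim$cyt3), protocol,
    window = window)
  kd_true <- tryCatch(invert_steps(steps_true), error = function(e) NULL)
  dA <- per_rc_to_dA(sim$cyt3, rc_uM, delta_eps, path_cm)
  trace <- absorbance_trace(sim$time, apply_noise(dA, noise),
                            wavelength_pair = "551-540",
                            delta_eps = delta_eps, path_cm = path_cm,
                            rc_uM = rc_uM, protocol = protocol,
                            n_averages = noise$n_averages)
  truth <- list(preset = preset$name, treatment = preset$treatment,
                steps = as.list(unclass(steps_true)),
                kd = if (!is.null(kd_true))
                  kd_true[c("K_D1", "K_D2", "K_D3")],
                implied_kd = preset$implied_kd,
                pool_fraction = preset$pool_fraction,
                rates = unclass(preset$rates),
                sigma = noise$sigma, n_averages = noise$n_averages,
                seed = noise$seed)
  list(trace = trace, truth = truth)
}

#' Generate a synthetic continuous-illumination experiment
#'
#' Emulates strong continuous excitation. For untreated presets the rate
#' set is the three-phase design calibration: light-limited initial slope
#' `k_L`, a quinol-turnover-limited stationary slope and a pool-limited
#' tail (defaults 1.5e4, 3e3 and 50 cyt3+/RC/s with pool exhaustion near
#' 10 ms). Treatments are honoured: terbutryne blocks the quinone gate so
#' the trace saturates at one turnover.
#'
#' @param preset A [strain_preset()] or name; only its treatment flags and
#'   pool poise modify the design rates.
#' @param duration Trace length, s.
#' @param k_L Excitation rate, s^-1 (the designed initial slope).
#' @param noise A [noise_model()].
#' @param slopes Design slopes `c(initial, stationary, tail)` in
#'   cyt3+/RC/s.
#' @param t_pool Designed pool-exhaustion time, s.
#' @param sampling Output sampling interval, s.
#' @inheritParams generate_flash_experiment
#' @return A list with `trace` and `truth` (design slopes, breakpoint
#'   estimates, rates, seed).
#' @export
generate_continuous_experiment <- function(preset = "rvx_wt",
                                           duration = 30e-3,
                                           k_L = 1.5e4,
                                           noise = noise_model(),
                                           slopes = c(k_L, 3e3, 50),
                                           t_pool = 1e-2,
                                           rc_uM = 1, path_cm = 1,
                                           delta_eps = 21.1,
                                           sampling = 5e-5) {
  if (is.character(preset)) preset <- strain_preset(preset)
  stopifnot(inherits(preset, "strain_preset"))
  if (slopes[1] <= 0) {          # dark control: no light, no chemistry
    design <- list(rates = rate_set(k_L = 0, k_bc1 = 0),
                   break1_est = NA_real_)
    t_pool <- NA_real_
  } else {
    design <- calibrate_continuous_design(slopes, t_pool)
  }
  rates <- design$rates
  rates$terbutryne <- preset$rates$terbutryne
  rates$myxothiazol <- preset$rates$myxothiazol
  rates$dithionite <- preset$rates$dithionite
  rates$k_ext <- preset$rates$k_ext
  protocol <- illumination_protocol("continuous", duration,
                                    sampling = sampling)
  sim <- simulate_continuous(rates, protocol,
                             pool_fraction = preset$pool_fraction)
  dA <- per_rc_to_dA(sim$cyt3, rc_uM, delta_eps, path_cm)
  trace <- absorbance_trace(sim$time, apply_noise(dA, noise),
                            wavelength_pair = "551-540",
                            delta_eps = delta_eps, path_cm = path_cm,
                            rc_uM = rc_uM, protocol = protocol,
                            n_averages = noise$n_averages)
  truth <- list(preset = preset$name, treatment = preset$treatment,
                slopes = slopes,
                break1_est = design$break1_est, break2_est = t_pool,
                rates = unclass(rates), sigma = noise$sigma,
                n_averages = noise$n_averages, seed = noise$seed)
  list(trace = trace, truth = truth)
}

#' Generate a ferricyanide titration series
#'
#' Progressive oxidation of the cytochrome pool by ferricyanide is emulated
#' as a single-exponential decay of the reduced-pool fraction,
#' `r(t_inc) = r0 * exp(-k_ox * t_inc)` (default half-time 30 min). Each
#' incubation time yields a flash experiment at that pool poise; the
#' ground-truth donor constants decline monotonically with incubation.
#'
#' @param preset A [strain_preset()] or name.
#' @param t_inc Incubation times, s, non-negative.
#' @param k_ox Pool oxidation rate constant, s^-1 (`>= 0`).
#' @param protocol,noise,rc_uM,path_cm,delta_eps As in
#'   [generate_flash_experiment()]. Per-element seeds are derived from
#'   `noise$seed` so the series is reproducible.
#' @return A list of elements `list(t_inc =, trace =, truth =)`, in input
#'   order.
#' @export
generate_ferricyanide_titration <- function(preset, t_inc,
                                            k_ox = log(2) / 1800,
                                            protocol =
                                              default_flash_protocol(),
                                            noise = noise_model(),
                                            rc_uM = 1, path_cm = 1,
                                            delta_eps = 21.1) {
  if (k_ox < 0) stop("oxidation rate must be non-negative", call. = FALSE)
  if (any(t_inc < 0))
    stop("incubation times must be non-negative", call. = FALSE)
  if (is.character(preset)) preset <- strain_preset(preset)
  lapply(seq_along(t_inc), function(i) {
    p <- apply_redox_poise(preset, exp(-k_ox * t_inc[i]))
    p$treatment <- "ferricyanide"
    ns <- noise
    if (!is.null(ns$seed)) ns$seed <- ns$seed + i - 1L
    ex <- generate_flash_experiment(p, protocol, ns, rc_uM, path_cm,
                                    delta_eps)
    list(t_inc = t_inc[i], trace = ex$trace, truth = ex$truth)
  })
}

#' Write a generated experiment with its ground truth
#'
#' Writes the trace via [write_trace()] and the ground truth to
#' `<path>.truth.json`.
#'
#' @param experiment A list with `trace` and `truth` as returned by the
#'   generators.
#' @param path CSV path for the trace.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(experiment, path) {
  write_trace(experiment$trace, path)
  jsonlite::write_json(experiment$truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
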