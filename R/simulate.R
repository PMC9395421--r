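# Mean-field ODE machinery for the RC turnover chain model.
#
# The 48 discrete states evolve linearly except for cytochrome docking: a
# reduced cytochrome binds the vacant site at k_bind * r and an oxidized one
# at k_bind * (1 - r), where r is the instantaneous reduced fraction of the
# pool, so the docking site exchanges with the pool at its redox poise.
# Three bookkeeping scalars ride along: net oxidized cytochrome per RC,
# cumulative pool re-reduction by the bc1 complex, and electrons exported as
# quinol.  The observable cytochrome signal is net oxidation minus
# cumulative re-reduction.

build_chain_model <- function(rates, light_on) {
  er <- effective_rates(rates)
  st <- rc_states()
  n <- nrow(st)
  M <- matrix(0, n, n, dimnames = list(st$label, st$label))
  B <- matrix(0, n, n, dimnames = list(st$label, st$label))

  add <- function(M, from, to, k) {
    if (any(k > 0) && length(from)) {
      M[cbind(to, from)] <- M[cbind(to, from)] + k
      diag(M)[from] <- diag(M)[from] - k
    }
    M
  }
  relabel <- function(from, P = NULL, QA = NULL, QB = NULL, donor = NULL) {
    s <- st[from, ]
    if (!is.null(P)) s$P <- P
    if (!is.null(QA)) s$QA <- QA
    if (!is.null(QB)) s$QB <- QB
    if (!is.null(donor)) s$donor <- donor
    match(sprintf("%s.QA%d.%s.%s", s$P, s$QA, s$QB, s$donor), st$label)
  }

  # photochemistry under continuous light: open RCs only
  if (light_on && !er$dithionite) {
    from <- which(st$P == "P" & st$QA == 0L)
    M <- add(M, from, relabel(from, P = "Pp", QA = 1L), er$k_L)
  }
  # donor electron transfer: P+ with bound reduced cytochrome, reversible.
  # The reverse rate (donor poise) is indexed by the state's acceptor
  # electron count -- the donor availability in the i-hole state -- so an
  # RC that has turned over i times equilibrates at the i-th poise
  # irrespective of wall-clock flash number.
  et_from <- which(st$P == "Pp" & st$donor == "c2")
  M <- add(M, et_from, relabel(et_from, P = "P", donor = "c3"), er$k_ET)
  etr_from <- which(st$P == "P" & st$donor == "c3")
  n_e <- st$QA + c(QB = 0, QBm = 1, QBH2 = 2, empty = 2)[st$QB]
  poise_idx <- pmin(pmax(n_e, 1L), length(er$k_ETr))
  etr_rate <- er$k_ETr[poise_idx[etr_from]]
  M <- add(M, etr_from, relabel(etr_from, P = "Pp", donor = "c2"),
           etr_rate)
  # cytochrome release (either redox state)
  from <- which(st$donor == "c3")
  M <- add(M, from, relabel(from, donor = "vac"), er$k_unbind)
  from <- which(st$donor == "c2")
  M <- add(M, from, relabel(from, donor = "vac"), er$k_unbind)
  # docking from the pool: reduced at k_bind * r (matrix B), oxidized at
  # k_bind * (1 - r) (matrix B3)
  B3 <- matrix(0, n, n, dimnames = list(st$label, st$label))
  bind_from <- which(st$donor == "vac")
  B <- add(B, bind_from, relabel(bind_from, donor = "c2"), 1)
  B3 <- add(B3, bind_from, relabel(bind_from, donor = "c3"), 1)
  # interquinone electron transfers
  from <- which(st$QA == 1L & st$QB == "QB")
  M <- add(M, from, relabel(from, QA = 0L, QB = "QBm"), er$k_AB1)
  from <- which(st$QA == 1L & st$QB == "QBm")
  M <- add(M, from, relabel(from, QA = 0L, QB = "QBH2"), er$k_AB2)
  # quinol release and quinone rebinding
  qbh2 <- which(st$QB == "QBH2")
  M <- add(M, qbh2, relabel(qbh2, QB = "empty"), er$k_Qex)
  from <- which(st$QB == "empty")
  M <- add(M, from, relabel(from, QB = "QB"), er$k_Qex)
  # external donor (ferrocene): P+ -> P without cytochrome chemistry
  from <- which(st$P == "Pp")
  M <- add(M, from, relabel(from, P = "P"), er$k_ext)

  list(states = st, M = M, B = B, B3 = B3, rates = er,
       et_from = et_from, etr_from = etr_from, etr_rate = etr_rate,
       bind_from = bind_from,
       c2_idx = which(st$donor == "c2"), qbh2 = qbh2)
}

chain_derivs <- function(t, y, mod) {
  n <- nrow(mod$states)
  x <- y[seq_len(n)]
  r <- y[n + 1L]
  er <- mod$rates
  kb2 <- er$k_bind * r          # reduced cytochrome docking
  kb3 <- er$k_bind * (1 - r)    # oxidized cytochrome docking
  dx <- mod$M %*% x
  if (kb2 > 0) dx <- dx + kb2 * (mod$B %*% x)
  if (kb3 > 0) dx <- dx + kb3 * (mod$B3 %*% x)
  # pool reduced fraction: loses by reduced docking, gains by reduced
  # release and bc1 re-reduction
  dr <- if (er$N_pool > 0)
    (-kb2 * sum(x[mod$bind_from]) +
       er$k_unbind * sum(x[mod$c2_idx])) / er$N_pool +
    er$k_bc1 * (1 - r) else 0
  dcyt <- er$k_ET * sum(x[mod$et_from]) -
    sum(mod$etr_rate * x[mod$etr_from])
  dresup <- if (er$N_pool > 0) er$k_bc1 * (1 - r) * er$N_pool else 0
  dexp <- 2 * er$k_Qex * sum(x[mod$qbh2])
  list(c(as.numeric(dx), dr, dcyt, dresup, dexp))
}

# analytic Jacobian of the full (occupancy + bookkeeping) system; the
# bookkeeping scalars do not feed back into the occupancies, only r does
chain_jac <- function(t, y, mod) {
  n <- nrow(mod$states)
  x <- y[seq_len(n)]
  r <- y[n + 1L]
  er <- mod$rates
  m <- length(y)
  J <- matrix(0, m, m)
  J[seq_len(n), seq_len(n)] <- mod$M + er$k_bind * r * mod$B +
    er$k_bind * (1 - r) * mod$B3
  J[seq_len(n), n + 1L] <- er$k_bind * as.numeric((mod$B - mod$B3) %*% x)
  if (er$N_pool > 0) {
    J[n + 1L, mod$bind_from] <- -er$k_bind * r / er$N_pool
    J[n + 1L, mod$c2_idx] <- J[n + 1L, mod$c2_idx] +
      er$k_unbind / er$N_pool
    J[n + 1L, n + 1L] <- -er$k_bind * sum(x[mod$bind_from]) / er$N_pool -
      er$k_bc1
    J[n + 3L, n + 1L] <- -er$k_bc1 * er$N_pool
  }
  J[n + 2L, mod$et_from] <- er$k_ET
  J[n + 2L, mod$etr_from] <- J[n + 2L, mod$etr_from] - mod$etr_rate
  J[n + 4L, mod$qbh2] <- 2 * er$k_Qex
  J
}

integrate_chain <- function(mod, y0, times, rtol = 1e-8) {
  out <- deSolve::ode(y = y0, times = times, func = chain_derivs,
                      parms = mod, method = "lsoda",
                      jacfunc = chain_jac, jactype = "fullusr",
                      rtol = rtol, atol = 1e-12)
  if (nrow(out) < length(times) || any(!is.finite(out)))
    stop(sprintf(paste0("ODE integration produced non-finite values ",
                        "(k_L=%g, k_AB1=%g, k_AB2=%g, k_ET=%g, k_bind=%g)"),
                 mod$rates$k_L, mod$rates$k_AB1, mod$rates$k_AB2,
                 mod$rates$k_ET, mod$rates$k_bind), call. = FALSE)
  out
}

# pack integration output rows into the rc_simulation container
as_rc_simulation <- function(out, mod, rates, protocol) {
  n <- nrow(mod$states)
  occ <- out[, 1L + seq_len(n), drop = FALSE]
  colnames(occ) <- mod$states$label
  r <- out[, n + 2L]
  cum <- out[, n + 3L]
  resup <- out[, n + 4L]
  exported <- out[, n + 5L]
  pplus <- rowSums(occ[, mod$states$P == "Pp", drop = FALSE])
  structure(list(
    time = out[, 1L],
    occupancy = occ,
    cyt3 = cum - resup,
    cyt3_cum = cum,
    pplus = pplus,
    pool_fraction = r,
    exported = exported,
    rates = rates,
    protocol = protocol,
    states = mod$states
  ), class = "rc_simulation")
}

# Relax to the dark steady state before illumination.  With a reversible
# donor (k_ETr > 0) and a partially oxidized pool, the dark equilibrium
# holds some P+ (the pool oxidizes part of the special pair); starting
# from it keeps the pre-flash baseline flat.  Bookkeeping is zeroed so
# observables count light-induced chemistry only.
dark_adapt <- function(rates, pool_fraction, rtol, duration = 2e-2) {
  y0 <- c(rc_initial_state(rates, pool_fraction),
          r = if (rates$N_pool > 0) pool_fraction else 0,
          cyt = 0, resup = 0, exported = 0)
  if (all(rates$k_ETr == 0)) return(y0)
  mod <- build_chain_model(rates, light_on = FALSE)
  out <- integrate_chain(mod, y0, c(0, duration), rtol)
  y <- out[nrow(out), -1L]
  n <- nrow(mod$states)
  y[n + 2L] <- y[n + 3L] <- y[n + 4L] <- 0
  y
}

#' Simulate RC turnover under continuous illumination
#'
#' Integrates the mean-field chain model from the dark-adapted state under
#' continuous excitation at rate `k_L`. The cumulative oxidized cytochrome
#' per RC is monotone non-decreasing whenever pool re-reduction is disabled
#' (`k_bc1 = 0`), and its initial slope equals `k_L` when light is the
#' rate-limiting step.
#'
#' @param rates A [rate_set()].
#' @param protocol An [illumination_protocol()] with `mode = "continuous"`.
#' @param pool_fraction Initial reduced fraction of the cytochrome pool.
#' @param rtol Relative tolerance of the stiff integrator.
#' @return An object of class `rc_simulation` with elements `time`,
#'   `occupancy` (state-by-time matrix), `cyt3` (observed oxidized
#'   cytochrome per RC), `cyt3_cum` (cumulative, ignoring re-reduction),
#'   `pplus` (P+ per RC), `pool_fraction` and `exported` (electrons leaving
#'   as quinol).
#' @examples
#' pr <- illumination_protocol("continuous", duration = 2e-3)
#' sim <- simulate_continuous(rate_set(terbutryne = TRUE), pr)
#' tail(sim$cyt3, 1)  # -> 1 cyt3+/RC: single turnover when Q_B is blocked
#' @export
simulate_continuous <- function(rates, protocol, pool_fraction = 1,
                                rtol = 1e-8) {
  stopifnot(inherits(protocol, "illumination_protocol"))
  if (protocol$mode != "continuous")
    stop("protocol mode must be 'continuous'", call. = FALSE)
  mod <- build_chain_model(rates, light_on = TRUE)
  y0 <- dark_adapt(rates, pool_fraction, rtol)
  times <- seq(0, protocol$duration, by = protocol$sampling)
  out <- integrate_chain(mod, y0, times, rtol)
  as_rc_simulation(out, mod, rates, protocol)
}

#' Apply a saturating flash to an occupancy vector
#'
#' A saturating flash instantaneously closes every open RC: all occupancy in
#' states with P reduced and Q_A oxidized moves to the corresponding
#' P+ Q_A- state with the same Q_B-site and donor-site coordinates. Closed
#' states are untouched, so the operator is idempotent and conserves total
#' occupancy.
#'
#' @param y Named occupancy vector over [rc_states()] (as produced by
#'   [rc_initial_state()]).
#' @return The post-flash occupancy vector.
#' @examples
#' y <- rc_initial_state(rate_set())
#' yf <- apply_flash(y)
#' sum(yf)  # 1
#' @export
apply_flash <- function(y) {
  st <- rc_states()
  if (length(y) != nrow(st)) stop("occupancy vector of length 48 expected",
                                  call. = FALSE)
  open <- which(st$P == "P" & st$QA == 0L)
  closed <- match(sprintf("Pp.QA1.%s.%s", st$QB[open], st$donor[open]),
                  st$label)
  moved <- y[open]
  y[open] <- 0
  y[closed] <- y[closed] + moved
  y
}

#' Simulate a train of saturating flashes
#'
#' Alternates the instantaneous flash operator with dark relaxation of the
#' chain model between flashes, and extracts the per-flash cytochrome
#' oxidation increments. Step `i` is the increase of cumulative oxidized
#' cytochrome per RC between the firing of flash `i` and the firing of flash
#' `i + 1` (or the end of the trace for the last flash).
#'
#' @inheritParams simulate_continuous
#' @param protocol An [illumination_protocol()] with `mode = "flash_train"`.
#' @return An `rc_simulation` with an additional element `steps`, a
#'   [step_heights()] object of the per-flash increments.
#' @examples
#' pr <- illumination_protocol("flash_train", duration = 1.6e-3)
#' sim <- simulate_flash_train(rate_set(terbutryne = TRUE), pr)
#' sim$steps  # first step ~1, later steps 0
#' @export
simulate_flash_train <- function(rates, protocol, pool_fraction = 1,
                                 rtol = 1e-8) {
  stopifnot(inherits(protocol, "illumination_protocol"))
  if (protocol$mode != "flash_train")
    stop("protocol mode must be 'flash_train'", call. = FALSE)
  ft <- protocol$flash_times
  if (length(ft) > 1L && any(diff(ft) < protocol$sampling))
    stop("flash times closer than the sampling interval", call. = FALSE)
  mod <- build_chain_model(rates, light_on = FALSE)
  grid <- seq(0, protocol$duration, by = protocol$sampling)
  y <- dark_adapt(rates, pool_fraction, rtol)
  bounds <- c(0, ft, protocol$duration)
  rows <- NULL
  pre_flash_cum <- numeric(length(ft))
  nst <- nrow(mod$states)
  for (seg in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1L]
    if (seg > 1L) {  # a flash fires at t0
      pre_flash_cum[seg - 1L] <- y[nst + 2L]
      y[seq_len(nst)] <- apply_flash(y[seq_len(nst)])
    }
    tt <- c(t0, grid[grid > t0 & grid <= t1], t1)
    tt <- tt[c(TRUE, diff(tt) > 1e-12)]   # drop near-duplicate times
    if (length(tt) < 2L) tt <- c(t0, t1)
    out <- integrate_chain(mod, y, tt, rtol)
    y <- out[nrow(out), -1L]
    keep <- if (seg == 1L) seq_len(nrow(out)) else -1L
    rows <- rbind(rows, out[keep, , drop = FALSE])
  }
  sim <- as_rc_simulation(rows, mod, rates, protocol)
  if (length(ft)) {
    fin <- c(pre_flash_cum[-1L], sim$cyt3_cum[length(sim$cyt3_cum)])
    sim$steps <- step_heights(fin - pre_flash_cum)
  } else {
    sim$steps <- NULL
  }
  sim
}

#' Closed-form RC re-opening law
#'
#' The fraction of RCs that have re-opened a time `t` after a saturating
#' flash, when re-opening requires completion of one irreversible donor-side
#' step (rate `k_D`) and one irreversible acceptor-side step (rate `k_A`):
#' `(1 - exp(-k_A t)) * (1 - exp(-k_D t))`. The law is symmetric in the two
#' rates and tends to 1 as `t` grows.
#'
#' @param t Time since the flash, s (vectorized, `t >= 0`).
#' @param k_A,k_D Acceptor- and donor-side rate constants, s^-1 (`> 0`).
#' @return Re-opened fraction in `[0, 1]`.
#' @examples
#' reopening_fraction(1e-4, k_A = 1e4, k_D = 1e4)  # (1 - exp(-1))^2
#' @export
reopening_fraction <- function(t, k_A, k_D) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (k_A <= 0 || k_D <= 0) stop("rates must be positive", call. = FALSE)
  (1 - exp(-k_A * t)) * (1 - exp(-k_D * t))
}

#' @export
print.rc_simulation <- function(x, ...) {
  cat(sprintf("RC turnover simulation (%s), %d samples over %g s\n",
              x$protocol$mode, length(x$time), x$protocol$duration))
  cat(sprintf("  final cyt3+/RC = %.4g, final P+/RC = %.4g\n",
              x$cyt3[length(x$cyt3)], x$pplus[length(x$pplus)]))
  if (!is.null(x$steps))
    cat("  steps:", paste(signif(unclass(x$steps), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.rc_simulation <- function(x, ...) {
  data.frame(time_s = x$time, cyt3plus_per_rc = x$cyt3,
             pplus_per_rc = x$pplus, x$occupancy, check.names = FALSE)
}

#' @export
plot.rc_simulation <- function(x, ...) {
  graphics::plot(x$time * 1e3, x$cyt3, type = "l", xlab = "time (ms)",
                 ylab = "per RC", ...)
  graphics::lines(x$time * 1e3, x$pplus, lty = 2)
  graphics::legend("topleft", legend = c("cyt c3+/RC", "P+/RC"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Export a simulated trajectory to CSV with a JSON sidecar
#'
#' Writes the tidy trajectory (`time_s`, `cyt3plus_per_rc`, `pplus_per_rc`,
#' one column per discrete state) and a JSON sidecar holding the rate set
#' and protocol.
#'
#' @param sim An `rc_simulation`.
#' @param path CSV output path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "rc_simulation"))
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  meta <- list(rates = unclass(sim$rates),
               protocol = unclass(sim$protocol))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
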