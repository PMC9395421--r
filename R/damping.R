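#' Per-flash cytochrome oxidation step heights
#'
#' @param x Numeric vector of length 3: the oxidized cytochrome increments
#'   (cyt3+/RC) after flashes 1-3. The equilibrium damping model guarantees
#'   `0 <= D3 <= D2 <= D1 <= 1`; measured or simulated values may exceed
#'   these bounds slightly, so the constructor only checks sign and length.
#' @return An object of class `step_heights` (named numeric, `d1 d2 d3`).
#' @examples
#' step_heights(c(0.9, 0.882, 0.694))
#' @export
step_heights <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x)))
    stop("step_heights needs three finite values", call. = FALSE)
  structure(stats::setNames(x, c("d1", "d2", "d3")), class = "step_heights")
}

#' @export
print.step_heights <- function(x, ...) {
  cat("Cytochrome oxidation steps (cyt3+/RC):",
      paste(sprintf("D%d = %.4g", 1:3, unclass(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Generalized donor and acceptor equilibrium constants
#'
#' The donor constants `K_D1..K_D3` express the availability of reduced
#' cytochrome to P+ after flashes 1-3 (binding/exchange plus electron
#' transfer combined); the acceptor constants `K_A1, K_A2` express the
#' Q_A-/Q_B electron equilibria with one or two electrons on the acceptor
#' side. All are dimensionless and non-negative; `Inf` is accepted (a fully
#' one-sided equilibrium).
#'
#' @param K_D1,K_D2,K_D3 Donor-side constants, `>= 0`.
#' @param K_A1,K_A2 Acceptor-side constants, `>= 0`, default `Inf`.
#' @return An object of class `equilibrium_constants`.
#' @examples
#' equilibrium_constants(9, 49, 3.7)
#' @export
equilibrium_constants <- function(K_D1, K_D2, K_D3, K_A1 = Inf, K_A2 = Inf) {
  k <- c(K_D1 = unname(K_D1), K_D2 = unname(K_D2), K_D3 = unname(K_D3),
         K_A1 = unname(K_A1), K_A2 = unname(K_A2))
  if (any(is.na(k)) || any(k < 0))
    stop("equilibrium constants must be non-negative (Inf allowed)",
         call. = FALSE)
  structure(as.list(k), class = "equilibrium_constants")
}

#' @export
print.equilibrium_constants <- function(x, ...) {
  cat(sprintf("K_D = (%.4g, %.4g, %.4g), K_A = (%.4g, %.4g)\n",
              x$K_D1, x$K_D2, x$K_D3, x$K_A1, x$K_A2))
  invisible(x)
}

# K/(1+K), with the K -> Inf limit equal to 1
eq_frac <- function(K) ifelse(is.infinite(K), 1, K / (1 + K))

#' Forward damping model: equilibrium constants to step heights
#'
#' Maps the generalized equilibrium constants to the three flash-induced
#' cytochrome oxidation steps:
#' \deqn{\Delta_1 = \frac{K_{D1}}{1+K_{D1}}}
#' \deqn{\Delta_2 = \frac{K_{A1}}{1+K_{A1}} \cdot \Delta_1 \cdot
#'   \frac{K_{D2}}{1+K_{D2}}}
#' \deqn{\Delta_3 = \frac{K_{A1}}{1+K_{A1}} \frac{K_{A2}}{1+K_{A2}} \cdot
#'   \Delta_1 \frac{K_{D2}}{1+K_{D2}} \frac{K_{D3}}{1+K_{D3}}}
#' so that `0 <= D3 <= D2 <= D1 <= 1` for any non-negative constants.
#'
#' @param K An [equilibrium_constants()] object.
#' @return A [step_heights()] object.
#' @examples
#' forward_steps(equilibrium_constants(9, 49, 3.7))  # Rvx WT constants
#' @export
forward_steps <- function(K) {
  stopifnot(inherits(K, "equilibrium_constants"))
  d1 <- eq_frac(K$K_D1)
  d2 <- eq_frac(K$K_A1) * d1 * eq_frac(K$K_D2)
  d3 <- eq_frac(K$K_A1) * eq_frac(K$K_A2) * d1 * eq_frac(K$K_D2) *
    eq_frac(K$K_D3)
  step_heights(c(d1, d2, d3))
}

#' Invert step heights to donor equilibrium constants
#'
#' Under the approximation that the acceptor-side equilibria lie far to the
#' right (`K_A >> 1`), the donor constants follow directly from the measured
#' steps: `K_D1 = D1/(1-D1)`, `K_D2 = r2/(1-r2)` with `r2 = D2/D1`, and
#' `K_D3 = r3/(1-r3)` with `r3 = D3/D2`. Supplying finite acceptor constants
#' through `K_A` divides each step ratio by the corresponding
#' `K_Ai/(1+K_Ai)` factor first, giving the exact inversion of the forward
#' model for known acceptor equilibria.
#'
#' @param steps A [step_heights()] object (or numeric length-3 vector).
#' @param K_A Acceptor constants `c(K_A1, K_A2)` assumed known; default
#'   `c(Inf, Inf)` (the neglect-acceptor approximation).
#' @param clip_tol If `NULL` (default) a step ratio at or above 1 is an
#'   error (no damping: the constant is unidentifiable). If a small positive
#'   number, ratios in `[1, 1 + clip_tol]` are clipped just below 1 instead;
#'   larger ratios still raise.
#' @return An [equilibrium_constants()] with the recovered `K_D` and the
#'   assumed `K_A`.
#' @examples
#' invert_steps(step_heights(c(0.5, 0.25, 0.125)))  # K_D = (1, 1, 1)
#' @export
invert_steps <- function(steps, K_A = c(Inf, Inf), clip_tol = NULL) {
  if (!inherits(steps, "step_heights")) steps <- step_heights(steps)
  d <- unclass(steps)
  if (d[1] <= 0)
    stop("D1 = 0: donor constants undefined", call. = FALSE)
  if (d[1] >= 1 && is.null(clip_tol))
    stop("D1 >= 1: no damping, K_D1 unidentifiable", call. = FALSE)
  if (length(K_A) != 2L || any(K_A < 0))
    stop("K_A must be two non-negative values", call. = FALSE)
  fix <- function(r, what) {
    if (!is.finite(r) || r <= 0)
      stop(sprintf("step ratio %s is not in (0, 1)", what), call. = FALSE)
    if (r >= 1) {
      if (!is.null(clip_tol) && r <= 1 + clip_tol) r <- 1 - 1e-9
      else stop(sprintf(
        "no damping: step ratio %s >= 1, constant unidentifiable", what),
        call. = FALSE)
    }
    r
  }
  d1 <- fix(d[1], "D1")
  r2 <- fix(d[2] / d[1] / eq_frac(K_A[1]), "D2/D1")
  r3 <- fix(d[3] / d[2] / eq_frac(K_A[2]), "D3/D2")
  equilibrium_constants(K_D1 = d1 / (1 - d1), K_D2 = r2 / (1 - r2),
                        K_D3 = r3 / (1 - r3), K_A1 = K_A[1], K_A2 = K_A[2])
}

#' Damping ratio as a function of flash delay
#'
#' The ratio of consecutive step heights when the later flash is delayed by
#' `T` follows the re-opening law scaled by its equilibrium asymptote:
#' `ratio(T) = R_inf * (1 - exp(-k_A T)) * (1 - exp(-k_D T))`. The curve is
#' monotone increasing in `T` and tends to `R_inf`.
#'
#' @param k_A,k_D Acceptor- and donor-side rate constants, s^-1 (`> 0`).
#' @param R_inf Asymptotic (equilibrium) damping level, in `(0, 1]`.
#' @param delays Flash delays, s, strictly increasing and positive.
#' @param pair Flash-pair label, `"2/1"` or `"3/2"`.
#' @return An object of class `damping_curve`: a data frame with columns
#'   `delay_s`, `ratio` and attributes `pair`, `k_A`, `k_D`, `R_inf`.
#' @examples
#' damping_vs_delay(1.2e4, 1e6, 1, delays = c(5e-5, 1e-4, 2e-4, 1e-3))
#' @export
damping_vs_delay <- function(k_A, k_D, R_inf, delays, pair = "2/1") {
  if (any(delays <= 0)) stop("delays must be positive", call. = FALSE)
  if (any(diff(delays) <= 0))
    stop("delays must be strictly increasing", call. = FALSE)
  if (R_inf <= 0 || R_inf > 1)
    stop("R_inf must be in (0, 1]", call. = FALSE)
  ratio <- R_inf * reopening_fraction(delays, k_A, k_D)
  damping_curve(delays, ratio, pair = pair)
}

#' Construct a damping curve
#'
#' @param delay_s Flash delays, s, strictly increasing.
#' @param ratio Step ratios (D2/D1 or D3/D2); values in `[0, 1.05]` (a small
#'   noise overshoot above 1 is tolerated).
#' @param pair Flash-pair label, `"2/1"` or `"3/2"`.
#' @return A `damping_curve` data frame.
#' @export
damping_curve <- function(delay_s, ratio, pair = "2/1") {
  pair <- match.arg(pair, c("2/1", "3/2"))
  if (any(diff(delay_s) <= 0))
    stop("delays must be strictly increasing", call. = FALSE)
  if (any(ratio < 0) || any(ratio > 1.05))
    stop("ratios must lie in [0, 1.05]", call. = FALSE)
  structure(data.frame(delay_s = delay_s, ratio = ratio),
            pair = pair, class = c("damping_curve", "data.frame"))
}

#' Read/write a damping curve as two-column CSV
#'
#' The file holds `delay_s, ratio` with a leading comment line naming the
#' flash pair.
#'
#' @param curve A [damping_curve()].
#' @param path File path.
#' @return `write_damping_curve` returns `path` invisibly;
#'   `read_damping_curve` returns a `damping_curve`.
#' @export
write_damping_curve <- function(curve, path) {
  stopifnot(inherits(curve, "damping_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# flash pair %s", attr(curve, "pair")), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_damping_curve
#' @export
read_damping_curve <- function(path) {
  first <- readLines(path, n = 1L)
  pair <- if (grepl("3/2", first)) "3/2" else "2/1"
  df <- utils::read.csv(path, comment.char = "#")
  damping_curve(df$delay_s, df$ratio, pair = pair)
}

#' Convert a ferricyanide titration step series to equilibrium constants
#'
#' Applies [invert_steps()] to each element of a step-height series recorded
#' at increasing incubation times with an oxidant, preserving order. An
#' inversion failure is re-raised with the offending incubation time in the
#' message.
#'
#' @param step_series A data frame with columns `t_inc` (incubation time, s)
#'   and `d1`, `d2`, `d3`, or a list of `list(t_inc =, steps =)` pairs.
#' @param ... Passed to [invert_steps()] (e.g. `K_A`, `clip_tol`).
#' @return A data frame with columns `t_inc`, `K_D1`, `K_D2`, `K_D3`.
#' @examples
#' titration_to_kd(data.frame(t_inc = 0, d1 = 0.5, d2 = 0.25, d3 = 0.125))
#' @export
titration_to_kd <- function(step_series, ...) {
  if (is.data.frame(step_series)) {
    items <- lapply(seq_len(nrow(step_series)), function(i)
      list(t_inc = step_series$t_inc[i],
           steps = step_heights(unlist(step_series[i, c("d1", "d2", "d3")]))))
  } else {
    items <- step_series
  }
  rows <- lapply(items, function(el) {
    K <- tryCatch(invert_steps(el$steps, ...), error = function(e)
      stop(sprintf("at incubation time %g s: %s", el$t_inc,
                   conditionMessage(e)), call. = FALSE))
    data.frame(t_inc = el$t_inc, K_D1 = K$K_D1, K_D2 = K$K_D2,
               K_D3 = K$K_D3)
  })
  if (!length(rows))
    return(data.frame(t_inc = numeric(), K_D1 = numeric(),
                      K_D2 = numeric(), K_D3 = numeric()))
  do.call(rbind, rows)
}
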