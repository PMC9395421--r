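# Absorbance-trace containers and reduction to model-ready quantities.

# oxidation gives a negative absorbance change at both difference pairs used
# here (cytochrome 551-540 nm and P/P+ 790-750 nm); the TMPD pair rises.
PAIR_SIGNS <- c("551-540" = -1, "790-750" = -1, "611-675" = 1)

#' Construct a difference-absorbance trace
#'
#' A uniformly sampled difference-absorbance time series with the metadata
#' needed to convert it to concentrations: wavelength pair, difference
#' extinction coefficient, optical path, optional RC concentration, the
#' illumination protocol and the number of averaged sweeps.
#'
#' @param time_s Sample times, s, strictly increasing and uniform within 1%.
#' @param delta_A Absorbance difference (dimensionless).
#' @param wavelength_pair Label such as `"551-540"` (cytochrome) or
#'   `"790-750"` (P/P+).
#' @param delta_eps Difference extinction coefficient, mM^-1 cm^-1
#'   (default 21.1, the cytochrome c 551-540 nm value; 20 is an alternative
#'   literature value, and 70 applies to P/P+).
#' @param path_cm Optical path length, cm.
#' @param rc_uM RC concentration, uM (optional; enables per-RC units).
#' @param protocol Optional [illumination_protocol()].
#' @param n_averages Number of averaged sweeps.
#' @param sign Direction of the absorbance change upon oxidation (+1 or -1);
#'   defaults to the wavelength-pair convention, and is metadata, never
#'   inferred from the data.
#' @return A data frame of class `absorbance_trace` with columns `time_s`,
#'   `delta_A` and the metadata in attributes.
#' @examples
#' tr <- absorbance_trace(seq(0, 1e-3, 5e-5), rep(-0.0211, 21), rc_uM = 1)
#' @export
absorbance_trace <- function(time_s, delta_A, wavelength_pair = "551-540",
                             delta_eps = 21.1, path_cm = 1, rc_uM = NA_real_,
                             protocol = NULL, n_averages = 1L,
                             sign = NULL) {
  stopifnot(length(time_s) == length(delta_A), length(time_s) >= 2L)
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 0.01 * mean(dt))
    stop("time grid must be uniform within 1%", call. = FALSE)
  if (!is.numeric(delta_eps) || delta_eps <= 0)
    stop("delta_eps must be positive", call. = FALSE)
  if (path_cm <= 0) stop("path length must be positive", call. = FALSE)
  if (is.null(sign)) {
    sign <- if (wavelength_pair %in% names(PAIR_SIGNS))
      PAIR_SIGNS[[wavelength_pair]] else -1
  }
  structure(data.frame(time_s = as.numeric(time_s),
                       delta_A = as.numeric(delta_A)),
            wavelength_pair = wavelength_pair, delta_eps = delta_eps,
            path_cm = path_cm, rc_uM = rc_uM, protocol = protocol,
            n_averages = as.integer(n_averages), sign = sign,
            class = c("absorbance_trace", "data.frame"))
}

#' @export
print.absorbance_trace <- function(x, ...) {
  cat(sprintf(
    "Absorbance trace %s: %d samples, dt = %g s, n_averages = %d\n",
    attr(x, "wavelength_pair"), nrow(x), mean(diff(x$time_s)),
    attr(x, "n_averages")))
  cat(sprintf("  delta_eps = %g mM^-1 cm^-1, path = %g cm, [RC] = %g uM\n",
              attr(x, "delta_eps"), attr(x, "path_cm"), attr(x, "rc_uM")))
  invisible(x)
}

#' Convert an absorbance trace to concentrations (Beer-Lambert)
#'
#' `c(t) = sign * delta_A(t) / (delta_eps * l)`, with the sign chosen from
#' the wavelength-pair metadata so that oxidation is always reported
#' positive (cytochrome oxidation gives a negative absorbance change at
#' 551-540 nm). If the RC concentration is set, a per-RC column is added.
#'
#' @param trace An [absorbance_trace()].
#' @return A data frame with columns `time_s`, `conc_uM` and, when `[RC]` is
#'   known, `per_rc`; protocol metadata is carried in attributes.
#' @examples
#' tr <- absorbance_trace(c(0, 5e-5), c(-0.0211, -0.0211), rc_uM = 0.5)
#' absorbance_to_concentration(tr)$per_rc  # 2 cyt3+/RC
#' @export
absorbance_to_concentration <- function(trace) {
  stopifnot(inherits(trace, "absorbance_trace"))
  eps <- attr(trace, "delta_eps")
  if (is.null(eps) || !is.finite(eps))
    stop("delta_eps is not configured on this trace", call. = FALSE)
  sgn <- attr(trace, "sign")
  conc_mM <- sgn * trace$delta_A / (eps * attr(trace, "path_cm"))
  out <- data.frame(time_s = trace$time_s, conc_uM = conc_mM * 1e3)
  rc <- attr(trace, "rc_uM")
  if (is.finite(rc) && rc > 0) out$per_rc <- out$conc_uM / rc
  attr(out, "protocol") <- attr(trace, "protocol")
  out
}

#' Extract per-flash step heights from a concentration series
#'
#' Averages the trace over a plateau window after each flash and differences
#' consecutive plateau levels. The default window, 100-350 us after the
#' flash, sits inside a 400 us flash spacing and past the 50 us instrument
#' resolution. The level before the first flash is the pre-flash baseline.
#'
#' @param conc Data frame with `time_s` and a per-RC value column (`per_rc`
#'   if present, otherwise the second column).
#' @param protocol An [illumination_protocol()] in flash-train mode (or
#'   `NULL` to use the protocol attached to `conc`).
#' @param window Plateau window `c(start, end)` in s after each flash.
#' @return A [step_heights()] object.
#' @examples
#' t <- seq(0, 1.6e-3, 5e-5)
#' pr <- illumination_protocol("flash_train", 1.6e-3)
#' y <- (t >= 2e-4) + 0.8 * (t >= 6e-4) + 0.6 * (t >= 1e-3)
#' extract_steps(data.frame(time_s = t, per_rc = y), pr)
#' @export
extract_steps <- function(conc, protocol = NULL,
                          window = c(100e-6, 350e-6)) {
  if (is.null(protocol)) protocol <- attr(conc, "protocol")
  if (is.null(protocol) || protocol$mode != "flash_train")
    stop("a flash_train protocol is required", call. = FALSE)
  ft <- protocol$flash_times
  if (!length(ft)) stop("protocol contains no flashes", call. = FALSE)
  if (window[1] < 0 || window[2] <= window[1])
    stop("invalid plateau window", call. = FALSE)
  gaps <- diff(c(ft, protocol$duration))
  if (any(window[2] > gaps))
    stop("plateau window overlaps the next flash", call. = FALSE)
  t <- conc$time_s
  v <- if ("per_rc" %in% names(conc)) conc$per_rc else conc[[2L]]
  plateau <- function(f) {
    sel <- t >= f + window[1] & t <= f + window[2]
    if (!any(sel)) stop("no samples inside the plateau window",
                        call. = FALSE)
    mean(v[sel])
  }
  levels <- vapply(ft, plateau, numeric(1))
  base_sel <- t < ft[1]
  baseline <- if (any(base_sel)) mean(v[base_sel]) else 0
  d <- diff(c(baseline, levels))
  if (length(d) < 3L) d <- c(d, rep(0, 3L - length(d)))
  step_heights(d[1:3])
}

#' Average traces sharing a time grid
#'
#' Pointwise mean of several sweeps of the same experiment; the sweep counts
#' add, so white noise shrinks as `1/sqrt(n)`.
#'
#' @param traces List of [absorbance_trace()] objects on identical grids and
#'   wavelength pairs.
#' @return A single averaged `absorbance_trace`.
#' @export
average_traces <- function(traces) {
  stopifnot(length(traces) >= 1L)
  ref <- traces[[1L]]
  for (tr in traces[-1L]) {
    if (nrow(tr) != nrow(ref) ||
        max(abs(tr$time_s - ref$time_s)) > 1e-12 * max(ref$time_s))
      stop("traces are not on the same time grid", call. = FALSE)
    if (!identical(attr(tr, "wavelength_pair"),
                   attr(ref, "wavelength_pair")))
      stop("traces measure different wavelength pairs", call. = FALSE)
  }
  dA <- rowMeans(do.call(cbind, lapply(traces, `[[`, "delta_A")))
  n <- sum(vapply(traces, attr, integer(1), which = "n_averages"))
  absorbance_trace(ref$time_s, dA,
                   wavelength_pair = attr(ref, "wavelength_pair"),
                   delta_eps = attr(ref, "delta_eps"),
                   path_cm = attr(ref, "path_cm"),
                   rc_uM = attr(ref, "rc_uM"),
                   protocol = attr(ref, "protocol"), n_averages = n,
                   sign = attr(ref, "sign"))
}

#' Normalize a concentration series to a single-turnover reference
#'
#' Divides the series by the amplitude of a single-turnover reference signal
#' (e.g. the flash-induced P+ amplitude of a cytochrome-less strain), so
#' that one turnover maps to 1.0 per RC.
#'
#' @param conc Data frame with a value column (`per_rc` or second column).
#' @param reference Positive reference amplitude in the same units.
#' @return The series with the value column divided by `reference`.
#' @export
normalize_to_reference <- function(conc, reference) {
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0)
    stop("reference amplitude must be a positive scalar", call. = FALSE)
  col <- if ("per_rc" %in% names(conc)) "per_rc" else names(conc)[2L]
  conc[[col]] <- conc[[col]] / reference
  conc
}

#' Read/write an absorbance trace as CSV plus JSON sidecar
#'
#' The CSV holds `time_s, delta_A`; the sidecar (same path with `.json`
#' appended) records wavelength pair, extinction coefficient, path length,
#' RC concentration, protocol and sweep count.
#'
#' @param trace An [absorbance_trace()].
#' @param path CSV file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns the
#'   reconstituted `absorbance_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "absorbance_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  pr <- attr(trace, "protocol")
  meta <- list(wavelength_pair = attr(trace, "wavelength_pair"),
               delta_eps = attr(trace, "delta_eps"),
               path_cm = attr(trace, "path_cm"),
               rc_uM = attr(trace, "rc_uM"),
               n_averages = attr(trace, "n_averages"),
               sign = attr(trace, "sign"),
               protocol = if (!is.null(pr)) unclass(pr))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pr <- meta$protocol
  protocol <- if (!is.null(pr))
    illumination_protocol(pr$mode, pr$duration,
                          flash_times = as.numeric(pr$flash_times),
                          saturating = pr$saturating, sampling = pr$sampling)
  absorbance_trace(df$time_s, df$delta_A,
                   wavelength_pair = meta$wavelength_pair,
                   delta_eps = meta$delta_eps, path_cm = meta$path_cm,
                   rc_uM = if (is.null(meta$rc_uM)) NA_real_ else meta$rc_uM,
                   protocol = protocol, n_averages = meta$n_averages,
                   sign = meta$sign)
}
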