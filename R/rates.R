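#' Microscopic rate constants and pool parameters of the chain model
#'
#' Collects every rate constant, the cytochrome pool size and the inhibitor
#' flags that parameterize the RC turnover model.
#'
#' @param k_L Photon absorption (excitation) rate under continuous light,
#'   s^-1. Ignored in flash-train mode, where flashes are saturating and
#'   instantaneous.
#' @param k_AB1,k_AB2 First and second interquinone electron-transfer rates
#'   (Q_A- Q_B -> Q_A Q_B- and Q_A- Q_B- -> Q_A Q_BH2), s^-1.
#' @param k_Qex Quinol release and quinone rebinding rate at the Q_B site,
#'   s^-1. Both elementary steps (Q_BH2 -> empty and empty -> Q_B) proceed at
#'   this rate; the default corresponds to the millisecond-scale quinone
#'   exchange of purple-bacterial RCs.
#' @param k_bind Pseudo-first-order docking rate of a reduced cytochrome at
#'   the vacant donor site, s^-1 at a fully reduced pool; the instantaneous
#'   rate is `k_bind` times the reduced-pool fraction.
#' @param k_unbind Release rate of the oxidized cytochrome from the docking
#'   site, s^-1.
#' @param k_ET Electron-transfer rate from the bound reduced cytochrome to
#'   P+, s^-1.
#' @param k_ETr Reverse electron-transfer rate (P to bound oxidized
#'   cytochrome), s^-1. The default 0 makes donor oxidation irreversible;
#'   a positive value gives the donor side a true equilibrium
#'   (`K = k_ET / k_ETr`), which together with the pool redox state
#'   produces the stable partial oxidation plateaus seen in flash trains.
#'   May be a vector of up to three values, indexed by the RC's acceptor
#'   electron count: the donor poise in the i-hole state (the generalized
#'   donor availability falls as progressively poorer donors remain after
#'   each turnover). A scalar applies one poise throughout.
#' @param N_pool Number of reduced cytochromes available per RC
#'   (dimensionless pool size). `N_pool = 0` disables donor resupply
#'   entirely (cytochrome-less strains).
#' @param k_bc1 First-order re-reduction rate of the oxidized pool by the
#'   bc1 complex, s^-1. Default (10 ms)^-1; the myxothiazol flag divides it
#'   by ten, i.e. (100 ms)^-1.
#' @param k_ext Pseudo-first-order re-reduction rate of P+ by an external
#'   donor such as ferrocene, s^-1 (its concentration vastly exceeds P+, so
#'   a pseudo-first-order treatment is adequate).
#' @param terbutryne Logical; blocks both interquinone transfers
#'   (`k_AB1 = k_AB2 = 0`).
#' @param myxothiazol Logical; slows pool re-reduction tenfold.
#' @param dithionite Logical; pre-reduces the acceptor side (Q_A-), which
#'   disables photochemistry.
#' @return An object of class `rate_set` (a named list).
#' @examples
#' rate_set(terbutryne = TRUE)
#' @export
rate_set <- function(k_L = 1.5e4, k_AB1 = 1e4, k_AB2 = 7.2e3, k_Qex = 1e3,
                     k_bind = 5e4, k_unbind = 5e4, k_ET = 5e4, k_ETr = 0,
                     N_pool = 10, k_bc1 = 100, k_ext = 0,
                     terbutryne = FALSE, myxothiazol = FALSE,
                     dithionite = FALSE) {
  rs <- list(k_L = k_L, k_AB1 = k_AB1, k_AB2 = k_AB2, k_Qex = k_Qex,
             k_bind = k_bind, k_unbind = k_unbind, k_ET = k_ET,
             k_ETr = k_ETr,
             N_pool = N_pool, k_bc1 = k_bc1, k_ext = k_ext,
             terbutryne = isTRUE(terbutryne),
             myxothiazol = isTRUE(myxothiazol),
             dithionite = isTRUE(dithionite))
  num <- unlist(rs[1:11])
  if (any(!is.finite(num)) || any(num < 0))
    stop("all rates and N_pool must be finite and non-negative",
         call. = FALSE)
  if (!length(k_ETr) %in% 1:3)
    stop("k_ETr must have length 1 to 3", call. = FALSE)
  class(rs) <- "rate_set"
  rs
}

# resolve inhibitor flags into effective rate values
effective_rates <- function(rs) {
  stopifnot(inherits(rs, "rate_set"))
  er <- rs
  if (rs$terbutryne) er$k_AB1 <- er$k_AB2 <- 0
  if (rs$myxothiazol) er$k_bc1 <- rs$k_bc1 / 10
  er
}

#' @export
print.rate_set <- function(x, ...) {
  cat("RC chain-model rate set (s^-1 unless noted)\n")
  v <- x[1:11]
  cat(paste(sprintf("  %-9s %s", names(v),
                    vapply(v, function(z)
                      paste(signif(z, 6), collapse = ", "),
                      character(1))),
            collapse = "\n"), "\n")
  flags <- c("terbutryne", "myxothiazol", "dithionite")
  on <- flags[unlist(x[flags])]
  if (length(on)) cat("  flags:   ", paste(on, collapse = ", "), "\n")
  invisible(x)
}

#' Illumination protocol
#'
#' Describes how the sample is excited: continuous light, or a train of
#' saturating flashes at given times, with a fixed output sampling interval.
#'
#' @param mode `"continuous"` or `"flash_train"`.
#' @param duration Total simulated/recorded time, s.
#' @param flash_times Flash firing times, s, strictly increasing and within
#'   `[0, duration]` (flash-train mode). The default places three flashes
#'   400 us apart starting 200 us into the trace, as in a three-flash
#'   experiment.
#' @param saturating Logical; saturating flashes close every open RC.
#' @param sampling Output sampling interval, s (default 50 us, the
#'   instrument time resolution).
#' @return An object of class `illumination_protocol`.
#' @examples
#' illumination_protocol("flash_train", duration = 1.6e-3)
#' @export
illumination_protocol <- function(mode = c("continuous", "flash_train"),
                                  duration,
                                  flash_times = if (mode == "flash_train")
                                    2e-4 + 4e-4 * (0:2) else numeric(),
                                  saturating = TRUE,
                                  sampling = 5e-5) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0,
            is.numeric(sampling), sampling > 0)
  if (mode == "flash_train") {
    if (length(flash_times)) {
      if (any(diff(flash_times) <= 0))
        stop("flash times must be strictly increasing", call. = FALSE)
      if (any(flash_times < 0) || any(flash_times > duration))
        stop("flash times must lie within [0, duration]", call. = FALSE)
    }
  } else {
    flash_times <- numeric()
  }
  structure(list(mode = mode, duration = duration,
                 flash_times = as.numeric(flash_times),
                 saturating = isTRUE(saturating), sampling = sampling),
            class = "illumination_protocol")
}

#' @export
print.illumination_protocol <- function(x, ...) {
  cat("Illumination protocol:", x$mode, "\n")
  cat(sprintf("  duration %g s, sampling %g s\n", x$duration, x$sampling))
  if (x$mode == "flash_train")
    cat("  flashes at:", paste(signif(x$flash_times, 4), collapse = ", "),
        "s\n")
  invisible(x)
}
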