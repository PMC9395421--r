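#' Enumerate the discrete reaction-center states
#'
#' The chain model tracks every reaction center (RC) as one of the discrete
#' states formed by the cross product of four coordinates:
#' \itemize{
#'   \item special-pair redox state: `"P"` (reduced) or `"Pp"` (oxidized, P+);
#'   \item primary quinone electron count `QA`: 0 or 1;
#'   \item secondary quinone (Q_B) site: `"QB"` (oxidized quinone bound),
#'     `"QBm"` (semiquinone, one electron), `"QBH2"` (quinol, two electrons),
#'     or `"empty"` (quinol released, site awaiting a fresh quinone);
#'   \item donor docking site: `"vac"` (vacant), `"c2"` (reduced cytochrome
#'     bound) or `"c3"` (oxidized cytochrome bound).
#' }
#'
#' No combination is physically excluded, so the state space has
#' 2 x 2 x 4 x 3 = 48 members. The ordering is deterministic: the special-pair
#' coordinate varies fastest, then `QA`, then the Q_B site, then the donor
#' site (the order produced by [expand.grid()] over the coordinate levels
#' listed above).
#'
#' @return A data frame with one row per state and columns `P`, `QA`, `QB`,
#'   `donor` and a unique `label` of the form `"P.QA0.QB.c2"`.
#' @examples
#' st <- rc_states()
#' nrow(st)              # 48
#' head(st$label)
#' @export
rc_states <- function() {
  g <- expand.grid(
    P = c("P", "Pp"),
    QA = c(0L, 1L),
    QB = c("QB", "QBm", "QBH2", "empty"),
    donor = c("vac", "c2", "c3"),
    stringsAsFactors = FALSE,
    KEEP.OUT.ATTRS = FALSE
  )
  g$label <- sprintf("%s.QA%d.%s.%s", g$P, g$QA, g$QB, g$donor)
  g
}

# index of a single state by coordinates
rc_state_index <- function(states, P, QA, QB, donor) {
  i <- which(states$P == P & states$QA == QA & states$QB == QB &
               states$donor == donor)
  if (length(i) != 1L) stop("no such RC state", call. = FALSE)
  i
}

#' Dark-adapted initial occupancy vector
#'
#' All occupancy starts in the open state with an oxidized quinone bound at
#' the Q_B site (`P`, `QA0`, `QB`). The donor docking site starts at its
#' dark exchange equilibrium: occupied with probability
#' `k_bind / (k_bind + k_unbind)`, and a bound cytochrome is reduced with
#' probability `pool_fraction` (the reduced fraction of the pool it
#' exchanges with). Cytochrome-less configurations (`k_bind = 0`) start
#' vacant. With the dithionite flag the acceptor side is pre-reduced
#' (`QA1`), which blocks photochemistry.
#'
#' @param rates A [rate_set()].
#' @param pool_fraction Initial reduced fraction of the cytochrome pool in
#'   `[0, 1]`. Used by the ferricyanide-titration generator and the strain
#'   presets.
#' @return Named occupancy vector over [rc_states()], summing to 1.
#' @export
rc_initial_state <- function(rates, pool_fraction = 1) {
  stopifnot(pool_fraction >= 0, pool_fraction <= 1)
  st <- rc_states()
  y <- stats::setNames(numeric(nrow(st)), st$label)
  qa0 <- if (isTRUE(rates$dithionite)) 1L else 0L
  donor_present <- rates$k_ET > 0 && (rates$N_pool > 0 || rates$k_bind > 0)
  occ <- if (donor_present && rates$k_bind + rates$k_unbind > 0)
    rates$k_bind / (rates$k_bind + rates$k_unbind) else 0
  y[rc_state_index(st, "P", qa0, "QB", "c2")] <- occ * pool_fraction
  y[rc_state_index(st, "P", qa0, "QB", "c3")] <- occ * (1 - pool_fraction)
  y[rc_state_index(st, "P", qa0, "QB", "vac")] <- 1 - occ
  y
}
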