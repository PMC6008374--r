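#' Construct an instrument profile
#'
#' Models the differences seen when the same plate is acquired on different
#' cytometers: per-channel multiplicative gains, a spillover mixing matrix over
#' the fluorescence channels, and a hard saturation ceiling (ADC range). The
#' profile is applied to linear intensities after event generation.
#'
#' @param gains Named numeric vector of per-channel gains (> 0); channels
#'   absent from the vector keep gain 1.
#' @param spillover Square non-negative matrix with unit diagonal over (a
#'   subset of) the fluorescence channels `dye1`, `dye2`, `detect`,
#'   `detect2`; rows are normalized to sum to 1 before use. `NULL` means no
#'   spillover.
#' @param saturation_ceiling Maximum recordable intensity.
#' @param id Instrument identifier recorded into simulated wells.
#' @return An `ev_instrument` object.
#' @export
instrument_profile <- function(gains = c(), spillover = NULL,
                               saturation_ceiling = 262144, id = "sim") {
  if (length(gains) > 0 && any(gains <= 0)) {
    abort_validation("instrument gains must be > 0")
  }
  if (!is.null(spillover)) {
    if (!is.matrix(spillover) || nrow(spillover) != ncol(spillover) ||
        is.null(rownames(spillover)) ||
        !identical(rownames(spillover), colnames(spillover))) {
      abort_validation("spillover must be square with matching dimnames")
    }
    if (any(spillover < 0) || any(abs(diag(spillover) - 1) > 1e-12)) {
      abort_validation("spillover must be non-negative with unit diagonal")
    }
    spillover <- spillover / rowSums(spillover)  # row-stochastic
  }
  structure(list(gains = gains, spillover = spillover,
                 saturation_ceiling = saturation_ceiling, id = id),
            class = "ev_instrument")
}

#' The identity instrument: unit gains, no spillover
#' @param id Instrument identifier.
#' @return An [instrument_profile()] that leaves events unchanged (below the
#'   saturation ceiling).
#' @export
instrument_identity <- function(id = "sim") instrument_profile(id = id)

#' A pair of distinct, invertible instrument profiles
#'
#' Returns two profiles emulating the situation where the same assay plate is
#' read on two cytometers with different laser/filter configurations: the
#' first is the identity reference, the second has shifted per-channel gains
#' and a small dye/reporter spillover. Both are invertible (positive gains,
#' strictly diagonally dominant spillover), so neither destroys the bead map.
#'
#' @return List of two [instrument_profile()]s, named `a` and `b`.
#' @export
make_profile_pair <- function() {
  ch <- c("dye1", "dye2", "detect")
  sp <- diag(3)
  dimnames(sp) <- list(ch, ch)
  # residual post-compensation spillover; dye-into-dye only, since the
  # bead-ID dyes are orders of magnitude brighter than the reporter and
  # uncompensated dye-into-reporter leakage would swamp the EV signal
  sp["dye1", "dye2"] <- 0.01   # FITC into PE
  sp["dye2", "dye1"] <- 0.008
  sp["detect", "dye2"] <- 0.003
  list(
    a = instrument_identity(id = "inst-A"),
    b = instrument_profile(
      gains = c(scatter1 = 1.1, scatter2 = 0.9, dye1 = 1.3, dye2 = 0.8,
                detect = 1.6),
      spillover = sp, id = "inst-B")
  )
}

#' Apply an instrument profile to an event table
#'
#' Spillover mixes the fluorescence channels, then per-channel gains scale all
#' channels, then intensities clip at the saturation ceiling. Replaying the
#' same simulated well through two profiles emulates acquiring one physical
#' plate on two cytometers.
#'
#' @param table An [event_table()] of linear (untransformed) intensities.
#' @param profile An [instrument_profile()].
#' @return A new [event_table()] with the profile's `id` as instrument.
#' @export
apply_profile <- function(table, profile) {
  stopifnot(inherits(table, "ev_events"), inherits(profile, "ev_instrument"))
  if (isTRUE(table$transformed)) {
    abort_validation("instrument profiles apply to linear intensities only")
  }
  ev <- table$events
  sp <- profile$spillover
  if (!is.null(sp) && nrow(ev) > 0) {
    ch <- intersect(rownames(sp), names(ev))
    m <- as.matrix(ev[ch])
    # observed_j = sum_i true_i * S[i, j]; S rows index source channels
    ev[ch] <- m %*% sp[ch, ch, drop = FALSE]
  }
  for (ch in intersect(names(profile$gains), names(ev))) {
    ev[[ch]] <- ev[[ch]] * profile$gains[[ch]]
  }
  ev[] <- lapply(ev, function(x) pmin(x, profile$saturation_ceiling))
  event_table(ev, well_id = table$well_id, instrument_id = profile$id)
}
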