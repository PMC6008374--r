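#' Fit a saturating dose-response curve to one marker's titration
#'
#' Least-squares fit of the two-parameter Langmuir curve
#' `delta_mfi = P * D / (K + D)` over a log-spaced dose grid: `P` is the
#' plateau (corrected MFI at saturating EV input) and `K` the half-saturation
#' dose in particles. Parameters are constrained positive. A response that
#' never rises meaningfully above zero is classed `undetected` and returns no
#' fit. An optional Hill exponent can be freed for steeper-than-Langmuir
#' curves.
#'
#' @param doses Input particle doses (>= 3 distinct positive values).
#' @param dmfi Mean corrected MFI per dose (replicate-averaged).
#' @param hill If `TRUE`, also fit a Hill exponent `h` in
#'   `P * D^h / (K^h + D^h)`.
#' @return List of class `ev_dose_fit`: `plateau`, `half_saturation`,
#'   (`hill`), `detection_class`, `fitted`, `residual_sd`, `converged`.
#' @export
fit_dose_response <- function(doses, dmfi, hill = FALSE) {
  ok <- is.finite(doses) & is.finite(dmfi) & doses > 0
  doses <- doses[ok]; dmfi <- dmfi[ok]
  if (length(unique(doses)) < 3) {
    abort_insufficient("need >= 3 distinct positive doses to fit a dose-response curve")
  }
  if (max(dmfi) <= 0) {
    return(structure(list(plateau = NA_real_, half_saturation = NA_real_,
                          detection_class = "undetected", fitted = NULL,
                          residual_sd = NA_real_, converged = FALSE),
                     class = "ev_dose_fit"))
  }
  df <- data.frame(d = doses, y = dmfi)
  start <- list(P = max(dmfi), K = stats::median(doses))
  fml <- y ~ P * d / (K + d)
  lower <- c(P = 1e-12, K = 1e-12)
  if (hill) {
    fml <- y ~ P * d^h / (K^h + d^h)
    start$h <- 1
    lower <- c(lower, h = 0.1)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(plateau = NA_real_, half_saturation = NA_real_,
                          detection_class = "undetected", fitted = NULL,
                          residual_sd = NA_real_, converged = FALSE),
                     class = "ev_dose_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(plateau = unname(cf["P"]),
                 half_saturation = unname(cf["K"]),
                 hill = if (hill) unname(cf["h"]) else NULL,
                 detection_class = "robust",
                 fitted = stats::fitted(fit),
                 residual_sd = stats::sigma(fit),
                 converged = TRUE),
            class = "ev_dose_fit")
}

#' Blank-based limit of detection from a titration
#'
#' The LoD is the smallest input dose whose mean corrected MFI exceeds
#' `k * control_sd` (the classic k-sigma-of-blank rule; `control_sd` is the
#' SD of the corrected signal across replicate control wells). When the
#' threshold is crossed between two measured doses, the LoD is log-linearly
#' interpolated between them, since titrations span decades. A response
#' landing exactly on the threshold at a measured dose returns that dose;
#' a response never exceeding the threshold returns `Inf`.
#'
#' @param doses Input particle doses; unordered input is sorted, duplicate
#'   doses are averaged.
#' @param dmfi Mean corrected MFI per dose.
#' @param control_sd SD of corrected MFI over replicate blanks (>= 0).
#' @param k Threshold multiplier (> 0), default 3.
#' @return List: `lod` (dose, possibly `Inf`), `threshold`,
#'   `detection_class` (`robust` if crossed, else `undetected`).
#' @export
estimate_lod <- function(doses, dmfi, control_sd, k = 3) {
  stopifnot(control_sd >= 0, k > 0)
  ok <- is.finite(doses) & is.finite(dmfi)
  doses <- doses[ok]; dmfi <- dmfi[ok]
  o <- order(doses)
  doses <- doses[o]; dmfi <- dmfi[o]
  if (anyDuplicated(doses) > 0) {
    agg <- stats::aggregate(dmfi, by = list(dose = doses), FUN = mean)
    doses <- agg$dose; dmfi <- agg$x
  }
  thr <- k * control_sd
  above <- dmfi >= thr
  if (!any(above)) {
    return(list(lod = Inf, threshold = thr, detection_class = "undetected"))
  }
  i <- which(above)[1]
  lod <- if (dmfi[i] == thr || i == 1) {
    doses[i]
  } else {
    # log-linear interpolation between the bracketing doses
    ld <- log10(doses[i - 1]) +
      (thr - dmfi[i - 1]) / (dmfi[i] - dmfi[i - 1]) *
      (log10(doses[i]) - log10(doses[i - 1]))
    10^ld
  }
  list(lod = lod, threshold = thr, detection_class = "robust")
}

#' Dilution-consistency check for near-background markers
#'
#' A marker detected close to background is trusted only if its signal rises
#' consistently with input dose. The check passes when the Spearman rank
#' correlation of dose vs corrected MFI equals 1 (monotone increase, ties
#' tolerated) or when the slope of a linear fit on log10 dose is
#' significantly positive (one-sided t test on the fit). Markers failing the
#' check are classed `near-background` if their signal sits above the display
#' reference line (apparent but unvalidated) and `undetected` otherwise.
#'
#' @param doses >= 3 dilution doses.
#' @param dmfi Corrected MFI at each dilution.
#' @param reference_line Display reference intensity (see
#'   [annotate_positivity()]).
#' @param alpha One-sided significance level for the slope test.
#' @return List: `monotone_flag`, `detection_class`, `spearman`,
#'   `slope_p`.
#' @export
dilution_consistency <- function(doses, dmfi, reference_line = 1,
                                 alpha = 0.05) {
  if (length(doses) < 3 || length(dmfi) != length(doses)) {
    abort_insufficient("dilution consistency requires >= 3 dilutions")
  }
  rho <- suppressWarnings(
    stats::cor(doses, dmfi, method = "spearman"))
  slope_p <- NA_real_
  if (length(unique(doses)) >= 3 && stats::sd(dmfi) > 0) {
    fit <- stats::lm(dmfi ~ log10(doses))
    tt <- summary(fit)$coefficients
    if (nrow(tt) >= 2) {
      tval <- tt[2, "t value"]
      slope_p <- stats::pt(tval, df = fit$df.residual, lower.tail = FALSE)
    }
  }
  monotone <- isTRUE(rho == 1) ||
    (is.finite(slope_p) && slope_p < alpha && isTRUE(rho > 0))
  cls <- if (monotone) {
    "robust"
  } else if (mean(dmfi) > reference_line) {
    "near-background"
  } else {
    "undetected"
  }
  list(monotone_flag = monotone, detection_class = cls,
       spearman = rho, slope_p = slope_p)
}

#' Titration analysis for every marker of a panel
#'
#' Applies [fit_dose_response()], [estimate_lod()] and
#' [dilution_consistency()] across the markers of a replicate-averaged
#' titration, producing the per-marker dose-response summary.
#'
#' @param dmfi_by_dose Matrix or data frame of mean corrected MFI with one
#'   row per panel population (rownames = marker names) and one column per
#'   dose.
#' @param doses Dose per column.
#' @param control_sd SD of corrected MFI across replicate control wells; a
#'   scalar or per-marker vector.
#' @param k LoD threshold multiplier.
#' @param reference_line Display reference intensity.
#' @return Tibble of class `ev_titration`: per marker, `lod`, `plateau`,
#'   `half_saturation`, `monotone_flag`, `detection_class`.
#' @export
titration_analysis <- function(dmfi_by_dose, doses, control_sd, k = 3,
                               reference_line = 1) {
  m <- as.matrix(dmfi_by_dose)
  stopifnot(ncol(m) == length(doses))
  if (length(control_sd) == 1) control_sd <- rep(control_sd, nrow(m))
  rows <- lapply(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    fit <- tryCatch(fit_dose_response(doses, y),
                    evplex_insufficient_data_error = function(e) NULL)
    lod <- estimate_lod(doses, y, control_sd[i], k)
    dc <- tryCatch(dilution_consistency(doses, y, reference_line),
                   evplex_insufficient_data_error = function(e)
                     list(monotone_flag = NA, detection_class = NA_character_))
    cls <- if (lod$detection_class == "undetected") {
      "undetected"
    } else if (isTRUE(dc$monotone_flag)) {
      "robust"
    } else {
      "near-background"
    }
    lod_val <- lod$lod
    thr_val <- lod$threshold
    tibble::tibble(marker_name = rownames(m)[i],
                   lod = lod_val,
                   threshold = thr_val,
                   plateau = if (is.null(fit)) NA_real_ else fit$plateau,
                   half_saturation = if (is.null(fit)) NA_real_ else
                     fit$half_saturation,
                   monotone_flag = isTRUE(dc$monotone_flag),
                   detection_class = cls)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ev_titration", class(out))
  out
}

#' Recommended assay input window from a titration analysis
#'
#' The usable input window runs from the largest LoD among detected markers
#' (below it, some detected markers fall under their blank threshold) up to
#' the dose at which the flattest detected marker reaches 90% of its fitted
#' plateau (beyond it, more input adds little signal and bead saturation
#' compresses differences). For the Langmuir curve the 90% point is `9 * K`.
#'
#' @param titration An `ev_titration` from [titration_analysis()].
#' @return List: `window` (length-2 numeric, or `NULL` when nothing is
#'   detected), `caveat` (a reminder that unknown samples should still be
#'   titrated), `n_detected`.
#' @export
recommend_input <- function(titration) {
  det <- titration[titration$detection_class != "undetected" &
                     is.finite(titration$lod), , drop = FALSE]
  caveat <- paste("EV yield and surface composition differ between sources;",
                  "titrate unknown samples or run them at several dilutions",
                  "whenever possible.")
  if (nrow(det) == 0) {
    warning("no detected markers; cannot recommend an input window")
    return(list(window = NULL, caveat = caveat, n_detected = 0L))
  }
  lower <- max(det$lod)
  fitted_rows <- det[is.finite(det$plateau) & is.finite(det$half_saturation), ,
                     drop = FALSE]
  upper <- if (nrow(fitted_rows) > 0) {
    # 90%-of-plateau dose of the flattest (smallest-plateau) detected marker
    9 * fitted_rows$half_saturation[which.min(fitted_rows$plateau)]
  } else NA_real_
  list(window = c(lower = lower, upper = upper), caveat = caveat,
       n_detected = nrow(det))
}
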