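#' Demultiplexing parameters
#'
#' @param transform Scale transform applied to the dye (bead-ID) channels
#'   before assignment: `"asinh"` (x -> asinh(x / cofactor)) or
#'   `"log10-shift"` (x -> log10(x + cofactor)).
#' @param cofactor Transform cofactor `c` (> 0); 150 is a conventional asinh
#'   cofactor for conventional-cytometer fluorescence.
#' @param tau Assignment threshold: maximum Mahalanobis distance to the
#'   nearest centroid; events farther than `tau` from every centroid stay
#'   unassigned.
#' @param min_events Minimum singlet events per population below which the
#'   population is QC-flagged (its MFI is considered unreliable).
#' @param singlet_gate Axis-aligned ellipse in raw scatter space retaining
#'   single beads: list with `center` (length 2) and `radius` (length 2).
#'   The default matches a 4-micron bead singlet cloud with doublets at about
#'   twice the scatter.
#' @return An `ev_demux_params` list.
#' @export
demux_params <- function(transform = c("asinh", "log10-shift"),
                         cofactor = 150, tau = 4, min_events = 30,
                         singlet_gate = list(center = c(50000, 30000),
                                             radius = c(12000, 10000))) {
  transform <- match.arg(transform)
  stopifnot(cofactor > 0, tau > 0, min_events >= 0,
            length(singlet_gate$center) == 2, length(singlet_gate$radius) == 2,
            all(singlet_gate$radius > 0))
  structure(list(transform = transform, cofactor = cofactor, tau = tau,
                 min_events = min_events, singlet_gate = singlet_gate),
            class = "ev_demux_params")
}

apply_dye_transform <- function(x, params) {
  switch(params$transform,
         "asinh" = asinh(x / params$cofactor),
         "log10-shift" = log10(x + params$cofactor))
}

invert_dye_transform <- function(y, params) {
  switch(params$transform,
         "asinh" = params$cofactor * sinh(y),
         "log10-shift" = 10^y - params$cofactor)
}

#' Transform the dye channels of an event table
#'
#' Replaces the two bead-ID dye channels by their transformed values
#' (monotone and invertible), leaving scatter and reporter channels linear.
#' Population assignment operates on this scale, where the hard-dyed bead
#' clusters are approximately Gaussian.
#'
#' @param table An [event_table()] with linear intensities.
#' @param params A [demux_params()].
#' @return The event table with transformed dye channels (marked as such).
#' @export
transform_events <- function(table, params = demux_params()) {
  stopifnot(inherits(table, "ev_events"))
  if (isTRUE(table$transformed)) return(table)
  table$events$dye1 <- apply_dye_transform(table$events$dye1, params)
  table$events$dye2 <- apply_dye_transform(table$events$dye2, params)
  table$transformed <- TRUE
  table
}

#' Gate single-bead events in scatter space
#'
#' Retains events inside the axis-aligned scatter ellipse of
#' `params$singlet_gate`; coincident-bead (doublet) events, whose scatter is
#' roughly the sum of two singlets', fall far outside it and are excluded.
#'
#' @param table An [event_table()].
#' @param params A [demux_params()].
#' @return List with `events` (the retained singlets), `excluded` (count) and
#'   `keep`, the logical retention mask in original event order.
#' @export
gate_singlets <- function(table, params = demux_params()) {
  stopifnot(inherits(table, "ev_events"))
  g <- params$singlet_gate
  d2 <- ((table$events$scatter1 - g$center[1]) / g$radius[1])^2 +
    ((table$events$scatter2 - g$center[2]) / g$radius[2])^2
  keep <- d2 <= 1
  kept <- table
  kept$events <- table$events[keep, , drop = FALSE]
  kept$n_events <- sum(keep)
  list(events = kept, excluded = sum(!keep), keep = keep)
}

#' Assign singlet events to capture-bead populations
#'
#' The demultiplexer proper: each transformed event is assigned to the panel
#' population whose centroid is nearest in Mahalanobis distance (computed
#' under that population's own dispersion), or left unassigned when the
#' nearest centroid is farther than `params$tau`. Ties break deterministically
#' to the lowest population id. An optional Gaussian-mixture refinement mode
#' re-estimates the component means/covariances by a panel-initialized EM
#' before the final assignment, which absorbs modest instrument drift of the
#' bead map (see Details of [demux_params()] for the reference-panel default).
#'
#' @param table A transformed [event_table()] (see [transform_events()]);
#'   passing an untransformed table is an error.
#' @param panel An [ev_panel()].
#' @param params A [demux_params()].
#' @param refine `"none"` (reference-panel assignment) or `"gmm"`.
#' @return An `ev_demux` result: `assignment` (per-event population id, or
#'   `NA` for unassigned), `counts` (per-population events), `unassigned`
#'   count, `unassigned_fraction`, and `qc` (from [qc_counts()], initially
#'   unflagged).
#' @export
assign_populations <- function(table, panel, params = demux_params(),
                               refine = c("none", "gmm")) {
  refine <- match.arg(refine)
  stopifnot(inherits(table, "ev_events"), inherits(panel, "ev_panel"))
  if (!isTRUE(table$transformed)) {
    abort_validation("events must be transformed before assignment (see transform_events)")
  }
  if (nrow(panel) == 0) abort_validation("empty panel")

  x <- cbind(table$events$dye1, table$events$dye2)
  n <- nrow(x)
  centroids <- cbind(panel$centroid_dye1, panel$centroid_dye2)
  covs <- lapply(seq_len(nrow(panel)), function(i) {
    matrix(c(panel$disp11[i], panel$disp12[i],
             panel$disp12[i], panel$disp22[i]), 2, 2)
  })

  if (refine == "gmm" && n >= 10 * nrow(panel)) {
    fit <- refine_gmm(x, centroids, covs)
    centroids <- fit$centroids
    covs <- fit$covs
  }

  d2 <- matrix(Inf, n, nrow(panel))
  for (i in seq_len(nrow(panel))) {
    si <- solve(covs[[i]])
    dx <- x[, 1] - centroids[i, 1]
    dy <- x[, 2] - centroids[i, 2]
    d2[, i] <- si[1, 1] * dx^2 + 2 * si[1, 2] * dx * dy + si[2, 2] * dy^2
  }
  nearest <- max.col(-d2, ties.method = "first")  # first = lowest id (sorted)
  mind2 <- d2[cbind(seq_len(n), nearest)]
  assignment <- panel$id[nearest]
  assignment[mind2 > params$tau^2] <- NA_integer_

  counts <- stats::setNames(
    vapply(panel$id, function(id) sum(assignment == id, na.rm = TRUE),
           integer(1)),
    panel$marker_name)
  structure(list(assignment = assignment,
                 counts = counts,
                 unassigned = sum(is.na(assignment)),
                 unassigned_fraction = if (n > 0) mean(is.na(assignment)) else 0,
                 doublets_excluded = 0L,
                 panel_ids = panel$id,
                 qc = stats::setNames(rep(FALSE, nrow(panel)),
                                      panel$marker_name)),
            class = "ev_demux")
}

# Panel-initialized Gaussian-mixture EM over the two dye channels. Component
# means/covariances start at the panel's centroids/dispersions and are
# re-estimated from the data, absorbing instrument drift of the bead map.
# Covariances are shrunk toward the panel dispersion, which keeps all 39
# components well-conditioned even when a population catches few events.
refine_gmm <- function(x, centroids, covs, max_iter = 25, tol = 1e-6,
                       shrink = 0.2) {
  k <- nrow(centroids)
  n <- nrow(x)
  mu <- centroids
  sig <- covs
  w <- rep(1 / k, k)
  log_resp <- function() {
    ld <- vapply(seq_len(k), function(i) {
      si <- solve(sig[[i]])
      dx <- x[, 1] - mu[i, 1]; dy <- x[, 2] - mu[i, 2]
      q <- si[1, 1] * dx^2 + 2 * si[1, 2] * dx * dy + si[2, 2] * dy^2
      -q / 2 - log(2 * pi) - log(det(sig[[i]])) / 2 + log(w[i])
    }, numeric(n))
    ld - apply(ld, 1, max)   # stable softmax in log space
  }
  for (iter in seq_len(max_iter)) {
    z <- exp(log_resp())
    z <- z / rowSums(z)
    nk <- colSums(z)
    mu_new <- cbind(colSums(z * x[, 1]), colSums(z * x[, 2])) / nk
    for (i in seq_len(k)) {
      if (nk[i] < 3) next   # too few events: keep the panel model
      dx <- x[, 1] - mu_new[i, 1]; dy <- x[, 2] - mu_new[i, 2]
      s11 <- sum(z[, i] * dx * dx) / nk[i]
      s12 <- sum(z[, i] * dx * dy) / nk[i]
      s22 <- sum(z[, i] * dy * dy) / nk[i]
      sig[[i]] <- (1 - shrink) * matrix(c(s11, s12, s12, s22), 2, 2) +
        shrink * covs[[i]]
    }
    w <- pmax(nk, 1e-6) / sum(pmax(nk, 1e-6))
    shift <- max(abs(mu_new[nk >= 3, , drop = FALSE] -
                       mu[nk >= 3, , drop = FALSE]))
    mu[nk >= 3, ] <- mu_new[nk >= 3, ]
    if (shift < tol) break
  }
  list(centroids = mu, covs = sig)
}

#' Flag populations with too few singlet events
#'
#' Populations whose assigned singlet count falls below
#' `params$min_events` get a QC flag; flagged populations carry no positivity
#' annotation downstream because a median over very few beads is unstable.
#'
#' @param result An `ev_demux` result from [assign_populations()].
#' @param params A [demux_params()].
#' @return The result with its `qc` flags set.
#' @export
qc_counts <- function(result, params = demux_params()) {
  stopifnot(inherits(result, "ev_demux"))
  result$qc <- result$counts < params$min_events
  result
}

#' Full per-well demultiplexing pipeline
#'
#' Convenience wrapper: transform dye channels, gate singlets, assign the
#' retained events to populations, and QC the counts. The returned assignment
#' covers all original events: `"doublet-excluded"` events carry the label
#' `-1`, unassigned singlets `NA`.
#'
#' @inheritParams assign_populations
#' @return An `ev_demux` result over all events of the well.
#' @export
demux_well <- function(table, panel, params = demux_params(),
                       refine = c("none", "gmm")) {
  gated <- gate_singlets(table, params)
  transformed <- transform_events(gated$events, params)
  res <- assign_populations(transformed, panel, params, refine = refine)

  full <- rep(-1L, table$n_events)
  full[gated$keep] <- res$assignment
  res$assignment <- full
  res$doublets_excluded <- gated$excluded
  qc_counts(res, params)
}
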