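#' Per-population median fluorescence intensity
#'
#' The assay's primary per-well summary: the median of the reporter channel
#' over the singlet events assigned to each capture-bead population. The
#' median (not the mean) is the field's convention for bead MFIs because it
#' is robust to the long right tail of fluorescence distributions.
#' Populations with zero assigned events get `NA` and keep their QC flag;
#' missing values propagate downstream, never imputed.
#'
#' @param table The [event_table()] the demux result was computed on.
#' @param demux The matching `ev_demux` result (from [demux_well()] or
#'   [assign_populations()]).
#' @param channel Reporter channel role to summarize (default `"detect"`).
#' @return Tibble with one row per panel population: `pop_id`, `marker_name`,
#'   `n_events`, `mfi`, `qc_flag`.
#' @export
population_mfi <- function(table, demux, channel = "detect") {
  stopifnot(inherits(table, "ev_events"), inherits(demux, "ev_demux"))
  if (!channel %in% names(table$events)) {
    abort_validation(paste0("unknown reporter channel: ", channel))
  }
  if (length(demux$assignment) != table$n_events) {
    abort_validation("demux result does not match event table (event counts differ)")
  }
  vals <- table$events[[channel]]
  mfi <- vapply(demux$panel_ids, function(id) {
    v <- vals[!is.na(demux$assignment) & demux$assignment == id]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))
  tibble::tibble(pop_id = demux$panel_ids,
                 marker_name = names(demux$counts),
                 n_events = as.integer(demux$counts),
                 mfi = mfi,
                 qc_flag = unname(demux$qc) | is.na(mfi))
}

check_same_panel <- function(sample, control) {
  if (!identical(sample$pop_id, control$pop_id) ||
      !identical(sample$marker_name, control$marker_name)) {
    abort_validation("sample and control MFI tables cover different panels")
  }
}

#' Background-correct a sample well against its matched control
#'
#' Computes the EV surface signature: per population, the sample-well median
#' reporter intensity minus the matched buffer/medium control well's, i.e.
#' `delta_mfi = mfi_sample - mfi_control`. The control well contains capture
#' beads and detection antibodies but no EVs, so the subtraction removes
#' nonspecific antibody binding and instrument background. Negative values
#' are preserved — they are informative noise, not errors.
#'
#' @param sample,control Per-population MFI tibbles from [population_mfi()],
#'   computed on the sample and matched control wells over the same panel.
#' @param panel Optional [ev_panel()] used to attach each population's role.
#' @return A signature tibble (`ev_signature`): `pop_id`, `marker_name`,
#'   `role` (if panel given), `n_events`, `mfi_sample`, `mfi_control`,
#'   `delta_mfi`, `qc_flag`.
#' @export
background_correct <- function(sample, control, panel = NULL) {
  check_same_panel(sample, control)
  out <- tibble::tibble(
    pop_id = sample$pop_id,
    marker_name = sample$marker_name,
    n_events = sample$n_events,
    mfi_sample = sample$mfi,
    mfi_control = control$mfi,
    delta_mfi = sample$mfi - control$mfi,
    qc_flag = sample$qc_flag | control$qc_flag
  )
  if (!is.null(panel)) {
    out <- dplyr::left_join(out,
                            tibble::tibble(pop_id = panel$id, role = panel$role),
                            by = "pop_id")
    out <- dplyr::relocate(out, "role", .after = "marker_name")
  }
  class(out) <- c("ev_signature", class(out))
  out
}

#' Annotate signature rows against a display reference line
#'
#' Labels each population's corrected MFI as `"above"`, `"at"` or `"below"` a
#' reference intensity (default 1 reporter unit, the dotted line drawn on the
#' assay's plots for cross-plot comparability). The label is a display aid
#' only — the output metadata records it as "reference line, not an objective
#' threshold" — because no single MFI cutoff defines marker positivity.
#' QC-flagged rows carry no annotation.
#'
#' @param table An `ev_signature` from [background_correct()].
#' @param reference_line Reference intensity (> 0).
#' @return The signature with a `positivity` column and a
#'   `reference_line_note` attribute.
#' @export
annotate_positivity <- function(table, reference_line = 1) {
  stopifnot(inherits(table, "ev_signature"), reference_line > 0)
  pos <- dplyr::case_when(
    table$qc_flag ~ NA_character_,
    is.na(table$delta_mfi) ~ NA_character_,
    table$delta_mfi > reference_line ~ "above",
    table$delta_mfi == reference_line ~ "at",
    TRUE ~ "below"
  )
  table$positivity <- pos
  attr(table, "reference_line") <- reference_line
  attr(table, "reference_line_note") <-
    "reference line, not an objective threshold"
  table
}

#' Replicate statistics over signature tables
#'
#' Mean, sample SD (n - 1 denominator, appropriate for the small replicate
#' counts typical of this assay) and CV% of `delta_mfi` per population over
#' replicate wells. The CV is reported only where the mean is nonzero and at
#' least two replicates contributed.
#'
#' @param tables List of >= 2 `ev_signature` tables on the same panel.
#' @return Tibble: `pop_id`, `marker_name`, `n_replicates`, `mean_delta_mfi`,
#'   `sd_delta_mfi`, `cv_pct`.
#' @export
replicate_stats <- function(tables) {
  if (length(tables) < 2) abort_validation("need >= 2 replicate signature tables")
  ref <- tables[[1]]
  for (t in tables[-1]) check_same_panel(ref, t)
  m <- matrix(vapply(tables, function(t) t$delta_mfi, numeric(nrow(ref))),
              nrow = nrow(ref))
  mean_d <- rowMeans(m)
  sd_d <- apply(m, 1, stats::sd)
  cv <- ifelse(mean_d != 0, 100 * sd_d / abs(mean_d), NA_real_)
  tibble::tibble(pop_id = ref$pop_id, marker_name = ref$marker_name,
                 n_replicates = length(tables),
                 mean_delta_mfi = mean_d, sd_delta_mfi = sd_d, cv_pct = cv)
}

#' One-call signature for a sample/control well pair
#'
#' Runs the standard per-measurement pipeline — demultiplex both wells,
#' median reporter per population, background correction, positivity
#' annotation — and returns the signature table.
#'
#' @param sample_table,control_table [event_table()]s for the sample well and
#'   its matched control.
#' @param panel An [ev_panel()].
#' @param params A [demux_params()].
#' @param reference_line Display reference intensity for
#'   [annotate_positivity()].
#' @return An annotated `ev_signature`.
#' @export
well_signature <- function(sample_table, control_table, panel,
                           params = demux_params(), reference_line = 1) {
  dx_s <- demux_well(sample_table, panel, params)
  dx_c <- demux_well(control_table, panel, params)
  sig <- background_correct(population_mfi(sample_table, dx_s),
                            population_mfi(control_table, dx_c),
                            panel = panel)
  annotate_positivity(sig, reference_line)
}
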