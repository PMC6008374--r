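# Shared fixtures, built in code.

# A small panel for fast simulations: two capture markers + the two isotype
# controls, centroids well separated on the default transformed grid.
mini_panel <- function(markers = c("CD9", "CD24"), dispersion_sd = 0.12) {
  full <- default_panel(dispersion_sd)
  keep <- full[full$marker_name %in%
                 c(markers, "mIgG1 isotype", "REA isotype"), , drop = FALSE]
  ev_panel(keep, version_tag = "mini")
}

# Config matching the mini panel: single-antibody detection so the detection
# mix exists in the panel.
mini_config <- function(seed = 1L, ...) {
  ab <- hek_abundance_profile()
  sim_config(abundance = ab, detection_mix = "CD9", seed = seed, ...)
}

sample_ann <- function(dose, well_id = "S1", instrument_id = "sim") {
  well_annotations(well_id, "sample", input_dose = dose,
                   instrument_id = instrument_id, matched_control_id = "C1")
}

control_ann <- function(well_id = "C1", instrument_id = "sim") {
  well_annotations(well_id, "control", instrument_id = instrument_id)
}

# Manually assembled per-population MFI table (population_mfi shape), for
# arithmetic-level tests of background correction and log ratios.
make_mfi <- function(markers, values, n_events = 100L, qc = FALSE) {
  tibble::tibble(pop_id = seq_along(markers), marker_name = markers,
                 n_events = as.integer(n_events), mfi = values,
                 qc_flag = rep_len(qc, length(markers)))
}

# ev_demux object over an explicit assignment vector, for median-level tests.
make_demux <- function(assignment, panel_ids, marker_names) {
  counts <- stats::setNames(
    vapply(panel_ids, function(id) sum(assignment == id, na.rm = TRUE),
           integer(1)), marker_names)
  structure(list(assignment = assignment, counts = counts,
                 unassigned = sum(is.na(assignment)),
                 unassigned_fraction = mean(is.na(assignment)),
                 doublets_excluded = 0L, panel_ids = panel_ids,
                 qc = stats::setNames(rep(FALSE, length(panel_ids)),
                                      marker_names)),
            class = "ev_demux")
}

# Events table with given reporter values all at one population's centroid
# (linear dye space), inside the singlet gate.
events_at_centroid <- function(panel, pop_row, detect, cofactor = 150) {
  n <- length(detect)
  event_table(tibble::tibble(
    scatter1 = rep(50000, n), scatter2 = rep(30000, n),
    dye1 = cofactor * sinh(panel$centroid_dye1[pop_row]),
    dye2 = cofactor * sinh(panel$centroid_dye2[pop_row]),
    detect = detect))
}

# Mean corrected MFI per dose for one marker, through the standard pipeline
# (demux + median + background correction), averaged over replicates.
titration_curve <- function(wells, panel, marker,
                            params = demux_params()) {
  sigs <- lapply(Filter(function(w) w$ann$kind == "sample", wells), function(w) {
    ctrl <- wells[[w$ann$matched_control_id]]
    sig <- well_signature(w$events, ctrl$events, panel, params)
    tibble::tibble(dose = w$ann$input_dose,
                   delta_mfi = sig$delta_mfi[sig$marker_name == marker])
  })
  df <- dplyr::bind_rows(sigs)
  agg <- stats::aggregate(df$delta_mfi, by = list(dose = df$dose), FUN = mean)
  list(doses = agg$dose, dmfi = agg$x)
}

# Blank threshold ingredient: per-population variance of the control-well MFI
# across replicate control wells, pooled over the panel (all populations share
# the background model), scaled by sqrt(2) because a corrected signal
# subtracts an independently measured control.
control_sd_from_wells <- function(wells, panel, params = demux_params()) {
  ctrls <- Filter(function(w) w$ann$kind == "control", wells)
  mfis <- vapply(ctrls, function(w) {
    dx <- demux_well(w$events, panel, params)
    population_mfi(w$events, dx)$mfi
  }, numeric(nrow(panel)))
  sqrt(mean(apply(mfis, 1, stats::var))) * sqrt(2)
}
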