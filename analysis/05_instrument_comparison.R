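#!/usr/bin/env Rscript
# Cross-instrument comparison: replay the same simulated sample/control wells
# through two instrument profiles (different gains, residual spillover,
# saturation), demultiplex each acquisition with per-instrument bead-map
# refinement, and compare log10 sample/control ratio signatures.
# Writes results/instrument_concordance.csv and results/logratio_heatmap.csv.

suppressPackageStartupMessages(library(evplex))

panel <- read_panel(system.file("extdata", "panel_synthetic_grid.yaml",
                                package = "evplex"))
cfg <- sim_config(seed = 20260103L)
w <- simulate_well(panel, cfg,
                   well_annotations("S1", "sample", input_dose = 2e8,
                                    matched_control_id = "C1")[1, ])
cfg_c <- cfg; cfg_c$seed <- cfg$seed + 1L
wc <- simulate_well(panel, cfg_c, well_annotations("C1", "control")[1, ])

pair <- make_profile_pair()
lr_for <- function(profile) {
  ws <- apply_profile(w$events, profile)
  wcs <- apply_profile(wc$events, profile)
  log_ratio(population_mfi(ws, demux_well(ws, panel, refine = "gmm")),
            population_mfi(wcs, demux_well(wcs, panel, refine = "gmm")),
            panel = panel, sample_id = "HEK293T-CM",
            instrument_id = profile$id)
}
lr_a <- lr_for(pair$a)
lr_b <- lr_for(pair$b)

conc <- compare_runs(lr_a, lr_b)
print(conc)
utils::write.csv(conc$per_marker, "results/instrument_concordance.csv",
                 row.names = FALSE)

hm <- heatmap_export(list(`inst-A` = lr_a, `inst-B` = lr_b),
                     "results/logratio_heatmap.csv")
message(sprintf("Spearman rho = %.3f over %d markers; heatmap matrix %dx%d",
                conc$spearman, conc$n_markers, nrow(hm), ncol(hm)))
message("rank concordance >= 0.9 indicates the same markers stand out on ",
        "both instruments despite different axis scaling")
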