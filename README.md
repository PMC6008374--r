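# evplex

Analysis of multiplex bead-based flow-cytometry assays for extracellular
vesicle (EV) surface signatures.

These assays capture EVs from a sample on 39 hard-dyed, antibody-coated bead
populations (37 candidate surface antigens + 2 isotype controls), each
identified by its position in two dye channels (FITC × PE), and read the
bead-bound EVs out through APC-labelled detection antibodies (typically a
pan-tetraspanin anti-CD9/CD63/CD81 mix). `evplex` is for researchers running
such assays who want a scripted, reproducible pipeline instead of manual
gating: it demultiplexes events to bead populations, computes
background-corrected median-fluorescence signatures, compares runs across
instruments, and estimates per-marker detection limits from titrations.

## What it computes

* **Demultiplexing** — singlet gating in scatter space, asinh transform of
  the dye channels, and assignment of each event to the nearest panel
  centroid by Mahalanobis distance $d_p(x) = \sqrt{(x-\mu_p)^\top
  \Sigma_p^{-1} (x-\mu_p)}$, unassigned beyond a threshold τ (default 4).
  An optional panel-initialized Gaussian-mixture refinement absorbs
  instrument drift of the bead map.
* **Signatures** — per-population median reporter intensity (MFI), corrected
  against the matched buffer/medium control well:
  ΔMFI\_p = MFI\_sample,p − MFI\_control,p (negatives kept).
* **Cross-instrument comparison** — R\_p = log10(MFI\_sample,p /
  MFI\_control,p) on raw medians (gain cancels in the ratio), with Spearman
  rank concordance between runs.
* **Titration analysis** — Langmuir fits ΔMFI = P·D/(K+D), blank-based
  limits of detection (smallest dose with ΔMFI > k·SD\_blank, k = 3,
  log-interpolated), a dilution-consistency check for near-background
  markers, and a recommended assay input window.
* **Simulation** — a seeded generative model of the assay (bead clusters,
  Langmuir capture, log-normal noise, doublets, instrument profiles) used
  by the tests and the analysis scripts; see the methods vignette
  (`vignettes/evplex-methods.Rmd`).

I/O: FCS 3.1 (list mode, float) and a plain-text CSV event dialect; panels
and well annotations in YAML; all result tables as CSV.

## Worked example

Simulate a HEK293T-like sample well and its matched medium control, then
compute the surface signature:

```r
library(evplex)

panel <- read_panel(system.file("extdata", "panel_synthetic_grid.yaml",
                                package = "evplex"))
cfg  <- sim_config(seed = 1)
well <- simulate_well(panel, cfg,
          well_annotations("S1", "sample", input_dose = 1e8,
                           matched_control_id = "C1")[1, ])
cfg$seed <- 2
ctrl <- simulate_well(panel, cfg, well_annotations("C1", "control")[1, ])

sig <- well_signature(well$events, ctrl$events, panel)
head(dplyr::arrange(sig, dplyr::desc(delta_mfi)), 5)
#>   pop_id marker_name n_events mfi_sample mfi_control delta_mfi positivity
#> 1     23        CD63      267      51.38      1.0862     50.30      above
#> 2      6         CD9      258      51.19      0.9745     50.22      above
#> 3     25        CD81      240      51.15      1.3121     49.83      above
#> 4     13        CD29      249      43.40      1.1395     42.26      above
#> 5     20       CD49e      251      18.65      1.2489     17.40      above
```

The four strongest corrected signals are the tetraspanins CD9/CD63/CD81 and
the integrin CD29 (the canonical strongly-positive set for HEK293T-derived
EVs), with CD49e intermediate — ~50, ~42 and ~17 reporter units here. The
`positivity` column annotates rows against a display reference line at 1
unit (a plotting aid, explicitly not an objective positivity threshold);
isotype-control rows sit at ΔMFI ≈ 0.

The `analysis/` directory holds the full narrative workflow as numbered
scripts, each writing its tables under `results/`:

```sh
Rscript analysis/01_simulate_wells.R        # triplicate sample + control wells (FCS + CSV)
Rscript analysis/02_demux_qc.R              # per-population counts and QC flags
Rscript analysis/03_signatures.R            # signatures + replicate statistics
Rscript analysis/04_titration_lod.R         # dose-response fits, LoDs, input window
Rscript analysis/05_instrument_comparison.R # two-instrument log-ratio concordance
```

For example, `04_titration_lod.R` prints per-marker LoDs (abundant
tetraspanins become detectable at roughly tenfold lower input than the
low-abundance tier) and `05_instrument_comparison.R` reports the Spearman
rank concordance of log-ratio signatures across two simulated instrument
profiles (≈ 0.96 with per-instrument bead-map refinement).

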