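---
title: "Methods: multiplex bead-based EV surface signatures with evplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplex bead-based EV surface signatures with evplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and what this package computes

Multiplex bead-based EV assays capture extracellular vesicles (EVs) on a mix
of 39 hard-dyed antibody-coated bead populations — 37 against candidate EV
surface antigens plus two isotype-control populations that estimate
nonspecific binding. Each bead population is identified by its position in
two dye channels (FITC x PE on a conventional cytometer); bead-captured EVs
are then counterstained with APC-labelled detection antibodies, typically a
pan-tetraspanin anti-CD9/CD63/CD81 cocktail. Because each 4 µm bead carries
many EVs, the per-bead reporter signal is a bulk, semi-quantitative readout
of how abundant each antigen is on the EVs of a sample.

`evplex` implements the analysis chain for this assay:

1. **Demultiplexing** (`demux_well()`): singlet gating in scatter space,
   asinh transform of the dye channels, and nearest-centroid assignment of
   every event to a bead population by Mahalanobis distance against a panel
   definition, with an optional mixture-refinement mode.
2. **Signatures** (`well_signature()`): per-population median reporter
   intensity (MFI), background-corrected by subtracting the matched
   buffer/medium control well, with replicate statistics and a display
   reference line.
3. **Cross-instrument comparison** (`log_ratio()`, `compare_runs()`):
   log10 sample/control ratios, which cancel instrument gain, summarized by
   Spearman rank concordance.
4. **Titrations** (`fit_dose_response()`, `estimate_lod()`,
   `dilution_consistency()`, `recommend_input()`): Langmuir dose-response
   fits, blank-based limits of detection, and an input-window
   recommendation.
5. **Simulation** (`simulate_well()`, `simulate_titration()`): a seeded
   generative model of the whole assay, so that every stage above is
   testable end to end without cytometer data.

## The generative model

The simulator is not a fixture but the package's statement of the data it
assumes. For a well with input dose $D$ (particles, from nanoparticle
tracking analysis) and a bead population whose capture marker $m$ has
epitope abundance $A_m$ (mean detectable epitopes per captured EV), the
expected number of EVs bound per bead follows a Langmuir saturation law

$$ n_m \;=\; f_{\mathrm{inc}} \, N_{\max} \,
   \frac{D_m}{K + D_m}, \qquad D_m = D \cdot A_m / \max_m A_m , $$

where $N_{\max}$ is the bead's capture capacity, $K$ the half-saturation
dose, and $f_{\mathrm{inc}} \in (0,1]$ the fraction of equilibrium capture
reached (1 for overnight incubation; shortened protocols reach less, which
is why 1 h capture reads dimmer than overnight). Scaling the effective dose
by relative abundance encodes that a marker carried by fewer EVs captures
proportionally fewer; $A_m = 0$ and isotype controls capture nothing. The
expected reporter signal above background is

$$ s_m \;=\; \beta \, n_m \sum_{d \in \text{detection mix}} A_d , $$

with $\beta$ the reporter brightness per bound detection epitope. Per-bead
reporter values are a log-normal background (mean $b$, SD $\sigma_b$) plus
$s_m$ under mean-preserving multiplicative log-normal noise of log-scale SD
$\sigma$. Dye coordinates are bivariate normal around each population's
centroid in asinh space and mapped back to linear intensities; doublets are
sums of two random singlets' channel values; instrument profiles apply
spillover, per-channel gain and a saturation ceiling to the linear
intensities.

Two consequences used as oracles throughout the tests: at $D = K$ (for the
most abundant marker, $\sigma \to 0$) the mean reporter is exactly
$b + \beta (N_{\max}/2) \sum_d A_d$, and halving $f_{\mathrm{inc}}$ halves
the expected corrected signal exactly.

### Default parameters

| parameter | default | units | why |
|---|---|---|---|
| `half_saturation` K | 5e8 | particles | puts the onset of detectability between 5e5 and 5e6 particles for the brightest markers and saturation near 5e9, matching the dynamic range a 5e5–5e8 titration explores |
| `capture_capacity` Nmax | 100 | EVs/bead | order of magnitude for a 4 µm bead binding ~100 nm vesicles |
| `brightness` β | 0.02 | units/epitope | with the pan-tetraspanin detection sum (150 epitopes) gives a ~300-unit plateau, i.e. bright-marker corrected MFIs of tens of units at 1e8 input |
| `background_mean` / `background_sd` | 2 / 3 | units | skewed per-bead background whose median sits near 1 unit, so the customary reference line at 1 is meaningful |
| `noise_sigma` σ | 0.15 | log units | typical per-bead multiplicative spread |
| `doublet_rate` | 0.02 | — | few-percent coincidence at plate-reader flow rates |
| `events_per_population` | 250 | events | 39 x 250 ≈ 10k singlets/well, the 7k–12k range a plate run records |
| abundances | CD9/CD63/CD81 = 50, CD29 = 40, CD49e = 15, CD41b/CD24/CD146/MCSP = 4, others 0 | epitopes/EV | ordinal HEK293T-like pattern (tetraspanins and CD29 strong, CD49e intermediate, a low tier, the rest absent); absolute values are invented model parameters |

The packaged panel (`inst/extdata/panel_synthetic_grid.yaml`) is
**synthetic**: the commercial kit's dye-space map is proprietary, so
centroids sit on a 6x7 grid (minus three vacancies) in asinh space with
spacing 0.8 against a within-population SD of 0.12 (≈ 6.7 SD). This
preserves the structure of the demultiplexing problem — many well-separated
clusters with touching tails — without the vendor's coordinates.

## Demultiplexing choices

* **Reference-panel assignment, not clustering.** The assay is gated against
  a known bead map, so the default assigns each event to the nearest
  centroid under that population's own dispersion (Mahalanobis), unassigned
  beyond `tau = 4`. Ties break to the lowest population id, which makes
  assignment deterministic. Defaults `cofactor = 150` (asinh), `tau = 4`,
  `min_events = 30` are conventional for cytometry and all exposed in
  `demux_params()`.
* **Mixture refinement for drift.** `refine = "gmm"` runs a panel-initialized
  EM over the two dye channels, re-estimating component means and
  covariances before the final assignment. Covariances are shrunk 20% toward
  the panel dispersion and components catching fewer than 3 events keep the
  panel model, which keeps all 39 components well-conditioned. The E-step is
  computed in log space with a row-max shift so that responsibilities stay
  proper even when the observed map is far from the nominal panel. This mode
  is the automated analogue of re-gating the bead map on each instrument,
  and it is the mode the cross-instrument pipeline uses: with plain
  reference-panel assignment, a gain-shifted bead map flips enough boundary
  events to jitter the medians of null markers, whose log-ratios are
  otherwise exact ties — rank concordance then collapses for reasons that
  have nothing to do with the markers that matter.
* **Singlet gate.** An axis-aligned ellipse in raw scatter at 4 scatter-SDs
  around the singlet cloud. Doublets, being sums of two singlets, sit near
  twice the scatter and fall far outside; the false-exclusion rate of true
  singlets is under 1% by construction ($\chi^2_2 > 16$).

## Signature and comparison choices

* **Median, not mean**, per population — robust to the long right tail of
  fluorescence. Populations with no events propagate `NA`, never imputed.
* **Negative corrected MFIs are kept.** Background subtraction of a matched
  control makes small negative values legitimate noise; clipping would bias
  replicate statistics.
* **The reference line at 1 unit is a display aid.** Outputs carry the
  annotation "reference line, not an objective threshold"; ties are labelled
  `"at"` rather than forced into a class.
* **Sample SD (n−1)** for replicate statistics, appropriate for triplicates.
* **Log ratios for cross-instrument work** use raw (uncorrected) medians:
  a common gain multiplies both wells and cancels in the ratio, which
  subtraction does not. Medians are floored at `epsilon = 1` unit (the
  smallest intensity quantum worth resolving) so ratios stay finite; the
  floor is recorded in the output. Spearman rank correlation summarizes
  concordance because what should agree across instruments is which markers
  stand out, not absolute scale. "Positive" for the both/either tally
  defaults to R > log10(2), i.e. a sample median at least twice its control.

## Titration choices

* **Langmuir (no Hill coefficient) by default**, matching the capture
  model; a Hill exponent is an optional flag. Fits use
  Levenberg–Marquardt least squares with positive bounds, started at
  (max response, median dose).
* **LoD = smallest dose with corrected MFI above $k \times$ blank SD**, the
  standard blank-based convention, $k = 3$ by default and exposed. Between
  bracketing doses the crossing is interpolated log-linearly (titrations
  span decades); a response exactly at threshold returns that dose, and a
  response that never crosses returns `Inf` with class `undetected`.
* **Blank SD estimation.** The recommended estimator (used by the analysis
  scripts) takes the variance of each population's control-well MFI across
  replicate control wells, pools it over populations, and scales by
  $\sqrt2$ because a corrected signal subtracts an independently measured
  control. Pooling matters: a per-marker SD from a handful of blank wells is
  a $\chi^2$ with very few degrees of freedom, and thresholds built from it
  vary severalfold between markers by chance alone.
* **Dilution consistency.** A marker near background is trusted only if its
  signal rises with dose: Spearman rho of exactly 1 (ties tolerated) or a
  significantly positive slope on log-dose (one-sided t, default
  $\alpha = 0.05$). Markers failing the check are `near-background` when
  their mean signal sits above the reference line and `undetected`
  otherwise. With only three dilutions a pure-noise series is rank-monotone
  one time in six, so the check gains specificity quickly with more
  dilutions; the property tests use five to six.
* **Input window.** From the largest LoD among detected markers up to the
  90%-of-plateau dose (9K for a Langmuir curve) of the flattest detected
  marker, reported with the caveat that unknown samples should still be
  titrated or run at several dilutions.

## Problem sizes and determinism

All simulations stream per-well sub-seeds deterministically from one master
seed, so any multi-well experiment reruns bit-identically; end-to-end CSV
outputs are byte-stable under a fixed seed. The test suite works at desk
scale by design: full-panel wells of ~10k events; parameter-recovery sweeps
of 50 seeded titrations on a 3-population panel (6 doses x 5 replicates);
specificity tallies of 100 seeded runs on 4-population panels. The
dose grids are chosen to bracket what they estimate — half-saturation
recovery needs doses beyond K, while LoD comparisons use the classic
5e5–5e8 grid where thresholds are crossed.

## What passing tests do and do not show

The simulator emulates: well-separated hard-dyed bead clusters with Gaussian
dispersion in transformed dye space, Langmuir capture with abundance-scaled
effective dose, log-normal background and signal noise, coincident-bead
doublets, replicate wells, titration series, and instrument profiles
(gain, residual spillover, saturation). It deliberately does **not**
emulate: bead cross-linking by single EVs bridging two populations (the
doublet model is coincidence-only), free-antibody competition, carryover
between wells, per-population differences in nonspecific binding (all
populations share one background model — real isotype beads in plasma
behave worse), compensation artefacts beyond a fixed residual spillover
matrix, or acquisition-time drift within a well. Passing tests therefore
demonstrate that the analysis chain is correct for data with the assumed
structure, not that the assay itself performs to any specification on real
samples; conclusions about real EV preparations still require the titration
and dilution-consistency checks on the actual data.

## Known limitations

* The panel's dye-space map is invented; real kits require a panel file
  matching their lot documentation.
* FCS support covers list-mode float (3.0/3.1) single-dataset files —
  sufficient for cytometer list-mode exports and the simulator, but not
  integer data types or ANALYSIS segments.
* Absolute calibration (MESF) is out of scope; all intensities are
  arbitrary units, which is why cross-instrument work goes through rank
  statistics on log ratios.
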