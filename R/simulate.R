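#' Simulation configuration for the synthetic bead assay
#'
#' Parameterizes the generative model used to emulate the multiplex
#' capture-bead assay. Each antibody-coated bead can capture many EVs; the
#' expected number of EVs bound per bead of a population whose capture marker
#' is m follows a Langmuir saturation law
#'
#'   n = f_inc * Nmax * D_m / (K + D_m),   D_m = D * A_m / max(A)
#'
#' where `D` is the well's input particle dose and the effective dose `D_m`
#' scales with the capture marker's epitope abundance `A_m` (a marker carried
#' by no EVs, `A_m = 0`, captures nothing). Each captured EV presents the
#' epitopes of the detection-antibody mix, so the mean reporter signal above
#' background is `brightness * n * sum(A_d over detection mix)`. Per-bead
#' reporter values are the sum of a log-normal background (mean
#' `background_mean`, SD `background_sd`) and the signal term under
#' mean-preserving multiplicative log-normal noise of SD `noise_sigma` (log
#' scale). Isotype-control populations never capture (`n = 0`).
#'
#' @param abundance Named numeric vector: mean detectable-epitope count per
#'   captured EV for each marker (0 = absent). Defaults to the packaged
#'   HEK293T-like profile ([hek_abundance_profile()]).
#' @param capture_capacity `Nmax`, maximum EVs bound per bead.
#' @param half_saturation `K`, input dose (particles) at which a maximally
#'   abundant marker's beads reach `Nmax/2` capture. Scalar, or a named
#'   per-marker vector.
#' @param brightness Reporter units per bound detection-antibody epitope.
#' @param detection_mix Markers in the detection-antibody cocktail (default:
#'   pan-tetraspanin CD9/CD63/CD81).
#' @param background_mean,background_sd Mean and SD of the per-bead log-normal
#'   reporter background.
#' @param noise_sigma Log-scale SD of the multiplicative noise on the per-bead
#'   signal component.
#' @param incubation_factor Fraction of equilibrium capture reached in (0, 1];
#'   1 for overnight capture, < 1 for shortened (e.g. 1 h) protocols.
#' @param doublet_rate Fraction of recorded events that are two coincident
#'   beads.
#' @param events_per_population Expected singlet events per bead population
#'   (per-population counts are Poisson around this).
#' @param scatter_mean,scatter_sd Length-2: mean and SD of the two scatter
#'   channels for single beads.
#' @param dye_cofactor asinh cofactor linking the panel's transformed-space
#'   centroids to linear dye intensities.
#' @param seed Integer master seed; all per-well randomness streams from it.
#' @return An `ev_sim_config` list.
#' @export
sim_config <- function(abundance = hek_abundance_profile(),
                       capture_capacity = 100,
                       half_saturation = 5e8,
                       brightness = 0.02,
                       detection_mix = c("CD9", "CD63", "CD81"),
                       background_mean = 2,
                       background_sd = 3,
                       noise_sigma = 0.15,
                       incubation_factor = 1,
                       doublet_rate = 0.02,
                       events_per_population = 250,
                       scatter_mean = c(50000, 30000),
                       scatter_sd = c(3000, 2500),
                       dye_cofactor = 150,
                       seed = 1L) {
  stopifnot(all(abundance >= 0), capture_capacity >= 0,
            all(half_saturation > 0), brightness >= 0,
            background_mean > 0, background_sd >= 0, noise_sigma >= 0,
            incubation_factor > 0, incubation_factor <= 1,
            doublet_rate >= 0, doublet_rate < 1,
            events_per_population > 0, dye_cofactor > 0)
  structure(list(abundance = abundance, capture_capacity = capture_capacity,
                 half_saturation = half_saturation, brightness = brightness,
                 detection_mix = detection_mix,
                 background_mean = background_mean,
                 background_sd = background_sd, noise_sigma = noise_sigma,
                 incubation_factor = incubation_factor,
                 doublet_rate = doublet_rate,
                 events_per_population = events_per_population,
                 scatter_mean = scatter_mean, scatter_sd = scatter_sd,
                 dye_cofactor = dye_cofactor, seed = as.integer(seed)),
            class = "ev_sim_config")
}

#' Packaged HEK293T-like marker abundance profile
#'
#' Ordinal pattern of epitope abundances per captured EV: the tetraspanins
#' CD9/CD63/CD81 and the integrin CD29 high, CD49e intermediate,
#' CD41b/CD24/CD146/MCSP low, all other markers absent. The ordering mirrors
#' what the assay reports for HEK293T-conditioned medium; the absolute epitope
#' counts are invented model parameters, not measurements.
#'
#' @return Named numeric vector over the 37 markers of [default_panel()].
#' @export
hek_abundance_profile <- function() {
  markers <- setdiff(panel_marker_names(),
                     c("mIgG1 isotype", "REA isotype"))
  ab <- stats::setNames(rep(0, length(markers)), markers)
  ab[c("CD9", "CD63", "CD81")] <- 50
  ab["CD29"] <- 40
  ab["CD49e"] <- 15
  ab[c("CD41b", "CD24", "CD146", "MCSP")] <- 4
  ab
}

# Deterministic per-well sub-seed stream from a master seed.
well_subseed <- function(master, index) {
  as.integer((as.numeric(master) * 100003 + index * 9973) %% 2147483647)
}

# Expected reporter signal above background for each panel population at dose D
# (pre-instrument scale, singlets).
expected_signal <- function(panel, config, dose) {
  ab <- config$abundance
  a_ref <- max(ab, 1e-300)
  det_sum <- sum(ab[intersect(config$detection_mix, names(ab))])
  vapply(seq_len(nrow(panel)), function(i) {
    if (panel$role[i] == "isotype_control") return(0)
    nm <- panel$marker_name[i]
    a_m <- if (nm %in% names(ab)) ab[[nm]] else 0
    if (is.na(a_m) || a_m == 0 || dose == 0) return(0)
    ks <- config$half_saturation
    k_m <- if (length(ks) > 1 && nm %in% names(ks)) ks[[nm]] else ks[[1]]
    d_eff <- dose * a_m / a_ref
    n_p <- config$incubation_factor * config$capture_capacity *
      d_eff / (k_m + d_eff)
    config$brightness * n_p * det_sum
  }, numeric(1))
}

#' Simulate one assay well
#'
#' Generates the event table a cytometer would record for one well: for every
#' panel population, singlet events with dye coordinates drawn from the
#' population's centroid/dispersion (in asinh space, then mapped back to
#' linear intensities), scatter from the singlet scatter model, and reporter
#' values from the capture model described in [sim_config()]. A
#' `doublet_rate` fraction of events are coincident-bead doublets, formed by
#' summing the channel values of two random singlet draws. Control wells
#' (`ann$kind == "control"`) are forced to dose 0, so every population reads
#' pure background. Finally the instrument profile (gain, spillover,
#' saturation) is applied.
#'
#' @param panel An [ev_panel()].
#' @param config An [sim_config()]; markers in its `detection_mix` must exist
#'   in the panel.
#' @param ann A single-row [well_annotations()] (or list with `well_id`,
#'   `kind`, `input_dose`).
#' @param instrument An [instrument_profile()].
#' @return List with `events` (an [event_table()]) and `truth`: per-event true
#'   labels (`pop_id`, with `pop_id2` set for doublets) plus the
#'   per-population expected reporter mean `b + signal` on the
#'   pre-instrument scale.
#' @export
simulate_well <- function(panel, config, ann,
                          instrument = instrument_identity()) {
  stopifnot(inherits(panel, "ev_panel"), inherits(config, "ev_sim_config"))
  missing_det <- setdiff(config$detection_mix, panel$marker_name)
  if (length(missing_det) > 0) {
    abort_validation(paste0("detection-mix marker(s) not in panel: ",
                            paste(missing_det, collapse = ", ")))
  }
  dose <- if (identical(ann$kind, "control")) 0 else ann$input_dose
  sig <- expected_signal(panel, config, dose)
  bg <- lnorm_params(config$background_mean, config$background_sd)

  withr::with_seed(config$seed, {
    n_pop <- stats::rpois(nrow(panel), config$events_per_population)
    pop_idx <- rep(seq_len(nrow(panel)), n_pop)
    n_s <- length(pop_idx)

    # dye coordinates: MVN in transformed space around each centroid
    z1 <- stats::rnorm(n_s); z2 <- stats::rnorm(n_s)
    sd1 <- sqrt(panel$disp11[pop_idx])
    sd2 <- sqrt(panel$disp22[pop_idx])
    rho <- panel$disp12[pop_idx] / (sd1 * sd2)
    t1 <- panel$centroid_dye1[pop_idx] + sd1 * z1
    t2 <- panel$centroid_dye2[pop_idx] +
      sd2 * (rho * z1 + sqrt(pmax(0, 1 - rho^2)) * z2)
    dye1 <- config$dye_cofactor * sinh(pmax(t1, 0))
    dye2 <- config$dye_cofactor * sinh(pmax(t2, 0))

    scatter1 <- pmax(0, stats::rnorm(n_s, config$scatter_mean[1],
                                     config$scatter_sd[1]))
    scatter2 <- pmax(0, stats::rnorm(n_s, config$scatter_mean[2],
                                     config$scatter_sd[2]))

    background <- stats::rlnorm(n_s, bg$meanlog, bg$sdlog)
    s <- sig[pop_idx]
    noise <- if (config$noise_sigma > 0) {
      stats::rlnorm(n_s, -config$noise_sigma^2 / 2, config$noise_sigma)
    } else 1
    detect <- background + s * noise

    singlets <- tibble::tibble(scatter1, scatter2, dye1, dye2, detect)
    truth <- tibble::tibble(pop_id = panel$id[pop_idx],
                            pop_id2 = NA_integer_)

    n_d <- round(config$doublet_rate / (1 - config$doublet_rate) * n_s)
    if (n_d > 0 && n_s > 1) {
      i1 <- sample.int(n_s, n_d, replace = TRUE)
      i2 <- sample.int(n_s, n_d, replace = TRUE)
      doublets <- singlets[i1, ] + singlets[i2, ]
      singlets <- dplyr::bind_rows(singlets, doublets)
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        pop_id = panel$id[pop_idx[i1]], pop_id2 = panel$id[pop_idx[i2]]))
    }

    ord <- sample.int(nrow(singlets))
    events <- event_table(singlets[ord, ], well_id = ann$well_id,
                          instrument_id = instrument$id)
    truth <- truth[ord, ]
  })

  events <- apply_profile(events, instrument)
  list(events = events,
       truth = list(labels = tibble::add_column(truth,
                                                event = seq_len(nrow(truth)),
                                                .before = 1),
                    expected_reporter = tibble::tibble(
                      pop_id = panel$id,
                      marker_name = panel$marker_name,
                      expected_mean = config$background_mean + sig,
                      expected_signal = sig)))
}

#' Simulate a titration series
#'
#' One sample well per dose x replicate, plus one matched dose-0 control well
#' per replicate, with annotations linked sample -> control. Each well gets a
#' deterministic sub-seed streamed from the configuration's master seed, so a
#' whole titration reruns bit-identically.
#'
#' @param panel An [ev_panel()].
#' @param config An [sim_config()]; its `seed` is the master seed.
#' @param doses Non-empty vector of input particle doses (each >= 0).
#' @param replicates Number of replicate wells per dose.
#' @param instrument An [instrument_profile()].
#' @return List of wells; each element has `events`, `truth` (as in
#'   [simulate_well()]) and `ann`, its single-row annotation.
#' @export
simulate_titration <- function(panel, config, doses = c(5e5, 5e6, 5e7, 5e8),
                               replicates = 1,
                               instrument = instrument_identity()) {
  if (length(doses) < 1) abort_validation("doses must be non-empty")
  if (any(doses < 0)) abort_validation("doses must be >= 0")
  wells <- list()
  idx <- 0
  for (r in seq_len(replicates)) {
    ctrl_id <- sprintf("C_r%d", r)
    idx <- idx + 1
    ann_c <- well_annotations(ctrl_id, "control", sample_id = "buffer",
                              input_dose = 0, instrument_id = instrument$id)
    cfg_c <- config
    cfg_c$seed <- well_subseed(config$seed, idx)
    wells[[ctrl_id]] <- c(simulate_well(panel, cfg_c, ann_c[1, ], instrument),
                          list(ann = ann_c))
    for (d in seq_along(doses)) {
      idx <- idx + 1
      wid <- sprintf("S_d%d_r%d", d, r)
      ann_s <- well_annotations(wid, "sample",
                                sample_id = sprintf("dose_%g", doses[d]),
                                input_dose = doses[d],
                                instrument_id = instrument$id,
                                matched_control_id = ctrl_id)
      cfg_s <- config
      cfg_s$seed <- well_subseed(config$seed, idx)
      wells[[wid]] <- c(simulate_well(panel, cfg_s, ann_s[1, ], instrument),
                        list(ann = ann_s))
    }
  }
  wells
}
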