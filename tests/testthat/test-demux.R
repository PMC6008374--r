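test_that("dye transforms are monotone, invertible and fix zero", {
  params <- demux_params(cofactor = 150)
  tab <- event_table(tibble::tibble(scatter1 = 1:5, scatter2 = 1:5,
                                    dye1 = c(0, 10, 100, 1000, 1e5),
                                    dye2 = c(0, 5, 50, 500, 5e4),
                                    detect = 0))
  tr <- transform_events(tab, params)
  expect_equal(tr$events$dye1[1], 0)              # asinh(0) = 0
  expect_true(all(diff(tr$events$dye1) > 0))      # order preserved
  back <- evplex:::invert_dye_transform(tr$events$dye1, params)
  expect_equal(back, tab$events$dye1, tolerance = 1e-12)
  # transforming twice is a no-op
  expect_identical(transform_events(tr, params)$events, tr$events)

  params_log <- demux_params(transform = "log10-shift", cofactor = 1)
  tr2 <- transform_events(tab, params_log)
  expect_equal(tr2$events$dye2, log10(tab$events$dye2 + 1))
})

test_that("singlet gate retains central events and excludes simulated doublets", {
  params <- demux_params()
  center <- params$singlet_gate$center
  tab <- event_table(tibble::tibble(scatter1 = rep(center[1], 10),
                                    scatter2 = rep(center[2], 10),
                                    dye1 = 1, dye2 = 1, detect = 1))
  g <- gate_singlets(tab, params)
  expect_equal(g$excluded, 0)
  expect_equal(g$events$n_events, 10)

  panel <- mini_panel()
  w <- simulate_well(panel, mini_config(seed = 21L, doublet_rate = 0.1),
                     sample_ann(1e8)[1, ])
  g <- gate_singlets(w$events, params)
  is_doublet <- !is.na(w$truth$labels$pop_id2)
  expect_gte(mean(!g$keep[is_doublet]), 0.90)   # >= 90% of true doublets out

  w0 <- simulate_well(panel, mini_config(seed = 22L, doublet_rate = 0),
                      sample_ann(1e8)[1, ])
  g0 <- gate_singlets(w0$events, params)
  expect_lte(g0$excluded / w0$events$n_events, 0.01)  # false exclusion <= 1%
})

test_that("events assign to the nearest centroid, with threshold and tie rules", {
  panel <- default_panel()
  params <- demux_params()
  # events exactly at each centroid assign to that population
  at <- event_table(tibble::tibble(
    scatter1 = 50000, scatter2 = 30000,
    dye1 = 150 * sinh(panel$centroid_dye1),
    dye2 = 150 * sinh(panel$centroid_dye2),
    detect = 0))
  res <- assign_populations(transform_events(at, params), panel, params)
  expect_equal(res$assignment, panel$id)

  # an event far from every centroid stays unassigned
  far <- event_table(tibble::tibble(scatter1 = 50000, scatter2 = 30000,
                                    dye1 = 150 * sinh(9.5),
                                    dye2 = 150 * sinh(9.5), detect = 0))
  res_far <- assign_populations(transform_events(far, params), panel, params)
  expect_true(is.na(res_far$assignment))
  expect_equal(res_far$unassigned_fraction, 1)

  # equidistant between two equal-dispersion centroids: lowest id wins
  mid <- transform_events(event_table(tibble::tibble(
    scatter1 = 50000, scatter2 = 30000,
    dye1 = 1, dye2 = 1, detect = 0)), params)
  mid$events$dye1 <- (panel$centroid_dye1[1] + panel$centroid_dye1[2]) / 2
  mid$events$dye2 <- panel$centroid_dye2[1]
  res_mid <- assign_populations(mid, panel, params)
  expect_equal(res_mid$assignment, panel$id[1])

  # untransformed input is rejected
  expect_error(assign_populations(at, panel, params),
               class = "evplex_validation_error")
})

test_that("assignment matches ground truth exactly when dye noise vanishes", {
  panel <- default_panel(dispersion_sd = 1e-4)
  cfg <- sim_config(seed = 30L, events_per_population = 100,
                    doublet_rate = 0)
  w <- simulate_well(panel, cfg, sample_ann(1e8)[1, ])
  # assign with the nominal panel (its default dispersion), not the tight one
  res <- demux_well(w$events, default_panel(), demux_params())
  truth <- w$truth$labels$pop_id
  gated <- res$assignment != -1L
  acc <- mean(res$assignment[gated] == truth[gated], na.rm = TRUE)
  expect_equal(acc, 1)
})

test_that("demultiplexing partitions events and is permutation-equivariant", {
  panel <- default_panel()
  params <- demux_params()
  for (seed in c(41L, 42L, 43L)) {
    w <- simulate_well(panel, sim_config(seed = seed), sample_ann(1e8)[1, ])
    res <- demux_well(w$events, panel, params)
    expect_equal(sum(res$counts) + res$unassigned + res$doublets_excluded,
                 w$events$n_events)
    expect_gte(res$unassigned_fraction, 0)
    expect_lte(res$unassigned_fraction, 1)
  }

  w <- simulate_well(panel, sim_config(seed = 44L), sample_ann(1e8)[1, ])
  res <- demux_well(w$events, panel, params)
  perm <- withr::with_seed(1, sample.int(w$events$n_events))
  wp <- w$events
  wp$events <- wp$events[perm, ]
  resp <- demux_well(wp, panel, params)
  expect_identical(resp$assignment, res$assignment[perm])
  expect_identical(resp$counts, res$counts)
})

test_that("default spacing keeps reference-panel assignment accuracy above 99%", {
  panel <- default_panel()  # centroid spacing = 6.7 within-population SDs
  cfg <- sim_config(seed = 50L, doublet_rate = 0)
  w <- simulate_well(panel, cfg, sample_ann(1e8)[1, ])
  res <- demux_well(w$events, panel)
  gated <- res$assignment != -1L
  acc <- mean(res$assignment[gated] == w$truth$labels$pop_id[gated],
              na.rm = TRUE)
  expect_gte(acc, 0.99)
})

test_that("population counts are QC-flagged only when below the minimum", {
  panel <- mini_panel()
  w <- simulate_well(panel, mini_config(seed = 60L), sample_ann(1e8)[1, ])
  res <- demux_well(w$events, panel)
  expect_false(any(res$qc))

  # a population with no events is flagged
  res0 <- make_demux(assignment = rep(1L, 50), panel_ids = c(1L, 2L),
                     marker_names = c("A", "B"))
  expect_true(qc_counts(res0, demux_params())$qc[["B"]])
  expect_false(qc_counts(res0, demux_params())$qc[["A"]])

  # at the default 250 events per population, full-panel wells almost never
  # flag; tally over seeded runs
  flags <- vapply(1:25, function(s) {
    ww <- simulate_well(default_panel(), sim_config(seed = s),
                        sample_ann(1e8)[1, ])
    any(demux_well(ww$events, default_panel())$qc)
  }, logical(1))
  expect_gte(mean(!flags), 0.95)
})

test_that("panel-initialized mixture refinement absorbs instrument drift of the bead map", {
  panel <- default_panel()
  drift <- instrument_profile(gains = c(dye1 = 1.45, dye2 = 0.7),
                              id = "drifted")
  w <- simulate_well(panel, sim_config(seed = 70L, doublet_rate = 0),
                     sample_ann(1e8)[1, ], instrument = drift)
  truth <- w$truth$labels$pop_id
  plain <- demux_well(w$events, panel, refine = "none")
  refined <- demux_well(w$events, panel, refine = "gmm")
  acc <- function(res) {
    g <- res$assignment != -1L
    mean(res$assignment[g] == truth[g], na.rm = TRUE)
  }
  expect_gte(acc(refined), 0.95)
  expect_gte(acc(refined), acc(plain) - 0.01)
})
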