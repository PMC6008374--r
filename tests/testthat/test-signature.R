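test_that("population MFI is the median reporter over assigned events", {
  panel <- mini_panel()
  tab <- events_at_centroid(panel, 1, detect = c(1, 2, 3))
  dx <- make_demux(rep(panel$id[1], 3), panel$id, panel$marker_name)
  m <- population_mfi(tab, dx)
  expect_equal(m$mfi[1], 2)                      # odd-count median
  expect_true(is.na(m$mfi[2]))                   # no events -> missing + flag
  expect_true(m$qc_flag[2])

  # one extreme outlier among 99 identical values leaves the median unchanged
  tab2 <- events_at_centroid(panel, 1, detect = c(rep(7, 99), 1e6))
  dx2 <- make_demux(rep(panel$id[1], 100), panel$id, panel$marker_name)
  expect_equal(population_mfi(tab2, dx2)$mfi[1], 7)

  expect_error(population_mfi(tab, dx, channel = "nope"),
               class = "evplex_validation_error")
})

test_that("per-population medians equal a brute-force grouping by ground truth", {
  panel <- mini_panel()
  cfg <- mini_config(seed = 80L, doublet_rate = 0)
  w <- simulate_well(panel, cfg, sample_ann(1e8)[1, ])
  dx <- demux_well(w$events, panel)
  m <- population_mfi(w$events, dx)
  # oracle: group the reporter values by the simulator's labels directly
  oracle <- vapply(panel$id, function(id) {
    stats::median(w$events$events$detect[w$truth$labels$pop_id == id])
  }, numeric(1))
  # demux is not perfect, so medians agree to a small tolerance
  expect_equal(m$mfi, oracle, tolerance = 0.01)
})

test_that("background correction subtracts matched-control medians, keeping negatives", {
  s <- make_mfi(c("CD9", "mIgG1 isotype"), c(25.0, 1.2))
  c_ <- make_mfi(c("CD9", "mIgG1 isotype"), c(1.5, 1.1))
  sig <- background_correct(s, c_)
  expect_equal(sig$delta_mfi, c(23.5, 0.1))

  # self-subtraction: all-zero signature
  sig0 <- background_correct(s, s)
  expect_equal(sig0$delta_mfi, c(0, 0))

  # negatives preserved, never clipped
  signeg <- background_correct(c_, s)
  expect_equal(signeg$delta_mfi, c(-23.5, -0.1))

  # translation consistency: adding k to both medians leaves delta unchanged
  k <- 17.3
  sk <- s; sk$mfi <- sk$mfi + k
  ck <- c_; ck$mfi <- ck$mfi + k
  expect_equal(background_correct(sk, ck)$delta_mfi, sig$delta_mfi)

  # mismatched panels are a validation error
  other <- make_mfi(c("CD63", "mIgG1 isotype"), c(1, 1))
  expect_error(background_correct(s, other),
               class = "evplex_validation_error")
})

test_that("positivity annotation labels against the reference line, ties as 'at'", {
  s <- make_mfi(c("CD9", "CD63", "mIgG1 isotype"), c(26, 2.0, 1.2))
  c_ <- make_mfi(c("CD9", "CD63", "mIgG1 isotype"), c(1.5, 1.0, 1.1))
  sig <- annotate_positivity(background_correct(s, c_), reference_line = 1)
  expect_equal(sig$positivity, c("above", "at", "below"))
  expect_match(attr(sig, "reference_line_note"), "not an objective threshold")

  zero <- background_correct(s, s)
  expect_true(all(annotate_positivity(zero)$positivity == "below"))

  # QC-flagged rows carry no annotation
  sq <- make_mfi(c("CD9", "mIgG1 isotype"), c(26, 1.2), qc = c(TRUE, FALSE))
  sigq <- annotate_positivity(background_correct(sq, make_mfi(
    c("CD9", "mIgG1 isotype"), c(1, 1))))
  expect_true(is.na(sigq$positivity[1]))
})

test_that("replicate statistics use the sample SD and report CV%", {
  s <- function(v) background_correct(make_mfi("CD9", v),
                                      make_mfi("CD9", 0))
  # identical replicates: SD and CV are 0
  same <- replicate_stats(list(s(10), s(10), s(10)))
  expect_equal(same$sd_delta_mfi, 0)
  expect_equal(same$cv_pct, 0)

  trio <- replicate_stats(list(s(10), s(12), s(14)))
  expect_equal(trio$mean_delta_mfi, 12)
  expect_equal(trio$sd_delta_mfi, 2)               # n - 1 denominator
  expect_equal(trio$cv_pct, 100 * 2 / 12, tolerance = 1e-12)

  expect_error(replicate_stats(list(s(10))),
               class = "evplex_validation_error")
  expect_error(replicate_stats(list(s(10),
                                    background_correct(make_mfi("CD63", 1),
                                                       make_mfi("CD63", 0)))),
               class = "evplex_validation_error")
})

test_that("replicate variability matches the closed-form SD of a log-normal median", {
  # With constant background b and mean-preserving log-normal noise of SD
  # sigma on the signal, a well's corrected MFI is median(b + s*exp(sigma*Z -
  # sigma^2/2)) - b. Its sampling SD over wells follows the asymptotic
  # variance of a sample median, 1 / (4 n f(m)^2), with f the density of the
  # shifted log-normal at its median.
  panel <- mini_panel()
  sigma <- 0.1
  n_target <- 400
  cfg <- mini_config(seed = 90L, noise_sigma = sigma, background_sd = 0,
                     doublet_rate = 0, events_per_population = n_target)
  dose <- 2e8
  s_true <- cfg$brightness * cfg$capture_capacity *
    dose / (cfg$half_saturation + dose) * sum(cfg$abundance["CD9"])

  dmfi <- vapply(1:60, function(r) {
    cfg_r <- cfg; cfg_r$seed <- 1000L + r
    w <- simulate_well(panel, cfg_r, sample_ann(dose)[1, ])
    dx <- demux_well(w$events, panel)
    m <- population_mfi(w$events, dx)
    m$mfi[m$marker_name == "CD9"] - cfg$background_mean
  }, numeric(1))

  meanlog <- log(s_true) - sigma^2 / 2
  med <- exp(meanlog)                          # median of the signal term
  f_med <- stats::dlnorm(med, meanlog, sigma)
  sd_closed <- 1 / (2 * f_med * sqrt(n_target))

  # Monte-Carlo SE of a sample SD over R wells ~ sd / sqrt(2 (R - 1))
  mc_se <- sd_closed / sqrt(2 * (length(dmfi) - 1))
  expect_lt(abs(stats::sd(dmfi) - sd_closed), 3 * mc_se)
  expect_equal(mean(dmfi), s_true, tolerance = 0.02)
})

test_that("isotype controls and dose-0 wells read as zero signal", {
  panel <- default_panel()
  iso_ok <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 200L + s)
    w <- simulate_well(panel, cfg, sample_ann(1e8, "S")[1, ])
    cfg2 <- cfg; cfg2$seed <- 500L + s
    wc <- simulate_well(panel, cfg2, control_ann("C")[1, ])
    sig <- well_signature(w$events, wc$events, panel)
    iso <- sig$delta_mfi[sig$role == "isotype_control"]
    # SE of the background median difference bounds honest control noise
    lp <- evplex:::lnorm_params(cfg$background_mean, cfg$background_sd)
    med <- stats::qlnorm(0.5, lp$meanlog, lp$sdlog)
    se_median <- 1 / (2 * stats::dlnorm(med, lp$meanlog, lp$sdlog) *
                        sqrt(cfg$events_per_population))
    all(abs(iso) < 3 * sqrt(2) * se_median)
  }, logical(1))
  expect_gte(mean(iso_ok), 0.95)

  # a dose-0 "sample" is statistically indistinguishable from its control
  cfg <- sim_config(seed = 300L)
  w0 <- simulate_well(panel, cfg, sample_ann(0, "S0")[1, ])
  cfgc <- cfg; cfgc$seed <- 301L
  wc <- simulate_well(panel, cfgc, control_ann()[1, ])
  sig0 <- well_signature(w0$events, wc$events, panel)
  expect_true(all(abs(sig0$delta_mfi) < 1))
  expect_lt(abs(mean(sig0$delta_mfi)), 0.1)
})
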