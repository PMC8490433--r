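# Baseline estimation, event detection, annotation.

test_that("constant noiseless trace gives an exact baseline", {
  sch <- two_state_scheme(1e4, 5, i_p = -100, delta_i = -60)
  p <- sample_state_path(sch, 0, 1, seed = 1)
  tr <- render_trace(p, sch, noise_model(0), acq_nofilter(1))
  bl <- estimate_baseline(tr)
  expect_equal(bl$mean_Ip, -100)
  expect_equal(bl$sd_Ip, 0)
})

test_that("Gaussian baseline is recovered to high accuracy", {
  sch <- two_state_scheme(1e4, 5, i_p = 50, delta_i = -30)
  p <- sample_state_path(sch, 0, 4, seed = 2)
  tr <- render_trace(p, sch, noise_model(2), acq_nofilter(4), seed = 2)
  bl <- estimate_baseline(tr)         # 1e5 samples, mean 50, sd 2
  expect_lt(abs(bl$mean_Ip - 50), 0.05)
  expect_lt(abs(bl$sd_Ip - 2) / 2, 0.1)
})

test_that("static-blockage segment means route mirrors the 500-event protocol", {
  set.seed(3)
  means <- rnorm(500, 160, 1.2)       # 500 I_p events, SD across events
  bl <- estimate_baseline(segment_means = means)
  expect_equal(bl$method, "segment_means_gaussian")
  expect_lt(abs(bl$mean_Ip - 160), 1.2 / sqrt(500) * 2.5)
  expect_error(estimate_baseline(segment_means = rnorm(20)),
               class = "stochsense_insufficient_data_error")
})

test_that("a balanced bimodal histogram raises an ambiguity error", {
  set.seed(4)
  x <- c(rnorm(5e4, 0, 1), rnorm(5e4, 30, 1))
  tr <- structure(list(current = x, acq = acq_nofilter()),
                  class = "sense_trace")
  expect_error(estimate_baseline(tr), "manual",
               class = "stochsense_ambiguity_error")
})

test_that("flat trace yields zero events and in-noise thresholds are refused", {
  sch <- ts_scheme()
  p <- sample_state_path(sch, 0, 4, seed = 5)
  tr <- render_trace(p, sch, noise_model(2), acq_nofilter(4), seed = 5)
  bl <- estimate_baseline(tr)
  ev <- detect_events(tr, bl, nominal_delta_i = -60)
  expect_equal(nrow(ev), 0L)
  expect_error(detect_events(tr, bl, nominal_delta_i = -10),
               "noise band", class = "stochsense_config_error")
})

test_that("noiseless detection recovers ground-truth boundaries exactly", {
  sch <- ts_scheme()
  tr <- simulate_trace(sch, 1e-3, 20, noise = noise_model(0),
                       acq = acq_nofilter(20), seed = 6)
  bl <- list(mean_Ip = 160, sd_Ip = 0.5)   # nonzero sd: threshold guard
  ev <- detect_events(tr, bl, -60)
  # a bound period truncated by the end of the recording is right-censored:
  # present in detection, dropped from the completed-event ground truth
  ev <- ev[ev$end_sample < length(tr$current), ]
  gt <- gt_bound_events(tr)
  # events rendered onto >= 3 sample midpoints survive min_duration
  n_mid <- floor(gt$t_end * 25000 + 0.5) - floor(gt$t_start * 25000 + 0.5)
  gt <- gt[n_mid >= 3, ]
  expect_equal(nrow(ev), nrow(gt))
  m <- match_detection(ev, gt, 25000, tol_samples = 2)
  expect_equal(m$rate, 1)
  expect_lt(max(abs(c(m$start_err, m$end_err))), 1)
})

test_that("detection at SNR 10 finds nearly all events with tight boundaries", {
  sch <- ts_scheme(k_on = 2e3)            # sparser events, 50+ in 100 s
  acq <- acq_default(100)
  sdv <- baseline_sd_for_snr(10, -60, acq)
  tr <- simulate_trace(sch, 1e-3, 100, noise = noise_model(sdv), acq = acq,
                       seed = 7)
  bl <- list(mean_Ip = 160, sd_Ip = 6)
  ev <- detect_events(tr, bl, -60)
  gt <- gt_bound_events(tr)
  gt <- gt[gt$dwell >= 5 * 3 / 25000, ]
  expect_gt(nrow(gt), 50)
  m <- match_detection(ev, gt, 25000, tol_samples = 2)
  expect_gte(m$rate, 0.98)
})

test_that("raising min_duration is monotone in the event count", {
  sch <- ts_scheme(k_off = 50)            # many short events
  tr <- simulate_trace(sch, 1e-3, 30, noise = noise_model(3),
                       acq = acq_default(30), seed = 8)
  bl <- list(mean_Ip = 160, sd_Ip = 1)
  durs <- c(1, 2, 3, 5, 10, 25) / 25000
  counts <- vapply(durs, function(md)
    nrow(detect_events(tr, bl, -60, min_duration = md)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-cycle time is conserved across events, gaps and lead time", {
  sch <- add_absorbing_state(ts_scheme(k_on = 5e4, k_off = 2), "Ib", 0.05)
  tr <- simulate_irreversible_run(sch, 1e-3, n_cycles = 3, cycle_duration = 20,
                                  dead_time = 1, noise = noise_model(2),
                                  seed = 9)
  bl <- list(mean_Ip = 160, sd_Ip = 1)
  ev <- detect_events(tr, bl, -60)
  expect_gt(nrow(ev), 0)
  for (cy in unique(ev$cycle)) {
    evc <- ev[ev$cycle == cy, ]
    if (!nrow(evc)) next
    win <- tr$cycles[tr$cycles$cycle == cy, ]
    lead <- evc$start_s[1] - win$t_start
    tail_t <- win$t_end - evc$end_s[nrow(evc)]
    total <- sum(evc$t_off_s) + sum(evc$t_on_s, na.rm = TRUE) + lead + tail_t
    expect_equal(total, win$t_end - win$t_start, tolerance = 1e-9)
  }
})

test_that("annotation reports the signed amplitude convention", {
  # positive-going class (polyol adduct convention) and negative-going class
  for (di in c(+20, -20)) {
    sch <- two_state_scheme(1e4, 5, i_p = 100, delta_i = di)
    tr <- simulate_trace(sch, 1e-3, 20, noise = noise_model(1),
                         acq = acq_default(20), seed = 10 + di)
    bl <- list(mean_Ip = 100, sd_Ip = 1 * 0.3)
    ev <- annotate_events(tr, detect_events(tr, bl, di))
    expect_gt(nrow(ev), 20)
    expect_true(all(sign(ev$delta_I_pA) == sign(di)))
    expect_lt(abs(mean(ev$delta_I_pA) - di), 1.5)
  }
})

test_that("events at the baseline level annotate to zero amplitude", {
  sch <- ts_scheme()
  tr <- simulate_trace(sch, 1e-3, 5, noise = noise_model(0),
                       acq = acq_nofilter(5), seed = 30)
  bl <- list(mean_Ip = 160, sd_Ip = 0.1)
  ev <- detect_events(tr, bl, -60)
  # overwrite one event window with exactly baseline samples
  i <- ev$start_sample[1]:ev$end_sample[1]
  tr$current[i + 1L] <- 160
  ann <- annotate_events(tr, ev[1, , drop = FALSE])
  expect_equal(ann$delta_I_pA, 0)
})

test_that("no false positives arise on event-free filtered noise", {
  sch <- ts_scheme()
  p <- sample_state_path(sch, 0, 8, seed = 11)
  acq <- acq_default(8)
  sdv <- baseline_sd_for_snr(10, -60, acq)
  tr <- render_trace(p, sch, noise_model(sdv), acq, seed = 11)
  bl <- list(mean_Ip = 160, sd_Ip = 6)     # threshold = 5 x sd
  ev <- detect_events(tr, bl, -60)
  expect_equal(nrow(ev), 0L)
})
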