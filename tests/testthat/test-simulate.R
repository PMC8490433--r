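# Concentration series, irreversible reload cycles and labelled mixtures.

test_that("zero-concentration trace contains no bound segments", {
  traces <- simulate_concentration_series(ts_scheme(), c(0, 1e-3),
                                          duration = 10, seed = 1)
  expect_length(traces, 2)
  expect_false("Ib" %in% traces[["0"]]$path$state)
  expect_true("Ib" %in% traces[["0.001"]]$path$state)
})

test_that("ground-truth event counts scale with concentration", {
  conc <- c(0.2, 0.4, 0.6, 0.8, 1.0) * 1e-3
  traces <- simulate_concentration_series(ts_scheme(), conc, duration = 200,
                                          seed = 42)
  counts <- vapply(traces, function(tr) nrow(gt_bound_events(tr)), numeric(1))
  unbound <- vapply(traces, function(tr)
    unname(path_occupancy(tr$path)["Ip"]), numeric(1))
  expected <- 1e4 * conc * unbound
  # each count within 4 sd of its Poisson expectation
  expect_true(all(abs(counts - expected) <= 4 * sqrt(expected)))
  # monotone increase over this range
  expect_true(all(diff(counts) > 0))
})

test_that("a repeated series call with the same master seed is bit-identical", {
  conc <- c(2e-4, 6e-4)
  a <- simulate_concentration_series(ts_scheme(), conc, 5,
                                     noise = noise_model(2), seed = 9)
  b <- simulate_concentration_series(ts_scheme(), conc, 5,
                                     noise = noise_model(2), seed = 9)
  expect_identical(lapply(a, `[[`, "current"), lapply(b, `[[`, "current"))
  expect_error(simulate_concentration_series(ts_scheme(), numeric(0), 5),
               class = "stochsense_config_error")
})

test_that("absorption rate zero gives one uninterrupted reactive cycle", {
  sch <- add_absorbing_state(ts_scheme(), from = "Ib", rate = 0)
  expect_warning(
    tr <- simulate_irreversible_run(sch, 1e-3, n_cycles = 1,
                                    cycle_duration = 20, seed = 2),
    "single-cycle")
  expect_equal(unique(tr$path$cycle), 1L)
  expect_false("terminated" %in% tr$path$state)
})

test_that("four reloads give exactly five cycles and exponential absorption clocks", {
  sch <- add_absorbing_state(ts_scheme(k_on = 5e4, k_off = 2), from = "Ib",
                             rate = 1)
  tr <- simulate_irreversible_run(sch, 1e-3, n_cycles = 5, cycle_duration = 30,
                                  dead_time = 1, seed = 8)
  expect_setequal(unique(tr$path$cycle), 1:5)
  # within each cycle, nothing follows the absorbing state
  p <- tr$path[tr$path$state != ".dead", ]
  for (cy in 1:5) {
    pc <- p[p$cycle == cy, ]
    hit <- which(pc$state == "terminated")
    if (length(hit)) expect_equal(hit, nrow(pc))
  }
  # competing-risks oracle: cumulative bound time before absorption is
  # exponential with the absorption rate; check the mean over many cycles
  bound_clock <- vapply(1:400, function(s) {
    p1 <- sample_state_path(sch, 1e-3, 1e6, seed = 5000 + s)
    sum((p1$t_end - p1$t_start)[p1$state == "Ib"])
  }, numeric(1))
  sem <- sd(bound_clock) / sqrt(length(bound_clock))
  expect_lt(abs(mean(bound_clock) - 1), 3.5 * sem)
})

test_that("post-absorption trace is quiet at baseline noise", {
  sch <- add_absorbing_state(ts_scheme(k_on = 1e5, k_off = 5), from = "Ib",
                             rate = 5)
  tr <- suppressWarnings(          # single-cycle warning is expected here
    simulate_irreversible_run(sch, 1e-3, n_cycles = 1, cycle_duration = 60,
                              noise = noise_model(2),
                              acq = acq_nofilter(), seed = 4))
  p <- tr$path
  term <- p[p$state == "terminated", ]
  expect_equal(nrow(term), 1L)
  fs <- 25000
  idx <- (floor(term$t_start * fs) + 5):(floor(term$t_end * fs) - 5)
  expect_lt(abs(sd(tr$current[idx]) - 2), 0.1)
  expect_lt(abs(mean(tr$current[idx]) - 160), 0.1)
})

test_that("single-class mixture behaves like a plain simulation", {
  cls <- list(only = list(scheme = ts_scheme()))
  tr <- simulate_mixture(cls, proportions = 1, concentration = 1e-3,
                         duration = 60, seed = 12)
  lab <- tr$meta$event_labels
  expect_true(all(lab$class == "only"))
  # event rate consistent with k_on * c over unbound time
  unbound <- sum((tr$path$t_end - tr$path$t_start)[tr$path$state == "Ip"])
  expect_lt(abs(nrow(lab) - 1e4 * 1e-3 * unbound), 4 * sqrt(1e4 * 1e-3 * unbound))
})

test_that("mixture class counts fall in the multinomial bulk and signs follow config", {
  cls <- list(
    neg1 = list(scheme = ts_scheme(k_on = 3e4, k_off = 20, delta_i = -40)),
    neg2 = list(scheme = ts_scheme(k_on = 3e4, k_off = 20, delta_i = -60)),
    pos = list(scheme = ts_scheme(k_on = 3e4, k_off = 20, delta_i = +30)))
  tr <- simulate_mixture(cls, proportions = rep(1 / 3, 3),
                         concentration = 1e-3, duration = 25, seed = 5)
  lab <- tr$meta$event_labels
  n <- nrow(lab)
  expect_gt(n, 200)
  counts <- table(factor(lab$class, levels = names(cls)))
  # multinomial 99% band per class
  band <- 2.58 * sqrt(n * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - n / 3) <= band))
  # per-event sign convention: rendered level below baseline for neg classes,
  # above for the positive class
  fs <- 25000
  ok <- vapply(seq_len(n), function(i) {
    a <- floor(lab$t_start[i] * fs) + 2L
    b <- max(a, floor(lab$t_end[i] * fs) - 1L)
    m <- mean(tr$current[a:b]) - 160
    if (lab$class[i] == "pos") m > 0 else m < 0
  }, logical(1))
  expect_gt(mean(ok), 0.95)        # short events smear across boundaries
  expect_error(simulate_mixture(cls, c(0.5, 0.5, 0.5), 1e-3, 5),
               class = "stochsense_config_error")
  cls_bad <- cls
  cls_bad$pos$scheme <- ts_scheme(i_p = 100)
  expect_error(simulate_mixture(cls_bad, rep(1 / 3, 3), 1e-3, 5),
               "baseline", class = "stochsense_config_error")
})
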