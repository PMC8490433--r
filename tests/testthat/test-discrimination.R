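# Frequency split, noise features, SVC classification, decision regions.

test_that("a DC trace passes the split untouched", {
  x <- rep(42, 5000)
  sp <- frequency_split(x, cutoff = 100, fs = 25000)
  expect_lt(max(abs(sp$high_pass)), 1e-9 * 42)
  expect_equal(sp$low_pass, x, tolerance = 1e-12)
})

test_that("split is exactly additive for arbitrary input", {
  set.seed(1)
  x <- cumsum(rnorm(20000)) + 100
  sp <- frequency_split(x, cutoff = 100, fs = 25000)
  expect_lt(max(abs(sp$low_pass + sp$high_pass - x)), 1e-9)
  expect_error(frequency_split(x, cutoff = 13000, fs = 25000),
               class = "stochsense_config_error")
})

test_that("sinusoid gains match the analytic zero-phase Butterworth response", {
  fs <- 25000
  t <- (0:(fs * 2 - 1)) / fs
  for (f in c(10, 50, 100, 300, 800)) {
    x <- sin(2 * pi * f * t)
    sp <- frequency_split(x, cutoff = 100, order = 4, fs = fs)
    # amplitude by projection on the quadrature pair, away from the edges
    i <- (fs %/% 2):(3 * fs %/% 2)
    a <- 2 * mean(sp$low_pass[i] * sin(2 * pi * f * t[i]))
    b <- 2 * mean(sp$low_pass[i] * cos(2 * pi * f * t[i]))
    gain <- sqrt(a^2 + b^2)
    analytic <- 1 / (1 + (f / 100)^8)      # |H|^2: forward-backward pass
    expect_lt(abs(gain - analytic), 5e-3)
    if (f == 10) expect_gte(gain, 0.999)
  }
})

test_that("white-noise variance partitions across the split", {
  set.seed(2)
  x <- rnorm(1e5, sd = 3)
  sp <- frequency_split(x, cutoff = 100, fs = 25000)
  expect_lt(abs(var(sp$low_pass) + var(sp$high_pass) - var(x)) / var(x), 0.02)
  # high-pass SD from the analytic residual response (1 - |H|^2)
  f <- seq(0, 12500, length.out = 4097)
  hp_frac <- mean((1 - 1 / (1 + (f / 100)^8))^2)
  expect_lt(abs(sd(sp$high_pass) - 3 * sqrt(hp_frac)) / (3 * sqrt(hp_frac)),
            0.02)
})

test_that("features are near zero on a noiseless bound level", {
  sch <- ts_scheme(k_off = 1)
  tr <- simulate_trace(sch, 1e-3, 15, noise = noise_model(0),
                       acq = acq_nofilter(15), seed = 3)
  bl <- list(mean_Ip = 160, sd_Ip = 0.5)
  ev <- detect_events(tr, bl, -60)
  ev <- ev[which.max(ev$t_off_s), ]
  sp <- frequency_split(tr)
  # guard must clear the split filter's own settling (~100 Hz time scale)
  fe <- extract_features(sp, ev, guard_samples = 2000)
  expect_false(fe$guard_flag)
  expect_lt(fe$lp_sd, 1e-6)
  expect_lt(fe$hp_sd, 1e-6)
})

test_that("slow telegraph fluctuations load on lp_sd, broadband on hp_sd", {
  base <- ts_scheme(k_off = 0.5)          # ~2 s bound dwells
  mk <- function(state_noise, seed) {
    tr <- simulate_trace(base, 2e-3, 40, noise = noise_model(3, state_noise),
                         acq = acq_default(40), seed = seed)
    bl <- list(mean_Ip = 160, sd_Ip = 1)
    ev <- detect_events(tr, bl, -60)
    ev <- ev[ev$t_off_s > 0.5, ]
    fe <- extract_features(frequency_split(tr), ev)
    colMeans(fe[, c("lp_sd", "hp_sd")])
  }
  plain <- mk(list(), seed = 4)
  # a slow (<= 10 Hz spectral corner) flicker keeps its power below the
  # 100 Hz split; Lorentzian leakage above 100 Hz is ~0.4% of its variance
  slow <- mk(list(Ib = list(telegraph_amp = 6,
                            telegraph_rates = c(4, 4))), seed = 4)
  broad <- mk(list(Ib = list(broadband_sd = 6)), seed = 4)
  expect_gt(slow[["lp_sd"]], 3 * plain[["lp_sd"]])
  expect_lt(abs(slow[["hp_sd"]] - plain[["hp_sd"]]) / plain[["hp_sd"]], 0.05)
  expect_gt(broad[["hp_sd"]], 2 * plain[["hp_sd"]])
})

test_that("well-separated classes are classified almost perfectly", {
  feats <- separable_features(300, seed = 5)
  res <- evaluate_classifier(feats, feats$label, seed = 11)
  expect_gte(res$confusion$overall_accuracy, 0.99)
  # row sums equal held-out class counts
  held <- setdiff(seq_len(nrow(feats)), res$train_idx)
  expect_equal(unname(rowSums(res$confusion$table)),
               as.vector(table(feats$label[held])[rownames(res$confusion$table)]))
})

test_that("training is deterministic and single-class input degrades gracefully", {
  feats <- separable_features(60, seed = 6)
  m1 <- train_classifier(feats, feats$label)
  m2 <- train_classifier(feats, feats$label)
  expect_identical(m1$svm$coefs, m2$svm$coefs)
  expect_identical(m1$training_hash, m2$training_hash)
  one <- feats[feats$label == "A", ]
  expect_warning(m0 <- train_classifier(one, one$label), "single-class")
  expect_equal(as.character(predict(m0, one[1:5, ])), rep("A", 5))
  expect_equal(length(predict(m1, feats[0, ])), 0L)
  expect_error(predict(m1, data.frame(lp_sd = 1)),
               class = "stochsense_config_error")
})

test_that("events at training centroids get their class; pipeline is scale invariant", {
  feats <- separable_features(100, seed = 7)
  m <- train_classifier(feats, feats$label)
  centers <- data.frame(lp_sd = c(2, 10, 2), hp_sd = c(2, 2, 10))
  expect_equal(as.character(predict(m, centers)), c("A", "B", "C"))
  # affine unit rescaling (pA -> nA) with standardization on: same labels
  feats_nA <- feats
  feats_nA$lp_sd <- feats_nA$lp_sd / 1000
  feats_nA$hp_sd <- feats_nA$hp_sd / 1000
  m_nA <- train_classifier(feats_nA, feats_nA$label)
  expect_equal(as.character(predict(m_nA, feats_nA)),
               as.character(predict(m, feats)))
  # row-order permutation leaves predictions unchanged
  set.seed(8); perm <- sample(nrow(feats))
  m_p <- train_classifier(feats[perm, ], feats$label[perm])
  expect_equal(as.character(predict(m_p, feats)),
               as.character(predict(m, feats)))
})

test_that("mixture simulation events are recalled by their noise signature", {
  classes <- list(
    quiet = list(scheme = ts_scheme(k_on = 2e4, k_off = 1.5)),
    flicker = list(scheme = ts_scheme(k_on = 2e4, k_off = 1.5),
                   noise = noise_model(0, list(Ib = list(
                     telegraph_amp = 14, telegraph_rates = c(10, 10))))),
    buzzy = list(scheme = ts_scheme(k_on = 2e4, k_off = 1.5),
                 noise = noise_model(0, list(Ib = list(broadband_sd = 6)))))
  tr <- simulate_mixture(classes, proportions = rep(1 / 3, 3),
                         concentration = 1e-3, duration = 120,
                         baseline_sd = 1.5, acq = acq_default(), seed = 13)
  bl <- list(mean_Ip = 160, sd_Ip = 0.6)
  ev <- detect_events(tr, bl, -60)
  ev <- ev[ev$t_off_s > 0.4, ]
  lab <- rep(NA_character_, nrow(ev))
  gl <- tr$meta$event_labels
  mid <- (ev$start_s + ev$end_s) / 2
  for (i in seq_len(nrow(ev))) {
    hit <- which(gl$t_start <= mid[i] & gl$t_end >= mid[i])
    if (length(hit)) lab[i] <- gl$class[hit[1]]
  }
  keep <- !is.na(lab)
  fe <- extract_features(frequency_split(tr), ev[keep, ])
  res <- evaluate_classifier(fe, lab[keep], seed = 21)
  expect_gte(min(res$confusion$per_class_accuracy, na.rm = TRUE), 0.95)
})

test_that("confusion matrices count correctly, including unseen labels", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(unname(cm$table), matrix(c(1, 0, 1, 1), 2))
  expect_equal(cm$overall_accuracy, 2 / 3)
  perfect <- confusion_matrix(rep(c("x", "y"), 5), rep(c("x", "y"), 5))
  expect_true(all(perfect$per_class_accuracy == 1))
  expect_equal(perfect$overall_accuracy, 1)
  # label absent from predictions still appears as a zero column
  cm2 <- confusion_matrix(c("A", "B", "C"), c("A", "B", "B"))
  expect_equal(unname(cm2$table["C", "C"]), 0L)
  expect_equal(dim(cm2$table), c(3L, 3L))
  # property: row sums equal truth counts for random labelings
  set.seed(9)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    tr_lab <- sample(letters[1:4], n, replace = TRUE)
    pr_lab <- sample(letters[1:4], n, replace = TRUE)
    cm3 <- confusion_matrix(tr_lab, pr_lab)
    cnt <- table(factor(tr_lab, levels = rownames(cm3$table)))
    expect_equal(unname(rowSums(cm3$table)), as.vector(cnt))
  }
  expect_error(confusion_matrix(c("a", "b"), "a"),
               class = "stochsense_config_error")
})

test_that("decision grids reflect classifier geometry", {
  set.seed(10)
  two <- data.frame(lp_sd = c(rnorm(80, 2, 0.5), rnorm(80, 8, 0.5)),
                    hp_sd = c(rnorm(80, 2, 0.5), rnorm(80, 8, 0.5)),
                    label = rep(c("lo", "hi"), each = 80))
  m <- train_classifier(two, two$label, kernel = "linear")
  g <- decision_boundary_grid(m, c(0, 10), c(0, 10), resolution = 80)
  # boundary cells of a linear model lie on a straight band
  zb <- matrix(match(g$labels, g$levels), 80)
  bx <- c(); by <- c()
  for (i in 1:79) for (j in 1:80)
    if (zb[i, j] != zb[i + 1, j]) { bx <- c(bx, j); by <- c(by, i + 0.5) }
  fitln <- lm(by ~ bx)
  cell <- 10 / 80
  expect_lt(max(abs(residuals(fitln))) * cell, cell * 2)
  # training points sit in cells matching their predicted labels
  pred <- as.character(predict(m, two))
  gi <- findInterval(two$lp_sd, g$lp); gj <- findInterval(two$hp_sd, g$hp)
  ok <- gi >= 1 & gi <= 80 & gj >= 1 & gj <= 80
  expect_true(all(g$labels[cbind(gi[ok], gj[ok])] == pred[ok]))
  expect_error(decision_boundary_grid(m, c(1, 1), c(0, 10)),
               class = "stochsense_config_error")
})

test_that("three separable classes give three connected decision regions", {
  feats <- separable_features(100, seed = 12)
  m <- train_classifier(feats, feats$label)
  g <- decision_boundary_grid(m, c(-2, 14), c(-2, 14), resolution = 60)
  z <- g$labels
  # flood-fill count of connected components per label
  comps <- 0L
  seen <- matrix(FALSE, 60, 60)
  for (i in 1:60) for (j in 1:60) {
    if (seen[i, j]) next
    comps <- comps + 1L
    lab <- z[i, j]
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (all(q >= 1) && all(q <= 60) && !seen[q[1], q[2]] &&
            z[q[1], q[2]] == lab) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  expect_equal(comps, 3L)
})
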