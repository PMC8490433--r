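# Shared fixtures: canonical schemes, acquisition settings and noise
# calibration used across the suite. The canonical two-state scheme uses the
# nickel-coordination scale: k_on = 1e4 M^-1 s^-1, k_off = 5 s^-1
# (tau_off = 0.2 s), baseline 160 pA, blockage amplitude -60 pA.

ts_scheme <- function(k_on = 1e4, k_off = 5, i_p = 160, delta_i = -60) {
  two_state_scheme(k_on = k_on, k_off = k_off, i_p = i_p, delta_i = delta_i)
}

acq_default <- function(duration = NULL) {
  acquisition(sampling_rate = 25000, analog_corner = 1000, filter_order = 4,
              filter_type = "bessel", duration = duration)
}

acq_nofilter <- function(duration = NULL, fs = 25000) {
  acquisition(sampling_rate = fs, analog_corner = NULL, duration = duration)
}

# Ratio sd(filtered white noise)/sd(input) from the impulse-response energy.
filter_sd_ratio <- function(acq) {
  if (is.null(acq$analog_corner)) return(1)
  flt <- design_lowpass(acq$filter_order, acq$analog_corner,
                        acq$sampling_rate,
                        if (acq$filter_type == "butterworth") "butterworth"
                        else "bessel")
  h <- as.numeric(signal::filter(signal::Arma(b = flt$b, a = flt$a),
                                 c(1, rep(0, 8191))))
  sqrt(sum(h^2))
}

# SNR is |delta_i| over the white baseline-noise SD of the noise model
# (the SD before acquisition filtering).
baseline_sd_for_snr <- function(snr, delta_i, acq = NULL) {
  abs(delta_i) / snr
}

# Ground-truth bound events of a two-state trace (complete visits only).
gt_bound_events <- function(trace, state = "Ib") {
  p <- trace$path
  idx <- which(p$state == state)
  n <- nrow(p)
  idx <- idx[idx < n]               # drop the right-censored final segment
  data.frame(t_start = p$t_start[idx], t_end = p$t_end[idx],
             dwell = p$t_end[idx] - p$t_start[idx])
}

# Fraction of ground-truth events matched by a detected event with both
# boundaries within tol samples; also returns boundary errors.
match_detection <- function(events, gt, fs, tol_samples = 2) {
  if (!nrow(gt)) return(list(rate = NA_real_, start_err = numeric(0),
                             end_err = numeric(0)))
  matched <- logical(nrow(gt))
  start_err <- end_err <- rep(NA_real_, nrow(gt))
  for (i in seq_len(nrow(gt))) {
    if (!nrow(events)) break
    j <- which.min(abs(events$start_s - gt$t_start[i]))
    se <- (events$start_s[j] - gt$t_start[i]) * fs
    ee <- (events$end_s[j] - gt$t_end[i]) * fs
    start_err[i] <- se; end_err[i] <- ee
    matched[i] <- abs(se) <= tol_samples && abs(ee) <= tol_samples
  }
  list(rate = mean(matched), start_err = start_err, end_err = end_err)
}

# Three well-separated synthetic feature clusters in the (lp_sd, hp_sd)
# plane: centroid distance >= 6 within-class SDs (unit SD clusters).
separable_features <- function(n_per_class = 300, seed = 1) {
  set.seed(seed)
  centers <- list(A = c(2, 2), B = c(10, 2), C = c(2, 10))
  feats <- do.call(rbind, lapply(names(centers), function(cl) {
    data.frame(lp_sd = rnorm(n_per_class, centers[[cl]][1], 1),
               hp_sd = rnorm(n_per_class, centers[[cl]][2], 1),
               label = cl)
  }))
  feats$event_id <- seq_len(nrow(feats))
  feats
}
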