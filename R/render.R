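# Rendering a ground-truth state path into a sampled, noisy, filtered trace.

state_mean_lookup <- function(scheme) {
  setNames(scheme$states$current_pA, scheme$states$name)
}

# Simulate a secondary two-state telegraph fluctuation over one contiguous
# run of n samples. Returns a +/- amp/2 square signal (zero mean at
# stationarity); rates in s^-1.
telegraph_run <- function(n, dt, amp, up_rate, down_rate) {
  if (amp == 0 || (up_rate == 0 && down_rate == 0)) return(numeric(n))
  p_up <- if (up_rate + down_rate > 0) up_rate / (up_rate + down_rate) else 0.5
  s <- runif(1) < p_up
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    rate <- if (s) down_rate else up_rate
    len <- if (rate <= 0) n - i + 1L else max(1L, ceiling(rexp(1, rate) / dt))
    j <- min(n, i + len - 1L)
    out[i:j] <- if (s) amp / 2 else -amp / 2
    i <- j + 1L
    s <- !s
  }
  out
}

#' Render a state path into a sampled current trace
#'
#' Each sample takes the mean current of the state occupying its midpoint,
#' plus white baseline noise, plus any state-specific extra component from the
#' noise model (broadband Gaussian or a secondary telegraph fluctuation);
#' the result is then passed through the causal analog-filter emulation
#' configured in `acq`. With all noise terms zero and the filter disabled the
#' output is exactly the piecewise-constant state-mean signal.
#'
#' @param path A `state_path` from [sample_state_path()] (or spliced paths).
#' @param scheme The generating [kinetic_scheme()].
#' @param noise A [noise_model()].
#' @param acq An [acquisition()]; its `duration` defaults to the path span.
#' @param seed Optional integer seed for the noise draws.
#' @param meta Named list of metadata (concentration, voltage_mV,
#'   temperature_K, ...).
#' @return A `sense_trace`: list with `current` (pA), `time_step` (s),
#'   `acq`, `path` (ground truth), `cycles`, `meta`.
#' @export
render_trace <- function(path, scheme, noise = noise_model(0),
                         acq = acquisition(), seed = NULL, meta = list()) {
  stopifnot(inherits(path, "state_path") || is.data.frame(path))
  if (!is.null(seed)) set.seed(seed)
  t0 <- attr(path, "t0") %||% min(path$t_start)
  duration <- acq$duration %||% (max(path$t_end) - t0)
  if (max(path$t_end) < t0 + duration - 1e-12)
    stop_config("path does not cover the acquisition duration")
  fs <- acq$sampling_rate
  n <- round(duration * fs)
  tm <- t0 + (seq_len(n) - 0.5) / fs
  seg <- findInterval(tm, path$t_start)
  seg[seg < 1L] <- 1L
  st <- path$state[seg]

  means <- state_mean_lookup(scheme)
  base_i <- means[[scheme$baseline]]
  lv <- means[st]
  lv[st == ".dead"] <- base_i          # reload dead time sits at baseline
  x <- as.numeric(lv)

  if (noise$baseline_sd > 0) x <- x + rnorm(n, 0, noise$baseline_sd)
  if (length(noise$state_noise)) {
    dt <- 1 / fs
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      comp <- noise$state_noise[[r$values[k]]]
      if (is.null(comp)) next
      idx <- starts[k]:ends[k]
      if (!is.null(comp$broadband_sd) && comp$broadband_sd > 0)
        x[idx] <- x[idx] + rnorm(length(idx), 0, comp$broadband_sd)
      if (!is.null(comp$telegraph_amp) && comp$telegraph_amp > 0)
        x[idx] <- x[idx] + telegraph_run(length(idx), dt, comp$telegraph_amp,
                                         comp$telegraph_rates[1],
                                         comp$telegraph_rates[2])
    }
  }

  flt <- acquisition_filter(acq)
  if (!is.null(flt)) x <- iir_filter(flt, x)

  cyc <- path[path$state != ".dead", , drop = FALSE]
  cycles <- data.frame(
    cycle = sort(unique(cyc$cycle)),
    t_start = as.numeric(tapply(cyc$t_start, cyc$cycle, min)),
    t_end = as.numeric(tapply(cyc$t_end, cyc$cycle, max)))

  structure(list(current = x, acq = acq, path = path, cycles = cycles,
                 scheme = scheme,
                 meta = modifyList(list(seed = seed, units = "pA"), meta)),
            class = "sense_trace")
}

#' Simulate a stochastic-sensing trace
#'
#' Convenience wrapper: samples a Gillespie state path and renders it.
#'
#' @inheritParams render_trace
#' @inheritParams sample_state_path
#' @param duration Trace duration, s.
#' @return A `sense_trace` with ground truth attached.
#' @examples
#' sch <- two_state_scheme(1e4, 5, i_p = 160, delta_i = -60)
#' tr <- simulate_trace(sch, concentration = 1e-3, duration = 2,
#'                      noise = noise_model(2), seed = 7)
#' print(tr)
#' @export
simulate_trace <- function(scheme, concentration, duration,
                           noise = noise_model(0), acq = acquisition(),
                           seed = NULL) {
  acq$duration <- duration
  path <- sample_state_path(scheme, concentration, duration,
                            seed = if (is.null(seed)) NULL else derive_seed(seed, 1L))
  render_trace(path, scheme, noise, acq,
               seed = if (is.null(seed)) NULL else derive_seed(seed, 2L),
               meta = list(concentration = concentration, master_seed = seed))
}

#' @export
print.sense_trace <- function(x, ...) {
  n <- length(x$current)
  fs <- x$acq$sampling_rate
  cat(sprintf("Stochastic-sensing trace: %d samples (%.3f s at %g kHz)\n",
              n, n / fs, fs / 1000))
  if (!is.null(x$acq$analog_corner))
    cat(sprintf("  analog filter: %d-pole %s, %g Hz corner\n",
                x$acq$filter_order, x$acq$filter_type, x$acq$analog_corner))
  if (!is.null(x$path))
    cat(sprintf("  ground truth: %d segments, %d cycle(s)\n",
                nrow(x$path), length(unique(x$path$cycle))))
  if (!is.null(x$meta$concentration))
    cat(sprintf("  analyte concentration: %g mol/L\n", x$meta$concentration))
  invisible(x)
}

#' @export
plot.sense_trace <- function(x, from = 0, to = NULL, ...) {
  fs <- x$acq$sampling_rate
  n <- length(x$current)
  to <- to %||% (n / fs)
  i <- max(1, floor(from * fs)):min(n, ceiling(to * fs))
  plot((i - 0.5) / fs, x$current[i], type = "l", xlab = "time (s)",
       ylab = "current (pA)", ...)
  invisible(x)
}

# Samples (1-based index range) covered by a time interval, half-open.
time_to_samples <- function(t_start, t_end, fs) {
  c(floor(t_start * fs) + 1L, ceiling(t_end * fs))
}
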