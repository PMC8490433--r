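# Idealization: baseline estimation, event detection, annotation, sub-levels.

# Fit a Gaussian to the dominant mode of a sample histogram; returns
# center, width and the number of modes considered. Falls back to moment
# estimates over the dominant-mode neighbourhood if the nls fit fails.
fit_gaussian_mode <- function(x, bins = NULL) {
  x <- x[is.finite(x)]
  if (!length(x)) stop_insufficient("no finite samples for baseline fit")
  s <- sd(x)
  if (s == 0) return(list(center = x[1], width = 0, n_modes = 1L))
  bins <- bins %||% max(30L, min(200L, floor(sqrt(length(x)) / 2)))
  h <- hist(x, breaks = bins, plot = FALSE)
  cnt <- h$counts; mid <- h$mids
  # smooth, find local maxima
  k <- stats::dnorm(-3:3, sd = 1.5); k <- k / sum(k)
  sm <- as.numeric(stats::filter(cnt, k, sides = 2))
  sm[is.na(sm)] <- cnt[is.na(sm)]
  is_peak <- sm >= c(-Inf, head(sm, -1)) & sm >= c(tail(sm, -1), -Inf) & sm > 0
  peaks <- which(is_peak)
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 3)]
  peaks <- peaks[order(sm[peaks], decreasing = TRUE)]
  # a genuine second mode: comparable height, well separated, with a real
  # valley between the two candidates (histogram wiggles do not qualify)
  if (length(peaks) >= 2) {
    p1 <- peaks[1]; p2 <- peaks[2]
    valley <- min(sm[min(p1, p2):max(p1, p2)])
    if (sm[p2] >= 0.8 * sm[p1] && abs(p2 - p1) > 6 &&
        valley < 0.6 * sm[p2])
      stop_ambiguous(paste0("no dominant mode in the all-points histogram ",
                            "(two comparable modes at %.3g and %.3g pA): ",
                            "choose the baseline level manually"),
                     mid[p1], mid[p2])
  }
  p <- peaks[1]
  # contiguous region around the mode with counts above 10% of the peak
  lo <- p; while (lo > 1 && cnt[lo - 1] > 0.1 * cnt[p]) lo <- lo - 1
  hi <- p; while (hi < length(cnt) && cnt[hi + 1] > 0.1 * cnt[p]) hi <- hi + 1
  sel <- lo:hi
  w0 <- max(diff(mid[1:2]), sqrt(sum(cnt[sel] * (mid[sel] - mid[p])^2) / max(1, sum(cnt[sel]))))
  fit <- tryCatch(
    nls(y ~ a * exp(-(m - mu)^2 / (2 * sig^2)),
        data = data.frame(y = cnt[sel], m = mid[sel]),
        start = list(a = cnt[p], mu = mid[p], sig = w0),
        control = list(warnOnly = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    list(center = unname(cf["mu"]), width = abs(unname(cf["sig"])),
         n_modes = length(peaks))
  } else {
    inwin <- x >= mid[lo] - diff(mid[1:2]) / 2 & x <= mid[hi] + diff(mid[1:2]) / 2
    list(center = mean(x[inwin]), width = sd(x[inwin]), n_modes = length(peaks))
  }
}

#' Estimate the static blockage baseline (I_p)
#'
#' Either fits a Gaussian to the dominant mode of the trace's all-points
#' histogram, or — mirroring the static pore-blockage protocol, in which a
#' repeated voltage protocol collects several hundred I_p events whose means
#' are fit to a Gaussian — fits the supplied static-blockage segment means.
#' The Gaussian center is the baseline mean and the width its SD.
#'
#' @param trace A `sense_trace` (ignored when `segment_means` is given).
#' @param segment_means Optional numeric vector of per-segment mean currents
#'   from a static blockage measurement (typically >= 500).
#' @param min_samples Minimum number of samples/segments required.
#' @return A `baseline_estimate`: list with `mean_Ip`, `sd_Ip`, `n`,
#'   `method`.
#' @export
estimate_baseline <- function(trace = NULL, segment_means = NULL,
                              min_samples = 100L) {
  if (!is.null(segment_means)) {
    x <- segment_means[is.finite(segment_means)]
    if (length(x) < min_samples)
      stop_insufficient("need >= %d static-blockage segment means, got %d",
                        min_samples, length(x))
    g <- fit_gaussian_mode(x)
    method <- "segment_means_gaussian"
  } else {
    stopifnot(inherits(trace, "sense_trace"))
    x <- trace$current
    if (length(x) < min_samples)
      stop_insufficient("trace too short for baseline estimation")
    g <- fit_gaussian_mode(x)
    method <- "all_points_gaussian"
  }
  structure(list(mean_Ip = g$center, sd_Ip = g$width, n = length(x),
                 method = method),
            class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("Baseline: I_p = %.3f pA (SD %.3f pA), n = %d, %s\n",
              x$mean_Ip, x$sd_Ip, x$n, x$method))
  invisible(x)
}

default_guard_samples <- function(acq) {
  if (is.null(acq$analog_corner)) return(0L)
  as.integer(ceiling(acq$sampling_rate / (2 * pi * acq$analog_corner)))
}

# Least-squares boundary refinement: around each provisional edge, slide the
# acquisition filter's step response (the known shape of a level transition)
# over +/- 6 samples and keep the shift with the smallest residual. With the
# filter off the template is a discrete unit step, so noiseless boundaries
# are returned unchanged.
refine_boundaries <- function(x, starts, ends, mean_Ip, nominal_delta_i, flt,
                              max_shift = 6L, pre = 8L, post = 24L) {
  n <- length(x)
  if (is.null(flt)) {
    sr <- rep(1, post + max_shift + 1L)
  } else {
    sr <- filter_iir_cpp(flt$b, flt$a, rep(1, post + max_shift + 1L))
  }
  L <- length(sr)
  st <- function(arg) {
    out <- sr[pmin(pmax(arg, 0L) + 1L, L)]
    out[arg < 0L] <- 0
    out
  }
  shifts <- -max_shift:max_shift
  g <- 4L
  for (i in seq_along(starts)) {
    a <- starts[i]; b <- ends[i]
    interior <- (a + g):(b - g)
    dI <- if (length(interior) >= 4L && interior[1] <= b - g)
      median(x[pmin(pmax(interior, 1L), n)]) - mean_Ip else nominal_delta_i
    midpt <- (a + b) %/% 2L
    # rising (entry) edge
    w <- max(1L, a - pre - max_shift):min(n, min(a + post + max_shift, midpt))
    if (length(w) > 2L * max_shift + 2L) {
      ss <- vapply(shifts, function(d) {
        pred <- mean_Ip + dI * st(w - (a + d))
        sum((x[w] - pred)^2)
      }, numeric(1))
      starts[i] <- a + shifts[which.min(ss)]
    }
    # falling (exit) edge
    w <- max(1L, max(b - pre - max_shift, midpt)):min(n, b + post + max_shift)
    if (length(w) > 2L * max_shift + 2L) {
      ss <- vapply(shifts, function(d) {
        pred <- mean_Ip + dI * (1 - st(w - (b + d)))
        sum((x[w] - pred)^2)
      }, numeric(1))
      ends[i] <- b + shifts[which.min(ss)]
    }
    if (ends[i] <= starts[i]) ends[i] <- starts[i] + 1L
  }
  list(starts = starts, ends = ends)
}

#' Detect blockage events on top of the baseline
#'
#' Half-amplitude threshold detection with hysteresis: the deviation from the
#' baseline (in the direction of `nominal_delta_i`) must reach 50% of the
#' nominal amplitude for an event to be called; the event extends over the
#' surrounding excursion that stays above 25%, with both reported boundaries
#' placed at the half-amplitude crossings. When the trace carries an analog
#' filter, boundaries are compensated for the filter's half-amplitude step
#' delay. Events shorter than `min_duration` are discarded.
#'
#' @param trace A `sense_trace`.
#' @param baseline A `baseline_estimate` (or list with `mean_Ip`, `sd_Ip`).
#' @param nominal_delta_i Expected blockage amplitude `I_b - I_p`, pA
#'   (signed).
#' @param min_duration Minimum event duration, s (default 3 samples).
#' @param enter_frac,exit_frac Hysteresis thresholds as fractions of the
#'   nominal amplitude.
#' @param k_sd Refuse detection if the entry threshold is within `k_sd`
#'   baseline SDs of the baseline.
#' @param refine Refine each boundary by a least-squares fit of the
#'   acquisition filter's step response around the provisional crossing
#'   (default `TRUE`); this suppresses the noise-induced jitter of a single
#'   threshold crossing.
#' @return An `event_table`: data.frame with one row per event
#'   (`event_id`, `cycle`, `start_sample`/`end_sample` 0-based half-open,
#'   `start_s`, `end_s`, `t_off_s`, `t_on_s`), with detection settings and
#'   the baseline attached as attributes.
#' @export
detect_events <- function(trace, baseline, nominal_delta_i,
                          min_duration = NULL, enter_frac = 0.5,
                          exit_frac = 0.25, k_sd = 3, refine = TRUE) {
  stopifnot(inherits(trace, "sense_trace"))
  fs <- trace$acq$sampling_rate
  min_duration <- min_duration %||% (3 / fs)
  amp <- abs(nominal_delta_i)
  if (amp * enter_frac <= k_sd * baseline$sd_Ip)
    stop_config(paste0("detection threshold (%.3g pA) is inside the baseline ",
                       "noise band (%g x SD = %.3g pA); increase the nominal ",
                       "amplitude or reduce noise"),
                amp * enter_frac, k_sd, k_sd * baseline$sd_Ip)
  sgn <- sign(nominal_delta_i)
  d <- sgn * (trace$current - baseline$mean_Ip)
  above_exit <- d >= amp * exit_frac
  above_enter <- d >= amp * enter_frac

  r <- rle(above_exit)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)
  cum_enter <- cumsum(above_enter)
  starts <- integer(0); ends <- integer(0)
  if (length(keep)) {
    n_enter <- cum_enter[run_end[keep]] - c(0L, cum_enter)[run_start[keep]]
    keep <- keep[n_enter > 0L]
    if (length(keep)) {
      # boundaries at the half-amplitude (enter) crossings within each run
      starts <- vapply(keep, function(k) {
        i <- run_start[k]
        i + which(above_enter[i:run_end[k]])[1] - 1L
      }, integer(1))
      ends <- vapply(keep, function(k) {
        i <- run_start[k]
        i + max(which(above_enter[i:run_end[k]])) # half-open end
      }, integer(1))
    }
  }

  delay <- 0
  flt <- acquisition_filter(trace$acq)
  if (!is.null(flt)) delay <- filter_delay_samples(flt)
  starts <- pmax(1L, starts - as.integer(round(delay)))
  ends <- pmax(starts + 1L, ends - as.integer(round(delay)))

  if (refine && length(starts)) {
    ref <- refine_boundaries(trace$current, starts, ends, baseline$mean_Ip,
                             nominal_delta_i, flt)
    starts <- ref$starts; ends <- ref$ends
  }

  dur <- (ends - starts) / fs
  ok <- dur >= min_duration
  starts <- starts[ok]; ends <- ends[ok]

  cycles <- trace$cycles %||% data.frame(cycle = 1L, t_start = 0,
                                         t_end = length(d) / fs)
  start_s <- (starts - 1L) / fs
  end_s <- (ends - 1L) / fs
  cyc_idx <- findInterval(start_s, cycles$t_start)
  cyc_idx[cyc_idx < 1L] <- 1L
  cyc <- cycles$cycle[cyc_idx]
  # events must lie inside an analyzed window (not in reload dead time)
  inside <- start_s < cycles$t_end[cyc_idx]
  starts <- starts[inside]; ends <- ends[inside]
  start_s <- start_s[inside]; end_s <- end_s[inside]; cyc <- cyc[inside]

  t_on <- rep(NA_real_, length(starts))
  if (length(starts) > 1L) {
    gap <- start_s[-1L] - end_s[-length(end_s)]
    same <- cyc[-1L] == cyc[-length(cyc)]
    t_on[-1L][same] <- gap[same]
  }
  ev <- data.frame(event_id = seq_along(starts), cycle = cyc,
                   start_sample = starts - 1L, end_sample = ends - 1L,
                   start_s = start_s, end_s = end_s,
                   t_off_s = (ends - starts) / fs, t_on_s = t_on)
  structure(ev,
            baseline = baseline,
            settings = list(nominal_delta_i = nominal_delta_i,
                            min_duration = min_duration,
                            enter_frac = enter_frac, exit_frac = exit_frac,
                            k_sd = k_sd, delay_samples = delay),
            cycles = cycles, sampling_rate = fs,
            class = c("event_table", "data.frame"))
}

#' @export
`[.event_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("baseline", "settings", "cycles", "sampling_rate"))
      attr(out, a) <- attr(x, a)
    class(out) <- c("event_table", "data.frame")
  }
  out
}

#' Annotate events with amplitude and level-noise statistics
#'
#' Fills `delta_I_pA` (= event mean level - baseline mean; positive-going
#' events have positive values) and `level_sd_pA`, computed over the event
#' window with edge guard bands excluded to avoid transition smearing. Events
#' too short for the guard bands are computed on the full window and flagged.
#'
#' @param trace The `sense_trace` the events came from.
#' @param events An `event_table` from [detect_events()].
#' @param guard_samples Samples trimmed from each event edge (default: one
#'   analog-filter time constant).
#' @return The `event_table` with `delta_I_pA`, `level_sd_pA`,
#'   `guard_flag` columns added.
#' @export
annotate_events <- function(trace, events, guard_samples = NULL) {
  stopifnot(inherits(trace, "sense_trace"), inherits(events, "event_table"))
  g <- guard_samples %||% default_guard_samples(trace$acq)
  baseline <- attr(events, "baseline")
  x <- trace$current
  n_ev <- nrow(events)
  dI <- lsd <- numeric(n_ev); flag <- logical(n_ev)
  for (i in seq_len(n_ev)) {
    a <- events$start_sample[i] + 1L
    b <- events$end_sample[i]            # half-open: last sample is b
    if (b - a + 1L > 2L * g + 1L) {
      idx <- (a + g):(b - g)
    } else {
      idx <- a:b
      flag[i] <- TRUE
    }
    dI[i] <- mean(x[idx]) - baseline$mean_Ip
    lsd[i] <- if (length(idx) > 1L) sd(x[idx]) else 0
  }
  events$delta_I_pA <- dI
  events$level_sd_pA <- lsd
  events$guard_flag <- flag
  attr(events, "settings")$guard_samples <- g
  events
}

#' Resolve sub-level structure within an event
#'
#' Segments the bound region of an event into up to `n_levels` discrete
#' current levels (e.g. dynamic switching between two bound intermediates,
#' `I_b1` and `I_b2`): k-means level clustering on a median-filtered signal,
#' followed by run segmentation with short runs merged into their
#' predecessor. Clusters closer than `2 x` the within-level noise are
#' collapsed with a warning. The transition-count matrix includes the
#' baseline as entry/exit state.
#'
#' @param trace The parent `sense_trace`.
#' @param event One row of an `event_table` (data.frame row).
#' @param n_levels Requested number of bound levels (1..3).
#' @param min_segment Minimum sub-level segment length, samples.
#' @param median_k Median-filter window (odd), samples.
#' @return List with `segments` (level, t_start_s, t_end_s, mean_pA),
#'   `transitions` (count matrix among baseline + levels), `levels`
#'   (sorted level means), `collapsed` (logical).
#' @export
idealize_sublevels <- function(trace, event, n_levels, min_segment = 3L,
                               median_k = 5L) {
  stopifnot(inherits(trace, "sense_trace"))
  if (!n_levels %in% 1:3) stop_config("n_levels must be 1, 2 or 3")
  fs <- trace$acq$sampling_rate
  a <- event$start_sample + 1L
  b <- event$end_sample
  x <- trace$current[a:b]
  if (length(x) < 2L * min_segment)
    stop_insufficient("event too short for sub-level segmentation")
  xf <- if (length(x) > median_k) runmed(x, median_k) else x
  # level noise from robust first differences of the raw signal: immune to
  # the level structure itself (level switches are sparse outliers in diff)
  level_noise <- median(abs(diff(x))) / (0.6745 * sqrt(2))

  collapsed <- FALSE
  k <- n_levels
  repeat {
    if (k == 1L) {
      assign <- rep(1L, length(xf))
      centers <- mean(xf)
      break
    }
    km <- suppressWarnings(kmeans(xf, centers = k, nstart = 5, iter.max = 50))
    ord <- order(km$centers)
    centers <- sort(as.numeric(km$centers))
    assign <- match(km$cluster, ord)
    if (min(diff(centers)) >= 2 * level_noise) break
    k <- k - 1L
    collapsed <- TRUE
  }
  if (collapsed)
    warning(sprintf("cluster separation below 2x level noise: collapsed to %d level(s)", k))

  # merge runs shorter than min_segment into the previous run
  r <- rle(assign)
  if (length(r$lengths) > 1L) {
    merged_vals <- r$values; merged_lens <- r$lengths
    i <- 2L
    while (i <= length(merged_lens)) {
      if (merged_lens[i] < min_segment) {
        merged_lens[i - 1L] <- merged_lens[i - 1L] + merged_lens[i]
        merged_vals <- merged_vals[-i]; merged_lens <- merged_lens[-i]
        # re-merge identical neighbours
        if (i <= length(merged_vals) && merged_vals[i - 1L] == merged_vals[i]) {
          merged_lens[i - 1L] <- merged_lens[i - 1L] + merged_lens[i]
          merged_vals <- merged_vals[-i]; merged_lens <- merged_lens[-i]
        }
      } else i <- i + 1L
    }
    r <- list(values = merged_vals, lengths = merged_lens)
  }
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  seg_mean <- vapply(seq_along(r$values),
                     function(j) mean(x[seg_start[j]:seg_end[j]]), numeric(1))
  segments <- data.frame(
    level = paste0("L", r$values),
    t_start_s = (a - 1L + seg_start - 1L) / fs,
    t_end_s = (a - 1L + seg_end) / fs,
    mean_pA = seg_mean)

  lev_names <- paste0("L", seq_len(k))
  states <- c("base", lev_names)
  trans <- matrix(0L, length(states), length(states),
                  dimnames = list(states, states))
  seq_states <- c("base", paste0("L", r$values), "base")
  for (j in seq_len(length(seq_states) - 1L))
    trans[seq_states[j], seq_states[j + 1L]] <-
      trans[seq_states[j], seq_states[j + 1L]] + 1L
  list(segments = segments, transitions = trans,
       levels = setNames(centers, lev_names), collapsed = collapsed)
}
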