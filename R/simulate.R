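# Higher-level simulation drivers: concentration series, irreversible runs
# with voltage-reload cycles, and labelled mixtures.

#' Simulate a concentration titration series
#'
#' One trace per concentration, with per-trace seeds derived
#' deterministically from the master seed, so a repeated call with the same
#' master seed reproduces the series bit for bit.
#'
#' @inheritParams simulate_trace
#' @param concentrations Vector of analyte concentrations, mol/L.
#' @param seed Master seed.
#' @return Named list of `sense_trace` objects (names = concentration).
#' @export
simulate_concentration_series <- function(scheme, concentrations, duration,
                                          noise = noise_model(0),
                                          acq = acquisition(), seed = NULL) {
  if (length(concentrations) == 0)
    stop_config("empty concentration list")
  if (length(unique(concentrations)) < 2L)
    warning("fewer than 2 distinct concentrations: no titration slope can be fit")
  traces <- lapply(seq_along(concentrations), function(i) {
    simulate_trace(scheme, concentrations[i], duration, noise, acq,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, 10L + i))
  })
  names(traces) <- as.character(concentrations)
  traces
}

#' Simulate repeated measurement cycles of an irreversible reaction
#'
#' For a scheme with an absorbing state (an irreversibly reacted strand), a
#' single docked strand stops reporting events once absorbed. The
#' voltage-reload protocol ejects the strand and docks a fresh one, starting
#' a new measurement cycle; a fixed dead time separates cycles (ejection and
#' recapture). Ground truth records the cycle index of every segment.
#'
#' @inheritParams simulate_trace
#' @param n_cycles Number of measurement cycles (`n_cycles - 1` reloads).
#' @param cycle_duration Analyzed duration of each cycle, s.
#' @param dead_time Dead time between cycles, s (default 1).
#' @param linger If non-`NULL`, the reload is event-driven: the cycle ends
#'   `linger` seconds after absorption (capped at `cycle_duration`).
#' @return A `sense_trace`; its `path` carries per-cycle ground truth and
#'   `cycles` the analyzed window of each cycle.
#' @export
simulate_irreversible_run <- function(scheme, concentration, n_cycles,
                                      cycle_duration, dead_time = 1,
                                      linger = NULL, noise = noise_model(0),
                                      acq = acquisition(), seed = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (n_cycles < 1) stop_config("n_cycles must be >= 1")
  has_absorbing <- any(scheme$states$absorbing)
  if (has_absorbing && n_cycles == 1L)
    warning("absorbing state present but no reload scheduled: single-cycle run")
  absorbing_states <- scheme$states$name[scheme$states$absorbing]

  segs <- vector("list", 2L * n_cycles)
  t <- 0
  for (j in seq_len(n_cycles)) {
    p <- sample_state_path(scheme, concentration, cycle_duration,
                           seed = if (is.null(seed)) NULL else derive_seed(seed, 100L + j),
                           t0 = t, cycle = j)
    if (!is.null(linger) && length(absorbing_states)) {
      hit <- which(p$state %in% absorbing_states)[1]
      if (!is.na(hit)) {
        t_cut <- min(p$t_start[hit] + linger, t + cycle_duration)
        p <- p[p$t_start < t_cut, , drop = FALSE]
        p$t_end[nrow(p)] <- t_cut
      }
    }
    t <- max(p$t_end)
    segs[[2L * j - 1L]] <- p
    if (j < n_cycles && dead_time > 0) {
      segs[[2L * j]] <- data.frame(state = ".dead", t_start = t,
                                   t_end = t + dead_time, cycle = j)
      t <- t + dead_time
    }
  }
  path <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  path <- structure(path, duration = t, t0 = 0, scheme = scheme,
                    concentration = concentration,
                    class = c("state_path", "data.frame"))
  acq$duration <- t
  render_trace(path, scheme, noise, acq,
               seed = if (is.null(seed)) NULL else derive_seed(seed, 2L),
               meta = list(concentration = concentration, master_seed = seed,
                           dead_time = dead_time))
}

#' Simulate a labelled mixture of analyte classes
#'
#' Emulates simultaneous sensing of several analytes through one nano-reactor:
#' binding events are interleaved on a shared baseline, each event drawn
#' independently from one class per `proportions`; the generating class of
#' every event is recorded as ground truth. Each class is a scheme sharing the
#' baseline level, optionally with its own bound-state noise signature.
#'
#' @param classes Named list; each element is a list with `scheme` (a
#'   [kinetic_scheme()]) and optionally `noise` (a [noise_model()] whose
#'   `state_noise` applies to that class's bound states).
#' @param proportions Numeric vector summing to 1, one entry per class.
#' @param concentration Analyte concentration, mol/L (shared).
#' @param duration Trace duration, s.
#' @param baseline_sd White baseline noise SD, pA.
#' @param acq An [acquisition()].
#' @param seed Integer seed.
#' @return A `sense_trace`; `meta$event_labels` is a data.frame
#'   `(t_start, t_end, class)` of ground-truth events.
#' @export
simulate_mixture <- function(classes, proportions, concentration, duration,
                             baseline_sd = 0, acq = acquisition(), seed = NULL) {
  if (length(classes) != length(proportions))
    stop_config("one proportion per class required")
  if (abs(sum(proportions) - 1) > 1e-8)
    stop_config("proportions must sum to 1")
  if (is.null(names(classes)) || any(names(classes) == ""))
    stop_config("classes must be named")
  schemes <- lapply(classes, `[[`, "scheme")
  base_levels <- vapply(schemes, function(s)
    s$states$current_pA[s$states$name == s$baseline], numeric(1))
  if (max(base_levels) - min(base_levels) > 1e-9)
    stop_config("all class schemes must share the baseline level (got %s)",
                paste(signif(base_levels, 6), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  base_name <- schemes[[1]]$baseline
  base_i <- base_levels[[1]]
  # per-class entry rate from baseline at this concentration
  entry_rate <- vapply(schemes, function(s) {
    r <- effective_rates(s, concentration)
    sum(r$rate[r$from == s$baseline])
  }, numeric(1))
  agg_rate <- sum(proportions * entry_rate)

  seg_state <- character(0); seg_start <- numeric(0); seg_end <- numeric(0)
  lab_start <- numeric(0); lab_end <- numeric(0); lab_class <- character(0)
  t <- 0
  while (t < duration) {
    gap <- if (agg_rate > 0) rexp(1, agg_rate) else Inf
    t_event <- t + gap
    seg_state <- c(seg_state, base_name)
    seg_start <- c(seg_start, t); seg_end <- c(seg_end, min(t_event, duration))
    if (t_event >= duration) break
    k <- sample.int(length(classes), 1L, prob = proportions)
    cls <- names(classes)[k]
    sch <- schemes[[k]]
    rts <- effective_rates(sch, concentration)
    ent <- rts[rts$from == sch$baseline & rts$rate > 0, , drop = FALSE]
    state <- if (nrow(ent) == 1L) ent$to else
      ent$to[sample.int(nrow(ent), 1L, prob = ent$rate)]
    # walk within the class scheme until return to baseline
    te <- t_event
    ev_start <- t_event
    out <- split(rts[c("to", "rate")], rts$from)
    while (state != sch$baseline && te < duration) {
      o <- out[[state]]
      total <- if (is.null(o)) 0 else sum(o$rate)
      dwell <- if (total > 0) rexp(1, total) else duration - te
      seg_state <- c(seg_state, paste0(cls, ":", state))
      seg_start <- c(seg_start, te); seg_end <- c(seg_end, min(te + dwell, duration))
      te <- te + dwell
      if (total <= 0) break
      state <- if (nrow(o) == 1L) o$to else o$to[sample.int(nrow(o), 1L, prob = o$rate)]
    }
    lab_start <- c(lab_start, ev_start)
    lab_end <- c(lab_end, min(te, duration))
    lab_class <- c(lab_class, cls)
    t <- te
  }
  path <- data.frame(state = seg_state, t_start = seg_start, t_end = seg_end,
                     cycle = 1L, stringsAsFactors = FALSE)
  path <- structure(path, duration = duration, t0 = 0,
                    concentration = concentration,
                    class = c("state_path", "data.frame"))

  # combined pseudo-scheme + noise model for rendering
  st_rows <- list(data.frame(name = base_name, current_pA = base_i,
                             absorbing = FALSE))
  state_noise <- list()
  for (k in seq_along(classes)) {
    cls <- names(classes)[k]
    sch <- schemes[[k]]
    other <- sch$states[sch$states$name != sch$baseline, , drop = FALSE]
    if (nrow(other)) {
      other$name <- paste0(cls, ":", other$name)
      other$absorbing <- FALSE
      st_rows[[length(st_rows) + 1L]] <- other
    }
    nz <- classes[[k]]$noise
    if (!is.null(nz)) {
      for (nm in names(nz$state_noise))
        state_noise[[paste0(cls, ":", nm)]] <- nz$state_noise[[nm]]
    }
  }
  states <- do.call(rbind, st_rows)
  combined <- kinetic_scheme(states,
                             data.frame(from = character(0), to = character(0),
                                        rate = numeric(0),
                                        conc_coupled = logical(0)),
                             baseline = base_name)
  acq$duration <- duration
  tr <- render_trace(path, combined, noise_model(baseline_sd, state_noise),
                     acq, seed = NULL,
                     meta = list(concentration = concentration,
                                 master_seed = seed))
  tr$meta$event_labels <- data.frame(t_start = lab_start, t_end = lab_end,
                                     class = lab_class,
                                     stringsAsFactors = FALSE)
  tr
}
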