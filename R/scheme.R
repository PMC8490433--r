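#' Define a kinetic scheme for a stochastic-sensing nano-reactor
#'
#' A kinetic scheme is a continuous-time Markov model of the sensing strand:
#' named states with mean current levels (pA) and directed transition rates.
#' Rates flagged as concentration-coupled are multiplied by the mobile-analyte
#' concentration (mol/L) at simulation time, so a two-state instance with
#' association rate `k_on * c` and dissociation rate `k_off` is the standard
#' single-step bimolecular binding / unimolecular dissociation model.
#'
#' @param states data.frame with columns `name`, `current_pA` and optionally
#'   `absorbing` (logical; irreversible end states such as an oxidized
#'   reactant).
#' @param rates data.frame with columns `from`, `to`, `rate` (s^-1, or
#'   M^-1 s^-1 when concentration-coupled) and optionally `conc_coupled`
#'   (logical).
#' @param baseline Name of the baseline state: the static blockage level
#'   `I_p` on top of which binding events are observed.
#' @param open_pore_pA Optional open-pore current `I_0` (metadata only; the
#'   strand is docked throughout a run).
#' @return An object of class `kinetic_scheme`.
#' @examples
#' sch <- two_state_scheme(k_on = 1e4, k_off = 5, i_p = 160, delta_i = -60)
#' print(sch)
#' @export
kinetic_scheme <- function(states, rates, baseline, open_pore_pA = NULL) {
  states <- as.data.frame(states)
  rates <- as.data.frame(rates)
  if (!all(c("name", "current_pA") %in% names(states)))
    stop_config("`states` needs columns 'name' and 'current_pA'")
  if (is.null(states$absorbing)) states$absorbing <- FALSE
  states$name <- as.character(states$name)
  if (anyDuplicated(states$name))
    stop_config("duplicate state names: %s",
                paste(unique(states$name[duplicated(states$name)]), collapse = ", "))
  if (!all(is.finite(states$current_pA)))
    stop_config("state mean currents must be finite")
  if (!all(c("from", "to", "rate") %in% names(rates)))
    stop_config("`rates` needs columns 'from', 'to' and 'rate'")
  if (is.null(rates$conc_coupled)) rates$conc_coupled <- FALSE
  rates$from <- as.character(rates$from)
  rates$to <- as.character(rates$to)
  unknown <- setdiff(c(rates$from, rates$to), states$name)
  if (length(unknown))
    stop_config("rate refers to unknown state(s): %s", paste(unknown, collapse = ", "))
  if (any(!is.finite(rates$rate)) || any(rates$rate < 0))
    stop_config("all rates must be finite and >= 0")
  if (any(rates$from == rates$to))
    stop_config("self-transitions are not allowed")
  if (length(baseline) != 1L || !baseline %in% states$name)
    stop_config("`baseline` must name exactly one state")
  bad <- intersect(states$name[states$absorbing],
                   rates$from[rates$rate > 0])
  if (length(bad))
    stop_config("absorbing state(s) with nonzero exit rate: %s",
                paste(bad, collapse = ", "))
  structure(list(states = states, rates = rates, baseline = baseline,
                 open_pore_pA = open_pore_pA),
            class = "kinetic_scheme")
}

#' Two-state binding scheme
#'
#' Convenience constructor for the canonical telegraph model: baseline
#' blockage level `I_p` and one bound level `I_b = I_p + delta_i`, with
#' concentration-coupled association `k_on` (M^-1 s^-1) and dissociation
#' `k_off` (s^-1). `K_b = k_on / k_off`.
#'
#' @param k_on Association rate constant, M^-1 s^-1.
#' @param k_off Dissociation rate constant, s^-1.
#' @param i_p Baseline (static blockage) current, pA.
#' @param delta_i Blockage amplitude `I_b - I_p`, pA (negative-going events
#'   have `delta_i < 0`).
#' @param bound_name,baseline_name State names.
#' @return A `kinetic_scheme`.
#' @export
two_state_scheme <- function(k_on, k_off, i_p = 160, delta_i = -60,
                             bound_name = "Ib", baseline_name = "Ip") {
  kinetic_scheme(
    states = data.frame(name = c(baseline_name, bound_name),
                        current_pA = c(i_p, i_p + delta_i),
                        absorbing = FALSE),
    rates = data.frame(from = c(baseline_name, bound_name),
                       to = c(bound_name, baseline_name),
                       rate = c(k_on, k_off),
                       conc_coupled = c(TRUE, FALSE)),
    baseline = baseline_name)
}

#' Add an irreversible (absorbing) branch to a scheme
#'
#' Appends an absorbing state (e.g. an oxidized, unreactive strand) reached
#' from `from` at rate `rate` (s^-1). Once entered, no further transitions
#' occur until a voltage reload.
#'
#' @param scheme A `kinetic_scheme`.
#' @param from State from which absorption occurs.
#' @param rate Absorption rate, s^-1.
#' @param name Name of the absorbing state.
#' @param current_pA Mean current of the absorbing state; defaults to the
#'   baseline current (a quiet, fluctuation-free baseline).
#' @return A `kinetic_scheme`.
#' @export
add_absorbing_state <- function(scheme, from, rate, name = "terminated",
                                current_pA = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  base_i <- scheme$states$current_pA[scheme$states$name == scheme$baseline]
  states <- rbind(scheme$states,
                  data.frame(name = name, current_pA = current_pA %||% base_i,
                             absorbing = TRUE))
  rates <- rbind(scheme$rates,
                 data.frame(from = from, to = name, rate = rate,
                            conc_coupled = FALSE))
  kinetic_scheme(states, rates, scheme$baseline, scheme$open_pore_pA)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme:", nrow(x$states), "states,",
      nrow(x$rates), "transitions\n")
  cat("  baseline state:", x$baseline, "\n")
  st <- x$states
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %-12s %8.2f pA%s\n", st$name[i], st$current_pA[i],
                if (st$absorbing[i]) "  [absorbing]" else ""))
  rt <- x$rates
  for (i in seq_len(nrow(rt)))
    cat(sprintf("  %s -> %s : %g %s\n", rt$from[i], rt$to[i], rt$rate[i],
                if (rt$conc_coupled[i]) "M^-1 s^-1 (x [analyte])" else "s^-1"))
  invisible(x)
}

#' Describe state-dependent noise for trace rendering
#'
#' Baseline thermal/amplifier noise is white Gaussian with SD `baseline_sd`
#' (pA, before acquisition filtering) on every sample. On top of that, any
#' state can carry an extra component emulating the characteristic bound-state
#' fluctuations seen in stochastic sensing: either extra broadband Gaussian
#' noise (`broadband_sd`, pA) or a secondary two-state telegraph fluctuation
#' superimposed on the level (`telegraph_amp` pA peak-to-peak, with
#' `telegraph_rates = c(up_rate, down_rate)` in s^-1).
#'
#' @param baseline_sd White-noise SD in pA, applied to all samples.
#' @param state_noise Named list keyed by state name. Each element is a list
#'   with either `broadband_sd`, or `telegraph_amp` + `telegraph_rates`.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(2, state_noise = list(
#'   Ib = list(telegraph_amp = 10, telegraph_rates = c(20, 20))))
#' @export
noise_model <- function(baseline_sd = 0, state_noise = list()) {
  if (!is.finite(baseline_sd) || baseline_sd < 0)
    stop_config("baseline_sd must be >= 0")
  for (nm in names(state_noise)) {
    comp <- state_noise[[nm]]
    if (!is.null(comp$broadband_sd) && comp$broadband_sd < 0)
      stop_config("broadband_sd for state '%s' must be >= 0", nm)
    if (!is.null(comp$telegraph_amp)) {
      if (comp$telegraph_amp < 0)
        stop_config("telegraph_amp for state '%s' must be >= 0", nm)
      r <- comp$telegraph_rates
      if (is.null(r) || length(r) != 2L || any(r < 0))
        stop_config("telegraph_rates for state '%s' must be two rates >= 0", nm)
    }
  }
  structure(list(baseline_sd = baseline_sd, state_noise = state_noise),
            class = "noise_model")
}

#' Acquisition settings for trace rendering
#'
#' Emulates digitisation of a patch-clamp recording: sampling rate, analog
#' low-pass (anti-alias/bandwidth) filter, and an optional repeating voltage
#' protocol kept as metadata.
#'
#' @param sampling_rate Samples per second (default 25 kHz).
#' @param analog_corner Low-pass corner frequency in Hz (default 1 kHz);
#'   `NULL` disables filtering.
#' @param filter_order Analog filter order (poles), default 4.
#' @param filter_type `"bessel"` (default; Axopatch-style constant group
#'   delay) or `"butterworth"`.
#' @param voltage_protocol Optional data.frame `(level_mV, duration_s)`
#'   describing a repeated protocol, e.g. +180 mV (0.9 s) / -100 mV (0.3 s).
#' @param duration Recording duration in seconds.
#' @return An object of class `acquisition`.
#' @export
acquisition <- function(sampling_rate = 25000, analog_corner = 1000,
                        filter_order = 4, filter_type = c("bessel", "butterworth"),
                        voltage_protocol = NULL, duration = NULL) {
  filter_type <- match.arg(filter_type)
  if (sampling_rate <= 0) stop_config("sampling_rate must be > 0")
  if (!is.null(analog_corner)) {
    if (analog_corner <= 0 || analog_corner >= sampling_rate / 2)
      stop_config("analog_corner must satisfy 0 < corner < sampling_rate/2")
  }
  if (!is.null(duration) && duration <= 0) stop_config("duration must be > 0")
  structure(list(sampling_rate = sampling_rate, analog_corner = analog_corner,
                 filter_order = as.integer(filter_order),
                 filter_type = filter_type,
                 voltage_protocol = voltage_protocol, duration = duration),
            class = "acquisition")
}
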