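# Continuous-time Markov (Gillespie) sampling of the state path.

effective_rates <- function(scheme, concentration) {
  r <- scheme$rates
  mult <- ifelse(r$conc_coupled, concentration, 1)
  data.frame(from = r$from, to = r$to, rate = r$rate * mult,
             stringsAsFactors = FALSE)
}

#' Sample a ground-truth state path by the Gillespie algorithm
#'
#' Draws a continuous-time Markov path through the scheme: the dwell in each
#' state is exponential with that state's total exit rate, the successor is
#' chosen with probability proportional to the individual rates, and rates
#' flagged concentration-coupled are multiplied by `concentration` (mol/L).
#' The path starts in the baseline state and ends at `duration`, or spends the
#' remaining time in an absorbing state once one is entered.
#'
#' @param scheme A [kinetic_scheme()].
#' @param concentration Mobile-analyte concentration, mol/L (>= 0).
#' @param duration Path duration, s.
#' @param seed Optional integer seed.
#' @param start_state Starting state (default: the scheme baseline).
#' @param t0 Path start time (used internally for reload cycles).
#' @param cycle Cycle index attached to every segment.
#' @return A `state_path`: data.frame with columns `state`, `t_start`,
#'   `t_end`, `cycle`; attributes `duration` and `scheme`.
#' @examples
#' sch <- two_state_scheme(1e4, 5)
#' p <- sample_state_path(sch, concentration = 1e-3, duration = 10, seed = 1)
#' head(p)
#' @export
sample_state_path <- function(scheme, concentration, duration, seed = NULL,
                              start_state = NULL, t0 = 0, cycle = 1L) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (duration <= 0) stop_config("duration must be > 0")
  if (concentration < 0) stop_config("concentration must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  rates <- effective_rates(scheme, concentration)
  start_state <- start_state %||% scheme$baseline
  if (!start_state %in% scheme$states$name)
    stop_config("unknown start state '%s'", start_state)

  t_end_abs <- t0 + duration
  # pre-split outgoing rates per state
  out <- split(rates[c("to", "rate")], rates$from)
  state <- start_state
  t <- t0
  seg_state <- character(0); seg_start <- numeric(0); seg_end <- numeric(0)
  repeat {
    o <- out[[state]]
    total <- if (is.null(o)) 0 else sum(o$rate)
    if (total <= 0) {               # absorbing (or dead-end) state
      seg_state <- c(seg_state, state)
      seg_start <- c(seg_start, t); seg_end <- c(seg_end, t_end_abs)
      break
    }
    dwell <- rexp(1, total)
    if (t + dwell >= t_end_abs) {
      seg_state <- c(seg_state, state)
      seg_start <- c(seg_start, t); seg_end <- c(seg_end, t_end_abs)
      break
    }
    seg_state <- c(seg_state, state)
    seg_start <- c(seg_start, t); seg_end <- c(seg_end, t + dwell)
    t <- t + dwell
    nxt <- if (nrow(o) == 1L) o$to else
      o$to[sample.int(nrow(o), 1L, prob = o$rate)]
    state <- nxt
  }
  path <- data.frame(state = seg_state, t_start = seg_start, t_end = seg_end,
                     cycle = cycle, stringsAsFactors = FALSE)
  structure(path, duration = duration, t0 = t0, scheme = scheme,
            concentration = concentration,
            class = c("state_path", "data.frame"))
}

# Time spent in each state of a path (named numeric, seconds).
path_occupancy <- function(path) {
  occ <- tapply(path$t_end - path$t_start, path$state, sum)
  setNames(as.numeric(occ), names(occ))
}

# Dwell times of completed visits to `state` (last segment of each cycle is
# right-censored and excluded).
path_dwells <- function(path, state) {
  idx <- which(path$state == state)
  last_per_cycle <- tapply(seq_len(nrow(path)), path$cycle, max)
  idx <- setdiff(idx, as.integer(last_per_cycle))
  path$t_end[idx] - path$t_start[idx]
}
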