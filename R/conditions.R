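# Classed conditions so callers (and the command-line wrapper) can map
# failure modes to exit codes: config 2, data integrity 3, insufficient data 4.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("stochsense_config_error", "stochsense_error")))
}

stop_integrity <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("stochsense_integrity_error", "stochsense_error")))
}

stop_insufficient <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("stochsense_insufficient_data_error", "stochsense_error")))
}

stop_ambiguous <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("stochsense_ambiguity_error",
                                "stochsense_config_error", "stochsense_error")))
}

#' Map a stochsense condition to a process exit code
#'
#' Used by the command-line wrapper: 0 success, 2 configuration error,
#' 3 data-integrity error, 4 insufficient data, 1 anything else.
#'
#' @param cond A condition object.
#' @return Integer exit code.
#' @keywords internal
exit_code_for <- function(cond) {
  if (inherits(cond, "stochsense_config_error")) return(2L)
  if (inherits(cond, "stochsense_integrity_error")) return(3L)
  if (inherits(cond, "stochsense_insufficient_data_error")) return(4L)
  1L
}

# Deterministic child-seed derivation: a Lehmer step on the master seed mixed
# with the stream index, kept inside the 32-bit signed range.
derive_seed <- function(master, k) {
  m <- 2147483647
  s <- (as.numeric(master) %% m + 1)
  s <- (s * 48271) %% m
  as.integer((s + 104729 * as.numeric(k)) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
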