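#' Fit the two-state binding kinetics of a concentration series
#'
#' The central estimator: from event tables recorded at several analyte
#' concentrations, fit the dwell-time (`t_off`) and inter-event (`t_on`)
#' distributions per concentration, then recover the rate constants of the
#' single-step binding model — `1/tau_on = k_on * c` (slope of the titration
#' line), `1/tau_off = k_off` (mean across conditions) and
#' `K_b = k_on / k_off`.
#'
#' @param events A list of `event_table`s (or data.frames with `t_off_s`
#'   and `t_on_s` columns), one per concentration; or a single data.frame
#'   with a `concentration` column.
#' @param concentration Concentrations (mol/L) matching `events` when a
#'   list is given.
#' @param t_min Left truncation applied to the dwell MLE, s (the detector's
#'   minimum resolvable duration).
#' @param method Dwell estimator: `"mle"` (truncated-exponential MLE,
#'   default) or `"histogram"`.
#' @param force_origin Constrain the titration line through the origin.
#' @return An object of class `binding_kinetics` with components
#'   `rates` (k_on, k_off, K_b and SEs), `by_concentration` (per-condition
#'   tau fits), `kon_fit`, `koff_fit`, and `call`. Supported methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`.
#' @examples
#' \donttest{
#' sch <- two_state_scheme(1e4, 5, i_p = 160, delta_i = -60)
#' conc <- c(4, 7, 10) * 1e-4
#' traces <- simulate_concentration_series(sch, conc, duration = 60,
#'   noise = noise_model(2), seed = 42)
#' bl <- list(mean_Ip = 160, sd_Ip = 2)
#' evs <- lapply(traces, function(tr)
#'   detect_events(tr, bl, nominal_delta_i = -60))
#' fit <- fit_binding_kinetics(evs, concentration = conc)
#' coef(fit)
#' }
#' @export
fit_binding_kinetics <- function(events, concentration = NULL, t_min = 0,
                                 method = c("mle", "histogram"),
                                 force_origin = FALSE) {
  method <- match.arg(method)
  cl <- match.call()
  if (is.data.frame(events)) {
    if (is.null(events$concentration))
      stop_config("stacked event table needs a 'concentration' column")
    events <- split(events, events$concentration)
    concentration <- as.numeric(names(events))
  }
  if (is.null(concentration) || length(concentration) != length(events))
    stop_config("one concentration per event table required")
  fit1 <- function(v, kind) {
    v <- v[is.finite(v) & v > 0]
    if (method == "mle") fit_exponential_mle(v, t_min = t_min)
    else fit_exponential_histogram(v, t_min = t_min)
  }
  off_fits <- lapply(events, function(e) fit1(e$t_off_s, "t_off"))
  on_fits <- lapply(events, function(e) fit1(e$t_on_s, "t_on"))
  kon <- estimate_kon(concentration, on_fits, force_origin = force_origin)
  koff <- estimate_koff(off_fits, concentration = concentration)
  kb <- compute_Kb(kon, koff)
  by_conc <- data.frame(
    concentration = concentration,
    n_events = vapply(events, nrow, integer(1)),
    tau_on = vapply(on_fits, `[[`, numeric(1), "tau"),
    se_tau_on = vapply(on_fits, `[[`, numeric(1), "se_tau"),
    tau_off = vapply(off_fits, `[[`, numeric(1), "tau"),
    se_tau_off = vapply(off_fits, `[[`, numeric(1), "se_tau"),
    row.names = NULL)
  structure(list(
    rates = list(k_on = kon$k_on, se_k_on = kon$se,
                 k_off = koff$k_off, se_k_off = koff$se,
                 K_b = kb$K_b, se_K_b = kb$se),
    by_concentration = by_conc,
    kon_fit = kon, koff_fit = koff,
    method = method, t_min = t_min, force_origin = force_origin,
    call = cl),
    class = "binding_kinetics")
}

#' @export
print.binding_kinetics <- function(x, ...) {
  r <- x$rates
  cat("Two-state binding kinetics\n")
  cat(sprintf("  k_on  = %.4g +/- %.2g M^-1 s^-1\n", r$k_on, r$se_k_on))
  cat(sprintf("  k_off = %.4g +/- %.2g s^-1\n", r$k_off, r$se_k_off))
  cat(sprintf("  K_b   = %.4g +/- %.2g M^-1\n", r$K_b, r$se_K_b))
  cat(sprintf("  (%d concentrations, %d events, %s dwell fits)\n",
              nrow(x$by_concentration), sum(x$by_concentration$n_events),
              x$method))
  invisible(x)
}

#' @export
coef.binding_kinetics <- function(object, ...) {
  r <- object$rates
  c(k_on = r$k_on, k_off = r$k_off, K_b = r$K_b)
}

#' @export
summary.binding_kinetics <- function(object, ...) {
  structure(list(object = object), class = "summary.binding_kinetics")
}

#' @export
print.summary.binding_kinetics <- function(x, ...) {
  o <- x$object
  print(o)
  cat("\nPer-concentration dwell fits:\n")
  bc <- o$by_concentration
  bc$rate_on <- 1 / bc$tau_on
  bc$rate_off <- 1 / bc$tau_off
  print(format(bc, digits = 4), row.names = FALSE)
  cat(sprintf("\nTitration intercept: %.3g +/- %.2g s^-1 (expected ~ 0)\n",
              o$kon_fit$intercept, o$kon_fit$intercept_se))
  if (!is.null(o$koff_fit$conc_slope))
    cat(sprintf("1/tau_off vs c slope: %.3g +/- %.2g (expected ~ 0)\n",
                o$koff_fit$conc_slope, o$koff_fit$conc_slope_se))
  if (o$kon_fit$flagged)
    cat("WARNING: non-positive titration slope; k_on not interpretable\n")
  invisible(x)
}

#' Predicted event rate and occupancy at new concentrations
#'
#' @param object A `binding_kinetics` fit.
#' @param newdata data.frame with a `concentration` column (mol/L), or a
#'   numeric vector of concentrations.
#' @param ... Unused.
#' @return data.frame with `concentration`, expected event rate
#'   `rate_on` (= k_on * c, s^-1), `tau_on`, and equilibrium bound fraction
#'   `occupancy` (= c*K_b / (1 + c*K_b)).
#' @export
predict.binding_kinetics <- function(object, newdata, ...) {
  cc <- if (is.data.frame(newdata)) newdata$concentration else as.numeric(newdata)
  r <- object$rates
  rate_on <- r$k_on * cc
  data.frame(concentration = cc, rate_on = rate_on,
             tau_on = ifelse(rate_on > 0, 1 / rate_on, Inf),
             occupancy = cc * r$K_b / (1 + cc * r$K_b))
}

#' @export
plot.binding_kinetics <- function(x, ...) {
  bc <- x$by_concentration
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(bc$concentration * 1e3, 1 / bc$tau_on, pch = 19,
       xlab = "concentration (mM)", ylab = expression(1 / tau[on] ~ (s^-1)),
       main = "association", ...)
  abline(x$kon_fit$intercept, x$rates$k_on * 1e-3, col = 2)
  plot(bc$concentration * 1e3, 1 / bc$tau_off, pch = 19,
       xlab = "concentration (mM)", ylab = expression(1 / tau[off] ~ (s^-1)),
       main = "dissociation",
       ylim = range(c(0, 1 / bc$tau_off) * 1.1), ...)
  abline(h = x$rates$k_off, col = 2)
  invisible(x)
}
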