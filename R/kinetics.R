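# Dwell-time estimators and rate-constant calculations.
#
# The kinetic model: association is single-step bimolecular,
# 1/tau_on = k_on * [analyte]; dissociation is unimolecular,
# 1/tau_off = k_off; the equilibrium binding constant is K_b = k_on/k_off.

#' Truncated-exponential maximum-likelihood dwell fit
#'
#' For exponentially distributed dwells observed only above a truncation
#' point `t_min` (the detector's minimum resolvable duration), the MLE of the
#' time constant is `tau = mean(values) - t_min`, with standard error
#' `tau / sqrt(n)`. Values below `t_min` are dropped with a warning.
#'
#' @param values Dwell times or inter-event intervals, s.
#' @param t_min Left truncation point, s (>= 0).
#' @return An `exp_fit`: list with `tau`, `se_tau`, `n`, `method`,
#'   `t_min`.
#' @examples
#' fit_exponential_mle(c(1, 2, 3))  # tau = 2 s
#' @export
fit_exponential_mle <- function(values, t_min = 0) {
  values <- values[is.finite(values)]
  if (t_min < 0) stop_config("t_min must be >= 0")
  if (any(values < t_min)) {
    warning(sprintf("dropping %d value(s) below t_min", sum(values < t_min)))
    values <- values[values >= t_min]
  }
  n <- length(values)
  if (n < 5L) stop_insufficient("need >= 5 dwell values, got %d", n)
  tau <- mean(values) - t_min
  if (tau <= 0) stop_insufficient("non-positive tau estimate")
  structure(list(tau = tau, se_tau = tau / sqrt(n), n = n,
                 method = "mle", t_min = t_min),
            class = "exp_fit")
}

#' Histogram least-squares exponential dwell fit
#'
#' The histogram-fit route: bin the dwells (linear or log-spaced bins) and
#' least-squares fit the exponential bin-probability model
#' `count_i = n * (exp(-lo_i/tau) - exp(-hi_i/tau))` by `nls`.
#'
#' @param values Dwell times, s.
#' @param n_bins Number of bins.
#' @param log_spaced Use log-spaced bin edges.
#' @param t_min Left truncation point, s.
#' @return An `exp_fit` with `method = "histogram"`.
#' @export
fit_exponential_histogram <- function(values, n_bins = 30L, log_spaced = FALSE,
                                      t_min = 0) {
  values <- values[is.finite(values) & values >= t_min]
  n <- length(values)
  if (n < 30L) stop_insufficient("need >= 30 dwell values, got %d", n)
  v <- values - t_min
  if (max(v) <= min(v)) stop_config("degenerate dwell values: single-bin histogram")
  if (log_spaced) {
    lo <- max(min(v[v > 0]), 1e-9)
    edges <- exp(seq(log(lo * 0.999), log(max(v) * 1.001), length.out = n_bins + 1L))
    edges[1] <- 0
  } else {
    edges <- seq(0, max(v) * 1.001, length.out = n_bins + 1L)
  }
  cnt <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), nbins = n_bins)
  if (sum(cnt > 0) < 2L) stop_config("all dwell values fall in one bin")
  df <- data.frame(lo = edges[-length(edges)], hi = edges[-1], y = cnt)
  tau0 <- mean(v)
  fit <- nls(y ~ n * (exp(-lo / tau) - exp(-hi / tau)), data = df,
             start = list(tau = tau0))
  sm <- summary(fit)$coefficients
  structure(list(tau = unname(sm["tau", "Estimate"]),
                 se_tau = unname(sm["tau", "Std. Error"]),
                 n = n, method = "histogram", t_min = t_min),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit (%s): tau = %.4g s (SE %.2g), n = %d\n",
              x$method, x$tau, x$se_tau, x$n))
  invisible(x)
}

#' Association rate constant from a concentration titration
#'
#' Fits `1/tau_on = k_on * c` by (weighted) least squares of the event rate
#' against concentration; `k_on` is the slope. A free intercept is fit by
#' default and reported as a diagnostic (it should be close to zero for
#' single-step bimolecular association); `force_origin = TRUE` constrains it.
#'
#' @param concentration Concentrations, mol/L (>= 3 points).
#' @param fits List of `exp_fit` objects for `t_on` (or numeric vector of
#'   `tau_on` values).
#' @param force_origin Constrain the intercept to zero.
#' @param weighted Weight points by the inverse variance of `1/tau_on`.
#' @return A `kon_fit`: list with `k_on`, `se`, `intercept`,
#'   `intercept_se`, `flagged` (negative slope), and the underlying `lm`.
#' @export
estimate_kon <- function(concentration, fits, force_origin = FALSE,
                         weighted = TRUE) {
  if (length(concentration) < 3L)
    stop_config("need >= 3 concentrations to fit k_on, got %d",
                length(concentration))
  if (inherits(fits, "exp_fit")) fits <- list(fits)
  if (is.list(fits)) {
    tau <- vapply(fits, function(f) f$tau, numeric(1))
    se <- vapply(fits, function(f) f$se_tau, numeric(1))
  } else {
    tau <- as.numeric(fits); se <- rep(NA_real_, length(tau))
  }
  if (length(tau) != length(concentration))
    stop_config("one t_on fit per concentration required")
  y <- 1 / tau
  w <- if (weighted && all(is.finite(se)) && all(se > 0)) tau^4 / se^2 else NULL
  d <- data.frame(c = concentration, y = y)
  fit <- if (force_origin) lm(y ~ c + 0, data = d, weights = w)
         else lm(y ~ c, data = d, weights = w)
  sm <- summary(fit)$coefficients
  k_on <- unname(sm["c", "Estimate"])
  se_k <- unname(sm["c", "Std. Error"])
  ic <- if (force_origin) 0 else unname(sm["(Intercept)", "Estimate"])
  ic_se <- if (force_origin) 0 else unname(sm["(Intercept)", "Std. Error"])
  structure(list(k_on = k_on, se = se_k, intercept = ic, intercept_se = ic_se,
                 flagged = k_on <= 0, fit = fit),
            class = "kon_fit")
}

#' Dissociation rate constant from dwell-time fits
#'
#' `k_off` is the mean of the `1/tau_off` values across conditions, with its
#' SE by first-order propagation. If concentrations are supplied, the slope
#' of `1/tau_off` vs concentration is reported as a diagnostic: unimolecular
#' dissociation predicts no concentration dependence.
#'
#' @param fits List of `exp_fit` objects for `t_off` (or numeric `tau_off`).
#' @param concentration Optional concentrations for the independence check.
#' @return A `koff_fit`: list with `k_off`, `se`, and (optionally)
#'   `conc_slope`, `conc_slope_se`.
#' @export
estimate_koff <- function(fits, concentration = NULL) {
  if (inherits(fits, "exp_fit")) fits <- list(fits)
  if (is.list(fits)) {
    tau <- vapply(fits, function(f) f$tau, numeric(1))
    se <- vapply(fits, function(f) f$se_tau, numeric(1))
  } else {
    tau <- as.numeric(fits); se <- rep(0, length(tau))
  }
  if (!length(tau)) stop_insufficient("no t_off fits supplied")
  rate <- 1 / tau
  rate_se <- se / tau^2
  k_off <- mean(rate)
  se_k <- if (length(rate) > 1L)
    max(sd(rate) / sqrt(length(rate)), sqrt(sum(rate_se^2)) / length(rate))
  else rate_se[1]
  out <- list(k_off = k_off, se = se_k, n = length(rate))
  if (!is.null(concentration) && length(concentration) == length(rate) &&
      length(rate) >= 3L) {
    sl <- summary(lm(rate ~ concentration))$coefficients
    out$conc_slope <- unname(sl["concentration", "Estimate"])
    out$conc_slope_se <- unname(sl["concentration", "Std. Error"])
  }
  structure(out, class = "koff_fit")
}

#' Equilibrium binding constant
#'
#' `K_b = k_on / k_off` (M^-1), with SE by first-order error propagation.
#'
#' @param k_on,k_off Rate constants (numbers, or `kon_fit` / `koff_fit`).
#' @param se_kon,se_koff Standard errors (taken from the fit objects when
#'   those are passed).
#' @return List with `K_b` and `se`.
#' @export
compute_Kb <- function(k_on, k_off, se_kon = 0, se_koff = 0) {
  if (inherits(k_on, "kon_fit")) { se_kon <- k_on$se; k_on <- k_on$k_on }
  if (inherits(k_off, "koff_fit")) { se_koff <- k_off$se; k_off <- k_off$k_off }
  if (k_off <= 0)
    stop_config("K_b undefined for k_off <= 0 (irreversible regime)")
  Kb <- k_on / k_off
  se <- abs(Kb) * sqrt((se_kon / k_on)^2 + (se_koff / k_off)^2)
  list(K_b = Kb, se = se)
}

#' Arrhenius fit of rate constants vs temperature
#'
#' Ordinary least squares of `ln k` against `1/T`; the activation energy is
#' `Ea = -slope * R` (reported in kJ/mol) and the pre-factor `A` is
#' `exp(intercept)`.
#'
#' @param temperature Temperatures, K (>= 3 values spanning >= 5 K).
#' @param rate Rate constants, s^-1 (> 0).
#' @return List with `Ea_kJ_mol`, `ln_A`, `A`, `r_squared`, and the `lm`
#'   fit.
#' @export
fit_arrhenius <- function(temperature, rate) {
  if (length(temperature) < 3L)
    stop_config("need >= 3 temperatures for an Arrhenius fit")
  if (diff(range(temperature)) < 5)
    stop_config("temperature span must be >= 5 K")
  if (any(temperature <= 0)) stop_config("temperatures must be > 0 K")
  if (any(rate <= 0)) stop_config("rates must be > 0 for an Arrhenius fit")
  d <- data.frame(invT = 1 / temperature, lnk = log(rate))
  fit <- lm(lnk ~ invT, data = d)
  sm <- summary(fit)
  slope <- unname(coef(fit)["invT"])
  list(Ea_kJ_mol = -slope * .GAS_CONSTANT / 1000,
       ln_A = unname(coef(fit)["(Intercept)"]),
       A = exp(unname(coef(fit)["(Intercept)"])),
       r_squared = sm$r.squared, fit = fit)
}

#' Limit of detection from the association rate
#'
#' The LOD is defined as the minimum analyte concentration producing at
#' least `n_min` events during a continuous measurement of `t_obs` seconds
#' (defaults: 5 events in 10 min). With the expected-count criterion and the
#' unbound fraction ~ 1 at trace concentrations, `lod = n_min/(k_on * t_obs)`.
#' A stochastic variant instead finds the concentration at which a Poisson
#' count reaches `n_min` with probability `prob`.
#'
#' @param k_on Association rate constant, M^-1 s^-1 (or a `kon_fit`).
#' @param n_min Minimum number of events (default 5).
#' @param t_obs Observation time, s (default 600).
#' @param prob If non-`NULL`, use the Poisson criterion
#'   `P(N >= n_min) = prob`.
#' @return A `lod_estimate`: list with `lod` (mol/L), `n_min`, `t_obs`,
#'   `criterion`.
#' @export
compute_lod <- function(k_on, n_min = 5, t_obs = 600, prob = NULL) {
  if (inherits(k_on, "kon_fit")) k_on <- k_on$k_on
  if (k_on <= 0) stop_config("k_on must be > 0")
  if (is.null(prob)) {
    lod <- n_min / (k_on * t_obs)
    criterion <- "expected_count"
  } else {
    f <- function(c) stats::ppois(n_min - 1, k_on * c * t_obs, lower.tail = FALSE) - prob
    upper <- 10 * n_min / (k_on * t_obs)
    while (f(upper) < 0) upper <- upper * 10
    lod <- uniroot(f, c(1e-16, upper), tol = 1e-14)$root
    criterion <- sprintf("poisson_p%.2f", prob)
  }
  structure(list(lod = lod, n_min = n_min, t_obs = t_obs,
                 criterion = criterion),
            class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat(sprintf("LOD = %.3g mol/L (>= %g events in %g s, %s)\n",
              x$lod, x$n_min, x$t_obs, x$criterion))
  invisible(x)
}
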