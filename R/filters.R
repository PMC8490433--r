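# Digital low-pass design and fast IIR filtering.
#
# Butterworth coefficients come from signal::butter. Bessel low-pass design
# (constant group delay in the passband, the classic patch-clamp bandwidth
# filter) is implemented here: poles of the reversed Bessel polynomial,
# scaled so the -3 dB magnitude point lands on the requested corner, then
# mapped to z by the bilinear transform with corner pre-warping.

bessel_poly_coefs <- function(n) {
  k <- 0:n
  exp(lgamma(2 * n - k + 1) - (n - k) * log(2) - lgamma(k + 1) - lgamma(n - k + 1))
}

# |theta_n(j w)|^2 as a function of w, given ascending coefficients.
bessel_mag2 <- function(coefs, w) {
  n <- length(coefs) - 1L
  s <- complex(real = 0, imaginary = w)
  val <- vapply(s, function(si) sum(coefs * si^(0:(n))), complex(1))
  Mod(val)^2
}

# Analog Bessel low-pass prototype poles, -3 dB magnitude normalised to w = 1.
bessel_prototype_poles <- function(order) {
  coefs <- bessel_poly_coefs(order)
  poles <- polyroot(coefs)
  g2 <- coefs[1]^2
  f <- function(w) bessel_mag2(coefs, w) - 2 * g2   # |H|^2 = 1/2
  w3 <- uniroot(f, c(1e-3, 10 * order), tol = 1e-12)$root
  poles / w3
}

#' Design a digital low-pass filter
#'
#' @param order Filter order (poles), 1..8 for Bessel.
#' @param corner Corner (-3 dB) frequency, Hz.
#' @param fs Sampling rate, Hz.
#' @param type `"bessel"` or `"butterworth"`.
#' @return List with numerator `b` and denominator `a` coefficients
#'   (`a[1] = 1`).
#' @export
design_lowpass <- function(order, corner, fs, type = c("bessel", "butterworth")) {
  type <- match.arg(type)
  if (corner <= 0 || corner >= fs / 2)
    stop_config("corner must satisfy 0 < corner < fs/2 (Nyquist)")
  if (type == "butterworth") {
    flt <- signal::butter(order, 2 * corner / fs, type = "low")
    return(list(b = flt$b, a = flt$a))
  }
  if (order < 1 || order > 8) stop_config("Bessel design supports orders 1..8")
  wc <- 2 * fs * tan(pi * corner / fs)        # pre-warped analog corner
  p <- bessel_prototype_poles(order) * wc
  zp <- (2 * fs + p) / (2 * fs - p)           # bilinear transform
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)                    # unit DC gain
  list(b = b, a = a)
}

# Monic polynomial coefficients (descending powers) from its roots.
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
  coefs
}

# Causal IIR filtering (compiled kernel), initialised at the DC steady
# state of the first sample so a trace that starts on a level shows no
# warm-up transient (the filters here have unit DC gain).
iir_filter <- function(flt, x) {
  x <- as.numeric(x)
  if (!length(x)) return(x)
  x0 <- x[1]
  x0 + filter_iir_cpp(flt$b, flt$a, x - x0)
}

# Zero-phase (forward-backward) filtering; squared magnitude response.
zero_phase_filter <- function(flt, x) {
  y <- iir_filter(flt, x)
  rev(iir_filter(flt, rev(y)))
}

# Delay, in samples, at which the causal step response of the acquisition
# filter crosses half amplitude. Half-amplitude event detection on filtered
# steps is late by exactly this much, so detection subtracts it.
filter_delay_samples <- function(flt, max_n = 4096) {
  y <- filter_iir_cpp(flt$b, flt$a, rep(1, max_n))
  i <- which(y >= 0.5)[1]
  if (is.na(i)) stop_integrity("filter step response never reaches 0.5")
  if (i == 1L) return(0)
  # linear interpolation between samples i-1 and i
  (i - 1) - (y[i] - 0.5) / (y[i] - y[i - 1])
}

acquisition_filter <- function(acq) {
  if (is.null(acq$analog_corner)) return(NULL)
  type <- if (acq$filter_type == "butterworth") "butterworth" else "bessel"
  design_lowpass(acq$filter_order, acq$analog_corner, acq$sampling_rate, type)
}
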