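# stochsense

Simulation and kinetic analysis of single-molecule nanopore
stochastic-sensing traces.

## The problem

In stochastic sensing with a programmable nano-reactor, a reactive strand is
docked inside a protein nanopore and held by an applied potential. The
strand produces a static blockage level `I_p`; each time a mobile analyte
binds the tethered reactive group, the ionic current steps to a bound level
`I_b` and back, producing a random telegraph signal. Three per-event
quantities carry all the chemistry:

* the blockage amplitude `ΔI = I_b − I_p` (positive- or negative-going,
  depending on the analyte),
* the dwell time `t_off` (how long a single molecule stays bound),
* the inter-event interval `t_on` (how long the strand waits for the next
  binding).

For single-step bimolecular association and unimolecular dissociation the
dwell statistics obey

```
1/τ_on  = k_on · c        (τ_on  = mean inter-event interval)
1/τ_off = k_off           (τ_off = mean dwell time)
K_b     = k_on / k_off    (equilibrium binding constant, M⁻¹)
```

so `k_on` is the slope of `1/τ_on` against concentration, `k_off` the mean
of `1/τ_off` across conditions. Chemically similar analytes that produce
near-identical amplitudes can still be told apart by their bound-state noise
signature: the trace is split with a 100 Hz Butterworth filter into a
low-pass and a high-pass portion, each event is summarized by the SD of both
portions, and a support-vector classifier separates the classes in that
plane.

The package is for single-channel electrophysiologists and method developers
who want this entire chain — trace simulation with known ground truth, event
idealization, rate-constant estimation, temperature/LOD analysis, and
noise-signature classification — as tested, scriptable R functions.

## What's inside

| stage | functions |
| --- | --- |
| kinetic schemes | `kinetic_scheme()`, `two_state_scheme()`, `add_absorbing_state()` |
| simulation | `sample_state_path()` (Gillespie), `render_trace()`, `simulate_trace()`, `simulate_concentration_series()`, `simulate_irreversible_run()`, `simulate_mixture()` |
| idealization | `estimate_baseline()`, `detect_events()`, `annotate_events()`, `idealize_sublevels()` |
| kinetics | `fit_binding_kinetics()` (+ `print`/`summary`/`coef`/`predict`/`plot`), `fit_exponential_mle()`, `fit_exponential_histogram()`, `estimate_kon()`, `estimate_koff()`, `compute_Kb()`, `fit_arrhenius()`, `compute_lod()` |
| discrimination | `frequency_split()`, `extract_features()`, `train_classifier()`, `predict()`, `confusion_matrix()`, `decision_boundary_grid()` |
| files & pipeline | `write_trace()`/`read_trace()`, `write_events()`/`read_events()`, `run_pipeline()`, `read_run_config()` |

A thin command-line wrapper with `simulate` / `idealize` / `kinetics` /
`split-features` / `classify` subcommands ships at
`inst/cli/stochsense.R`.

## Worked example

Simulate a three-point nickel-style titration (baseline 160 pA, `ΔI` =
−60 pA, `k_on` = 1×10⁴ M⁻¹s⁻¹, `k_off` = 5 s⁻¹), idealize it, and recover
the rate constants:

```r
library(stochsense)

scheme <- two_state_scheme(k_on = 1e4, k_off = 5, i_p = 160, delta_i = -60)
conc   <- c(0.4, 0.7, 1.0) * 1e-3          # mol/L
traces <- simulate_concentration_series(scheme, conc, duration = 120,
            noise = noise_model(baseline_sd = 6), acq = acquisition(),
            seed = 42)

# baseline from a zero-analyte calibration recording
calib    <- simulate_trace(scheme, 0, 10, noise = noise_model(6),
                           acq = acquisition(duration = 10), seed = 1)
baseline <- estimate_baseline(calib)

events <- lapply(traces, function(tr)
  annotate_events(tr, detect_events(tr, baseline, nominal_delta_i = -60)))

fit <- fit_binding_kinetics(events, concentration = conc, t_min = 3/25000)
summary(fit)
```

```
Two-state binding kinetics
  k_on  = 1.037e+04 +/- 5.6e+02 M^-1 s^-1
  k_off = 5.182 +/- 0.16 s^-1
  K_b   = 2001 +/- 1.3e+02 M^-1
  (3 concentrations, 1052 events, mle dwell fits)

Per-concentration dwell fits:
 concentration n_events  tau_on se_tau_on tau_off se_tau_off rate_on rate_off
         4e-04      272 0.24407  0.014826  0.1959   0.011879   4.097    5.104
         7e-04      371 0.13423  0.006978  0.1882   0.009771   7.450    5.314
         1e-03      409 0.09815  0.004859  0.1951   0.009645  10.188    5.127

Titration intercept: -0.00815 +/- 0.34 s^-1 (expected ~ 0)
1/tau_off vs c slope: 37.4 +/- 3.8e+02 (expected ~ 0)
```

The recovered `k_on` (1.04×10⁴), `k_off` (5.18 s⁻¹) and `K_b` (2001 M⁻¹)
match the generating values within a few percent; the near-zero titration
intercept and the flat `1/τ_off` vs concentration are the model diagnostics
for bimolecular association and unimolecular dissociation. The detection
limit implied by this affinity:

```r
compute_lod(fit$kon_fit)
#> LOD = 8.04e-07 mol/L (>= 5 events in 600 s, expected_count)
```

i.e. ~0.8 µM for the five-events-in-ten-minutes criterion.

A complete declarative run (simulation → idealization → kinetics →
frequency-split classification, with all artifacts and a structured log) is
driven by a YAML config:

```r
run_pipeline(system.file("extdata", "demo-config.yaml", package = "stochsense"),
             output_dir = "demo-out")
```

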