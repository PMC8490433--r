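---
title: "Models and methods behind stochsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stochsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochsense)
```

# The kinetic model

A docked sensing strand switches among a small set of conductance states.
`stochsense` models this as a continuous-time Markov chain: each state has a
mean current (pA) and exponentially distributed holding times set by its
total exit rate. Association steps are concentration-coupled — their rate is
`k_on · c` with `c` the mobile-analyte concentration in mol/L — while
dissociation, intermediate switching and irreversible termination are
unimolecular. The canonical two-state instance,

$$ I_p \underset{k_\mathrm{off}}{\overset{k_\mathrm{on} c}{\rightleftharpoons}} I_b, $$

implies `1/τ_on = k_on·c`, `1/τ_off = k_off`, equilibrium occupancy
`c·K_b/(1+c·K_b)` with `K_b = k_on/k_off`. These identities are what the
estimation side inverts, and they double as the oracles for the test suite:
simulated paths are checked against the closed-form occupancy, the
exponential dwell law (Kolmogorov–Smirnov at α = 0.01 on ~10⁴ dwells), and
the Poisson statistics of event counts.

Assumptions worth keeping in mind: binding is single-step (no diffusion
limitation, no conformational sub-steps unless modelled explicitly as
states); rates are constant within a recording (voltage and temperature
enter only as metadata or via separate fits); and dissociation is
concentration-independent — the fitted model reports a `1/τ_off` vs `c`
slope precisely so departures from that assumption are visible.

# What the generator emulates — and what it does not

`render_trace()` converts a sampled state path into a current record:
state-mean current per sample, white Gaussian baseline noise (SD in pA
*before* acquisition filtering), optional per-state extra noise, and a
causal analog-filter emulation.

* **Acquisition.** Defaults follow common patch-clamp practice: 25 kHz
  sampling, 4-pole low-pass at 1 kHz. The filter type defaults to Bessel
  (constant group delay, the standard amplifier bandwidth filter);
  Butterworth is available. Coefficients are designed in-package (reversed
  Bessel-polynomial poles, −3 dB magnitude normalisation, bilinear transform
  with corner pre-warping) and verified in a test against an independent
  reference design.
* **Bound-state noise signatures.** Real bound levels often carry
  characteristic extra fluctuations. Because their spectral content is not
  uniquely determined by any single summary, two interchangeable mechanisms
  are provided: extra broadband Gaussian SD, and a secondary two-state
  telegraph fluctuation (peak-to-peak amplitude, up/down rates) superimposed
  symmetrically on the level. A slow telegraph (corner well below 100 Hz)
  loads almost entirely onto the low-pass feature; broadband noise loads
  onto the high-pass feature — this is the basis of the classification
  demonstrations.
* **Irreversible chemistry.** An absorbing state models a permanently
  reacted strand; `simulate_irreversible_run()` emulates the voltage
  eject/reload protocol with a fixed dead time (default 1 s) between
  measurement cycles and records per-cycle ground truth.
* **Mixtures.** `simulate_mixture()` draws each binding event independently
  from one of several labelled classes sharing a baseline, recording true
  labels — the ground truth for classifier recall.

Not emulated: baseline drift and 1/f wander, open-pore/capture dynamics,
membrane artifacts, voltage-dependent rate laws (voltage is metadata only),
and electro-osmotic physics. Passing tests therefore demonstrate
correctness of the analysis chain on stationary, drift-free telegraph
signals with known noise; they do not certify performance on recordings
whose dominant pathology is drift or capture instability.

# Idealization

* **Baseline.** Either a Gaussian fit to the dominant mode of the all-points
  histogram, or a Gaussian fit to user-supplied static-blockage segment
  means (the separate-calibration protocol; several hundred segments
  recommended). A genuine second mode of comparable height (≥ 80% of the
  dominant peak, separated, with a real valley between them) raises an
  ambiguity error instructing a manual level choice rather than guessing.
* **Detection.** Half-amplitude threshold crossing with hysteresis: an
  excursion must reach 50% of the nominal `ΔI` to count, and extends over
  the surrounding region above 25%, with reported boundaries at the 50%
  crossings. The entry threshold must clear `k_sd` (default 3) baseline SDs
  or detection refuses with a diagnostic. When an analog filter is present,
  boundaries are compensated by the filter's half-amplitude step delay and
  then refined by a least-squares slide of the known step response
  (±6 samples); the refinement restores exact boundaries on noiseless input
  and removes the asymmetric bias of first-crossing statistics. Events
  shorter than `min_duration` (default 3 samples = 0.12 ms at 25 kHz) are
  discarded; raising `min_duration` can only reduce the event count
  (tested). `t_on` is measured end-of-previous to start-of-current event and
  resets at cycle boundaries.
* **Level statistics.** Event mean and SD exclude an edge guard band of one
  filter time constant per side, to avoid transition smearing; events too
  short for guards use the full window and are flagged.
* **Sub-levels.** Bound-region samples are median-filtered (window 5) and
  k-means-clustered into up to 3 levels; runs shorter than 3 samples merge
  into their predecessor. Clusters closer than twice the level noise are
  collapsed with a warning, where level noise comes from robust first
  differences of the raw window (`median|Δx|/(0.6745√2)`) — a within-cluster
  SD would be biased small when k-means bisects unimodal noise and would
  never trigger the collapse. Dwell histograms use whole events by default;
  per-sub-level dwells are available from the segment table.

# Rate estimation

The primary dwell estimator is the left-truncated exponential MLE,
`τ̂ = mean(x) − t_min`, `SE = τ̂/√n` — exact, assumption-minimal, robust at
small n, and the truncation handles the detector's minimum resolvable
duration. A histogram least-squares route (linear or log-spaced bins,
exponential bin-probability model) is kept for parity with common practice;
a cross-method test requires the two to agree within 5% at large n. Neither
is claimed to be "the" historical method — both are provided. Fits require
n ≥ 5 (MLE) / n ≥ 30 (histogram) and raise an insufficient-data error below
that.

`estimate_kon()` fits `1/τ_on` against `c` by weighted least squares
(weights from the τ standard errors), with a free intercept by default — the
intercept is a model diagnostic that should be ≈ 0 — and a forced-origin
option. `estimate_koff()` averages `1/τ_off` across conditions (unweighted
by default, matching the usual practice of treating conditions as
replicates; a weighted option exists) and reports the concentration-slope
diagnostic. `compute_Kb()` propagates first-order errors.
`fit_arrhenius()` is OLS of `ln k` on `1/T` (≥ 3 temperatures spanning
≥ 5 K), `Ea = −slope·R`.

The detection limit uses the expected-count criterion
`lod = n_min/(k_on·t_obs)` with `n_min = 5` events in `t_obs = 600` s by
default; because "at least five events" is ambiguous about stochasticity, a
Poisson variant (`P(N ≥ n_min) = p`) is available. The expected-count LOD
is self-consistent by simulation: 200 recordings of 600 s at `c = lod`
average five ground-truth events.

# Frequency-split discrimination

`frequency_split()` applies a zero-phase (forward–backward) Butterworth
low-pass (default order 4, 100 Hz) and defines the high-pass portion as the
exact residual `x − lp`, which guarantees additivity to machine precision;
a causal single-pass variant exists for strict-causality workflows. The
effective low-pass amplitude response is the squared magnitude
`1/(1+(f/f_c)^{2n})`, verified against sinusoid projections within 0.5%.
Per-event features are the SD of each portion over the event window minus an
edge guard of two cut-off periods (default), which keeps the split filter's
own settling out of the statistics.

The classifier is a support-vector machine (RBF kernel, `C = 1`,
`γ = 1/(d·var)` on standardized features by default; the z-score parameters
are stored inside the model so raw-unit rescaling, pA to nA, cannot change
predictions). Training on fixed data is deterministic and the stored
training hash makes model provenance checkable. Reported accuracies use a
stratified 70/30 train/test split with a fixed seed; resubstitution numbers
can be produced but are never presented as held-out performance. The
bundled acceptance check uses a synthetic three-class construction with
centroids six within-class SDs apart — a scaled, fully specified analogue
of multi-analyte discrimination — because real per-class accuracies depend
on recordings that only exist on real hardware.

# Numerical and design choices

* Gillespie sampling uses R's exponential and categorical draws; a master
  seed deterministically derives per-stage child seeds (Lehmer step), so
  identical configs reproduce identical bytes.
* IIR filtering runs through a small compiled direct-form-II kernel,
  initialised at the DC steady state of the first sample so traces that
  begin on a level show no warm-up transient; it is cross-checked against a
  reference filter implementation in the tests.
* Sample intervals are 0-based half-open in stored event tables; sample k
  covers the time interval `[k/f_s, (k+1)/f_s)` and takes the state at its
  midpoint.
* Time conservation `Σt_off + Σt_on + lead/tail time = analyzed cycle
  duration` is enforced as a test invariant, which pins down the boundary
  and `t_on` conventions.
* Degenerate inputs fail loudly with classed conditions (configuration /
  data-integrity / insufficient-data), which the CLI maps to exit codes
  2/3/4.

Default problem sizes in the tests and the acceptance script — 600 s traces
for titrations, 100–120 s for detection checks, 10⁴ dwells for estimator
checks, 10⁵ samples for noise-partition checks, 300 events per class for
classification — were chosen so that Monte-Carlo error sits comfortably
inside each assertion's tolerance while a full run stays in the
couple-of-minutes range on one core.

# Known limitations

* Detection assumes a stable baseline; slow drift will smear the all-points
  histogram and should be corrected upstream (drift correction is out of
  scope).
* Boundary accuracy is physics-limited to roughly `σ_filtered/edge-slope`
  samples; at very low SNR dwell estimates inherit that jitter.
* The dwell model is single-exponential per state; multi-exponential
  mixtures (heterogeneous strands) are not fitted.
* Sub-level segmentation is k-means-based, not a hidden-Markov fit; very
  fast intermediate switching (dwells of a few samples) will be merged.
* `simulate_mixture()` interleaves events from a shared baseline and cannot
  represent analytes competing for the same site with saturation coupling.
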