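# Demonstration pipeline: a short concentration titration for kinetics plus
# a labelled two-class mixture for frequency-split classification.
seed: 20260930
output_dir: stochsense-demo-out

simulate:
  titration:
    scheme:
      k_on_per_molar_s: 1.0e+4
      k_off_per_s: 5
      i_p_pA: 160
      delta_i_pA: -60
    concentrations_molar: [4.0e-4, 7.0e-4, 1.0e-3]
    duration_s: 40
    noise:
      baseline_sd_pA: 6
    acquisition:
      sampling_rate_hz: 25000
      analog_corner_hz: 1000
      filter_order: 4
      filter_type: bessel
  mixture:
    classes:
      quiet:
        scheme: {k_on_per_molar_s: 2.0e+4, k_off_per_s: 8, i_p_pA: 160, delta_i_pA: -40}
      flickery:
        scheme: {k_on_per_molar_s: 2.0e+4, k_off_per_s: 8, i_p_pA: 160, delta_i_pA: -60}
        noise:
          state_noise:
            Ib: {telegraph_amp: 20, telegraph_rates: [15, 15]}
    proportions: [0.5, 0.5]
    concentration_molar: 1.0e-3
    duration_s: 40
    baseline_sd_pA: 4
    acquisition:
      sampling_rate_hz: 25000
      analog_corner_hz: 1000

idealize:
  nominal_delta_i_pA: -40
  baseline:
    mean_Ip_pA: 160
    sd_Ip_pA: 2

kinetics:
  method: mle

features:
  cutoff_hz: 100

classify:
  train_frac: 0.7
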