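# Default synthetic-mode pipeline configuration.
# Cohort layout: four groups, three visits, 116 regions x 130 time points
# at TR = 3 s; band-limited latent signals in 0.01-0.08 Hz plus white noise.
mode: synthetic
seed: 1
cohort:
  group_sizes: {NC: 29, EMCI: 23, LMCI: 24, AD: 23}
  n_visits: 3
  n_regions: 116
  n_timepoints: 130
  tr_seconds: 3.0
  signal_band: [0.01, 0.08]
  noise_sd: 0.5
  n_components: 5
  default_effects: true
prep:
  n_discard: 10
  low_hz: 0.01
  high_hz: 0.08
  filter_order: 4
connectivity:
  kind: both
  eps_rel: 1.0e-12
  aggregate: mean
stats:
  alpha: 0.05
  paired: true
  normalize: none
  correction: none
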