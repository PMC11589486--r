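# Example cultivar configuration for read_cultivar_config().
# Fields mirror cultivar_params(); omitted fields take the defaults.
# All presets here are synthetic stand-ins, not measured field values.
EarlyToy:
  oil_max: 15.5
  band_fall_onset: [62, 48, 70]   # early decline: wide hysteresis loop
  n_dates: 15
  replicates: 3
LateToy:
  oil_max: 20
  band_fall_onset: [110, 96, 120] # late decline: narrow loop
  n_dates: 15
  replicates: 3
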