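seed: 1
out_dir: '.'
parameters: []
design:
  n_ckrt: 7.0
  n_nonckrt: 9.0
  weight_group: mixed
  missingness_rate: 0.0
pta:
  'n': 1000.0
  mics:
  - 0.25
  - 0.5
  - 1.0
  - 2.0
  - 4.0
  - 8.0
  - 16.0
  thresholds:
  - 45.0
  - 65.0
  regimens:
    std_q8h:
      dose_per_kg: 40.0
      infusion_duration: 0.5
      interval: 8.0
    ckrt_adjusted:
      dose_per_kg: 40.0
      infusion_duration: 0.5
      interval: 8.0
      switch_at_dose: 4.0
      switch_interval: 12.0
    extended_4h:
      dose_per_kg: 40.0
      infusion_duration: 4.0
      interval: 8.0
    ci_60:
      dose_per_kg: 60.0
      infusion_duration: 24.0
      interval: 24.0
    ci_120:
      dose_per_kg: 120.0
      infusion_duration: 24.0
      interval: 24.0
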