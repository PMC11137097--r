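# Default end-to-end scenario: the emulated study design (27 CN + 56 AD
# cohort statistics; b = 0/1000/2000 with 30 directions) plus two
# demonstration imaging subjects, one CN-like and one AD-like
# perivascular gain.
seed: 20240529
output_dir: results/pipeline
phantom:
  shape: [40, 40, 18]
  spacing: [1.9, 1.9, 3.0]
protocol:
  n_dirs: 30
  bvalues: [1000, 2000]
  n_b0: 1
dwi:
  S0: 500
  snr: 30
imaging_subjects:
  - {id: CN01, pv_gain: 1.0e-4, target_centiloid: 0.4}
  - {id: AD01, pv_gain: 6.0e-6, target_centiloid: 78.5}
pet:
  injected_dose: 725   # MBq
  body_weight: 60      # kg
  background: 0.25
anchors:
  suvr_yc: 1.009
  suvr_ad100: 2.076
cohort: {}             # empty: use the shipped cohort defaults
stats:
  vsrad_denominator: max
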