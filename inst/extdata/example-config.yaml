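# exemplar model with KCNQ channels near the junction and a 40 Hz train
geometry:
  stem: {length_um: 75}
densities:
  kcnq: {soma: 0.4, stem: 0.4, proximal: 0.4}
stimulus:
  branch: peripheral
  dist_um: 4600
  amp_nA: 0.4
  freq_Hz: 40
  n_pulses: 10
  onset_ms: 5
simulation:
  dt_ms: 0.025
  duration_ms: 300
  record_dt_ms: 0.1
  record:
    - {branch: junction, dist_um: 0}
    - {branch: central, dist_um: 5000}
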