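# Example macroscopic (ensemble) configuration.
# Unstated keys fall back to the preset defaults; `barrier: auto` requests
# dwell-ratio calibration of the reduced barrier at load time.
potential:
  barrier: auto
  asymmetry_lambda: 0.5
integrator:
  dt: 5.0e-10
  seed: 7
  record_stride: 200
protocol:
  kind: force_clamp
  beta: 0.3
  duration: 2.5e-3
  n_trials: 11
ensemble:
  N: 64
  settle: 4.0e-3
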