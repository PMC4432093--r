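# Example run configuration for pureshiftr (read_run_config()).
# A spin system may be given inline (spins/couplings/base_freq/carrier_ppm),
# by file reference, or as a named synthetic fixture.
seed: 11
spin_system:
  fixture: minimal_pair
element:
  kind: gbird
  J_NH: 90
  ctp_g1: 16.6
  ctp_g2: 13.6
  ctp_duration: 0.0005
  stabilization: 0.0002
  exorcycle_steps: 2
acquisition:
  sw: 5000
  total_points: 1024
  n_chunks: 4
  droppoints: 0
processing:
  zero_fill: 16384
  apodize: none
analysis:
  peaks: true
  sidebands: true
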