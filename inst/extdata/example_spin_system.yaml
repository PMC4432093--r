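# Example spin-system file (read_spin_system()): one denatured-style amide
# residue with its 15N and alpha proton.
spins:
- label: HN
  isotope: H1
  shift_ppm: 8.24
  T2: 0.06
  role: active
- label: N
  isotope: N15
  shift_ppm: 114.15
  T2: 0.18
  role: passive
- label: HA
  isotope: H1
  shift_ppm: 4.3
  T2: 0.06
  role: passive
couplings:
- a: HN
  b: N
  J: 90.0
- a: HN
  b: HA
  J: 8.0
base_freq:
  H1: 500.0
  N15: 50.68
carrier_ppm:
  H1: 4.7
  N15: 115.0
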