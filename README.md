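# pureshiftr

Density-matrix simulation and analysis of **real-time pure shift
¹H–¹⁵N HSQC** NMR experiments on proteins.

In a protein ¹⁵N HSQC, every amide proton is split by its homonuclear
couplings (chiefly ³J(Hᴺ–Hα) of 4–9 Hz), which are comparable to the
natural linewidths: crowded regions blur and each resonance's height is
divided over its multiplet lines.  Real-time *pure shift* acquisition
removes the splitting during detection itself: the FID is acquired in
chunks of duration 1/sw_ps ≪ 1/J_HH, and between chunks a *J-refocusing
element* inverts the passive spins so homonuclear J evolution is
periodically rewound.  After concatenation, every amide gives a singlet —
better resolution *and*, for resolved multiplets, better sensitivity.

`pureshiftr` is aimed at NMR methods developers and students who want to
explore this machinery quantitatively on small spin systems:

* **spin systems & engine** — up to six spins (¹H/¹⁵N), exact unitary
  propagation with phenomenological T₁/T₂ relaxation, hard and shaped
  pulses, pulsed-field gradients over a spatial ensemble, phase cycling,
  windowed acquisition;
* **J-refocusing elements** — BIRD (core duration 1/¹J_NH, 11.1 ms at
  90 Hz) and band-selective BASHD (reBURP, ~2.4 ms), with or without
  coherence-transfer-pathway (CTP) gradient selection, plus the
  zero-duration ideal limit.  Net-propagator contract: identity on the
  N-bound (active) protons, 180° on passive protons;
* **selective pulses** — reBURP synthesis from its Fourier-cosine
  coefficients, Bloch-simulated inversion profiles, B1 calibration,
  bandwidth and time-bandwidth-product measurement;
* **water** — classical per-slice Bloch model with radiation damping,
  showing why CTP gradients recover clean water suppression;
* **processing** — chunk concatenation, interferogram assembly,
  apodization, zero-filling/FT, States and echo/antiecho (Rance–Kay) 2D
  transforms, axis referencing, JCAMP-DX export;
* **analysis** — peak picking, S/N, linewidths, decoupling-sideband
  quantification, and the closed-form sensitivity rules:
  multiplet-collapse gain `100·(Σp/max p − 1)`, finite-linewidth doublet
  gain `(πJT₂/2)²` (matched-filter convention; "vanishes" near
  J·T₂ = 0.1), and the time-shared duty-cycle penalty `100·(1 − √f)`.

## Worked example

A single amide residue (Hᴺ 8.24 ppm, ¹⁵N 114.15 ppm, Hα 4.30 ppm,
¹J_NH = 90 Hz, ³J_HH = 8 Hz, T₂ = 60 ms) acquired as six 32 ms chunks
with a BIRD element between them:

```r
library(pureshiftr)

sys <- minimal_pair(J_HH = 8, T2 = 0.060)
acq <- acquisition_plan(sw = 5000, total_points = 960, n_chunks = 6,
                        element = element_spec("bird", J_NH = 90))
acq
#> <acquisition_plan> 6 x 160 points, sw 5000 Hz, chunk 32 ms, sw_ps 31.25 Hz, element bird

cfid <- run_sequence(sys, realtime_acquisition(acq, sys),
                     phase_cycle = exorcycle(2),
                     init = ideal_start_state(sys, 0, "cos"))
spec <- zero_fill_and_ft(concatenate_chunks(cfid), 16384)
peak_pick(spec, 0.5 * max(Re(spec$intensity)))
#>    freq_hz      ppm   height index
#> 1 1770.137 8.240274 226.1801 13993
```

The 8 Hz doublet has collapsed to a single line at the amide shift
(1770 Hz from the carrier, 8.24 ppm).  Comparing against the same system
acquired conventionally:

```r
peak_fwhm(spec, 1770)                      # 6.95 Hz vs natural 5.31 Hz
sideband_scan(spec, 1770, acq$sw_ps, 1)    # first sidebands ~13 % at ±31.25 Hz
#> peak-height gain over the coupled spectrum: 42 %
```

The singlet is slightly broader than the natural linewidth (T₂ loss in
the 11.4 ms BIRD elements), small decoupling sidebands appear at
±sw_ps, and the collapse buys a 42 % peak-height gain — consistent with
the theory values `max_multiplet_gain(c(1, 1))` (+100 % ceiling) and
`decoupling_gain(8, 0.06)` (50 % at this J·T₂ after linewidth effects).

The same pipeline is scriptable from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/pureshift simulate --fixture minimal_pair --element bird --chunks 4 --out run
Rscript inst/cli/pureshift process  --in run.jdx --zf 16384 --out run_spec
Rscript inst/cli/pureshift analyze  --in run_spec.tsv --peaks --sidebands --sw_ps 39.0625 --out report
```

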