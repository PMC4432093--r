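---
title: "Simulating real-time pure shift 15N HSQC experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating real-time pure shift 15N HSQC experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pureshiftr)
```

## The problem

In a proton-detected ^1^H–^15^N HSQC spectrum of a protein, every amide
proton resonance is split by its homonuclear couplings — chiefly the
vicinal ^3^J(H^N^–H^α^) of 4–9 Hz.  Because amide linewidths in small or
disordered proteins are of the same order, the splitting both blurs
crowded regions and spreads each resonance's intensity over several
multiplet lines.  *Real-time pure shift* acquisition removes the splitting
during the acquisition itself: the FID is recorded in short chunks of
duration $1/\mathrm{sw_{ps}} \ll 1/J_{\mathrm{HH}}$, and between chunks a
*J-refocusing element* inverts the *passive* spins (everything except the
observed, ^15^N-bound amide protons) so that homonuclear J evolution is
periodically rewound.  After concatenating the chunks, each amide gives a
singlet at its chemical shift.

`pureshiftr` simulates this machinery from first principles on small spin
systems: exact density-matrix propagation through the pulse sequences,
the two J-refocusing element families (BIRD and band-selective BASHD,
with or without coherence-transfer-pathway gradient selection), a
classical water magnetization with radiation damping, the processing
chain from chunked FIDs to calibrated 1D/2D spectra, and the closed-form
sensitivity rules that govern when homodecoupling pays off.

## Spin model and engine

A `spin_system()` holds up to six spins (^1^H, ^15^N), their shifts,
scalar couplings and relaxation times.  The free Hamiltonian uses the
full isotropic coupling between like spins and the secular
$2\pi J\, I_z S_z$ term between heteronuclei (exact in the doubly
rotating frame).  Propagation is unitary,
$\rho \mapsto e^{-iHt}\rho\,e^{+iHt}$, via eigendecomposition, with
phenomenological relaxation applied per evolution segment: every
coherence $\rho_{ab}$ decays at $\sum_{i\,\mathrm{flipped}} 1/T_{2,i}$
(so a single-quantum coherence of spin $i$ decays at exactly
$1/T_{2,i}$), and populations relax toward thermal equilibrium at the
mean $1/T_1$ of the spins that declare one, or are frozen when none do.
This is deliberately simple — losses in these experiments are dominated
by transverse relaxation during the J-refocusing elements, and a full
Redfield treatment is out of scope.

Hard pulses are instantaneous rotations ($90^\circ_x$ takes $+z$ to
$-y$).  Shaped pulses are integrated as products of piecewise-constant
propagators over the waveform samples; a transmitter offset is realised
as a *centre-referenced* phase ramp, so the pulse stays phase coherent
with the main sequence and a refocusing pulse acts as a rotation about a
fixed transverse axis.  Gradients act over a spatial ensemble of density
matrices (slice midpoints across a 1.6 cm sample; 64 slices by default):
slice $k$ acquires the phase $\gamma_i G z_k \tau$ on each coherence.
Balanced gradient pairs around a refocusing pulse therefore cost the
solute nothing, while unbalanced coherence is destroyed at detection,
where slices are averaged.

## The J-refocusing elements

Both elements are double spin echoes whose net propagator, with perfect
pulses, is the *identity* on active protons — with no net shift
evolution — and a $180^\circ$ rotation on passive protons:

* **BIRD** (`bird_element()`): a hard-echo
  $\tau$–$180^\circ_y(\mathrm{H})$–$\tau$ followed by the BIRD sandwich
  $90^\circ_x$–$\Delta$–$180^\circ_x(\mathrm{H}){+}180^\circ(\mathrm{N})$–$\Delta$–$90^\circ_x$
  with $\Delta = 1/(2\,{}^1J_{\mathrm{NH}})$.  The core lasts
  $1/{}^1J_{\mathrm{NH}}$ — 11.1 ms at 90 Hz — independent of field.
  A second ^15^N $180^\circ$ trails the element so the ^15^N $z$ state is
  restored every time; placing it there (rather than next to the hard
  ^1^H 180) keeps $J_{\mathrm{NH}}$ refocused in the first echo, which is
  what lets the element meet its contract exactly.  The timing-overhead
  delays (blanking, power switching, the ^15^N-pulse time correction) are
  split symmetrically across the echo halves for the same reason.
* **BASHD** (`bashd_element()`): the hard echo followed by a symmetric
  echo around a band-selective reBURP $180^\circ$ centred on the amide
  region.  In-band protons are refocused twice (net identity), out-of-band
  protons once (net inversion).  Both 180s share a base phase so their
  axis rotations cancel for in-band spins.  The element is much shorter
  than BIRD (about 2.7 ms vs 11.4 ms with the default overheads), which
  is why BASHD loses less magnetization to $T_2$ between chunks; its
  price is reduced efficiency at the band edges and recoupling of any
  passive proton that strays into the band — both reproduced by the
  simulator and covered by tests.
* **ideal**: the zero-duration perfect-refocusing limit, implemented as
  an instantaneous inversion of the passive protons plus suppression of
  the active–passive couplings during the chunks.  A literal
  instantaneous inversion alone cannot make the concatenated FID equal
  the $J_{\mathrm{HH}}$-free reference pointwise (the J phase still ramps
  within each chunk); the limit of an infinitely fast element train does,
  and that is the oracle the tests use.

CTP gradient selection (`ctp_wrap()`, or the `gbird`/`gbashd` kinds)
inserts matched gradient pairs around each refocusing block, absorbing
the gradient and stabilization time into the neighbouring delays so the
echo symmetry and the BIRD timing condition are untouched.

The two-step element phase cycle (`exorcycle()`) is a rigid $90^\circ$
phase shift of all the element's ^1^H pulses with constant receiver: the
wanted pathway is conjugated twice per element and is invariant, while
single-refocusing error pathways change sign and cancel.  We verified
numerically that a $90^\circ$ shift of only one of the two 180s (classic
single-echo EXORCYCLE) would instead flip the sign of the wanted signal
on alternate chunks, which a constant receiver cannot undo in a
real-time experiment.  Note that with finite $T_2$ the two steps are not
bit-identical even with perfect pulses: the coherence visits different
operator pathways inside the element, so relaxation losses differ
slightly; equality holds exactly when relaxation is off.

## Real-time chunking

`acquisition_plan(sw, total_points, n_chunks)` enforces the integer
arithmetic of chunked acquisition: `sw_ps = sw / chunk_points` must be an
integer submultiple of the spectral width.  The event list produced by
`realtime_acquisition()` uses the standard half-edge layout — first and
last windows half a chunk long, one element per chunk period — so the
homonuclear J phase sweeps symmetrically about zero within every period.
The decoupling sidebands then fall at multiples of `sw_ps`.  With equal
chunks (element at the chunk boundaries) the modulation period doubles
and the first sidebands appear near `sw_ps/2`; we chose the half-edge
layout because the published sideband positions are at $\pm k\,
\mathrm{sw_{ps}}$.  A consequence is that the chunk records of a pure
shift FID are not all the same length ($\tau/2, \tau, \dots, \tau/2$),
so the chunk-rate metadata travels with the acquisition plan.

The chunk-count trade-off is the experiment's central dial: fewer,
longer chunks leave more J evolution per period (larger sidebands);
more, shorter chunks apply the element more often (more relaxation loss,
broader lines).  Both limbs are reproduced: at a fixed 192 ms total
acquisition the first-sideband amplitude decreases monotonically over
2, 3, 4, 6, 8 chunks, and the decoupled linewidth grows with element
duration (ideal < BASHD < BIRD) while never dropping below the natural
$1/(\pi T_2)$.

## Water

Water is classical and one-way coupled: a per-slice Bloch vector with
$T_1$, $T_2$ and mean-field radiation damping (fixed-step RK4, step
$\le 10\,\mu s$) is co-evolved with the sequence and added to the
receiver, but never enters the quantum state.  The pure shift elements
invert water (a passive proton) every chunk period, and radiation
damping converts the inverted $z$ magnetization into detectable
transverse signal — the mechanism that makes water suppression hard in
these experiments.  CTP gradients dephase that coherence; simultaneous
$x$/$y$ gradients on a triaxial probe behave identically in this model,
which deliberately does not resolve direction-dependent effects beyond
the dephasing itself.

Because the default crusher areas wind ~57 phase cycles across the
sample, a modest equispaced slice grid aliases badly.  The water grid
(128 slices by default) therefore also tracks the *intra-slice* linear
phase wound by gradients and attenuates each slice's contribution by the
exact segment average $\mathrm{sinc}(\kappa w/2)$; a 180° pulse flips the
winding, other pulses collapse it.  This restores the continuum crushing
limit (residual $\approx 0.6\,\%$ after one 0.5 ms, 16.6 G cm^−1^
gradient) at any slice count.  One caveat is documented honestly: the
*suppressed* residual is a near-cancellation remainder whose absolute
value still depends on discretization; what is stable — and what the
tests assert — is the unsuppressed residual and the suppression ratio
(an order of magnitude or more with CTP gradients on).

## Sensitivity rules

Three closed-form rules quantify when homodecoupling pays:

* `max_multiplet_gain()`: collapsing a multiplet of intensities $p$
  into a singlet of equal integral raises the tallest line by
  $100(\sum p/\max p - 1)$ percent in the zero-linewidth limit: +100 %
  for doublets and 1:2:1 triplets, +166.7 % for 1:3:3:1 quartets.
* `decoupling_gain(J, T2)`: the finite-linewidth gain, computed on
  matched-filtered Lorentzians (linewidth doubled), the standard
  convention for sensitivity comparisons.  In the unresolved regime the
  closed form is $(\pi J T_2/2)^2$; the general value is found by
  numeric maximization of the doublet lineshape, and the two agree to
  0.1 % for $J T_2 \le 0.15$.  At $J T_2 = 0.1$ the gain is 2.5 % — the
  decoupling advantage has effectively vanished, which we operationalize
  as $\le 5\,\%$.  (On raw, unfiltered lineshapes the same comparison
  gives $(\pi J T_2)^2$; the matched-filter convention is what makes the
  published threshold meaningful.)
* `duty_cycle_penalty(f)`: time-shared decoupling samples only a
  fraction $f$ of each dwell, costing $100(1-\sqrt f)$ percent in S/N —
  about 7 % at the standard 87 % duty cycle.

## Synthetic fixtures

`generate_fixture()` builds deterministic per-residue HN–N–H^α^ systems
in three styles that emulate the benchmark samples: a denatured
small-domain protein (amide ^1^H 7.8–8.7 ppm, $T_2 = 60$ ms), a folded
globular protein ($T_2 = 35$ ms) and a small antifungal protein
($T_2 = 55$ ms).  Each residue carries ^1^J~NH~ = 90 Hz (the value
consistent with the 11.1 ms BIRD duration; the exact per-sample value is
never stated, so 90 Hz is fixed once here) and a vicinal coupling drawn
uniformly from 4–9 Hz.  Residues are simulated independently and their
FIDs summed — inter-residue couplings and chemical exchange are not
modelled, and amide protons see exactly one passive partner.  Passing
tests therefore demonstrate the acquisition physics, not the full
spectral complexity of a real protein: real spectra add multiple
homonuclear partners per amide, shift degeneracy far beyond five
residues, and $T_2$ dispersion across residues.

## Numerical choices

* Rotating frame per isotope at the stated carrier; higher ppm means a
  positive offset in Hz.
* Spin count capped at six (matrix dimension 64) so every simulation is
  desk scale; typical test systems are three spins.
* FFT convention: $e^{+2\pi i \nu t}$ appears at $+\nu$; first point
  halved before transformation; ppm axes read decreasing left to right.
* Echo/antiecho pairs combine as $\cos = (E+A)/2$,
  $\sin = (E-A)/(2i)$ before the indirect transform.
* Sideband amplitudes are read at the nearest digital point, without
  interpolation, for reproducibility; the water residual window is
  $\pm 50$ Hz.
* B1 calibration is a golden-section search (relative tolerance
  $10^{-3}$) around the analytic flip-angle estimate; the bandwidth
  convention is the 80 % inversion-efficiency width, which reproduces
  the published reBURP bandwidth-duration pairings as a constant
  time-bandwidth product (measured 4.47 at the 80 % threshold; the
  printed pairings imply 4.88, inside the tested 4.4–5.4 window).
* The ~2 Hz systematic shift caused by short gradient-recovery times is
  not emulated (gradients recover instantly here); the internal
  referencing correction `reference_shift()` exists on the processing
  side, as in practice.
* Simulation sizes in the test-suite and acceptance script (three-spin
  residues, 128–1024 complex points, 16–32 $t_1$ increments, 16–128
  slices) were chosen as the smallest systems that still exhibit every
  effect of interest at the tested tolerances.

## Known limitations

Relaxation is phenomenological (no cross-correlation, no exchange);
hard pulses are instantaneous by default, so the published 32-step
cycle's benefit over two steps cannot be reproduced quantitatively;
heteronuclear decoupling during chunks is ideal rather than an explicit
WALTZ/GARP train; the water model is classical and does not feed back
into the solute; and the measured S/N values of the real protein spectra
are not reproduced — only the qualitative direction (decoupled S/N
exceeds coupled S/N for a resolved amide doublet) and the closed-form
sensitivity rules are asserted.
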