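---
title: "A biophysical model of spike propagation through the DRG T-junction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A biophysical model of spike propagation through the DRG T-junction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system

Unmyelinated (C-fiber) sensory neurons are pseudo-unipolar: a single stem
axon leaves the soma and bifurcates at the **T-junction** inside the
dorsal root ganglion into a thicker peripheral axon (toward the receptive
field) and a thinner central axon (toward the spinal cord). Every pain
signal must cross this branch point. The junction is an impedance
mismatch: the 3/2-power geometric ratio
\[
GR = \frac{d_{stem}^{3/2} + d_{central}^{3/2}}{d_{peripheral}^{3/2}}
\]
exceeds unity for realistic diameters (0.8 µm peripheral, 0.4 µm central,
1.2–1.4 µm stem), so orthodromic spikes are filtered, and trains of
spikes can fail there selectively at high rates. `drgtj` implements a
compartmental cable model of this neuron — soma (25 × 25 µm cylinder),
stem (150 µm × 1.4 µm by default), 100 µm finely resolved proximal axon
segments on both sides of the junction and 5 mm distal extensions — with
the membrane mechanisms thought to control junction filtering, and an
experiment layer that measures conduction velocity, input impedance,
propagation reliability, following frequency and ectopic (antidromic)
spike generation.

## Membrane mechanisms

All compartments carry a leak (1/R_m with a per-compartment calibrated
reversal, below) and, in the standard model, transient Na⁺ (NaV, m³h) and
delayed-rectifier K⁺ (KDR, n³l) conductances at 40 mS/cm² (somatic NaV
halved to 20 mS/cm²). Optional mechanisms: a two-state KCNQ (Kv7,
M-type) K⁺ conductance with logistic activation (half −35 mV, 10 mV
slope, bell-shaped time constant peaking at ≈ 43 ms); a high-threshold
Ca²⁺ conductance (m², Nernstian E_Ca at 308 K with 2 mM external Ca²⁺);
an SK-type Ca²⁺-activated K⁺ conductance (q²) driven by an intracellular
Ca²⁺ pool obeying
\[
\frac{d[\mathrm{Ca}]_i}{dt} = -0.026\, I_{Ca} - \frac{[\mathrm{Ca}]_i - [\mathrm{Ca}]_{rest}}{20\ \mathrm{ms}},
\qquad [\mathrm{Ca}]_{rest} = 50\ \mathrm{nM};
\]
Na⁺/K⁺ concentration dynamics (intracellular pool = compartment volume,
extracellular pool = 100 nm periaxonal shell, Nernstian E_Na/E_K at
308 K) and an electrogenic 3:2 Na⁺/K⁺ pump with Michaelis–Menten
dependence on [Na]_i (K_m = 10 mM).

Equilibrium potentials are fixed at E_Na = +55 mV and E_K = −90 mV
unless ion dynamics are enabled; the initial concentrations
([Na]ᵢ/[Na]ₒ = 14/111, [K]ᵢ/[K]ₒ = 140/4.7 mM) reproduce those values
exactly at 308 K. The leak reversal is solved per compartment so that the
total membrane current vanishes at −60 mV; an unstimulated simulation
holds the resting potential to fractions of a microvolt.

### Interpretive choices in the kinetics

Several of the rate equations this model family is built from circulate
in typographically ambiguous forms; the package adopts the following
readings (each is testable through the exported rate functions):

* **NaV rate denominators.** The α_m and β_m forms are of the
  Traub type, `k·x/(exp(x/s) − 1)`, with the removable singularity filled
  by its limit. The rest-relative voltage convention is made explicit:
  rates are evaluated at `v − v_ref`, with `v_ref` a calibration constant
  (see below).
* **KDR formalism.** The printed exponential pairs are used as
  Borg-Graham shape functions: `x_inf = 1/(1+α(V))`,
  `τ = β(V)/(a₀(1+α(V)))`, activation half-voltage −32 mV and
  inactivation half-voltage −61 mV, with the rate scales `a₀` left as
  calibration constants and a floor on each time constant (the raw
  expression collapses to microseconds far from the half-voltage, which
  would delete the current during every spike).
* **SK rates.** The Ca²⁺ dependence is `exp((12·log10([Ca]_mM)+c)/s)`
  with the constants 0.00246/28.48/4 (α) and 0.006/60.4/35 (β), signs
  resolved so that the open probability *increases* with [Ca]ᵢ and is
  ≈ 0 at 50 nM rest (the literal sign reading inverts the Ca dependence,
  which contradicts the channel's biology). The α divisor 4.5 used by the
  upstream channel family is available via `tj_kinetics(sk_div_a = 4.5)`.

## Calibration

Four constants are not fixed by the equations: the NaV voltage reference
`v_ref`, the KDR rate scales `a0_n`, `a0_l`, and the somatic CaV density.
They were calibrated **once** against the passive/active benchmarks of
this preparation (resting potential −60 mV, somatic spike, peripheral
conduction velocity ≈ 0.5 m/s, critical NaV density for junction
crossing, 110 Hz base following frequency) and then frozen as package
defaults:

| constant | value | role |
|---|---|---|
| `v_ref` | −45.3 mV | positions NaV activation (half ≈ −20 mV, between the fast TTX-sensitive and TTX-resistant nociceptor channels); sets excitability, CV and junction safety factor |
| `a0_n` | 0.007 ms⁻¹ | KDR activation/deactivation speed; sets spike repolarization and the relative refractory tail that limits following frequency |
| `a0_l` | 10⁻⁸ ms⁻¹ | KDR slow inactivation effectively static at its −60 mV steady state (0.48); prevents slow excitability drift across long trains |
| CaV density | 3 mS/cm² (somatic) | largest value at which the soma does not fire Ca²⁺ bursts during 10 Hz trains |

Two further protocol-level constants follow from the calibration: train
stimuli use 0.4 nA (1 ms) pulses — at this voltage dependence a 0.2 nA
pulse sits at the train rheobase and intermittently fails to *generate*
spikes, which would confound every propagation measure — and the
critical-density sweep verifies spike generation at 1.5 nA for the same
reason. Single-pulse protocols (e.g. conduction velocity) keep 0.2 nA.

### What the calibration can and cannot reach

The calibration surface is over-determined: with the rate equations
above, one voltage shift must set threshold, conduction velocity, spike
amplitude and the junction safety factor together, and they disagree.
The frozen defaults are the Pareto point that preserves the *dynamic*
phenomena (finite following frequency near 100 Hz at the 75 µm stem,
monotone KCNQ suppression of following frequency with saturation at high
density, the stem-length dependence of filtering, echo-free trains).
Known residual disagreements with the literature benchmarks, all
reproduced by `scripts/acceptance.R` and asserted at their published
tolerances in `tests/testthat/test-acceptance.R`:

* The passive somatic input resistance and slowest time constant of this
  exact morphology are 259 MΩ and 9.1 ms (the numerical solution agrees
  with closed-form cable theory to four digits; the benchmark pair
  274 MΩ/8 ms corresponds almost exactly to the same model *without* the
  5 mm central extension).
* Conduction velocity scales with √diameter in a uniform-membrane cable,
  so the peripheral/central pair can match the benchmark ratio 0.54/0.28
  (ratio 1.93) only approximately; the calibration favors the central
  value (0.253 m/s) and the junction-dependent dynamics, leaving the
  peripheral CV at 0.374 m/s.
* The somatic spike overshoots (≈ 101 mV amplitude vs. the 73 mV
  benchmark) because the m-gate rates are an order of magnitude faster
  than the h-gate at spike take-off for any voltage reference, so the
  peak rides toward E_Na.
* The ultrafast h recovery (τ_h < 1 ms at rest) removes the
  Na⁺-de-inactivation mechanism behind KCNQ-enabled ectopic antidromic
  spikes, and shrinks the single-spike junction safety margin's
  sensitivity: a fresh spike crosses the junction down to ≈ 15 mS/cm²
  axonal NaV (benchmark 35), although *trains* at 40 mS/cm² genuinely
  fail at the junction above ≈ 100 Hz.
* SK-mediated filtering at 10 Hz requires a standing junction
  hyperpolarization far larger than the somatic SK conductance can
  produce before the required CaV density turns the soma into a Ca²⁺
  burster; the SK machinery (Ca²⁺ pool, q² gating, somatic or axonal
  placement) is implemented and unit-tested, but the 10 Hz failure
  phenomenon itself is outside this kinetics family.

## Numerics

The branched cable equation is integrated implicitly: a backward-Euler
solve of the voltage system on the tree (Hines-ordered elimination,
exact in one pass) staggered with exact-exponential (Rush–Larsen) gating
updates from steady-state/τ tables precomputed on a 0.025 mV grid by the
same R rate functions exposed to the user, so the kinetics exist in one
place. Ion pools update explicitly. A trapezoid (Crank–Nicolson) variant
is available and is used in the oracle tests, where it matches an
independent `deSolve::lsoda` integration of the identical two-compartment
system to < 0.1 mV through a full spike at dt = 2 µs. Backward Euler is
the default because it damps the sub-microsecond axial modes of 1 µm
compartments at practical time steps.

Default dt is 10 µs; the experiment layer and the acceptance script run
at 25 µs, where halving dt changes the junction spike amplitude by
< 0.5% and its arrival time by < 2%, and doubling every section's
compartment count changes amplitude by < 0.1%. The zero-area junction
node is an ordinary resistive node of the tree solve (three axial
neighbors, no capacitance). Degenerate inputs (non-finite state, zero
areas elsewhere, negative densities) are rejected with errors.

Impedance and voltage-transfer analysis run on the purely passive tree
(R_m, C_m, R_a only): the complex admittance system at s = j·2πf is
factored by the same tree elimination in O(n); a dense complex solve is
retained as an independent cross-check, and the two agree to 10⁻⁹.
Resting active conductances are negligible at −60 mV for these kinetics
(< 10⁻³ mS/cm²), so "passive" and "resting" impedance coincide here.

## Experiment layer

* **Reliability / following frequency.** Trains of 20 pulses at 4.6 mm in
  the peripheral axon; spikes detected 5 mm into the central axon
  (−10 mV upward crossings, 2 ms refractory window). Stimuli 2–20 are
  scored (the first spike of a train always propagates); a stimulus
  counts as propagated when a central spike falls in a latency window
  anchored on the first spike's latency, with greedy 1:1 matching.
  Following frequency = highest frequency with 100% reliability, from a
  coarse ladder plus bisection (1 Hz resolution below 40 Hz, 2 Hz
  above; ties to the lower frequency). Train length 20 is exposed as a
  parameter; the base model's following frequency is unchanged for
  trains of 10–40 pulses (failures appear from the second or third
  stimulus on, not late in the train).
* **Early/late mode separation.** Near the junction the waveform is
  bimodal (orthodromic spike, then the soma-reflected spike ≈ 1.5–3 ms
  later). The amplitude profile takes the *first* local maximum at each
  site; at the junction node itself the two modes begin to merge for
  spikes wider than the reflection delay.
* **Ectopic classification.** Events at two peripheral sites are paired
  within a conduction-time window; a proximal event preceding its distal
  partner (or lacking one) is antidromic, a distal event with no
  proximal partner is a collision.
* **Stem length.** 150 µm everywhere except the KCNQ experiments
  (75 µm, following the experimental series they reproduce); the SK and
  pump experiments use 150 µm.
* **Pump/ion experiment.** 100 Hz × 20 spikes with concentration dynamics
  enabled at a low (1.3·10⁻⁶ mA/cm²) and 1000-fold higher maximal pump
  density. Only the ratio of the two levels is constrained by the
  literature; the absolute scale was chosen so that the high level
  equals the density whose resting Na⁺ extrusion balances the resting
  NaV window influx. The leak calibration is done on the pump-free model
  for both levels so the raised pump expresses its electrogenic
  hyperpolarizing shift instead of having it absorbed into E_leak.
  Because a Michaelis–Menten pump sized this way cannot also balance
  resting K⁺ fluxes against a 100 nm shell, concentration updates
  integrate fluxes *relative to the resting baseline* computed at
  initialization — the standard compensating-transport idiom — so the
  resting state is an exact fixed point of the ion dynamics.

## What the toy fixtures do and do not show

The oracle fixtures (single RC compartment, two-compartment active pair,
uniform 2 mm cable vs. the analytic infinite-cable step response,
symmetric Y-junction) validate the integrator: time constants, charge
conservation, spatial spread, branch symmetry and ODE-level equivalence.
They say nothing about the biological fidelity of the kinetics — that is
the role of the benchmark suite above, whose residual disagreements are
listed in the calibration section. Equally, the deterministic generator
produces no channel noise, no spontaneous activity and no biological
variability: passing tests demonstrate correct numerics and the stated
emergent phenomena for this single parameterization, not robustness
across the physiological population.

## Reproducing the benchmark table

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes every benchmark from scratch (≈ 3 minutes): passive R_N and
τ₀, both conduction velocities, the somatic spike amplitude, the
geometric-ratio unity crossing, the critical NaV density, and the
following-frequency ladder (base, KCNQ 0.2/0.8 mS/cm², somatic SK), and
writes them as JSON.
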