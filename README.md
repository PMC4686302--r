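# drgtj — spike propagation through the DRG T-junction

`drgtj` is a biophysical, multicompartment model of an unmyelinated
(C-fiber) sensory neuron for studying how action potentials cross the
T-junction — the branch point inside the dorsal root ganglion where the
peripheral axon (0.8 µm), the central axon (0.4 µm) and the stem axon to
the soma meet. Every pain signal from the periphery must traverse this
junction, and its impedance mismatch makes it the natural site of
spike-train filtering; the package exists to quantify that filtering and
how membrane conductances (KCNQ/Kv7 M-current, SK-type Ca²⁺-activated K⁺
current, Na⁺/K⁺ pump, ion accumulation) regulate it.

At its core is the branched cable equation on a compartment tree,

C_m ∂V/∂t = −Σ_x ḡ_x · gate_x(V,[Ca]) · (V − E_x) + axial currents + I_inj,

with Hodgkin–Huxley-style NaV (m³h) and delayed-rectifier (n³l)
channels, a two-state KCNQ gate, a high-threshold Ca²⁺ channel (m²), an
SK channel (q²) driven by intracellular Ca²⁺ dynamics, Nernstian
reversal potentials at 308 K, and a per-compartment leak reversal solved
so the cell rests at −60 mV. The integrator is an implicit (backward
Euler or trapezoid) tree solve staggered with exact-exponential
(Rush–Larsen) gating updates, compiled in C++. A frequency-domain module
computes input impedance and soma→junction voltage transfer on the
passive tree, and an experiment layer measures conduction velocity,
spike-amplitude profiles, propagation reliability, following frequency
and ectopic (antidromic) spike generation under parameter sweeps.
Filtering at a branch point is summarized by the geometric ratio
GR = (d₁^{3/2} + d₂^{3/2}) / d_parent^{3/2}; GR > 1 means the daughters
load the parent and attenuate the arriving spike.

## A worked example

```r
library(drgtj)

## impedance mismatch at the junction: stem 1.4 um, central 0.4 um,
## peripheral 0.8 um parent
geometric_ratio(0.8, c(1.4, 0.4))
#> [1] 2.668586

cable <- discretize(build_geometry())
cable
#> T-junction compartment graph: 502 compartments, total area 0.000218 cm^2
#> passive: Rm = 10000 Ohm cm^2, Ra = 100 Ohm cm, Cm = 1 uF/cm^2

## input impedance at the junction for a 250 Hz signal (a ~2 ms spike)
input_impedance(cable, "junction", freq_Hz = 250)
#> [1] 54.90647

## evoke one orthodromic spike 4.6 mm out in the peripheral axon
model <- tj_model(cable)
trace <- run_simulation(model, tj_stimulus("peripheral", 4600),
                        duration = 45, dt = 0.025,
                        record = list(list("peripheral", 3600),
                                      list("peripheral", 1600),
                                      list("junction", 0),
                                      list("central", 4000)))
trace
#> tj_trace: 45 ms at 0.025 ms sampling, 4 site(s): peripheral@3600, ...
#>   junction@0         V in [-74.04, 34.26] mV

## the spike crosses the junction, attenuated there (~94 mV vs ~99 mV
## in the peripheral axon), and conducts at:
conduction_velocity(trace, c("peripheral@3600", "peripheral@1600"))
#> [1] 0.3743101

detect_spikes(trace$time, trace$v[, "junction@0"])
#>    t_cross t_peak  peak_mV amplitude_mV
#> 1 14.44136  14.75 34.26289     94.26289

## trains fail at the junction above ~100 Hz (75 um stem)
prop <- propagation_reliability(
  tj_model(discretize(build_geometry(stem_length = 75))), 120)
prop
#> propagation at 120 Hz: 10/19 scored stimuli -> 52.6% reliability
```

The numbers mean: the junction carries a 2.7-fold 3/2-power mismatch for
orthodromic spikes; its input impedance dips to ~55 MΩ (lowest point of
the whole tree); a single spike still crosses, losing ~5 mV of amplitude
at the node; and at 120 Hz about half of the spikes in a train fail to
reach the distal central axon, the hallmark of junction low-pass
filtering. `following_frequency()` automates the frequency search, and
`density_map()` places KCNQ/CaV/SK conductances by region to reproduce
the filtering experiments (`list_presets()` enumerates the standard
configurations).

A command-line interface wrapping the same functions is installed as
`exec/drgtj` (`drgtj simulate --config model.yaml --out results/`), with
YAML configs, CSV/JSON outputs and a JSON run record carrying the
calibration constants.

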