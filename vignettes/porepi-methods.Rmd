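---
title: "Methods: pi-helix pore states, hydration and conductance in a toy Nav pore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pi-helix pore states, hydration and conductance in a toy Nav pore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Eukaryotic voltage-gated sodium (Nav) channels are pseudo-tetramers whose
four pore-lining S6 helices can each adopt either a fully α-helical
conformation or carry a short π-helical stretch below the selectivity
filter. A π-helix hydrogen-bonds i→i+5 instead of i→i+4, inserting one
extra residue per turn; everything downstream of the bulge is rotated by
roughly one residue of register. At the activation gate this register
shift swaps which side chains face the pore lumen, changing the
hydrophobicity of the gate, and with it pore hydration, the free-energy
barrier to ion permeation and ultimately the single-channel conductance.
`porepi` packages the chain of analyses that connects these levels:

1. secondary-structure assignment and register-shift geometry
   (`assign_secondary_structure()`, `predict_pore_facing()`,
   `register_shift_map()`);
2. pore hydration from water-density profiles
   (`water_density_profile()`, `classify_gate_hydration()`);
3. ion-permeation free energy by well-tempered metadynamics
   (`run_wt_metadynamics()`, `reconstruct_free_energy()`,
   `barrier_height()`);
4. conductance from permeation-event counting under voltage
   (`detect_permeation_events()`, `replicate_conductance()`,
   `compare_models()`);
5. the composition → conductance-class decision logic
   (`classify_pore_state()`), and an orchestrating pipeline
   (`run_pipeline()`).

Channel-scale all-atom MD is far outside a desk-scale R package, so the
dynamical substrate is a deliberately simple Brownian-dynamics pore
(`simulate_pore()`) whose statistics the analysis layers can be validated
against exactly.

## The toy pore model

Ions move by overdamped Langevin dynamics along the pore axis z,

$$\Delta z = \frac{D}{k_B T} F(z)\,\Delta t + \sqrt{2 D \Delta t}\;\eta,$$

with $F(z) = -\,dU_{\rm PMF}/dz + q e V / L_z$. Units are Å, ps, kcal/mol,
K and elementary charges ($k_B T = 0.596$ kcal/mol at 300 K). The PMF is a
sum of Gaussians — one Gaussian barrier centered in the activation gate is
the standard scenario shape. The voltage enters as a uniform axial force
on ions only, the constant-field analogue of applying an electric field in
MD conduction runs. Ions also diffuse laterally and are confined to the
pore cylinder by rejection, the simplest scheme that leaves the axial
statistics untouched. The axial coordinate is periodic, so a steadily
driven ion recrosses the pore image after image, which is exactly what the
event counter must handle.

Waters are not propagated: every stored frame resamples `n_waters`
positions from the occupancy profile implied by the `dewetting_factor`
(uniform outside the gate slab, scaled by `1 - dewetting_factor` inside
it). The downstream hydration analyses consume occupancy statistics only,
so water kinetics would add cost without adding information. The default
`n_waters = 210` makes the bulk number density of the default cylinder
(radius 5 Å, length 80 Å) match liquid water (0.033 Å⁻³).

Initial ion positions are drawn from the Boltzmann distribution of the
PMF (ignoring voltage). This is a deliberate choice: at barriers of
4–6 kcal/mol the spontaneous crossing time exceeds any desk-scale run by
orders of magnitude, so a trajectory started on one side would never
equilibrate across the barrier. Seeding from equilibrium makes the
marginal distribution stationary from the first frame, which the
Boltzmann-inversion oracle and the equilibrium histogram test rely on.

Key defaults: box 30 × 30 × 80 Å, pore radius 5 Å, gate (−10, 10) Å,
D = 0.02 Å²/ps, dt = 1 ps, 10⁵ steps per replicate, 6 replicates,
−500 mV. With these, a flat-PMF ion drifts
$v = D q e |V| / (k_B T L_z) \approx 4.8\times10^{-3}$ Å/ps, about six
pore traversals per replicate — enough events for replicate statistics
without leaving the toy regime. Stored frames default to every 50th step;
net event counts are lap-topological (they equal the number of completed
box traversals), so storage striding does not bias them, which the
wrapped/unwrapped oracle-equivalence tests confirm.

## Event counting and conductance

An event is one complete traversal of the gate slab: the detector is a
double-gate state machine that records +1 when an ion that last entered
the slab from below exits above (mirror for −1), so re-crossings inside
the slab never double-count. Conductance uses the event-counting
definition

$$g = \frac{|N_{\rm net}|\, q\, e}{T\, |V|},$$

with $N_{\rm net}$ the *signed net* count in the field direction. Net
rather than gross counting matches the drift-current definition and is
robust to the occasional diffusive back-crossing. Replicate SEM uses the
sample SD with n − 1 over the per-replica conductances, and model
contrasts use a two-sided Welch t-test — the unequal-variance form, since
replicate variances of different pore models have no reason to be equal.
Degenerate zero-variance inputs are resolved by convention (identical
constant samples → p = 1).

One published arithmetic wrinkle is documented rather than hidden: an
experimental 17.5 pS converts to 6.125 events per 100 ns only at an
effective |V| ≈ 0.56 V, whereas N = g·|V|·T/e at the nominal 0.5 V gives
≈ 5.47 events. `estimate_conductance()` computes both conversions
faithfully; the package defaults to the literal 0.5 V everywhere.

## Hydration profiles

`water_density_profile()` bins waters inside a sampling cylinder
(default radius 5 Å, bins 1 Å) and normalizes by a bulk density taken
from a reference slab far from the gate. The hydration call takes the
*minimum* normalized density over the gate bins: below 0.05 the gate is
`dehydrated`, below 0.5 `partially_dehydrated`, else `hydrated`. The
cutoffs are package choices — the literature reports hydration
qualitatively ("continuously hydrated" vs "complete dehydration") — and
sit far from the generator's operating points (a dewetting factor of 0.3
gives ≈ 0.7, a factor of 1.0 gives exactly 0), so the calls are
insensitive to their precise values. Whether to restrict sampling radially
or use whole-box slabs is likewise unstated in the sources this mirrors;
the cylindrical convention is the package's choice and is stated on the
result object.

## Well-tempered metadynamics

The free-energy module biases the axial coordinate of a single tagged ion.
Every `stride` steps (default 500) a Gaussian hill of width σ (1 Å) is
deposited at the current CV value with tempered height

$$w = w_0 \exp\!\big(-V_{\rm bias}(s) / ((\gamma - 1)\,k T)\big),$$

default $w_0 = 0.3$ kcal/mol and γ = 10. The bias and its force are
accumulated on a 0.1 Å grid, with ±1 periodic Gaussian images. The
estimator is $F(z) = -\frac{\gamma}{\gamma-1} V_{\rm bias}(z)$, min-shifted
to zero. Voltage is zeroed during free-energy runs: the permeation free
energy is an equilibrium property, estimated separately from conduction
runs.

Two numerical choices matter in practice. First, the reported profile can
time-average the bias over the converged tail of the deposition history
(`tail_average`, 0.5 in the pipeline): the instantaneous well-tempered
bias fluctuates around the true profile with an amplitude that does not
vanish, and tail-averaging damps exactly that fluctuation. Second,
convergence is handled by fixed-length runs validated against an
independent Boltzmann-inversion oracle ($F = -kT\ln\rho$ on an unbiased
trajectory) rather than by hill-height thresholds — simpler, and directly
testable: on a 4 kcal/mol Gaussian barrier a 2 × 10⁶-step run recovers
the barrier within ±0.5 kcal/mol and agrees with the oracle within
0.5 kcal/mol RMSD on the central grid. The barrier statistic itself is
max F over the gate minus min F over a bulk reference region, invariant
under additive shifts. The CV is the absolute ion z with the pore centered
at 0; defining it relative to a protein center is meaningless in a toy
with no protein dynamics.

## Helix geometry

`build_ideal_helix()` grows N/CA/C/O backbones by natural-extension
(NeRF) placement from standard covalent geometry, with per-residue
(φ, ψ, τ) set by the secondary-structure string: α uses the textbook
(−57°, −47°) with τ = 111°, giving a 1.55 Å rise; π uses (−88°, −40°)
with a slightly opened τ = 115°, tuned on the builder itself so the
i→i+5 carbonyl–amide geometry satisfies the package's H-bond criterion
(O···N ≤ 3.5 Å, C=O···N angle ≥ 120°) at a 1.16 Å rise. Because an i→i+5
bond spans four intervening residues, the builder applies π dihedrals to
residues (s+2)..e of a requested stretch s..e; this calibration makes the
build → assign round trip exact for stretches of five or more residues,
and the round trip is enforced by test.

The assigner is geometric (distance + angle), not DSSP's electrostatic
energy model — simpler and adequate for ideal and near-ideal helices; π
takes precedence over α on overlapping patterns because π detection is
the purpose. Pore-facing prediction reconstructs an ideal Cβ from the
backbone by tetrahedral geometry (so side-chain-free PDB files work, and
glycine gets a placeholder) and calls a residue pore-facing when the
CA→Cβ direction is within 60° of the inward radial direction; the cutoff
encodes a categorical "faces the pore" judgment. `register_shift_map()`
is then pure residue arithmetic — numbers at or beyond the bulge advance
by one — and applying it at the three Nav1.5 S6 helices reproduces the
canonical pore-facing swaps (I409/V413 → L410/A414, F937/I941 →
I938/I942, V1766/I1770 → N1767/A1771, rotating the conserved DIV
asparagine into the pore).

## The state model and the pipeline

`classify_pore_state()` encodes the decision logic over the per-subunit
composition: with DIII-S6 π-helical (as in every resolved structure), π
in both DI and DIV ⇒ fully conductive; in exactly one ⇒ subconductance;
in neither ⇒ nonconducting; DII never changes the class. Compositions
with an α-helical DIII are flagged "outside modeled space" rather than
extrapolated — no structure or simulation has probed them. Functional
labels (O candidate, S2 candidate) are advisory strings, reflecting how
tentatively such assignments are made.

`default_scenarios()` maps each of the eight modeled compositions to a
toy parameterization: the reported per-model barrier where one exists
(2.9, 3.4, 4.1, 4.1, 4.8, 5.0 kcal/mol), and a 6.5 kcal/mol stand-in for
the two dehydrated nonconducting states, chosen so the Kramers-rate
expectation for the toy is below 0.1 events per replicate. Gate dewetting
is 1.0 / 0.3 / 0.0 for nonconducting / subconductance / fully conductive
scenarios. `run_pipeline()` then chains simulate → events → conductance →
hydration → metadynamics → classification per scenario, with per-scenario
seeds derived from one base seed; a failing scenario is logged and
skipped, and the report embeds a config hash.

## What the generator does and does not emulate

The generator reproduces the *statistical* features the analyses need:
drift–diffusion under a PMF plus field, equilibrium Boltzmann statistics,
replicate structure, tunable gate dewetting and the barrier–conductance
anticorrelation. It does not emulate protein dynamics (the real study
restrains Cα positions but allows side-chain motion; the toy has no
protein degrees of freedom at all), water kinetics, ion–ion interactions,
selectivity-filter chemistry or lipids. Consequently, passing tests
validate the analysis pipeline and the structural reasoning, not the
absolute conductances of the toy: those scale with $D\,n_{\rm ions}$ and
land at ~10–100 pS only by construction of the defaults, and no claim is
made that the toy reproduces published per-model conductance values.

## Problem sizes and numerical choices

The test suite runs replicate conduction at 10⁵ steps × 6 replicas,
equilibrium histograms at 10⁶ pooled samples (100 independent ions), and
metadynamics recovery at 2 × 10⁶ steps against an oracle built from
64 ions × 10⁵ steps — sizes chosen so every stochastic check has a wide
seed-robust margin while the full suite stays in the minutes range.
Degenerate inputs fail loudly and early: non-finite PMF forces, drift
steps exceeding a tenth of the box, empty hill tables, empty frames,
zero voltage in a conductance conversion, sub-2 replicate SEMs, gates
outside the profile. Unwrapping warns when a single-frame displacement
reaches half the box, where the minimum image becomes ambiguous.

## Known limitations

- The conductance scale of the toy is set by its diffusion constant and
  ion count, not by channel electrophysiology; only contrasts and
  orderings across scenarios are meaningful.
- The H-bond criterion is tuned for ideal and near-ideal helices;
  heavily distorted experimental helices may need DSSP-class methods.
- Water resampling removes any coupling between ion passage and gate
  wetting; hydrophobic-gating kinetics cannot be studied in this toy.
- The subconductance dewetting level (0.3) is a single representative
  value; the package does not attempt per-model hydration calibration.
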