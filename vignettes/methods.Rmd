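---
title: "Methods: models, calibrations and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibrations and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kv7em)
```

This vignette documents the science implemented in `kv7em`: the gating
model and its assumptions, the curve-processing and fitting conventions,
the energetic and classification rules, the contact and pore analyses, and
the synthetic-data generators used to validate everything. Where a choice
was genuinely open, the decision and its rationale are recorded here.

## The gating model

KV7.1-style channels are modelled with a single-VSD, three-state chain

$$R \;\underset{\beta_1}{\overset{\alpha_1}{\rightleftharpoons}}\; I
  \;\underset{\beta_2}{\overset{\alpha_2}{\rightleftharpoons}}\; A$$

where the pore conducts in both the intermediate (IO) and activated (AO)
VSD conformations with relative conductances $g_{IO}$ and $g_{AO}$. This
deliberately ignores the four-subunit architecture — a simplification that
is standard for this channel's two-open-state phenomenology and keeps every
downstream quantity analytic. Rates take the Eyring form
$k(V) = k_0 e^{\pm z_k V / V_T}$ with $V_T = RT/F \approx 25.4$ mV at
295.15 K (recordings at 21–23 °C; `thermal_voltage()` is configurable).

Because the chain is reversible, steady-state occupancies follow
$(P_R, P_I, P_A) \propto (1, K_1, K_1 K_2)$ with
$K_i = \alpha_i/\beta_i$, and relaxation after a voltage step is solved
exactly by eigendecomposition of the $3\times3$ generator (the tests check
it against an explicit-Euler integrator at 100-fold finer steps).

**Calibration, not measurement.** No rate constants or IO/AO conductance
ratios are published for this system, so the defaults are explicit
calibration values:

| parameter | default | rationale |
|---|---|---|
| $V_{1/2}$ step 1 / step 2 | −50 / +40 mV | well-separated F–V components, as observed in VCF |
| $z$ per step | 2 e0 | steep, clearly resolvable components |
| midpoint rate step 1 / 2 | 10 / 2 s⁻¹ | relaxation complete within a 4-s pulse |
| barrier asymmetry $\phi$ | 0.75 | slow deactivation at the tail potential (see below) |
| $g_{AO}/g_{IO}$ | 4 | AO dominates wild-type conductance |
| fluorescence amplitudes $A_1/A_2$ | 0.6 / 0.4 | both steps visible in ΔF/F |
| $E_K$ | −90 mV | physiological potassium reversal |

The charge of each step is split $\phi z$ on the forward and $(1-\phi)z$
on the backward barrier. With a symmetric split the backward rates at the
−40 mV tail step are fast enough that occupancancies relax measurably within
the tail-current measuring window, corrupting the "instantaneous" tail.
$\phi = 0.75$ makes deactivation slow at moderately negative potentials —
which is also the experimental phenotype of this channel — so tail currents
report the end-of-pulse open probability faithfully.

`construct_modifier()` expresses mutants and manoeuvres: conductance scale
factors (KCNE1-like and F351A-like suppression zero out $g_{IO}$;
AO-specific coupling loss zeroes $g_{AO}$), VSD locks (charge-swap
backgrounds pin $P_I = 1$ or $P_A = 1$), an expression factor, and a rigid
midpoint shift `dv_shift` used by the benchmark generators (a field beyond
the minimal modifier concept, added because a rigid G–V translation is the
cleanest way to inject a known activation-energy change without touching
the curve shape).

## VCF signal model and curve extraction

Simulated recordings follow

$$F(t) = F_0\, e^{-t/\tau_b}\,[1 + A_1 (P_I + P_A) + A_2 P_A] +
  \varepsilon,\qquad
  I(t) = E\,(g_{IO} P_I + g_{AO} P_A)(V - E_K) + \varepsilon$$

with additive Gaussian noise per sample and mono-exponential
photobleaching (default $\tau_b = 30$ s). Default protocol: 2 s holding at
−80 mV, 4 s test pulses, 0.5 s tail at −40 mV, 1 kHz sampling. Every
stochastic operation takes a mandatory seed and restores the caller's RNG.

Processing decisions:

* **Baseline.** The photobleaching trend is fitted to the first 2 s at the
  holding potential and extrapolated over the sweep. The default model is
  linear (the minimal assumption when only "fit and extrapolate" is
  specified); an exponential model is selectable and is the right choice
  when the bleach is known to be mono-exponential — the linear model leaves
  a small curvature residual over long sweeps.
* **ΔF/F** divides the corrected trace by the fitted baseline level at the
  sweep start, so the denominator includes the resting-state fluorescence —
  the same convention an experimenter applies when F₀ is read off the
  recording.
* **F–V** averages ΔF/F over the final 100 ms of the test pulse and
  normalises to the maximum across voltages. Because the holding potential
  (−80 mV) leaves a small resting intermediate-state occupancy, the
  extracted F–V is offset relative to the scheme's absolute curve; fits
  that need absolute component parameters use `free_scale = TRUE` (offset +
  scale), which recovers the component midpoints of the default scheme to
  better than 0.1 mV on noiseless data.
* **G–V** averages the tail current over a 4 ms window starting 1 ms after
  the tail step (the gap skips the capacitive-artifact region; both are
  configurable) and normalises to the maximum.
* **Degenerate normalisation.** If the pre-normalisation maximum is below
  5× the holding-period noise, the curve is flagged (warning + attribute)
  instead of silently normalising noise — important for zero-conductance
  constructs.

## Boltzmann fitting

`fit_boltzmann()` and `fit_double_boltzmann()` use bounded
Levenberg–Marquardt (`minpack.lm`) with multi-start initialisation: a
5×5 quantile grid over the two midpoints for the double fit, ties broken
by lower residual then smaller $A_1$. Bounds default to $z \in (0, 10]$,
$V_{1/2} \in [-150, 100]$ mV. Components are reported ordered
($V_{1/2,1} < V_{1/2,2}$). Degeneracy — collapsed midpoints (< 5 mV apart)
or a vanishing amplitude — raises a warning flag rather than silently
reporting an unidentifiable decomposition; flat curves return a
non-converged result. A midpoint pinned at its bound is treated as
non-convergence (the transition was not spanned by the data). Whether the
original analyses constrained amplitudes is unknown; both amplitudes are
free here by default, with `free_amplitude`/`free_scale` switches.

## Coupling energetics and classification

Activation energy uses $\Delta G = -zFV_{1/2}$ with $F = 23.06$
kcal mol⁻¹ V⁻¹ and $V_{1/2}$ in volts, taking $(z, V_{1/2})$ from the
single-Boltzmann G–V fit. The double-mutant-cycle coupling energy is
$\Delta\Delta G = G_{12} + G_0 - G_1 - G_2$ (invariant under a common
offset; energies are accepted in absolute form because that is how they
are conventionally reported), with interaction declared at
$|\Delta\Delta G| \ge 1$ kcal/mol. The screen rule flags a mutant when its
mean-plus-SEM current increase falls strictly below the wild-type mean
minus twice the wild-type SEM; strict `<` implements "below the line", and
rows marked `no_current` or `inactivating` are never flagged because their
currents cannot be interpreted under the rule.

The **four-test phenotype classifier** consumes: relative standalone
current; fluorescence detection; detection of both F–V components; and the
current ratios under KCNE1-like suppression, in the
activated-locked vs intermediate-locked backgrounds, and under F351A-like
suppression. The published experiments report these outcomes only
qualitatively, so the numeric cutoffs are package choices, embedded in
every report: a conditional ratio below 0.2 is "suppressed", a standalone
current above 0.3× wild type is "robust". AO-specific loss requires *all
four* tests to agree plus intact two-component fluorescence; any mixed
pattern is `inconclusive`, as is a contradictory panel (e.g. robust
current without membrane expression).

One readout needed a sharper definition than "current normalised to WT":
with $g_{AO}/g_{IO} = 4$, an AO-specific-loss construct retains only ~26%
of the wild-type *peak* current even though its conductance at the
voltages where it opens is nearly wild-type-like — experimentally such
constructs are described as having robust standalone currents. The
classifier therefore measures relative standalone current as the maximum
over test voltages of the construct/WT tail-current ratio, excluding
voltages where the WT tail is below 10% of its peak. At zero noise this
yields ~0.97 for the AO-loss construct and 0 for coupling-dead constructs,
cleanly separated by the 0.3 threshold.

## Benchmark generators: what they emulate, what they do not

`generate_vcf_panel()` produces recordings for phenotype constructs
(wild-type-like, classic coupling loss, AO-specific loss, expression null)
and DMC quadruples. A coupling energy δ is injected as an extra midpoint
shift on the double mutant, $\delta V = -\delta/(z_{\rm eff} F)$, where
$z_{\rm eff}$ is obtained by fitting the scheme's analytic G–V with the
same single-Boltzmann procedure the pipeline applies — so recovery tests
are exact up to noise and fit-window effects. Two generator-design
decisions matter:

* DMC quadruples are generated with the IO conductance suppressed, so each
  construct's G–V is a clean single-component transition ($z \approx 2$).
  With the full two-component conductance a single-Boltzmann activation
  energy is not a well-posed quantity — its fitted $z$ drifts with the
  position of the voltage window — and no fitting pipeline could recover
  δ reliably; suppressing IO makes the benchmark measure the pipeline, not
  the mis-specification.
* DMC panels use a −120…+100 mV test grid so all four midpoints stay
  inside the measured range for δ up to 4.4 kcal/mol.

Default noise (current SD 0.3 on tail currents of ~40 units; ΔF/F noise
0.002) is calibrated to typical VCF signal-to-noise; with it, recovered
|ΔΔG| errors are ≲ 0.1 kcal/mol (SD ≈ 0.06).

`generate_contact_trajectory()` builds C4-symmetric pseudo-trajectories in
which each residue pair toggles, per frame and subunit, between "in
contact" (rule distance = cutoff − 1 Å) and "apart" (cutoff + 2 Å) with the
planted per-state probability, plus 0.05 Å positional jitter. Sidechains
are reduced to exactly the atoms each interaction rule needs, arranged so
that the rule distance equals the anchor separation. The default pair set
spans all five interaction categories and all state-dependence groups,
including a sub-0.6 pair that is only detectable through the differential
rule. What this does *not* emulate: real rotamer chemistry, correlated
motions between subunits (draws are independent Bernoulli), drifting
contacts near the cutoff, or frame-to-frame autocorrelation — so passing
tests demonstrate correctness of the counting and rule machinery, not
robustness to every property of real trajectories.

`generate_toy_pore()` stacks rings of carbon atoms (24 per ring, 0.25 Å
apart) at radius $r(z) + R_{\rm atom}$ so the on-axis clearance equals the
analytic $r(z)$; cylinder and smooth-hourglass shapes are provided, the
hourglass waist defaulting to 0.9 Å — the scale of a closed-state gate
constriction.

## Contact analysis conventions

* Frequencies pool all (frame, subunit) samples:
  $f = \#\{d < \text{cutoff}\} / (n_{\rm frames}\times 4)$, with strict
  "below". Candidate screening uses the time-averaged minimum sidechain
  heavy-atom distance ≤ 5 Å. Presence in a state model requires
  $f \ge 0.6$ (≈ three of four subunits); if no model reaches 0.6, a model
  is called present when its frequency exceeds the lowest model by ≥ 0.4.
  An alternative flat 0.4 threshold appears in some summary figures of
  this literature; both thresholds are arguments, the 0.6 + differential
  rule is the default.
* Atom sets are explicit, editable tables: terminal methyls (ALA CB; VAL
  CG1/CG2; LEU CD1/CD2; ILE CD1, CG2; THR CG2; MET CE), aromatic rings
  (PHE/TYR six-ring, TRP six-membered ring — a flagged choice vs the full
  nine-atom system, HIS five-ring), charge groups/heteroatoms (ARG
  NE/NH1/NH2, LYS NZ, ASP OD1/OD2, GLU OE1/OE2, HIS ND1/NE2, plus
  sidechain O/N of SER/THR/ASN/GLN/TYR/TRP). The Met–Leu "branched carbon"
  is LEU CG. Category precedence: Met–aromatic and Met–Leu first, then
  aromatic π-stacking (even when the ring carries a polar atom), then
  electrostatic when both residues have polar atoms, then aliphatic;
  uncategorised pairs fall back to the generic shortest sidechain
  heavy-atom distance at 5.1 Å.
* Inter-subunit pairs are evaluated against both neighbouring chains
  (i→i+1 and i→i−1 under the cyclic A–B–C–D arrangement) and reported
  separately, because "adjacent subunit" is direction-ambiguous in a
  domain-swapped tetramer.
* Residue numbers are taken verbatim from the input chain records;
  glycines are excluded from candidate screening with a note.

## Pore profiler

At each axial step (default 0.125 Å) the profiler maximises the clearance
$\min_i(|c - x_i| - R_i)$ over sphere centres $c$ in the slice plane,
restricted to a 5 Å disc around the axis: 250 Metropolis iterations with
Gaussian proposals (SD 0.3 Å) under geometric cooling from 0.5 to 0.01 Å
of clearance, then a Nelder–Mead polish; the best centre seeds the next
slice so the probe follows a curved pore. Radii are clamped to [0, 5 Å];
empty slices report exactly the 5 Å cap. Hard-sphere radii are an explicit
table (C 1.85, N 1.75, O 1.65, S 2.0, P 2.1, H 1.0 Å) so profiles are
bit-reproducible from a config; established pore software embeds its own
radius sets, so agreement with published profiles is expected only
approximately. The default axis is the gyration-tensor symmetry axis (the
eigenvector whose eigenvalue is most separated from the other two — unique
for a C4 assembly); any axis can be supplied as origin + direction or two
points. The profile is invariant under rigid transformation of structure
and axis together, and the annealing result can never fall below the
axis-centred clearance (both properties are tested).

## Numerical choices and degenerate inputs

* Master-equation solutions via real eigendecomposition (reversible chains
  have real spectra); conservation is enforced to ≤ 1e−9 drift in tests.
* Fit tie-breaks: lowest RSS, then smallest $A_1$; midpoint-at-bound =
  non-converged; flat curves refuse to fit.
* `min_radius()` breaks ties by smallest |z| and flags all-at-cap windows
  as degenerate.
* File writes are atomic (temp + rename); delimited outputs are
  tab-separated, '.' decimal; PDB I/O tolerates missing element columns by
  inferring the element from the atom name.
* Problem sizes used in tests and the acceptance script — panels of ≤ 16
  recordings at 9–12 sweeps, 120–200 frames × 8 pairs × 4 models,
  ~100-slice pore profiles, 200 fit replicates — were chosen as the
  smallest sizes at which the statistical checks have comfortable margins
  (e.g. ≥ 5σ binomial separation for presence calls at 800 samples).

## Known limitations

* The gating model is single-VSD; cooperative four-subunit behaviour,
  inactivation, and temperature dependence are out of scope.
* Energetics assume the G–V is adequately described by one Boltzmann
  component; for strongly two-component conductances the derived ΔG is
  procedure-dependent (see the generator-design discussion above).
* The contact machinery analyses geometry only — no force-field energies,
  no hydrogens, no solvent.
* The pore profiler reports geometry, not conductance; a narrow profile
  does not by itself determine whether a conformation conducts.
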