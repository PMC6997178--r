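# kv7em

Quantitative tools for studying **two-stage electro-mechanical (E–M)
coupling** in KV7.1-style voltage-gated potassium channels.

KV7.1 (KCNQ1) opens its pore at two distinct voltage-sensor (VSD)
conformations: the intermediate-open (IO) and activated-open (AO) states.
Dissecting which residue interactions couple each VSD step to pore opening
requires a battery of quantitative analyses — voltage-clamp fluorometry
(VCF) curve processing, Boltzmann fitting, double-mutant-cycle (DMC)
thermodynamics, pharmacological screen statistics, state-dependent contact
analysis of structural models, and pore-geometry profiling. `kv7em`
implements that battery as a tested, reusable R pipeline, together with
synthetic-data generators with known ground truth so every stage can be
validated end to end without access to raw recordings or trajectories.

It is aimed at ion-channel biophysicists and structural bioinformaticians
who want reproducible, scriptable versions of these analyses.

## What it computes

**Gating model.** A three-state VSD scheme R ⇌ I ⇌ A with Eyring rates
`k(V) = k0·exp(±z·V/V_T)`, per-state conductances `g_IO`, `g_AO` and
two fluorescence amplitudes; simulators for steady state, voltage-step
relaxation, and full VCF recordings (current + fluorescence with
photobleaching and seeded noise).

**Curve analysis.** Photobleaching baseline correction over the holding
period, ΔF/F, F–V from end-of-pulse fluorescence, G–V from instantaneous
tail currents, and least-squares fits of

    G(V) = 1 / (1 + exp(−zF(V − V½)/RT))

as single or amplitude-weighted double Boltzmann (multi-start, bounded,
with degeneracy flags).

**Coupling energetics.** Activation energy ΔG = −zF·V½ (F = 23.06
kcal/mol/V), double-mutant-cycle coupling energy
ΔΔG = G₁₂ + G₀ − G₁ − G₂ with the |ΔΔG| ≥ 1 kcal/mol interaction rule, the
activator-screen hit rule (mutant mean + SEM below WT mean − 2·SEM), and a
four-test decision tree classifying constructs as WT-like, classic E–M
coupling loss, AO-specific loss, expression null, or inconclusive.

**Contact analysis.** Residue-pair interaction frequencies across
state-model trajectories (multi-model PDB, four chains), with the
interaction-type distance taxonomy — aliphatic methyl–methyl and aromatic
ring-centroid contacts at 5.1 Å, electrostatic heteroatom contacts at
3.5 Å, Met–aromatic at 7.1 Å, Met–Leu at 6.1 Å — presence calls (frequency
≥ 0.6, or ≥ 0.4 above the lowest model), state-dependence groups, candidate
screening at 5 Å mean sidechain distance, and Kabsch-superposition RMSD.

**Pore profiling.** A HOLE-style pore-radius profile: at every 0.125 Å
along the conduction axis the largest clearance sphere is found by
Metropolis simulated annealing plus a Nelder–Mead polish, capped at 5 Å.

## Worked example

```r
library(kv7em)

# Double-mutant cycle from published-style activation energies (kcal/mol)
dmc_cycle(1.7, 0.1, 1.2, -2.2, label = "L251-I268")
#>        pair  g0  g1  g2  g12  ddg abs_ddg interacting threshold
#> 1 L251-I268 1.7 0.1 1.2 -2.2 -1.8     1.8        TRUE         1

# Simulate a VCF recording of an AO-only construct and fit its G-V
s   <- gating_scheme()
rec <- simulate_vcf_recording(s, construct_modifier("IKs-like", g_io_scale = 0),
                              voltage_protocol(),
                              noise_sd = c(current = 0.3, fluorescence = 0.002),
                              seed = 1)
fit_boltzmann(extract_gv(rec), free_amplitude = TRUE)
#> single Boltzmann fit (converged)
#>     amp       z  v_half
#>  1.2163  1.9942 40.4821
#>   RSS = 0.0001076

# The fluorescence reports both VSD steps: a double Boltzmann recovers the
# two component midpoints (truth: -50 and +40 mV)
fit_double_boltzmann(extract_fv(rec, baseline_model = "exponential"),
                     free_scale = TRUE)
#> double Boltzmann fit (converged)
#>       c0      amp       a1       z1  v1_half       z2  v2_half
#>  -0.0521   1.1256   0.6046   2.0311 -49.5428   2.0302  39.6409
#>   RSS = 4.827e-05
```

The interaction call says the benchmark residue pair is energetically
coupled (|ΔΔG| = 1.8 ≥ 1 kcal/mol); the fitted `z ≈ 2` and `V½ ≈ +40 mV`
recover the second VSD step that drives AO conduction, and the F–V fit
separates the two VSD transitions near their true midpoints.

A command-line interface over the same functions is available via
`inst/scripts/kv7em` (subcommands `simulate-vcf`, `process-vcf`, `fit`,
`dmc`, `screen`, `phenotype`, `contacts`, `pore`, `make-synthetic`); every
run writes a JSON manifest with the seed and a configuration hash.

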