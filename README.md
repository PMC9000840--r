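# crowdsolv

Analysis toolkit for molecular-dynamics studies of **molecular crowding**
in small-crowder solutions: tetraethylene glycol (PEG-4) and water, with a
model protein (lysozyme) as the crowded species. The package implements
the full analysis layer such a study needs — solution composition
construction, translational diffusion with finite-size corrections, two
independent shear-viscosity estimators, a hard-sphere reference model,
and structural observables — together with synthetic-data generators
whose ground truth is known exactly, so every estimator is validated end
to end without any MD engine in the loop.

## What it computes

**Composition.** For a cubic box of volume *V* and a crowder
concentration *c* in % w/v (g crowder per 100 mL solution), the crowder
count is `N_peg = floor(c V N_A / (100 M_peg))` and water fills the
residual volume at its pure density (ideal mixing). Concentrations are
interconverted between % w/v, volume percent and weight percent, and the
crowder **volume fraction** φ is derived from the pure-component molar
volume.

**Diffusion.** From an unwrapped trajectory, the mean-squared
displacement over all sliding time origins gives the Einstein estimate

    D_PBC = slope(MSD vs lag) / 6 ,

corrected for periodic-image hydrodynamics (cubic box, ξ = 2.837297)

    D_0 = D_PBC + kB T ξ / (6 π η L) ,

with an additional size term `- 4 π R² / (3 L²)` inside the bracket for a
solute of hydrodynamic radius *R* (1.87 nm for lysozyme). The **Enskog
hard-sphere** reference

    D_HS / D_HS0 = (1 − φ)³ / (1 − 0.5 φ)

provides the purely excluded-volume decline against which simulated
normalized diffusion is compared, and `exponential_decline_fit()` fits
`exp(−k c)` to normalized declines.

**Viscosity.** Two estimators: the non-equilibrium
**periodic-perturbation** method, which inverts the steady velocity
response `v cos(2π z / l_z)` to a cosine acceleration of amplitude *A*
(default 0.05 nm/ps²) via `η = ρ A (l_z/2π)² / v`; and the equilibrium
**Einstein–Helfand** method, `η = V/(2 kB T) · d/dt ⟨[∫ P_offdiag dt']²⟩`
averaged over the six off-diagonal pressure-tensor components and time
origins, with a convergence report.

**Structure.** Kabsch superposition, backbone RMSD and per-residue RMSF;
non-normalized solvation RDFs whose plateau reads off the bulk number
density (33.3 nm⁻³ for water) and coordination numbers inside the 1.87 nm
shell; geometric hydrogen bonds (donor–acceptor ≤ 0.35 nm,
H–donor–acceptor ≤ 30°) classified by molecule class; pairwise
Coulomb + Lennard-Jones interaction energies with Lorentz–Berthelot
combination; Shrake–Rupley SASA split into hydrophobic (|q| < 0.2 e) and
hydrophilic parts.

## Worked example

```r
library(crowdsolv)

# composition of the 65% w/v solution in a 4 nm cubic box
solvent_counts(65, box(4))
#> $n_peg   [1] 128      # floor of 128.98
#> $n_water [1] 907

# quoted water-model comparison: simulated vs experimental viscosity
percent_deviation(0.31, 0.89)
#> underestimation by 65% (simulated 0.31 vs reference 0.89)

# recover a known diffusion constant from a synthetic Brownian trajectory
g   <- brownian_trajectory(1000, 2000, D_target = 1.0, seed = 301)
est <- diffusion_pbc(msd(g$unwrapped))
est$D_pbc
#> [1] 0.9919579            # 1e-5 cm^2/s, within 1% of the 1.0 target

# finite-size correction at water-like viscosity in a 4 nm box
yeh_hummer_correction(est$D_pbc, temperature = 298.15, eta = 0.31, L = 4)
#> [1] 1.491647

# hard-sphere decline at 40% crowder volume fraction
enskog_ratio(0.4)
#> [1] 0.27
```

A shell entry point is installed as `exec/crowdsolv` with subcommands
`composition-table`, `make-synthetic`, `analyze-diffusion`,
`analyze-viscosity-neq`, `analyze-viscosity-eq`, `analyze-structure`,
`sweep`, `percent-deviation` and `report`, each a thin wrapper over the
functions above.

## Scope

The package analyses trajectories; it does not run MD. Force-field
parameterization, Ewald electrostatics, thermostats/barostats and
secondary-structure assignment are out of scope, and reproducing
absolute densities/viscosities/diffusivities of real PEG-4 solutions
requires ns-scale engine trajectories that no desk-scale test can
replace — the synthetic generators validate the estimators, not the
force fields.
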