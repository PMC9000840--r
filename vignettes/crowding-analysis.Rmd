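---
title: "Methods: crowding analysis with crowdsolv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crowding analysis with crowdsolv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdsolv)
```

This vignette is the package's own account of the models and estimators
it implements, the choices made where several defensible designs exist,
and what the synthetic-data validation does and does not demonstrate
about real trajectories.

## The problem

In a cell, biomolecules move through solutions crowded by other
molecules. Crowding acts twice: excluded volume ("hard" interactions)
reduces the space available for diffusion, and transient attractive
contacts ("soft" interactions) add friction beyond what volume exclusion
predicts. A small crowder such as tetraethylene glycol (PEG-4, C8H18O5)
makes a convenient model system because it spans, within one chemical
species, the whole range from dilute aqueous solution to a pure crowder
liquid. The quantities of interest are the concentration dependence of
solvent and protein diffusion, the solution viscosity, and the structural
response of the protein: solvation shells, hydrogen bonding, interaction
energies, and the hydrophilic/hydrophobic split of its accessible
surface.

`crowdsolv` implements the analysis chain for such a study. It consumes
coordinates (GRO/PDB), trajectories (a plain-text frame format),
pressure-tensor series (XVG/CSV) and a per-atom topology table, and emits
tabular results. It never runs dynamics itself.

## Composition construction

Given a box of volume $V$ and a target concentration $c$ in % w/v, the
crowder count is

$$N_\mathrm{peg} = \left\lfloor \frac{c\,V\,N_A}{100\,M_\mathrm{peg}} \right\rfloor,$$

with $M_\mathrm{peg} = 194.23$ g/mol and a pure-liquid density of
1.12 g/mL, so $c$ ranges from 0 (pure water) to 112 % w/v (pure liquid).
Water fills the residual volume at 1.00 g/mL, again floored. The floor
rule (rather than rounding) is fixed by the 65 % w/v composition, whose
exact count 128.98 must map to 128 to be consistent with the rest of the
series. Three design points deserve a note:

* **Volume percent** is computed on the component-volume basis
  $100\,V_\mathrm{peg}/(V_\mathrm{peg}+V_\mathrm{water})$ (ideal mixing)
  rather than against the nominal box volume. The two differ only in the
  third digit, but the component basis is the one that makes a pure
  crowder liquid exactly 100 v% — with the box basis the realized
  molecule count of the pure liquid occupies 99.89 % of the nominal box
  and the floored column would read 99.
* **Pure-liquid boundary.** At exactly $c = 100\,\rho_\mathrm{peg}$ the
  solution is the pure crowder liquid and contains no water by
  definition; the residual-volume rule is bypassed there (it would
  otherwise admit 2 stray water molecules into the 0.07 % of box volume
  the floored crowder count leaves over).
* **Water-count ambiguity.** Reconstructed water counts differ by one or
  two molecules from typical published composition tables at
  intermediate concentrations; the exact historical rounding rule is not
  recoverable from the printed values alone. Tests therefore assert
  water counts within ±7 molecules, and exactly at the two unambiguous
  endpoints.

The crowder volume fraction $\phi = N_\mathrm{peg} M_\mathrm{peg} /
(N_A\,\rho_\mathrm{peg} V)$ uses the same ideal-mixing convention and is
clipped to $[0, 1]$.

## Diffusion

The mean-squared displacement is averaged over every particle and every
sliding time origin; multi-atom molecules are collapsed to mass-weighted
centres of mass first (the physically standard choice for a flexible
crowder and a protein, whose internal motions should not contaminate the
translational MSD). `diffusion_pbc()` fits an ordinary least-squares line
to the MSD over a lag window and reports slope/6 in units of
$10^{-5}\,\mathrm{cm^2/s}$.

* **Fit window.** Default 10–50 % of the maximum lag. The short-lag end
  is excluded because real MD has a ballistic/caging regime there; the
  long-lag end because few origins survive and the MSD estimate becomes
  noisy and correlated. Both ends are configurable.
* **Negative slopes** (possible in short, noisy windows) clamp to
  $D = 0$ with a warning rather than an error, so concentration sweeps
  do not abort on one bad window.
* **Wrapped input** is detected by a single-step jump larger than half a
  box length and refused with a pointer to `unwrap()`, which
  reconstructs continuous coordinates by accumulating minimum-image
  displacements (valid when sampling is fine enough that no particle
  travels $L/2$ between frames).

Periodic boundary conditions bias $D$ downward through hydrodynamic
self-interaction with periodic images. The correction adds
$k_B T\,\xi/(6\pi\eta L)$ with $\xi = 2.837297$ for a cubic box; for a
solute whose hydrodynamic radius $R$ is not small against $L$ the
bracket gains a $-4\pi R^2/(3L^2)$ term. At water-like viscosity
(0.31 mPa·s) in a 4 nm box the correction is about
$0.50 \times 10^{-5}\,\mathrm{cm^2/s}$ — comparable to the diffusion
constant itself, which is why the correction is not optional.

The Enskog hard-sphere ratio $(1-\phi)^3/(1-0.5\phi)$ serves as the
excluded-volume-only reference. Normalized declines are fitted with
$y = \exp(-k c)$ constrained through $(0, 1)$, matching the convention
of normalizing to 1 at the reference concentration before fitting;
$R^2$ is evaluated on the linear scale, and a constant series reports
$k = 0$, $R^2 = 0$ with a warning (the total sum of squares vanishes, so
the usual definition is indeterminate).

## Viscosity

**Periodic perturbation.** A cosine acceleration
$a_x(z) = A\cos(2\pi z/l_z)$ (default $A = 0.05$ nm/ps²) drives a steady
velocity profile whose amplitude $v$ inverts to
$\eta = \rho A (l_z/2\pi)^2 / v$. The amplitude is extracted by a
mass-weighted least-squares fit of $v\cos(2\pi z/l_z)$ against every
atom's wrapped $z$ — exact to machine precision on noiseless fields, and
the minimum-variance estimator under Gaussian velocity noise. A binned
discrete cosine projection over bin centres is computed alongside as a
cross-check; it is exactly orthogonal to a uniform drift but carries an
$O(\Delta\theta^2)$ binning attenuation (≈0.4 % at 20 bins), which is
why it is not the primary estimator.

**Einstein–Helfand.** From the six off-diagonal pressure-tensor
components,
$$\eta = \frac{V}{2 k_B T}\,\lim_{t\to\infty}\frac{d}{dt}\,
\frac{1}{6}\sum_{ij}\left\langle\Big[\int_{t_0}^{t_0+t} P_{ij}\,dt'\Big]^2\right\rangle_{t_0}.$$
The running integral is a trapezoidal cumulative sum; origins are taken
every 10 samples by default; the limiting slope is fitted over
20–80 % of the maximum lag. The maximum lag defaults to 1 % of the
series length: the statistical error of the squared displacement grows
roughly as $\sqrt{\mathrm{lag}/\mathrm{span}}$, so short lag windows
with many effectively independent origins estimate the slope far more
precisely, provided the window still sits well beyond the pressure
correlation time (users analysing slowly decorrelating systems should
raise `max_lag_fraction` accordingly). Engines that print only three
off-diagonal components are accommodated by mirroring
($P_{yx} = P_{xy}$, …). The running estimator $H(t)/t$ is recorded as a
convergence series, and `viscosity_convergence_report()` flags estimates
whose tail still drifts by more than 10 % — slow convergence is the
known failure mode of viscosity estimation in concentrated solutions.

The prefactor convention was validated against a process with a
closed-form answer rather than against any printed rendering of the
formula: for a stationary Gaussian pressure process with autocovariance
$\sigma_P^2 e^{-t/\tau}$, the Green–Kubo integral gives exactly
$\eta = V\sigma_P^2\tau/(k_B T)$, and the Einstein–Helfand slope must
converge to it.

## Structural observables

* **Superposition** is the SVD-based Kabsch algorithm with reflection
  correction; collinear references are refused. The test suite checks
  it against an independent quaternion-eigenvalue implementation.
* **RMSF** superposes frames onto the time-average structure with one
  refinement pass (superpose to frame 1, average, re-superpose to the
  average, re-average). Superposition itself drags isolated atomic
  motions slightly (the moving atom participates in the fit), so
  `superpose = FALSE` is available for lab-frame fluctuations.
* **Solvation RDFs** are deliberately *not* normalized by bulk density:
  the large-$r$ plateau then reads off the solvent number density
  directly (33.3 nm⁻³ for pure water). The protein–solvent distance is
  the minimum over protein atoms of the minimum-image distance to the
  solvent reference site — water's oxygen, the crowder's centre of mass.
  This convention is configurable because published peak positions
  depend on it and the original choice is rarely stated.
* **Hydrogen bonds** use the geometric criterion donor–acceptor
  ≤ 0.35 nm and hydrogen–donor–acceptor angle ≤ 30°, the convention of
  the standard GROMACS tool; both cutoffs are parameters. Donor
  hydrogens are attached to the nearest N/O of their residue within
  0.12 nm; a hydrogen with no such neighbour is a configuration error
  naming the atom.
* **Interaction energies** are plain pairwise sums within a 1.0 nm
  cutoff (Coulomb with $f = 138.935458$ kJ mol⁻¹ nm e⁻²; 12-6
  Lennard-Jones with Lorentz–Berthelot mixing) under minimum-image
  periodicity. No reciprocal-space term is included: engine energies
  computed with particle-mesh Ewald will differ in absolute value, so
  only trends across concentrations are comparable — a documented
  deviation, not an approximation error.
* **SASA** is Shrake–Rupley with a 0.14 nm probe, Bondi element radii
  and 960 quasi-uniform (golden-spiral) test points per atom — doubling
  the point count moves totals by under 0.5 %. Atoms with
  $|q| < 0.2\,e$ are summed as hydrophobic surface, the rest as
  hydrophilic; the two parts add to the total exactly by construction.

## Synthetic ground truth

Every estimator is validated against generators whose answer is known
exactly:

* `brownian_trajectory()` draws per-axis Gaussian increments of variance
  $2 D \Delta t$. Overdamped dynamics was chosen over full Langevin
  deliberately: the MSD is linear from the first lag, so fit-window
  effects are isolated from ballistic-regime effects. Consequently the
  validation says nothing about choosing fit windows in the presence of
  a ballistic regime — that remains the analyst's responsibility on real
  data.
* `cosine_flow_trajectory()` inverts the periodic-perturbation relation
  exactly to set the velocity amplitude for a target viscosity, with
  optional Gaussian noise; atom masses are set so the configured density
  is the realized one.
* `ou_pressure_series()` produces six independent AR(1) (discretised
  Ornstein–Uhlenbeck) components with stationary deviation $\sigma_P$
  and correlation time $\tau$, carrying its closed-form Green–Kubo
  viscosity in the metadata. Defaults ($\sigma_P = 80$ bar,
  $\tau = 2$ ps, $V = 64$ nm³, $T = 298.15$ K) give a water-like
  2 mPa·s and pressure fluctuations of realistic MD magnitude.
* `toy_solution()` packs protein beads (charges straddling the 0.2 e
  threshold), rigid 3-site waters (O −0.834 e, H +0.417 e) and 15-bead
  PEG-4 chains (small charges on carbons, larger on the hydroxyl groups)
  by rejection sampling at a 0.15 nm inter-molecular minimum distance.
  These charges are fixture choices that exercise every classification
  branch (donors, acceptors, hydrophobic split); they are not force-field
  claims.

All generators are deterministic given their seed, which is recorded in
the output metadata.

## Problem sizes and tolerances

The validation suite uses desk-scale problems chosen so each stochastic
tolerance has comfortable headroom: diffusion recovery within 10 % at
1000 particles × 2000 steps (observed ≈1–3 %); periodic-perturbation
viscosity exact (≤10⁻⁶ relative) without noise and within 2 % at 10 %
velocity noise on 10⁴ atoms; Einstein–Helfand within 15 % of the
closed form at 2 × 10⁵ samples (observed ≈1–8 % across seeds); the
homogeneous-gas density plateau within 2 % at ≈10⁵ site observations.
What passing these tests shows is that the estimators are correct and
unbiased at their documented tolerances on processes satisfying their
assumptions; what they cannot show is force-field accuracy, sampling
adequacy of any real trajectory, or the validity of the finite-size
corrections outside the dilute hydrodynamic regime they were derived
for.

## Known limitations

Orthorhombic boxes only (triclinic input is refused explicitly). Binary
XTC is not decoded — trajectories are interchanged through a documented
plain-text frame format. Rotational diffusion, anomalous-diffusion
exponents, Green–Kubo diffusion from velocity autocorrelations, Ewald
electrostatics and secondary-structure assignment are out of scope.
Interaction energies and hydrogen-bond counts depend on conventions
(cutoffs, site definitions) that are configurable but whose defaults
necessarily encode one choice among several reasonable ones.
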