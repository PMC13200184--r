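---
title: "Force matching and thermophysical property estimation with afmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force matching and thermophysical property estimation with afmtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmtools)
```

## What this package computes

`afmtools` implements the two halves of a property-prediction workflow in
which a classical force field is derived from reference forces (force
matching) and then used to extract thermophysical observables. In the
workflow this package mirrors, the reference forces come from
electronic-structure calculations and the observables from molecular
dynamics; here both are replaced by seeded synthetic generators with known
ground truth, so every estimator can be validated end to end on a desk-scale
problem. The molecule of interest is a cyclohexene-class hydrocarbon ring:
six carbons, one double bond, ten hydrogens.

## The force-field model

The nonbonded pair energy between atoms of types $i$ and $j$ is
Buckingham-class:

$$U_{ij}(r) = A_{ij} e^{-b_{ij} r} - \frac{C_{6,ij}}{r^6}
  \left[- \frac{C_{8,ij}}{r^8}\right] + \frac{k_e\, q_i q_j}{r},$$

with $A$ in kcal/mol, $b$ in 1/&Aring;, $C_6$ in kcal&nbsp;&Aring;$^6$/mol,
charges in elementary units and $k_e = 332.0637$ kcal&nbsp;&Aring;/(mol
e$^2$). Every unlike pair carries its own $(A, b, C_6)$ entry: there are no
combining rules, which is the structural reason hydrated-phase cross
parameters cannot be derived from two neat models and must be fitted to
solvent-containing reference data. Bonded terms are harmonic bonds
$k(r-r_0)^2$ and angles $k(\theta-\theta_0)^2$ plus a cosine torsion series
$\sum_n k_n (1+\cos n\phi)$, $n \le 3$. The $C_8$ term exists in the data
structure but defaults to zero: dispersion coefficients are treated as
frozen inputs from an upstream dispersion-specific fit throughout, never as
free parameters.

Intramolecular nonbonded interactions exclude first and second bonded
neighbours (1-2, 1-3) and keep 1-4 and beyond at full strength; this is the
dominant convention and it is configurable. Periodic evaluation uses the
orthorhombic minimum-image convention with the cutoff capped at half the
shortest box edge; there is no Ewald summation because the training
configurations are cluster-scale and the fitting target is short-range
force reproduction. Pair distances below 0.1 &Aring; raise an error rather
than returning astronomically large energies.

Two atom-typing schemes are supported, both derived purely from the graph
(so symmetric atoms always share a label): the *neat* scheme distinguishes
sp2 from sp3 carbons (2 carbon + 2 hydrogen types, 5 distinct bond terms on
the ring), and the *hydrated* scheme splits sp3 carbons into allylic and
homoallylic (3 + 3 types, 7 bond terms). The mixed-phase model reuses the
hydrated typing and charges.

## The staged force-matching fit

The fit minimises the weighted squared difference between model and
reference values over three observable classes: per-atom force components
of *active* atoms, molecular net forces, and molecular torques about each
molecule's centre of mass. Torque residuals are divided by a 1 &Aring;
lever arm so the three classes share units; the default weights are 1:1:1
because no principled asymmetry presents itself, and both are configurable.
For records that emulate a QM/MM partition only the solute atoms are
active, and molecular observables are formed only for fully active
molecules.

A key implementation fact: for fixed $b$, $r_0$, $\theta_0$ and charges,
the model forces are exactly linear in $A$, $C_6$, $C_8$ and the bonded
stiffnesses. The evaluator therefore returns a per-parameter basis
decomposition, and each stage solves an exact linear least-squares problem
in its free linear parameters. Nonlinear parameters ($b$, charges, $r_0$,
$\theta_0$) are refined by a bounded search (golden-section for one
parameter, L-BFGS-B for several; $b \in [1, 10]$ &Aring;$^{-1}$) wrapping
that linear solve. Charges are handled in the nonlinear set because the
Coulomb energy is bilinear in them ($q_i q_j$), not linear; in practice the
fits here follow the convention of pinning charges to the hydrated-model
values rather than refitting them.

Three numerical safeguards matter:

* **Column equilibration.** Repulsion basis columns at contact distance are
  of order $e^{-b r} \sim 10^{-5}$ while bonded-stiffness columns are
  $O(1)$; the design matrix is scaled to unit column norms before rank
  detection and solving, so the ridge penalty and the rank test act on a
  well-scaled problem.
* **Rank handling.** A rank-deficient design without a ridge either raises
  an error naming the unconstrained parameters or (default) warns and
  applies $\lambda = 10^{-8}$. Genuinely unconstrained parameters — for
  example solute-solute repulsion pairs that appear only at fixed 1-4
  distances inside a single solute molecule — are shrunk toward zero and
  refitted in a later stage that does constrain them.
* **Convergence.** Stages are cycled (block coordinate descent) until the
  objective stabilises, and because the remaining free parameters are then
  all linear, a final simultaneous solve lands on the joint optimum
  exactly instead of approaching it geometrically. The per-record basis is
  cached across linear-only stages, which is what makes the cycling cheap.

### The mixed-phase fit and its invariance

`joint_mixed_phase_fit()` fixes the charges to the hydrated-model values,
then (phase 1) runs a complete hydrated-only fit — solute-solvent repulsion,
then solute-solute terms as far as the hydrated records constrain them,
then bonded stiffnesses — and (phase 2) freezes the solute-solvent pairs
and refits solute-solute nonbonded plus a single bonded set against the
neat and hydrated records together. Because neat records contain no
solute-solvent pairs, they cannot inform those parameters, and the phase
structure makes the independence exact: the joint fit's solute-solvent
parameters are bit-identical to a hydrated-only fit from the same start.
The tests assert this at $10^{-10}$ with noisy data.

Fit quality is reported as RMSE, regression slope and $R^2$ per observable
class, pooled over vector components. The regression is through the origin
by default (forces are signed and symmetric about zero); an intercept
variant is available.

## Slab observables

Surface tension comes from the diagonal pressure anisotropy of a
two-interface slab,

$$\gamma = \frac{L_Z}{2}\left(\langle P_Z\rangle - \frac{\langle
P_X\rangle + \langle P_Y\rangle}{2}\right),$$

converted from bar&nbsp;nm to mN/m ($\times 0.1$). The same estimator
serves liquid-liquid interfacial tension; only the box contents differ.
Standard errors use block averaging, 5 blocks by default (matching a
1-$\sigma$, 68%-interval reporting convention); recovery checks in the
tests use 25 blocks because with 5 blocks the standard error *estimate*
itself carries ~35% noise and a nominal 2-SE band undercovers.

The liquid density of a slab uses a two-step, cavity-robust protocol:
step 1 finds the longest contiguous run of profile bins above a threshold
(default halfway between the profile's minimum and maximum — the
literature's specific threshold is not public, so it is a config key);
step 2 averages only the central fraction (default 0.5) of that run.
Interface roughness and cavities near the interface therefore cannot bias
the estimate, whereas the naive shortcut of reading the densest region is
biased high under fluctuations — the tests demonstrate both behaviours on
generated profiles. Vapor density averages the bins at least 1 nm away
from the liquid run.

## Critical point, vapor pressure, boiling point

The coexistence-envelope difference is fitted with a Wegner expansion,

$$\rho_l - \rho_g = \sum_{k=0}^{3} A_k |\tau|^{\beta_c + k\Delta},
\qquad \tau = 1 - T/T_C,$$

with 3D-Ising exponents fixed ($\beta_c = 0.325$, $\Delta = 0.5$). The
amplitudes are linear given $T_C$, so $T_C$ is found by a bounded 1-D
search (bracket: 1 K to 300 K above the highest data temperature; hitting
a bound is an error). The diameter is fitted as
$\rho_l + \rho_g = 2\rho_C + D_{1-\alpha'}|\tau|^{1-\alpha'} + D_1|\tau|$
with $\alpha' = 0.11$, by plain linear least squares.

A bias-variance caveat that the tests encode explicitly: at a
six-temperature design the four-amplitude expansion has a single residual
degree of freedom, and its $\tau$-power basis is nearly collinear. On
noiseless data the fit is exact (that is asserted to 0.5 K), but under 1%
multiplicative density noise $T_C$ is statistically unidentified — across
50 replicates roughly half the fits run to the search bound and the
global-minimum estimator scatters over hundreds of kelvin. The noisy
Monte-Carlo check therefore uses the leading-order estimator (one
amplitude) on a leading-order truth, where the mean $T_C$ error over 50
replicates stays well under 2 K. On real data the practical reading is:
keep the full expansion for precise, low-noise coexistence data and drop
to fewer terms as noise grows.

Vapor pressure follows the Antoine form $\ln P = A + B/(T+C)$, fitted by
least squares on $\ln P$ with an exact linear solve in $(A, B)$ nested in
a 1-D search over $C$. The form drifts over wide spans, so fits are
windowed: a low window for the boiling point and a high window for the
critical pressure (evaluated at $T_C$, with a warning when that
extrapolates past the window). Pressures are handled in bar and the fit
object carries a unit tag. The boiling threshold defaults to 1 atm with a
1 bar switch, since both conventions are current.

The free-energy route to the boiling point starts from
$\Delta G_{vap} = -RT\ln(\rho_g/\rho_l)$ and the ideal-gas relation

$$\ln\frac{P_g}{P^\circ} = \ln\frac{RT\rho_l/M}{P^\circ} -
\frac{\Delta G_{vap}}{RT},$$

evaluated at a few temperatures (default 298.15, 344, 364 K), correlated
linearly against $1/T$, and solved for the crossing of the boiling
threshold. Composing the two equations returns exactly $P = \rho_g R T/M$;
that identity is property-tested at machine precision. Because the
correlation is linear in $1/T$ *by construction*, the route agrees with
the Antoine route to well under 1 K only when the underlying truth is
itself Clausius-Clapeyron-like ($C \approx 0$); against a strongly curved
Antoine truth the two routes differ by a few kelvin, which is the same
order as the spread between the two routes' published applications. The
consistency check in the tests uses a shared $C = 0$ truth for exactly
this reason.

$\Delta G_{sol} = \Delta G_{vap} + \Delta G_{hyd}$ closes the
thermodynamic cycle (liquid to gas to hydrated), with uncertainties in
quadrature; the inputs arrive as numbers because free-energy perturbation
from raw trajectories is out of scope here.

## Transport and fluctuation estimators

* **Diffusion** uses the Einstein relation: multiple-time-origin MSD
  (origin stride 10 frames as a cost/variance trade-off, at most 200
  evenly spaced lags since the curve is smooth), straight-line fit over
  the 20-80% lag window, $D = \text{slope}/6$. A log-log slope test
  rejects ballistic input. The acceptance computation caps lags at 20% of
  the trajectory: long lags add variance without information once the
  regime is diffusive.
* **Viscosity** uses the Green-Kubo integral of the off-diagonal stress
  autocorrelation, averaged over the three components, trapezoidal,
  truncated by default at the ACF's first zero crossing (beyond it the
  empirical ACF is noise and the integral random-walks). The closed-form
  AR(1) and white-noise cases anchor the tests.
* **Compressibility** uses the equilibrium volume-fluctuation estimator
  $\kappa_T = \langle\delta V^2\rangle / (k_B T \langle V\rangle)$, and
  the vaporization enthalpy the textbook
  $\Delta H_{vap} = \langle U\rangle_{gas} - \langle U\rangle_{liq} + RT$.
  Both are standard substitutes chosen because the upstream workflow's
  exact recipes are not public; outputs are flagged accordingly in the
  report provenance.
* **Stokes-Einstein radius** $r = k_B T/(6\pi\eta D)$ converts $D$ and
  $\eta$ into a hydrodynamic size.

## The synthetic-data module

Every estimator has a generator with recorded ground truth (the
`"ground_truth"` attribute is the manifest); one master seed fans out to
named substreams so scenarios are independently reproducible and
bit-stable. Defaults follow the study conditions where they are cheap —
six coexistence temperatures from 360 to 460 K, free-energy points at
298.15/344/364 K, slab $L_Z = 12$ nm, surface tension 25.4 mN/m, diffusion
$0.99\times10^{-5}$ cm$^2$/s, compressibility
$1.0366\times10^{-3}$ MPa$^{-1}$ — and shrink elsewhere (tens of
molecules rather than hundreds).

Training configurations are built by overlap-rejected *cluster* packing:
each new molecule is anchored at van-der-Waals contact (1.9-3.2 &Aring;
gap) to a randomly chosen placed atom, with random rigid orientation and
0.05 &Aring; per-atom jitter. This matters: the short-range repulsion
parameters are identifiable only if the training set samples the repulsive
wall, and a loosely packed gas of molecules leaves $e^{-br}$ numerically
zero at all sampled distances. Reference forces are the ground-truth
evaluator's output plus i.i.d. Gaussian noise. The hydrated scenario
surrounds one solute with rigid three-site bent solvent molecules (types
`OW`/`HW`); this surrogate exists to exercise the QM/MM masking and
cross-pair logic, not to model water physics.

One generator default departs from the printed parameter set it otherwise
follows: combined with the tabulated amplitudes, critical temperature and
critical density, the tabulated diameter coefficients imply negative vapor
densities below ~440 K (the printed values are rounded independently and
are not mutually consistent). The generator keeps the amplitude set for
the branch difference — which is all the Wegner fit consumes — and uses
physical diameter defaults $(0, 1200)$ g/L; the rectilinear fit recovers
whatever diameter truth it is given, exactly, so nothing is lost.

What the generators deliberately do **not** emulate: real MD time
correlations beyond AR(1), polarization and many-body dispersion,
finite-size effects near criticality, quantum nuclear effects, and real
interfacial cavitation dynamics (cavities are carved geometrically).
Passing the closed-loop tests therefore demonstrates the *estimators* are
correct and unbiased under their stated statistical models, not that the
physics of a real liquid is captured.

## Problem sizes and runtime

The default test and acceptance runs use: 20 configurations of 8 molecules
for the zero-noise recovery fit; 6 + 6 configurations for the mixed-phase
invariance check; 50 replicates for the noisy critical-temperature study;
1000 particles over 10^4 steps for diffusion; 10^5 samples for
compressibility; 2 x 10^4 pressure-tensor samples for surface tension.
These sizes put every statistical recovery comfortably inside its
tolerance while keeping the whole suite at a few minutes on one core.

## Known limitations

* The evaluator is plain R and scales as $O(N^2)$ in atoms per
  configuration; it is meant for cluster-scale training data, not
  production trajectories.
* Ewald electrostatics, polarizable terms, virtual sites and
  hydrogen-bond-specific terms are not implemented.
* No long-range tail correction is applied to $\gamma$ for truncated
  dispersion, so slab tensions computed from truncated-potential data
  inherit that mild underestimate.
* Finite-size scaling corrections near the critical point are out of
  scope; the Wegner extrapolation inherits whatever finite-size bias the
  input densities carry.
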