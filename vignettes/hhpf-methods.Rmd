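---
title: "Hamiltonian hybrid particle-field MD: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hamiltonian hybrid particle-field MD: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhpfmd)
```

## The model

Hybrid particle-field (hPF) molecular dynamics replaces intermolecular
pair potentials by interactions between particles and smooth density
fields.  The Hamiltonian splits into three parts: the intramolecular
(bonded) energy of each molecule, an interaction functional $W$ of the
per-species *filtered* number densities, and an electrostatic functional
$W_{el}$ of the filtered charge density,

$$
\mathcal H = \sum_m H_0(\mathbf r^m, \mathbf p^m)
           + W[\tilde\phi_1,\dots,\tilde\phi_K]
           + W_{el}[\tilde\rho].
$$

Densities are assigned to a regular mesh by cloud-in-cell (CIC,
trilinear) interpolation and then smeared in reciprocal space by a
Gaussian transfer function

$$ \hat H(k) = e^{-\sigma^2 |k|^2 / 2}, $$

so the physical coarse-graining length $\sigma$ is a model parameter,
decoupled from the grid spacing $h$.  Forces and energies converge
systematically under grid refinement, and grid artifacts (aliasing)
are suppressed as $\sigma/h$ grows.  The default interaction density is
the standard mixing functional

$$
w = \frac{1}{2\phi_0}\Big(\sum_{kl}\chi_{kl}\,\tilde\phi_k\tilde\phi_l
    + \kappa^{-1}\big(\textstyle\sum_k\tilde\phi_k-\phi_0\big)^2\Big),
$$

with the Flory–Huggins mixing matrix $\chi$ (kJ/mol), the
incompressibility penalty $\kappa^{-1}$ (kJ/mol; conventionally
$7.45\,RT$, about 20 kJ/mol at 323 K), and the mean number density
$\phi_0 = N/V$.  Any other *local* functional of the filtered densities
can be supplied as an R expression in `phi_<species>`; its per-species
derivatives are obtained by symbolic differentiation (`stats::D`), so
the force path is agnostic to the functional form.  Nonlocal
functionals are out of scope.

The external potential acting on species $k$ is the functional
derivative convolved **once more** with the filter,
$V_k = H \star \partial w/\partial\tilde\phi_k$.  The second convolution
is forced by the chain rule: the energy depends on particle positions
only through $\tilde\phi = H\star(\text{CIC paint})$, so the derivative
with respect to a position picks up one filter factor from the energy
side and the assignment stencil from the painting side.  The package
verifies this by a finite-difference oracle (forces against
$-\partial W/\partial r_i$), which fails decisively if the second
convolution is omitted.

### Electrostatics

Because every charge is intrinsically smeared into a Gaussian cloud,
the electrostatic problem has no short-range part: everything is the
long-range (reciprocal-space) lobe of a particle-mesh Ewald sum.  The
filtered charge density $\tilde\rho$ is painted exactly like the number
densities; the periodic Poisson equation is solved in reciprocal space,
$\hat\Psi = 4\pi k_e\hat{\tilde\rho}/(\varepsilon_r k^2)$, with the
$k=0$ mode set to zero (the tinfoil / neutralizing-background
convention — the universal choice; a non-neutral system is legal and
triggers a warning).  The energy is
$W_{el} = \tfrac12 h^3\sum \tilde\rho\,\Psi$ and includes the cloud
self-energies ($k_e/(2\sigma\sqrt\pi)$ per unit charge in the isolated
limit, plus the Wigner background term $-1.4186\,k_e/L$ in a cubic
periodic box); both are configuration-independent at fixed $\sigma$, so
energy-conservation diagnostics are unaffected.  Two filtered unit
charges interact as $k_e\,\mathrm{erf}(d/2\sigma)/(\varepsilon_r d)$,
recovering plain Coulomb beyond a few $\sigma$.  The relative
permittivity defaults to 1 (bare beads, unit tests); aqueous
coarse-grained parametrizations conventionally use 80.  The charge
filter width defaults to the density filter width — a single smearing
length for the whole model.

### Bonded terms and backbone dipoles

Stretching ($\tfrac12 k_b(r-r_0)^2$), bending
($\tfrac12 k_a(\theta-\theta_0)^2$) and proper dihedrals
($c(1+\cos(n\varphi-\delta))$, IUPAC sign convention: cis $=0$,
right-handed positive) are standard.  The combined bending–torsional
backbone potential couples the bend angle $\gamma$ of a C$_\alpha$
triplet to the dihedral $\varphi$ of the quadruple,

$$ U = \tfrac12 k(\varphi)\,(\gamma - \gamma_0(\varphi))^2 + V_p(\varphi), $$

with $k$, $V_p$, $\gamma_0$ configurable cosine series in $\varphi$.
$\gamma$ is taken as the bend angle of the *first* triplet of each
quadruple, with consecutive quadruples sharing triplets; this
association is a convention of this package.  The series coefficients
have no canonical published values in a citable numeric form here, so
they are plain inputs with documented placeholders in the fixtures.

Peptide backbones can carry reconstructed dipoles: each
C$_\alpha$–C$_\alpha$ segment gets a $\pm q$ ghost pair at the segment
midpoint $\pm\,\delta\hat u$.  The default direction convention places
$\hat u$ in the plane of the local C$_\alpha$ triplet, perpendicular to
the segment (pointing to the side of the neighbouring site), so it
rotates with the backbone and depends on the local bend angle; the
convention is isolated in `reconstruct_dipoles()` and alternative
parametrizations are drop-in.  Ghost positions are never integrated:
electrostatic forces on them are pulled back onto the parent sites
through the placement Jacobian, which is computed by *complex-step
differentiation* of the placement map — exact to machine precision, so
the projected forces satisfy the same finite-difference oracle as every
other force family (and conserve total force and torque).  Collinear
triplets (|sin| below $10^{-8}$) fall back to a fixed perpendicular
with a warning; the same tolerance guards the bend/dihedral kernels.

## Force readout: two consistent choices

A genuine design tension exists on a finite mesh, familiar from
particle-mesh electrostatics (energy- versus momentum-conserving
schemes):

* **Exact readout** (`readout = "exact"`): differentiate the CIC
  interpolant of $V$ analytically.  The force is the exact negative
  gradient of the discrete energy at any resolution (the package's
  finite-difference oracle holds to $10^{-6}$ and better), but the
  trilinear stencil makes the force *discontinuous* when a particle
  crosses a cell face, which degrades long-run energy conservation
  (measured: $\sim 0.3$ %/ns on the bilayer benchmark).

* **Spectral readout** (`readout = "spectral"`, the default used by
  the integrator): differentiate $V$ in reciprocal space (Nyquist mode
  of the derivative zeroed on even grids) and interpolate the gradient
  back with the same CIC stencil.  The force is continuous in the
  positions and conserves energy extremely well (measured:
  $|{\rm drift}| \approx 5\times10^{-4}$ %/ns on the same benchmark),
  and a particle exerts exactly zero force on itself; it equals the
  exact gradient only up to interpolation error that vanishes under
  grid refinement.

Both are first-class; the consistency oracle pins the model down
through the exact readout, production dynamics use the spectral one.
Neither choice conserves momentum exactly — with the same kernel on
both sides the residual net force is assignment aliasing, decaying
roughly as $(h/\sigma)^2$; the energy ledger, not the momentum, is the
conserved diagnostic, and `remove_com_momentum()` exists for the
accumulated drift.

Related: the two-particle energy is *translation invariant* only up to
the same aliasing (measured: $5\times10^{-4}$ relative at
$\sigma/h=4$, $5\times10^{-5}$ at $\sigma/h\approx 11$); tests assert
the monotone decay rather than an unattainable absolute.

## Integration

The rRESPA (Trotter-factorized) propagator applies the slowly varying
field and electrostatic forces as velocity impulses of half the outer
step $\Delta t = n\,\delta t$ before and after $n$ inner
velocity-Verlet steps under the bonded forces only; exactly one field
evaluation per outer step (the opening impulse reuses the closing
evaluation of the previous step, since the positions have not moved in
between).  For $n = 1$ the step *is* velocity-Verlet under the summed
force, bitwise: the implementation delegates to the same code path with
the two force families summed before the kick.  Inner step default
0.01 ps (the stability scale of the bonded motions); the admissible
outer step grows with $\sigma$ (smoother fields), which the stability
test reproduces: on a homopolymer melt the breakdown moves from
$t_u \approx 0.2$–0.25 ps at $\sigma = 0.236$ nm to
$\approx 0.4$–0.5 ps at $\sigma = 0.472$ nm.

The scheme is exactly time-reversible up to floating point.  Round-off
injected at a velocity reversal is amplified exponentially by the
physical chaos of the melt (measured Lyapunov rate $\sim 0.4$/ps at
323 K), so a 2 × 50 ps round trip lands near $2\times10^{-7}$ nm while
a 2 × 25 ps one ($t_u = 0.05$ ps, 500 outer steps) stays below
$10^{-10}$ nm; the reversibility test uses the latter horizon.

Canonical sampling uses the global stochastic velocity-rescaling
thermostat (coupling time $\tau$, default 0.1 ps, applied once per
outer step): the kinetic energy relaxes on $\tau$ and samples its exact
canonical (chi-squared in $3N-3$ degrees of freedom) distribution,
verified by a Kolmogorov–Smirnov test in the suite; it preserves zero
net momentum and reduces to NVE as $\tau\to\infty$.  Temperature is
defined with the three centre-of-mass degrees of freedom removed
($3N - 3$) by default — a bookkeeping convention, not a physical claim.
The filter width may be rescheduled on the fly
(`sigma_schedule`, linear interpolation), the annealing device that
accelerates self-assembly at large $\sigma$ and then sharpens the
structure at small $\sigma$.

Runs are deterministic: one seed controls the whole stochastic stream
(thermostat noise; fixture builders take their own seeds), and
identical configurations reproduce trajectories bitwise in double
precision.  Single-precision mode (positions/velocities rounded through
32-bit floats once per outer step) is provided to mimic
reduced-precision production arithmetic; energies are always
accumulated in double.

## Filter-width calibration

`calibrate_sigma()` matches the grid-converged two-particle energy
curve (the Gaussian-core interaction
$\propto e^{-d^2/4\sigma^2}$ — the correlation of two
$\sigma$-Gaussians) to the pair energy of the *unfiltered*, grid-defined
model at a reference spacing, by default $h_{\rm ref} = 0.5875$ nm.
The unfiltered curve is alias-dependent (it depends on where the pair
sits relative to the grid), so it is averaged over random sub-grid
offsets and orientations — the reference curves in the literature are
smooth, which implies some such treatment, but the exact protocol is
not canonical and is therefore a documented choice here.  The converged
trial curve is evaluated through the exact reciprocal-space form of the
scan (the pair spectrum reduces to a plane-wave cross term on the
lattice), so each $\sigma$ evaluation is a cheap lattice sum with no
assignment-width bias.

The least-squares objective is also not canonical.  The default is the
energy curve with uniform weights over separations spanning
$[0, 3h_{\rm ref}]$; with that objective the best match at
$h_{\rm ref} = 0.5875$ nm is $\sigma_0 \approx 0.245$ nm.  The fit is
strongly weighting-dependent: relative-error weights (emphasizing the
curve tail) give $\approx 0.227$ nm, force-curve and joint fits
$\approx 0.245$ nm; simple moment matching of the CIC stencil
(variance $h^2/6$ per axis) gives $h/\sqrt6 = 0.240$ nm.  The widely
quoted matching value 0.236 nm lies inside this sensitivity band but is
not reproduced by any single objective above; `calibrate_sigma()`
therefore always reports the alternative fits in `$sensitivity`.
Fitted widths scale linearly with $h_{\rm ref}$, as dimensional
analysis requires.

## Fixtures: what the generators emulate

All test systems are built by seed-deterministic generators — nothing
is read from disk.

* `build_two_particle()` / `build_charged_pair()`: probes for the
  pair-interaction oracles.
* `build_homopolymer_melt()`: random-walk 10-bead homopolymers,
  harmonic bonds only ($r_0 = 0.5$ nm, $k_b = 1250$ kJ/mol/nm²,
  72 g/mol beads), Maxwell–Boltzmann velocities; density matched to the
  melt benchmarks ($\phi_0 \approx 8.3$ nm⁻³).
* `build_lipid_water_box()`: 10-bead coarse-grained lipids (choline-
  and phosphate-like head beads N, P; two glycerol beads G; two 3-bead
  hydrophobic C tails) in the shape of a 4-to-1 mapped phospholipid,
  plus water beads, at $\phi_0 \approx 8.5$ nm⁻³, either scattered or
  as a preassembled two-leaflet bilayer.  The accompanying
  `default_lipid_chi()` matrix is a *representative placeholder* with
  the qualitative structure of published coarse-grained lipid sets
  (strongly repulsive tail–water, mildly attractive head–water); it is
  **not** a published parameter set, and no quantitative claim in the
  test suite depends on its values — energy conservation, integrator
  identities and analytic limits hold for any smooth parameters, and
  the self-assembly check is a trend, not a rate.

What passing tests therefore show about real systems: the machinery
(filtering, forces, integration, sampling) is correct and convergent.
What they do not show: fidelity of any particular lipid's structure or
kinetics, which requires a calibrated interaction matrix and
paper-scale systems.

## Problem sizes and study conditions

Chosen once, as this package's desk-scale study conditions:

* Energy-conservation benchmark: 128 lipids + 725 waters (2004 beads,
  $\phi_0 = 8.49$ nm⁻³) in a 6.4 × 6.4 × 5.76 nm box; mesh 30 × 30 × 27
  so $h = 0.213$ nm and $\sigma = 4.7h \approx 1.0$ nm; inner step
  0.01 ps, field update 0.2 ps; 0.5 ns CSVR equilibration at 323 K
  (a freshly constructed fixture still relaxes structurally for a few
  hundred ps, and that activity inflates the apparent drift), then 1 ns
  NVE production; drift = OLS slope of the total energy as % of its
  mean magnitude per ns.  Measured: $|{\rm drift}| \approx 3
  \times10^{-4}$ %/ns, with a seed-to-seed spread of a few
  $10^{-4}$ from the stochastic component of a finite-window slope.
* Stability-ordering runs: 500-bead melt, 25 ps NVE per update
  interval, breakdown threshold 3 %/ns (the stable-regime noise floor
  is well below 1 %/ns, the broken regime is tens to hundreds).
* Self-assembly trend: 32 lipids + 320 waters in a 3.4 × 3.4 × 6.6 nm
  box, CSVR at 323 K, mesh 16 × 16 × 32, $\sigma \in \{0.236, 0.472\}$
  nm, 8 replicas each.  Pilot first-passage times to a spanning bilayer
  were 46–74 ps at the smaller and 22–38 ps at the doubled width, so
  the observation window is fixed at 40 ps — between the two scales,
  where the comparison is informative rather than saturated (any window
  long enough for both conditions to finish would trivially tie).
* Bilayer detection is a bespoke geometric criterion (there is no
  canonical detector): the tail beads must form a single $z$-slab
  (thickness < 0.6 of the box height after circular-mean recentering)
  that spans every column of a coarse $xy$ grid (no pore), with head
  beads present on both faces.  All thresholds are arguments and are
  returned in the diagnostics.

## Numerical conventions

* Units: nm, ps, g/mol, kJ/mol, elementary charge;
  $k_e = 138.935458$ kJ mol⁻¹ nm e⁻²,
  $R = 8.31446\times10^{-3}$ kJ mol⁻¹ K⁻¹.  Fixed constants, never
  inputs.
* Coordinates wrapped into $[0, L)$ per axis; minimum image for all
  bonded geometry; orthorhombic boxes only.
* FFTs: forward unnormalized, inverse carries $1/(n_xn_yn_z)$;
  angular wavenumbers $k = 2\pi m/L$ in FFT frequency order; Nyquist
  mode of odd-order spectral derivatives zeroed on even grids.
* The CIC assignment transfer function $\prod_d \mathrm{sinc}^2(k_dh_d/2)$
  is available for deconvolution (`compensate` in
  `pair_potential_scan()`), the standard particle-mesh compensation;
  the dynamical engine runs uncompensated, matching the plain
  formulation.
* Degenerate geometries: capped safe derivatives for near-collinear
  angles, skipped dihedral terms with collinear inner bonds, fixed
  perpendicular fallback for collinear dipole triplets — all counted
  and warned about.

## Known limitations

* Serial only; no domain decomposition or distributed FFT.  The layered
  update structure (field impulses around a bonded inner loop) is
  preserved, so the contract matches the parallel formulation.
* Constant volume only (NVE/NVT); no barostat, no virial/pressure.
* Local functionals only; CIC assignment only (no higher-order
  windows); isotropic filters only.
* Exact momentum conservation is sacrificed for energy consistency
  (see the readout discussion); net momentum performs a slow random
  walk and can be re-zeroed.
* The lipid and peptide parameters shipped with the fixtures are
  shape-compatible placeholders; quantitative structure prediction
  requires a calibrated $\chi$ matrix.
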