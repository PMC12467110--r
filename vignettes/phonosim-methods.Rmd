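---
title: "Simulating voice production with phonosim: models, numerics and scope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating voice production with phonosim: models, numerics and scope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonosim)
```

## The physical problem

Voiced speech is produced when air driven by lung pressure forces the vocal
folds into self-sustained oscillation; the pulsating glottal jet is the
acoustic source that the vocal tract then filters into formants. Subglottic
stenosis (SGS) — a narrowing of the airway below the folds, graded
clinically by the fraction of lumen area lost — changes the aerodynamic
load seen by the glottis and, at high grades, the voice itself. phonosim is
a desk-scale research simulator for this problem: it couples an
incompressible flow solver, a linear acoustic solver and a finite-element
tissue model around an idealized two-dimensional larynx, and provides the
full analysis chain (glottal waveform quotients, flow resistance, snapshot
POD of fold vibration, SPL, vocal efficiency, formant extraction) used to
quantify how stenosis severity degrades phonation.

## Hydrodynamic/acoustic splitting

The compressible flow variables are decomposed into an incompressible part
and a perturbed compressible (acoustic) part, `v = V + v'`, `p = P + p'`.
The incompressible pair `(V, P)` obeys the incompressible Navier–Stokes
equations; the acoustic pair obeys the linearized perturbed compressible
equations (LPCE),

    dv'/dt + grad(v' . V) + grad(p')/rho0 = 0
    dp'/dt + V . grad p' + gamma P div v' + v' . grad P = -dP/dt,

driven by the material time derivative of the hydrodynamic pressure. This
splitting lets the flow and the sound — which differ by two orders of
magnitude in propagation speed — be advanced with different schemes and
different time steps.

### Incompressible solver

Cell-centred collocated velocities and pressure on a (possibly
non-uniform) Cartesian grid; second-order central differences. Time
integration is a Van Kan fractional step: second-order Adams–Bashforth
convection (bootstrapped with forward Euler on the first step),
Crank–Nicolson diffusion, a pressure-correction Poisson solve and a
projection update. Face velocities are obtained by momentum interpolation
(Rhie–Chow) so the collocated arrangement does not checkerboard; after
projection the face-velocity divergence over fluid cells is at machine
precision (the suite enforces 1e-8). The Poisson and Helmholtz operators
are factorized once per geometry with sparse LU/Cholesky from the Matrix
package and reused across steps; a direct solve was chosen over an
iterative one because the desk-scale grids (tens of thousands of unknowns
at most) factor in milliseconds and the residual is then not a tunable.

Solid walls are immersed: each cell is flagged fluid or solid by ray-parity
tests against the closed interface polylines, and solid cells with a fluid
neighbour become ghost cells. For every ghost a body-intercept point is
found as the closest point on the surface; the mirror image of the ghost
centre through that point lies in the fluid and is evaluated by bilinear
interpolation, so that the boundary condition holds at the intercept
midway along the segment — second order, and exact for linear fields. When
part of a bilinear stencil is not fluid, the missing donors are replaced by
the boundary condition itself and the small system is solved directly,
which preserves linear exactness (the naive renormalization of weights
does not). Mass fluxes at immersed faces are set to the wall-normal
velocity directly: using lagged ghost mirrors there couples the stale
solid-cell pressure into the Rhie–Chow correction and is violently
unstable.

### Acoustic solver

Sixth-order tridiagonal compact finite differences in space (interior
alpha = 1/3; fourth-order compact at the second point; third-order
one-sided compact closure at the ends — the combination that is
time-stable, unlike the fourth-order closure) and the classical four-stage
Runge–Kutta method in time. Hard walls and open ends are realized by
parity mirror extensions of the fields before differencing (normal
velocity odd / pressure even at a wall; pressure odd / velocity even at an
open end): clamping boundary samples instead puts eigenvalues in the right
half plane at any CFL. In immersed geometries the derivative is taken per
maximal fluid run of each grid line with the wall parities applied at the
run ends; runs too short for the compact stencil fall back to second-order
centred differences. Lines being short, the tridiagonal solve is applied
as a cached dense inverse (one BLAS multiply per application).

Anechoic buffers occupy the outermost ten grid points of the open sides: a
raised-cosine damping-rate ramp applied multiplicatively per substep. The
peak rate defaults to eight sound-crossing rates of the buffer,
`8 c / (width h)`, which the 1D harness shows reflects well under 1% of an
outgoing pulse's amplitude over a double pass; the profile is a package
choice — any profile meeting the reflection bound is equivalent.

The acoustic step runs 16 substeps per flow step by default (the ratio of
the two stability limits); the flow fields and `dP/dt` (backward
difference of consecutive pressure fields) are held constant across the
substeps of one flow step. The ambient base pressure entering the sound
speed `c = sqrt(gamma P / rho)` is standard atmospheric, 101325 Pa.

### Tissue model

The vocal folds are linear, transversely isotropic, viscoelastic solids
with a body/cover layering. In the 2D reference model the fiber
(anterior–posterior) axis is out of plane and plane strain is assumed; the
in-plane constitutive matrix is obtained by inverting the 3D compliance
built from the five engineering constants and restricting it. Defaults
(kPa): cover E 1.33, E' 26.70, G 6.68, eta 0.9, eta' 0.0, with a vertical
stiffness gradient of 0.43 kPa/mm applied to the cover transverse modulus
along the inferior–superior coordinate (anchored at the inferior bound of
the layer, stiffening superiorly); body E 4.76, E' 95.24, G 23.81; tissue
density 1040 kg/m^3. The admissibility of the constants (positive definite
compliance) is checked at construction.

Constant-strain triangles with consistent mass; implicit Newmark time
stepping with exact elimination of the fixed-surface constraints.
Viscoelasticity is realized as Rayleigh damping (default alpha = 0,
beta = 1e-5 s — small, because no loss moduli are available for the layer
constants). The standalone integrator default is average acceleration
(beta 1/4, gamma 1/2; energy-conserving — the suite verifies 0.1% drift
per 100 steps); coupled runs use the dissipative variant gamma = 0.6,
beta = (gamma + 1/2)^2 / 4, whose algorithmic high-frequency damping
removes the non-physical grid-frequency ringing that the fluid otherwise
amplifies (next section).

Fold collision is a rigid-plane contact model: any wet-surface node
crossing its side's offset plane (midplane +/- 0.1 mm, i.e. a 0.2 mm
artificial total gap split symmetrically) is projected back and its normal
velocity zeroed. The residual gap keeps a thin fluid channel open so the
ghost-cell method always sees fluid between the folds; the corresponding
leakage area and flow floor are therefore features, not bugs, and the
metrics layer treats the closed-glottis level as a configurable closure
floor.

### Explicit three-step coupling and its stabilization

Each flow step: (1) the incompressible solve on the current deformed
interface, with the solid surface velocities as moving-wall conditions;
(2) the LPCE substeps on the same shape; (3) a solid step under the total
surface traction `-(P + p') n` (viscous traction omitted by default —
normal pressure dominates the fold drive; a config flag includes it), then
interface update and contact. There are no subiterations.

Loose coupling of an incompressible fluid to a light solid is subject to
the added-mass instability, and the desk-scale 2D fixture is unusually
exposed: the fold faces are large relative to the glottal and channel
cross-sections, so the pressure response to a wall-velocity fluctuation is
strong (the measured per-step gain of the bare scheme on the default
fixture is well above unity, independent of the time step and of tissue
stiffness). The package therefore applies first-order low-pass relaxation
to both interface exchanges — the traction passed to the solid and the
wall velocity passed to the fluid (relaxation factors 0.2 each, dissipative
Newmark as above). The filters act at the grid Nyquist scale; at phonation
frequencies (hundreds of Hz against a 5 microsecond step) their phase lag
is a few tens of microseconds and the resolved dynamics are unaffected.
This stabilization is a deliberate deviation from a pure unfiltered
explicit exchange: without it no coupled computation on this fixture is
possible at any time step.

The driving pressure (800 Pa inlet Dirichlet against 0 Pa outlet) is
ramped over 1 ms with a smoothstep to avoid an impulsive start against
kilopascal-stiffness tissue.

## Geometry and the stenosis parameterization

The fixture is a straight channel, 10 cm long and 2 cm wide, with a pair
of two-layer trapezoidal folds (1 cm inferior–superior thickness, medial
plateau, 1 cm anterior–posterior depth used to convert 2D gaps to areas)
protruding from the lateral walls to leave a configurable initial glottal
gap. The channel walls are immersed wall-region polygons extended past the
inlet/outlet planes (so near-boundary ghosts mirror across the lateral
wall, not an artificial end cap), which lets the same machinery carry the
deformed, stenosed wall. Structured fold meshes make the geometry
deterministic: identical configs give bit-identical fixtures.

Stenosis is the cosine constriction: within an axial window of length L
centred on the narrowest section, transverse coordinates scale by
`1 - (a/2)(1 - cos(2 pi y_c / L))` with `y_c` measured from the inferior
window bound; the taper is C1 at both ends, and the full cosine period
spans the window. Clinically motivated defaults: narrowest section 3.13 cm
below the superior fold surface, L = 1.0 cm; for anatomical tracts the
deformation is applied in a frame rotated 22 degrees about the z-axis (the
straight fixture uses 0). For a circular (or affinely circular) section
the hydraulic-diameter reduction `a` and the area severity `s` are related
by `s = 1 - (1 - a)^2`; the package provides both the closed form and a
polygon-area bisection calibration, which is the normative definition for
arbitrary sections. The clinical sweep severities 50/75/90/96% map to
a = 0.2929 / 0.5 / 0.6838 / 0.8.

In 2D the deformation acts on the single transverse coordinate, so the
width of the channel scales by `(1 - a)` at the narrowest plane — the
severity-to-width relation of a slot rather than a circle; severity labels
in the sweep refer to the circular-section convention throughout.

## Analysis suite

All metrics operate on uniformly sampled time-series records (tibbles)
and are pure functions of their inputs.

* **Cycle detection and phase averaging.** Cycle starts are rising
  crossings of the glottal area at the closure floor plus 10% of the
  amplitude; each cycle is divided into 1000 phase bins and averaged
  across cycles. The closure floor is the residual area of the enforced
  contact gap; the open/closed classification adds a 1% amplitude
  tolerance.
* **Quotients.** Open quotient = open fraction of the cycle; skewness
  quotient = flow acceleration duration over deceleration duration
  (onset-to-peak over peak-to-closure on the flow-active segment); MFDR =
  the steepest negative slope of the phase-averaged flow by centred
  differences (reported in L/s^2).
* **Fundamental frequency** from the dominant non-DC Fourier peak,
  refined by maximizing the windowed discrete-time Fourier magnitude.
* **Acoustics.** SPL from the RMS probe pressure re 20 micropascal, with
  1/r spherical spreading to a reporting distance; vocal efficiency
  `4 pi r^2 10^((SPL-120)/10) / (Ppul Ug)`.
* **Aerodynamics.** Flow resistance = cycle-mean pressure difference over
  cycle-mean flow (the mean-over-mean convention; the alternative
  mean-of-ratios is not used), for the stenosis span, the glottal span and
  their sum — additive by construction of the tap pairs. The area ratio is
  the cycle-averaged glottal area over the stenosis area
  `(1 - severity) x reference area`; the trans-glottal pressure-drop
  change is reported as a percentage of baseline.
* **POD.** Snapshot decomposition of mean-subtracted wet-surface
  displacements by SVD; energies are normalized squared singular values;
  the inner product is unweighted Euclidean (no mass matrix) —
  displacement snapshots uniformly sampled in time. Mode similarity across
  cases is the absolute normalized inner product (sign convention cannot
  change it), and requires identical surface meshes, which the fixture
  guarantees across severities since the stenosis deforms the tract, not
  the folds. Extreme states are the mean shape +/- the mode scaled by the
  peak temporal coefficient.
* **Formants.** `TF(f) = dp(f) / [dQ/dt](f)` with the time derivative
  taken before the transform, Hann window, single segment; bins with a
  near-zero source spectrum are masked, not divided. Formants are the
  first peaks above 5% prominence, parabolically refined. The pressure
  signal entering `dp` is the probe acoustic pressure relative to the
  far-field zero — the radiated-minus-ambient convention.

The synthetic waveform generator builds quarter-sine rise/fall pulse
trains with exactly prescribed f0, open quotient, skewness quotient, peak
levels and closure floors (defaults mimic the leakage of the contact gap:
flow floor 21% and area floor 20% of peak), plus optional seeded Gaussian
noise; every metric has a closed-form ground-truth value attached to the
record, which is how the analysis chain is verified to 1%.

## Problem sizes and what the tests do (and do not) show

The shipped configurations are deliberately small: a 48 x 72 grid over a
2.8 x 10 cm box, a few hundred tetrahedron-equivalent triangles per fold,
5 microsecond flow steps, sweeps of one-to-two hundred steps. These sizes
were chosen so every verification problem (Poiseuille to 1%, Taylor–Green
decay to 1%, second-order manufactured convergence, sixth-order interior
compact convergence, quarter-wave duct formants to 2%, beam theory to 2%)
runs in seconds to a couple of minutes on one core. They resolve the
physics of each component and the qualitative severity trends (flow drops
and stenosis resistance rises monotonically at high grade), but they do
not reach self-sustained fold oscillation — that requires several
phonation cycles (thousands of steps) and finer glottal resolution, and no
quantitative phonatory value from a full 3D anatomical simulation should
be expected from the fixture. The generator-driven verification of the
analysis suite is exact in the sense above but exercises idealized,
noise-controlled waveforms; real signals add cycle-to-cycle variability
that only the phase-averaging step addresses.

## Numerical choices and degenerate inputs

* Poisson systems without any Dirichlet face are singular; the solver
  demands an explicit gauge pin and mean-corrects the right-hand side.
* The severity map rejects severity outside [0, 1); the deformation
  rejects a >= 1 and windows extending beyond the surface.
* Cycle detection fails loudly on flat signals; quotients fail if the
  waveform never opens or the flow is flat; masked transfer-function bins
  propagate as NA rather than dividing by ~0.
* The instability detector aborts a run when any velocity exceeds a
  configurable bound (400 m/s by default) with a step-stamped message.
* Checkpoints serialize every prognostic field (including the
  Adams–Bashforth history and the interface filters), so a resumed run
  reproduces the uninterrupted trajectory exactly; a checkpoint is refused
  under a physics-relevant config change (run length and output cadence
  excluded).

## Known limitations

* The reference solvers are 2D; the geometry/STL layer is 3D-capable but
  the flow, acoustics and FEM operate on the plane-strain fixture.
* Explicit coupling requires the interface relaxation described above;
  configurations much stiffer or much lighter than the defaults may need
  stronger relaxation (both factors are exposed in the config).
* Contact is one-sided rigid-plane projection; no fold-fold force
  exchange.
* The acoustic solver's immersed treatment (parity extension per fluid
  run, ghost mirrors for sampling) is robust but formally reduces below
  sixth order near walls.
* No turbulence model: the kinematic viscosity default (6.6e-5 m^2/s,
  about a quarter of the physiological Reynolds number) plus the coarse
  grid regularize the supraglottal jet; fine-grid high-Re runs would need
  convective stabilization the package does not provide.
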