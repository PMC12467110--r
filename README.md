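# phonosim

Desk-scale fluid–structure–acoustic simulation of voice production with
subglottic stenosis, in R.

Voiced sound is made by airflow-driven vocal-fold oscillation; a subglottic
stenosis (SGS) — a narrowing of the airway below the folds, clinically
graded by the percentage of lumen area lost — changes the aerodynamic load
on the glottis and, at high grades, the voice. `phonosim` is a research
simulator for studying that interaction at desk scale. It is aimed at voice
and airway researchers who want a fully scriptable, testable 2D counterpart
of the large 3D phonation models: every solver stage, parameter and metric
is an ordinary R function.

The package implements:

* **Hydrodynamic/acoustic splitting.** The compressible problem is split
  into incompressible flow `(V, P)` and acoustic perturbations `(v', p')`:

  ```
  div V = 0,   dV/dt + div(VV) = -grad(P)/rho0 + nu0 lap(V)
  dv'/dt + grad(v'.V) + grad(p')/rho0 = 0
  dp'/dt + V.grad p' + gamma P div v' + v'.grad P = -dP/dt
  ```

  The flow solver is a Van Kan fractional-step scheme on a collocated
  Cartesian grid (AB2 convection, Crank–Nicolson diffusion, projection)
  with a sharp-interface ghost-cell immersed boundary; the acoustic solver
  uses sixth-order compact differences, four-stage Runge–Kutta, hard walls
  and ten-point anechoic buffers, substepped 16:1 inside each flow step.
* **Vocal-fold tissue.** Plane-strain finite elements with a two-layer
  (body/cover) transversely isotropic law, vertical stiffness gradient,
  Newmark time stepping and a rigid-plane contact model with a 0.2 mm
  artificial gap. Explicit three-step coupling carries the total pressure
  traction `-(P + p') n` to the folds and the fold velocities back to the
  flow.
* **Parametric stenosis.** The cosine constriction
  `x_s = x (1 - (a/2)(1 - cos(2 pi y_c / L)))` with severity
  `s = 1 - (1 - a)^2` for circular sections, clinical defaults (narrowest
  section 3.13 cm below the folds, L = 1 cm), and a severity sweep driver.
* **Analysis suite.** Cycle detection and 1000-bin phase averaging,
  fundamental frequency, open and skewness quotients, MFDR, SPL with 1/r
  reporting, vocal efficiency, flow resistances across stenosis/glottis,
  glottal-to-stenosis area ratio, snapshot POD of fold vibration with mode
  similarity, and source-filter formant extraction
  `TF(f) = dp(f)/[dQ/dt](f)`.

## Worked example

Generate a synthetic glottal pulse train with known ground truth and
recover the standard phonatory metrics:

```r
library(phonosim)

rec <- generate_waveforms(f0 = 154, tau_o = 0.69, tau_s = 1.32,
                          q_peak = 388, cycles = 10)
m <- phonatory_metrics(rec, closure_floor = attr(rec, "truth")$ag_floor)
round(as.data.frame(m[, c("f0", "tau_o", "tau_s", "mfdr", "Q_peak")]), 3)
#>        f0 tau_o tau_s    mfdr  Q_peak
#> 1 153.998 0.686  1.31 249.246 387.995
```

The record was built with a fundamental of 154 Hz, an open quotient of
0.69 (the glottis is open 69% of each cycle) and a skewness quotient of
1.32 (flow rises for 1.32 times as long as it falls); the analysis chain
recovers all of them to better than 1%, plus the maximum flow declination
rate in L/s² implied by the pulse shape.

Run the coupled simulator on the built-in larynx fixture and sweep
stenosis severity with rigid folds:

```r
sw <- run_experiment_matrix(
  list(flow = list(n_steps = 150), acoustics = list(enabled = FALSE),
       motion = list(mode = "static")),
  severities = c(0, 0.75, 0.90))
as.data.frame(sw[, c("severity", "Q_mean", "fr_sgs", "area_ratio", "dpvf_change")])
#>   severity   Q_mean   fr_sgs area_ratio dpvf_change
#> 1     0.00 195.3085 392246.9        0.2    0.000000
#> 2     0.75 185.0384 538766.5        0.8    5.250895
#> 3     0.90 175.2536 702788.5        2.0   10.265831
```

Mean glottal flow (mL/s) falls and the stenosis flow resistance
(Pa·s/m³) rises as severity grows, while the trans-glottal pressure drop
loses ~10% at 90% severity — the hallmark ordering by which a stenosis
first throttles the flow and only much later disturbs the folds.

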