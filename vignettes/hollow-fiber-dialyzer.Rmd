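---
title: "Modelling flow and solute transport in a hollow-fiber dialyzer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flow and solute transport in a hollow-fiber dialyzer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfdialyzer)
```

## The physical problem

A hollow-fiber dialyzer bundles thousands of semi-permeable fibers: blood
flows inside the fiber lumina while dialysate flows counter-current in the
shell around them. Small solutes (urea, creatinine) cross the membrane by
diffusion and, when a trans-membrane pressure (TMP) drives ultrafiltration,
by solvent drag. Wearable artificial kidney (WAK) devices operate this
exchanger at unusually low flow rates (tens of ml/min) with a single
dual-ventricle pulsatile pump that drives blood and dialysate in
counter-phase, which raises the TMP and with it the convective share of
solute removal.

`hfdialyzer` models one fiber and its dialysate annulus as an axisymmetric
Krogh unit with three radial regions — lumen (`0..R1`), porous membrane
(`R1..R2`), shell (`R2..R3`) — replicated `n_fibers` times. The defaults
describe a Multiflow M60 dialyzer: 4400 AN69 fibers, `R1` = 120 µm,
membrane thickness `h` = 50 µm, `R3` = 225 µm, length 15 cm, nominal
membrane area 0.6 m².

## Governing equations and assumptions

**Flow.** Steady incompressible continuity and momentum in axisymmetric
coordinates. The lumen Reynolds number of these devices is about 0.5, so
the default solver drops convective inertia (Stokes flow); a flag restores
it through Picard iteration and changes the solution by well under a
percent. The membrane is a rigid porous medium in the Brinkman
approximation: a Darcy resistance $\mu/k$ acts on the radial (superficial)
velocity, with the axial resistance a factor $10^4$ larger so the porous
annulus cannot short-circuit axial flow. Integrating the radial Darcy term
across the membrane recovers Starling's law of filtration,

$$v_w = L_p\,(\Delta P - \sigma\,\Delta\pi),$$

with hydraulic permeability $L_p = k/(\mu h)$. The working fluids are
protein-free (isotonic saline; density 1000 kg/m³, viscosity 1 mPa s), so
the osmotic term defaults to zero.

**Solute transport.** Steady convection–diffusion
$\nabla\!\cdot(\lambda\,\vec u\,C) = \nabla\!\cdot(D\nabla C)$ with
retardation $\lambda = 1-\sigma$ inside the membrane and 1 elsewhere, free
diffusivity $D$ in lumen and shell (identical on both sides, both aqueous)
and an effective membrane diffusivity $D_m$. For urea and creatinine the
default reflection coefficient is $\sigma = 0$: these small solutes are
not rejected by a high-flux membrane, and a non-zero $\sigma$ would
contradict the convective transfer the devices demonstrably achieve.

**Boundary conditions** mirror what a bench rig controls: fully developed
inlet velocity profiles carrying the measured inlet flows (blood at
$z=0$, dialysate counter-current at $z=L$), measured outlet pressures at
the two outlets, symmetry at the axis and (default) at `R3` — the
Krogh-cylinder stand-in for a periodic fiber array; a no-slip outer wall
is available. Concentrations are prescribed at the inlets and leave
through zero-diffusive-flux outlets.

**Quasi-steadiness.** The pulsatile pump runs at about 2 Hz. The lumen
momentum Womersley number $\alpha = R_1\sqrt{2\pi f/\nu} \approx 0.4$, so
the velocity field follows the instantaneous pressures; the mass-transfer
Womersley number is large ($\approx 11$), so the concentration field
cannot follow the pulsation at all and settles to the field of the mean
flow. Both regimes justify simulating at cycle-mean boundary values —
`synthesize_waveform()` and `time_mean()` produce those means, and
`quasi_steady_check()` evaluates the criterion. No transient solver is
provided, by design.

## Numerics

The flow solves on a staggered (MAC) tensor-product mesh: pressures at
cell centers, velocities on faces. Radial faces cluster toward the
membrane edges through a fixed tanh map on a uniform parameter grid, so
refinements nest exactly; the interfaces `R1`, `R2` always coincide with
faces and the membrane has an even cell count so a face lies on its
mid-surface. Continuity and momentum are assembled as one sparse linear
system and solved directly (`Matrix` LU) after row/column
max-equilibration — pressures in Pa and per-fiber fluxes in m³/s span
twenty orders of magnitude in coefficient size, and equilibration plus one
step of iterative refinement keeps the factorization well conditioned.
There is no pressure–velocity splitting to relax or tune; discrete
continuity holds to machine precision in every cell.

Across the free-flow/membrane interfaces the drag-dominated membrane
velocity profile is flat, so the shear-layer gradient is taken from the
free-side cell center to the interface itself; without this the effective
wall sits half a membrane cell too far out and the Poiseuille limit is
missed by over 10% at practical resolutions (with it, under 1%).

The solute equation is a conservative finite-volume discretization on the
same cells, using the staggered face fluxes of the converged flow — solute
conservation therefore inherits discrete continuity exactly (balance
errors are at solver precision, far below the 0.1% requirement). Diffusive
face conductances use harmonic two-sided averaging, which handles the
orders-of-magnitude jump of $D$ at the membrane interfaces and solves the
layered-annulus limit at second order. Convection uses a stable upwind
matrix with deferred correction to second order (linear-upwind axially,
central radially); plain upwind remains as a fallback
(`solute_options(scheme = "upwind")`). Radial transport is
diffusion-dominated (radial cell Peclet « 1) and axial numerical diffusion
is negligible against the physical axial convection, so the two schemes
differ by well under 1% on outlet concentrations. A guard rejects
solutions with oscillatory negative concentrations and advises refining.

The default mesh is 200 axial × 48 radial cells (24/8/16 per region; 9600
cells). Doubling both directions (38,400 cells) changes the
ultrafiltration of a calibrated case by 0.03%, so the default is
converged for all reported quantities; the unit-test suite uses coarser
meshes (≈80×30) that stay within a few percent, purely for speed.

**Reduced counter-current model.** `solve_flow_reduced()` collapses the
unit to a two-channel 1-D exchanger: lumen Poiseuille conductance
$\pi R_1^4/8\mu$, an annular-shell conductance integrated in closed form
(no slip at `R2`, zero shear at `R3`), and Starling leakage through the
nominal-area surface. The problem is linear, assembled with trapezoidal
coupling and solved directly — no shooting, no iteration. It agrees with
the 2-D solver on UF to about 1% across the calibrated bench cases (the
acceptance suite enforces 5%) and is the fast inner model of the
calibration loops.

**Areas and surfaces.** The nominal membrane area 0.6 m² equals the
*mid-membrane* surface area of 4400 fibers (the inner surface gives
0.497 m²). Starling velocities, UF integrals and the device law
$UF = L_p A\,\mathrm{TMP}$ are referenced to the nominal-area surface; the
Brinkman coefficient $k = L_p\mu h$ reproduces the same device
permeability within 1% (since $r_{mid}\ln(R_2/R_1) \approx h$).

## Calibration

`calibrate_lp()` reproduces the bench characterization procedure: a
bracketed root find on $f(L_p) = UF_{model}(L_p) - UF_{measured}$
(monotonicity is checked over the bracket $[10^{-13},10^{-9}]$ m/s/Pa
first), using the reduced model, with optional secant polishing against
the 2-D solver. Cases whose measured UF opposes the model TMP — the
porcine rows with negative ultrafiltration coefficients — admit no
solution under Starling filtration with zero osmotic pressure; the
calibrator reports the achievable UF range and `dialyzer_fit()` marks the
case infeasible rather than forcing a fit. Osmotic effects of real blood
are the plausible cause; modelling them is out of scope.

`calibrate_diffusivities()` fits $(D, D_m)$ per solute to the measured
blood and dialysate outlet concentrations of a reference case
(Nelder–Mead on log-parameters inside literature brackets
$[0.5,3]\times10^{-9}$ and $[0.3,3]\times10^{-10}$ m²/s). One structural
fact matters for interpreting the result: the model conserves solute
exactly, so its two outlet concentrations are both functions of a single
scalar — the total transfer — and the two diffusivities are identifiable
only up to a trade-off ridge (less free-side resistance can be traded
against more membrane resistance). The fit recovers the outlet
concentrations and the joint transfer resistance essentially exactly; the
individual split is pinned only by the brackets and the membrane leg's
dominance of the series resistance. The fit measures curvature along and
across the ridge and warns when the split is not identified, or when the
optimum sits on a bracket edge (as happens for creatinine on the bench
data, whose measured concentrations are internally inconsistent with its
clearance column). On the bench reference case the urea fit lands at
$D_m = 1.29\times10^{-10}$ m²/s, in close agreement with literature
membrane values, and reproduces both measured outlets within 0.6 mg/dL.

## Where the convective fraction is measured

In steady state the *total* radial solute flux is the same through every
membrane surface, but its convective/diffusive split is not: the
convective part $\lambda v C$ follows the concentration, which falls
across the membrane thickness. The split must therefore name its
reference surface. `flux_decomposition()` defaults to the blood-side
membrane face — the surface where solvent drag carries solute into the
membrane, and the convention under which the calibrated model's overall
convective urea shares (31% for the pulsatile case, 14% for the roller
case; entrance stations 41% and 24%, falling to 16% and 6% at the exit)
line up with the shares reported for this class of device. The
mid-surface and dialysate-side conventions are available and give
systematically lower fractions (25%/12% and 18%/9% overall); the choice
affects only the reported split, never the transfer itself.

## Performance metrics

All in bench units: TMP as the difference of mean compartment pressures
(mmHg); $K_{UF} = 60\,UF/\mathrm{TMP}$ (ml/hr/mmHg); the flow-weighted
generalized clearance $K = (Q_{b,in}C_{b,in} - Q_{b,out}C_{b,out})/C_{b,in}$,
which reduces to the conventional form when UF is small but remains
meaningful when UF reaches 30–50% of the blood flow as in WAK operation;
and the quadratic UF–TMP characteristic with $R^2$. Dimensionless numbers
follow the conventions that make the printed lumen Womersley number
(0.4 at 2 Hz, using the radius and angular frequency) reproducible;
some other tabulated dimensionless entries of the source bench study are
mutually inconsistent under any single convention and are treated as
diagnostics.

Comparisons against printed bench tables respect table precision: printed
flows and pressures carry half-unit rounding, so derived quantities are
compared within the worst-case propagation of that quantization (e.g. a
printed $K_{UF}$ of 14.0 against $60\cdot6/27 = 13.3$ recomputed from the
rounded inputs).

## The synthetic-data generator

`generate_case()`/`generate_table()` run the forward model at sampled
operating points with known ground-truth parameters and corrupt every
measured quantity with independent multiplicative Gaussian noise,
truncated at ±3 s.d., at the bench instrumentation levels — flows 8.5%,
pressures 12.5%, concentrations 6% (midpoints of the quoted 7–10%,
10–15%, 5–7% ranges) — then round to table precision (integer mmHg and
ml/min, one decimal for UF and concentrations). Rounding is part of the
measurement corruption and is disabled (`quantize = FALSE`) when studying
the noise-free limit. The default operating envelope mirrors the
pulsatile-pump bench rows: blood inflow 10–77 ml/min, dialysate inflow
30–42 ml/min, outlet pressures 5–33 and −32..−25 mmHg, spanning TMPs of
roughly 27–64 mmHg. The generator emulates quasi-steady *means* only — it
does not simulate raw time-series sensor noise, fiber-bundle
maldistribution, protein fouling or osmotic effects, so recovery results
bound what calibration can do under idealized bench statistics, not under
every failure mode of real blood experiments.

`recovery_study()` closes the loop: generate, calibrate each case, report
bias and RMSE against a first-order (delta-method) propagation of the
input noise, $\mathrm{sd}_{rel}(L_p) \approx (\sigma_f^2 +
\sigma_p^2(P_{b,out}^2+P_{d,out}^2)/\mathrm{TMP}^2)^{1/2}$. At the bench
noise levels with 50 cases the observed RMSE sits within a few percent of
that estimate and the bias is below 1%; noise-free recovery is exact to
solver tolerance.

## Known limitations

Newtonian fluid only (no hematocrit-dependent rheology); zero osmotic
pressure, hence no fit to the porcine backfiltration rows; uniform rigid
fiber bundle (no maldistribution or fiber collapse); no protein adsorption
or boundary-layer fouling; no charged-solute (Donnan) effects; no
whole-treatment dose metrics (KoA, Kt/V). The pulsatile waveform shapes
are stylized half-sinusoids with the measured means — adequate for the
quasi-steady pipeline, not for intra-cycle pressure extremes.
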