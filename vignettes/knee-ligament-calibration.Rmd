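---
title: "Calibrating knee ligament models from laxity measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating knee ligament models from laxity measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneelax)
```

## The problem

Subject-specific knee models need subject-specific ligament properties.
The measurable quantity that constrains those properties is joint laxity:
the displacement or rotation of the tibia relative to the femur under a
known applied force or torque, recorded at several flexion angles. Two
classes of laxity experiment exist. In-vivo-capable devices (here called
KLA-style) can apply anterior forces and internal/external torques at a
couple of flexion angles. Cadaveric robotic simulators (RKS-style) can
apply anterior-posterior, internal-external and varus-valgus loads over
the full flexion arc. The scientific question this package exercises is
whether the restricted in-vivo-style target set calibrates a model as well
as the rich in-vitro-style set.

Since the cadaveric source data are not redistributable inputs to a desk
tool, `kneelax` answers the question on *synthetic* knees with known
ground-truth parameters: generate a knee, measure it virtually with both
protocols, calibrate twice, and compare the two calibrated models on
protocols neither was calibrated to (AP laxity at clinical load, passive
flexion, pivot shift). `run_replication()` drives that whole experiment.

## Joint coordinates

All kinematics use the clinical six-degree-of-freedom joint coordinate
system: flexion-extension about a femur-fixed transepicondylar axis,
internal-external rotation about the tibia-fixed long axis, varus-valgus
about the mutually perpendicular floating axis, and translations measured
along those same three (generally non-orthogonal) axes. `gs_compose()`
realizes coordinates as a rigid femur-in-tibia pose via the intrinsic
rotation sequence z (tibial) - y' (floating) - x'' (femoral);
`gs_decompose()` inverts it, solving a small linear system for the
translations because the joint axes are not mutually orthogonal away from
neutral varus-valgus. Round-tripping is exact to below 1e-9 over the
physiological range, and the decomposition is singular only at 90 degrees
of varus-valgus, far outside physiology.

Signs follow the clinical convention (flexion, varus, internal, medial,
anterior, superior positive) for a left knee; `gs_mirror()` and
`mirror_knee()` map right knees onto the same convention by negating ML,
VrVl and IE. Internally, positive AP displaces the femur posteriorly
(equivalently the tibia anteriorly) and positive SI compresses the joint;
degrees and millimetres at every interface, radians only inside the
solver.

## Tissue mechanics

Ligament bundles are sets of straight-line tension-only fibers sharing two
material parameters: a reference-length ratio `r` setting the zero-load
length as `L0 = r * L_initial` (the fiber length in the initial
full-extension pose; `r < 1` means pretension, `r > 1` slack) and a
linear-region stiffness `k` in N/mm. The force law has a quadratic toe
region up to a strain of twice the toe parameter (default 0.03) and is
written in displacement form so the linear branch has slope exactly `k`
and the curve is C1-continuous at the junction. Closed-form strain
energies back the equilibrium solver, with gradient/force consistency
verified to 1e-6 relative in the test suite.

Cartilage contact is reduced to one point-contact element per condyle: a
femoral sphere articulating in a shallow spherical tibial dish (a flat
plateau is the infinite-dish-radius limit), with a tri-linear
force-overclosure law. The tri-linear slopes fold effective contact area
into stiffness; defaults (200, 800, 3000 N/mm with breakpoints at 0.2 and
0.5 mm) put the settling operating point in the first segment. The dish
gives the contact transverse centring stiffness, which is what the real
concave plateau plus menisci provide; without it a point contact on a
plane would leave the transverse plane restrained by ligaments alone.
Friction (recorded at 0.03) is *not* applied: in the quasi-static energy
formulation tangential forces at that coefficient are at most 3 % of the
normal force and would break the variational structure. This is a
documented limitation.

## Quasi-static equilibrium

The paper-scale explicit-dynamics machinery (settling with
temperature-switched damping, ramped load steps) is replaced by direct
potential-energy minimization with continuation, which reaches the same
quasi-static end states the protocol holds at. A load case prescribes
flexion and puts the other five DOF in load control; `solve_equilibrium()`

1. settles the joint under the model's SI compression (default 50 N,
   applied as a positive SI load; the value is configuration since the
   protocol's compression magnitude is not dictated by the physics),
2. steps flexion to the target in increments of at most 5 degrees,
3. ramps the target loads linearly in 10 substeps (path independence of
   the final state between 10 and 40 substeps is a tested property),

each stage being a damped-Newton minimization (compiled core, analytic
gradients, finite-difference Hessians, Levenberg regularization and an
energy-decrease acceptance rule) over (VrVl, IE, ML, AP, SI). Convergence
requires a residual norm below 1e-3 N, with rotational residuals expressed
as force equivalents over a 100 mm moment arm. Joint limits (defaults
±15 mm ML/AP, −5 to +10 mm SI — the protocol names no values, so these are
package configuration) flag dislocations and feed the calibration penalty;
they never clamp the solution. Warm starting from a previously solved
nearby state skips the continuation and falls back to it on
non-convergence.

## The calibration cost

Targets are grouped by loaded DOF and flexion angle (e.g. `anterior@30`),
because each group represents one physical laxity test at several load
levels. Per target and DOF the error is the settled simulated coordinate
minus the measured one; per (group, DOF) the score is the 75th percentile
(linear interpolation between order statistics) of absolute errors — one
settled measurement per trial makes the per-trial RMSE reduce to an
absolute error. Scores are normalized by the min-to-max span of that DOF
over *all* experimental targets, scaled by weights, and summed. Weights
default to 1.0 on a group's loaded DOF, 0.5 on its stated secondary DOF
(IE for AP-loaded groups and vice versa), 1.0 on AP/IE/VrVl for the
passive full-extension group, and 0 elsewhere; all are configurable
because the published weighting is not fully specified. If any trial
reaches an ML or SI joint limit the summed cost is squared once (for a
cost below 1, squaring *reduces* the number — the penalty's purpose is
shaping the search away from dislocating parameter regions, and the
squared form is retained as published). Non-converged target simulations
contribute a worst-case error equal to the DOF range rather than aborting
the optimizer.

## Two-phase optimization

Phase 1 is a global-best particle swarm over the box-bounded design
variables (the full model has 26: 14 reference ratios and 12 stiffnesses,
the three superficial MCL fibers sharing one stiffness). Constriction
coefficients (inertia 0.729, cognitive = social = 1.49445) are the
standard defaults since the original values are unstated; bound handling
clamps the position and zeroes the offending velocity component. Phase 2
polishes the swarm best with a bound-projected Nelder-Mead simplex
(standard 1/2/0.5/0.5 coefficients). Optionally the simplex is restarted
around its incumbent (`nm_restarts`): re-expanding a collapsed simplex is
the standard remedy for the flat reference-ratio/stiffness valleys this
cost exhibits, and the parameter-recovery experiment uses 4 restarts.
Every stochastic component takes an explicit seed and both phases record
best-so-far traces.

## The synthetic knee

Geometry is parametric-analytic rather than mesh-based: the calibration
physics only needs load sharing between discrete structures, which point
condyles and straight fibers preserve at desk scale. The flexion axis
passes through the condylar centers, so near-axis femoral attachments are
near-isometric through flexion as anatomically. Attachment sites follow
scripted rules relative to landmarks (the LCL origin, for instance, sits
1.4 mm superior and 3.1 mm posterior to the lateral epicondyle), with the
published fiber counts (30 fibers over 14 bundles) laid out equidistantly
along each attachment's major axis, and optional Gaussian jitter (default
0.5 mm) emulating attachment-identification uncertainty.

Default material parameters define a neutral reference state: stiffnesses
are the per-ligament means of the packaged calibrated-parameter table,
while reference ratios are near 1 — cruciates slightly pretensioned
(ACL 0.96/0.98), flexion-tightening structures slightly slack (PCL
1.02/1.03, ALS 1.03), capsule slightly taut (0.99). The published
specimen-specific ratios are *not* reused directly because they compensate
wrapped, curved ligament paths that straight-line fibers lack; applying
them verbatim produces a nonphysically pretensioned joint. On this default
knee the expected clinical behaviors hold and are tested: the ACL is the
most loaded group in every anterior laxity trial, the posterior trials
load the PCL, and removing the ACL in a pivot shift increases both the
anterolateral-structure load and the anterior translation.

Virtual measurement tables mirror the two experimental designs: KLA-style
tables carry anterior loads at thirds of the ~175 N maximum plus ±2.75 and
±5.5 N·m IE torques at 30° and 90° (the real device's intermediate load
levels are unpublished, so thirds are the declared default), 15 rows
including the passive full-extension row; RKS-style tables carry ±200 N
AP, ±7.5 N·m IE and ±10 N·m VrVl at 0/30/60/90°, 25 rows. Measurement
noise defaults to 0.3 mm / 0.3° SD, emulating motion-tracking error;
the replication experiment uses noise-free targets so that deviations
measure calibration error, not noise.

## What the replication shows, and does not

`run_replication(seed)` generates a knee, draws ground-truth parameters
uniformly within the published bounds, measures both protocols noise-free,
calibrates twice (8-bundle reduced model, 16 design variables, budget
15 particles × 40 swarm iterations + 100 simplex iterations), and
compares the calibrated models. Problem sizes are chosen so the whole
experiment runs in about a minute on one core; the reduced bundle set
(ACL_AM, ACL_PL, LCL, sMCL_M, dMCL, PCL_AL, ALS, POL) spans the anterior,
posterior, medial, lateral and rotational restraints. The same pattern the
cadaveric study reports emerges on synthetic knees: kinematic predictions
of the two calibrations agree closely (AP laxity RMSD well under the
2.5 mm headline bound, pivot rotations under 2.6°) while ligament-load
predictions can differ substantially — joint-level laxity pins down
kinematics long before it pins down the force distribution among
ligaments.

Passing these checks on synthetic knees shows the *pipeline* (targets,
cost, optimizer, solver) is sound and that the information content of a
KLA-style design suffices for kinematic calibration *of this model class*.
It does not validate the synthetic geometry against any real knee: real
ligaments wrap, cartilage deforms over areas, menisci and capsule
distribute load, and real measurement error is not white Gaussian noise.

## Numerical choices and limitations

* Energies in N·mm; torques converted from N·m at the interface.
* Solver tolerance 1e-3 N (translations; rotational components divided by
  a 100 mm arm); Newton step caps of 0.3 rad / 5 mm per iteration.
* Percentile type 7 (linear interpolation), matching `stats::quantile`'s
  default.
* Warm-start caching across cost evaluations makes a calibration run
  history-dependent only through its own deterministic evaluation
  sequence; identical seeds give identical results (tested).
* The reference-ratio/stiffness trade-off makes stiffness weakly
  identifiable from laxity endpoints alone (the recovery test bounds
  load-bearing reference ratios at 2 % but stiffnesses only at 15 %),
  mirroring the published observation that reference strain dominates.
* Ligament loads are not part of the cost, so calibrations agreeing in
  kinematics may disagree in loads; the replication reports the
  ligament-load RMSD to make that visible rather than hiding it.
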