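---
title: "Personalized closed-chain shoulder kinematic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized closed-chain shoulder kinematic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The problem

Marker-based shoulder kinematics is hard because the scapula glides over the
thorax: generic musculoskeletal models either leave the scapula
over-constrained (regression-driven) or under-constrained (free 6-DOF
bodies), and neither reproduces an individual's measured scapulothoracic
motion. `shoulderkin` implements a personalization framework for shoulder
kinematic models built around two ideas:

1. **A compact kinematic structure.** The scapulothoracic articulation is
   modeled with *spherical coordinates*: two orthogonal thorax-centered
   rotations (`q1` about the torso vertical axis, `q2` about the
   once-rotated anterior-posterior axis) followed by a radial translation
   `q3` along the twice-rotated lateral axis. Two optional scapula-centered
   rotations (`q4` approximately medial-lateral, `q5` approximately
   anterior-posterior) give the 4- and 5-DOF variants. A closed-chain
   shoulder model adds a 3-DOF glenohumeral joint (ISB-style Y-X-Y: plane
   of elevation, elevation, axial rotation), a 2-DOF sternoclavicular joint
   driving a scaled generic clavicle, and a point constraint tying the AC
   landmark on the scapula to the distal clavicle endpoint. The constraint
   closes a loop and removes three DOFs, leaving 6 (4-DOF scapula) or 7
   (5-DOF scapula) independent DOFs.

2. **Bi-level calibration.** Every joint carries 12 personalizable
   parameters: translation and orientation of its parent frame in the
   parent body and of its child frame in the child body. An outer
   nonlinear least squares adjusts selected joint parameters, body scale
   factors, constraint-point locations (and, if desired, marker positions);
   the residual for any candidate design is obtained by re-solving
   marker-based inverse kinematics (IK) for every frame of the motion data.
   The final product is a subject-specific model whose constrained
   kinematics reproduce the subject's measured marker trajectories.

# Kinematic model

## Frames, transforms, conventions

* Lengths are mm, angles rad internally (degrees only at I/O boundaries),
  time in s. TRC marker files are mm.
* All frame-orientation offsets use **body-fixed X-Y-Z Euler angles**
  (`R = Rx(a) Ry(b) Rz(c)`). The source convention for such offsets is not
  standardized across tools; this one is common in musculoskeletal modeling
  and is fixed in the model config schema so files are unambiguous.
* Quaternions (pose-trajectory input) are scalar-first, right-handed,
  normalized on construction.
* The torso frame follows ISB: origin at IJ, X anterior, Y superior,
  Z to the subject's right.

A joint's transform from parent body to child body is

```
parent_offset  o  motion_1(q)  o ... o  motion_k(q)  o  child_offset^-1
```

where each motion is an elementary rotation about, or translation along,
one axis of the *current* intermediate frame. Massless intermediate frames
are therefore represented implicitly by the ordered motion sequence — the
kinematics are identical to explicit intermediate bodies, the tree stays
simple, and each generalized coordinate drives exactly one motion. A
motion's value may also be an affine function of other coordinates, which
is how the coordinate coupler (below) is evaluated inside forward
kinematics rather than as an external constraint.

## Degrees of freedom

`independent_dof_count()` is the coordinate count minus three per point
constraint. The closed-chain model with a 5-DOF scapula has 10 coordinates
(5 scapula + 3 humerus + 2 clavicle), one point constraint, hence 7
independent DOFs; the 4-DOF variant has 6.

## Singularities

The spherical-coordinate chart is singular when `q2` reaches the poles
(±90°); shoulder motion stays far from them, and `q2` is bounded to ±80°
rather than specially handled. The Y-X-Y glenohumeral sequence is singular
at zero elevation (plane and axial rotation become collinear); the
synthetic motion scripts keep a small elevation baseline (0.2 rad) so that
test trajectories avoid the singular set, and users should expect the usual
Euler-sequence caveats near it. A related, subtler pitfall drove one design
choice in the synthetic subject: if the scapulothoracic child frame is
placed so that the radial coordinate `q3` operates near zero — i.e. the
spherical radius is baked into the child offset instead of the coordinate —
then at `q4 = 0` the rotations `q2` and `q5` become exactly redundant and
coordinates are no longer identifiable from markers. The generator
therefore puts the child frame at the scapula (near the landmark centroid)
with `q3` operating around 90 mm, which keeps the smallest singular value
of the coordinate-to-marker Jacobian comfortably away from zero over the
whole motion range.

# Inverse kinematics

Each frame solves a damped least-squares problem over the generalized
coordinates: the residual stacks the 3-D component errors of every visible
marker plus the closure residual (the vector between the two
constraint-attached points) scaled by `closure_weight`. Key settings
(`ik_settings()`):

| setting | default | meaning |
|---|---|---|
| `closure_weight` | 1000 | soft-constraint weight on loop closure |
| `closure_tolerance` | 1 mm | assembly threshold |
| `failure_penalty` | 1000 mm | error reported for unassembled frames |
| `max_iterations` | 100 | per-frame LM iteration cap |
| `ftol`, `xtol`, `gtol` | 1e-12 | convergence tolerances |

Loop closure is a heavily weighted *soft* constraint rather than an
explicit manifold parameterization. This matches the intended behavior
under infeasible designs: when the outer optimization proposes joint
parameters for which the loop cannot close (closure residual above
`closure_tolerance` at the solution), the frame is flagged unassembled and
every marker error for that frame is replaced by `failure_penalty`, so the
outer search is pushed smoothly away from infeasible regions instead of
failing. With the default weight, closure residuals at feasible optima are
orders of magnitude below the tolerance.

The per-frame solver is a Levenberg–Marquardt iteration (monotone
acceptance, adaptive damping on the scaled normal equations, analytic
twist-based Jacobians — a rotation motion contributes `ω × (p − o)`, a
translation its axis, to every downstream point — and box bounds by
clamping) implemented in compiled code; a trajectory is solved frame by
frame with each frame warm-started from the previous solution (frame 1
from the model's stored neutral pose). Warm starts make solutions
trajectory-continuous and fast, and a reversed trajectory yields the
time-mirrored solutions.

Two safeguards address local-minimum branches of the per-frame problem.
First, chained trajectory solves are followed by a backward refinement
pass: each frame is re-solved from its successor's solution and the
better-fitting branch is kept, so a wrong branch entered near a singular
pose (where chaining would otherwise lock it in) is corrected from the
other side. Second, the closed-chain builder bounds the glenohumeral
coordinates (plane ±1.6, elevation −0.5 to 2.6, axial ±1.6 rad) to the
anatomical range, which excludes the mirrored Y-X-Y solution branch
(plane and axial shifted by π with elevation negated) that noisy
low-elevation frames can otherwise fall into.

Marker weights are equal; no weighting scheme is applied.

# Personalization

A `personalization_task()` names the marker data (optionally decimated to a
stage rate), the scalar design variables (selectors), and solver settings.
`run_sequence()` executes tasks in order, each starting from the previous
task's output model.

The outer optimizer (`outer_lm()`) is a damped least-squares loop with
forward-difference Jacobians and box bounds. Two numerical choices matter
and were made deliberately:

* **Absolute, kind-specific difference steps** — 1e-3 mm for translations,
  1e-5 rad for rotations, 1e-5 for scales. Steps *relative* to the current
  value (the default in classic MINPACK-style drivers) collapse for
  parameters near zero (a frame rotation of 0.05 rad would get a step of
  ~1e-9) and land below the inner IK solve tolerance, turning Jacobian
  columns into noise. The chosen steps sit well above the inner solver's
  precision and well below the objective's curvature scale.
* **Warm-start state updated only on accepted steps.** The outer residual
  is computed by re-solving IK for every frame; those inner solves are
  warm-started from the per-frame solutions of the last *accepted* outer
  iterate. All candidate evaluations within one iteration (Jacobian
  columns, trial steps) see the same warm-start basis, so the objective is
  a deterministic function of the design variables; the basis tracks the
  optimizer so inner solves stay cheap. Off-the-shelf least-squares
  drivers offer no hook for this kind of optimizer-state update, which is
  why the loop is implemented in the package.

Default design-variable bounds (overridable per selector) are ±50 mm on
frame translations, ±45° on frame rotations, and [0.5, 2] on scale
factors; they keep the search away from non-anatomical minima.

## The staged shoulder protocol

`shoulder_protocol()` builds the six-task sequence used for closed-chain
models, personalizing one anatomical joint at a time (reducing the risk of
local minima), with the five staged tasks on 20 Hz-decimated data and a
final combined task on the full-rate data:

1. glenohumeral center location in scapula and humerus (6 parameters);
2. clavicle scale along its long axis plus the AC constraint-point location
   in the clavicle (4);
3. sternoclavicular parent-frame orientation in the torso (3);
4. scapulothoracic parent-frame location in the torso (3);
5. scapulothoracic child-frame location and orientation in the scapula (6);
6. all of the above together at the native rate.

The concatenated marker file is decimated once (not per motion) for the
staged tasks. Two structural notes, both consequences of the generic
clavicle being a straight segment with only its endpoint kinematically
relevant: the clavicle's y/z scale factors are unobservable (stage 2
scales only the long axis), and the sternoclavicular parent *orientation*
(stage 3) is unobservable in this package's model — rotating that frame
about its own origin maps the clavicle-endpoint sphere onto itself and
merely re-parameterizes the two free clavicle rotations. Stage 3 is kept
for protocol fidelity and converges immediately with no effect here; with
richer clavicle geometry it would become active.

Of stage 2's four design variables, only the effective constraint radius
(the distance from the sternoclavicular origin to the scaled constraint
point) is fully observable; the damped outer iteration handles the
resulting rank deficiency by leaving the unobservable combinations at
their starting values.

`scapula_protocol()` personalizes the open-chain scapula-only models: the
full 12-parameter scapulothoracic selector set, run first on 20 Hz data
and then refined at the native rate.

Both protocols can equally be loaded from an XML settings file
(`load_personalization_settings()`; packaged examples under
`inst/extdata/`).

## What the point constraint does under scaling

Scaling a body rescales its landmarks and, for constraints constructed
with `scale_with_body = TRUE` (the default, and the configuration used by
the shoulder protocol), the constraint attachment points as well — so
personalizing the clavicle scale moves the AC attachment with the bone, as
it should.

# The coordinate coupler

Keeping scapular translation as a free coordinate complicates dynamic
applications (its motion reflects scapulothoracic contact, not only muscle
action). `fit_coupler()` regresses the radial translation on the two
thorax-centered rotations — `q3 ≈ c0 + c1 q1 + c2 q2`, ordinary least
squares pooled over all frames of all motions with equal weight — and
`apply_coupler()` substitutes that affine function for the coordinate
inside forward kinematics. The coupled coordinate is solved *exactly* (the
reduced model simply has one fewer independent coordinate), not enforced by
penalty; the closed-chain model drops from 7 to 6 independent DOFs. A
linear function is a first-order stand-in for the ellipsoid-like thorax
surface; on data generated with an exactly linear relation the coupled
model reproduces markers to solver precision, while on general shoulder
motion the linear fit leaves a residual of a few mm that propagates into
roughly threefold-larger marker errors — the price of removing the DOF.

# Synthetic study conditions

The package carries a first-class generator so every stage is testable
without downloads.

* `make_subject(seed)` draws an anatomically plausible right shoulder:
  five scapula landmarks (GC, IA, TS, PLA, AC), three humerus landmarks
  (HHC, LE, ME) and three static torso landmarks (IJ, C7, T8), with
  landmark spans of 50–300 mm per body, ground-truth joint parameters, and
  a clavicle whose orientation and scale are constructed so the AC loop
  closes exactly at the stored neutral pose. All draws come from R's
  default Mersenne–Twister stream seeded once; the caller's RNG state is
  restored.
* `make_catalog()` runs the ground-truth model along eight scripted tasks —
  FE, WFE, SA, WSA, CA, WCA (elevation tasks sweeping 120° of glenohumeral
  elevation up and down in three elevation planes, weighted variants with
  ~15% larger scapular and slightly smaller humeral ranges) and ERa90,
  ERaR (axial-rotation sweeps at 90° abduction and near rest). Scripts are
  piecewise-quintic (zero endpoint velocity and acceleration, C¹
  throughout). Seven drivers are scripted (scapular `q1 q2 q4 q5`, three
  glenohumeral rotations); scapular translation and the two clavicle
  rotations are solved per frame so the loop closes exactly. Poses are
  exported as quaternion trajectories and converted to gold-standard
  markers by `synthesize_markers()` — the identical path a user takes from
  measured 6-DOF kinematics. Defaults: 100 Hz, 2 s per task
  (single-repetition fluoroscopy-like trials), i.e. 1608 frames over the
  eight-motion catalog.
* Skin-marker noise (`add_sinusoidal_noise()`): per marker coordinate one
  amplitude, frequency, and phase drawn uniformly from ±6.5 mm, 0–6 Hz,
  0–2π, added as a single sinusoid over the whole motion; draws are per
  motion file. Ten noise realizations are represented by seeds 0–9 (the
  seeds themselves are arbitrary labels). The expected per-coordinate RMS
  is `sqrt(E[A²]/2) = 6.5/sqrt(6) ≈ 2.65` mm, i.e. a 3-D displacement RMS
  of `sqrt(3)·2.65 ≈ 4.6` mm.

What the generator does *not* emulate: real soft-tissue artifact (which is
motion-correlated, not a stationary sinusoid), inter-subject anthropometric
statistics, CT-derived bone geometry, or measurement dropout. Passing the
test suite on these fixtures demonstrates that the machinery is correct
and well-conditioned — that model-consistent data are reproduced to solver
precision and perturbed parameters are recovered — not that a particular
accuracy will be achieved on any real subject.

Test and acceptance runs use these problem sizes: the full eight-task
catalog (2 s, 100 Hz) for personalization checks, 0.5 s catalogs for unit
tests, staged tasks at 20 Hz, the noisy-data experiment personalized and
evaluated on 20 Hz data, and leave-one-out cross-validation with the full
staged protocol whose combined task runs on 20 Hz data per fold. These
sizes were chosen so that the whole pipeline — including the bi-level
optimization — exercises the same code paths as a full study at a
desk-scale cost.

# Degenerate inputs and tie-breaks

* IK frames in which every marker is missing are solved on the closure
  residual alone (the coordinates simply stay near the warm start) and
  flagged with a warning.
* `error_stats()` requires at least one finite distance and errors on an
  empty marker subset; unassembled frames carry the failure penalty and are
  included as reported.
* `fit_coupler()` refuses rank-deficient regressions (collinear `q1`, `q2`).
* Coordinate bounds are enforced by clamping inside the inner solver;
  rotational coordinates default to ±π, the scapulothoracic translation to
  ±200 mm.
* TRC time columns are regenerated from the data rate on read; the stored
  time column is not trusted.

# Limitations

* The outer problem is solved locally from the supplied starting model; no
  multi-start or global search is attempted, which is why the staged
  protocol order matters.
* Maximum marker error is not directly minimized (it is not differentiable);
  only the sum of squares is.
* The generic clavicle carries no observable geometry beyond its endpoint;
  see the protocol notes above.
* Linear couplers only; an ellipsoidal relation would track the thorax
  better and is left as future work.
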