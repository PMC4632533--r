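---
title: "A segment-based model of the lower limb: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A segment-based model of the lower limb: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segbody)
```

## The model

`segbody` estimates muscle, ligament and joint contact forces of one lower
limb during movement by inverse dynamics posed directly on the body segments.
The limb is five rigid bodies — foot, shank, thigh, pelvis and a massless
patella — each with six degrees of freedom; no kinematic joint constraints
are imposed. Joints are represented by the forces that act across them:
muscle and ligament tensions along their geometric paths, and bone-on-bone
contact forces at fixed contact points.

For each capture frame the Newton–Euler equations of the foot, shank and
thigh (three force and three moment components each) are assembled into one
indeterminate linear system `A x = b` whose unknowns `x` are the muscle
tensions, ligament tensions and joint reaction components. The redundancy is
resolved by minimising the cubic load-sharing cost
`J = sum (F_i/Fmax_i)^3 + sum (L_j/Lmax_j)^3` subject to `A x = b`,
`0 <= F_i <= Fmax_i`, `0 <= L_j <= Lmax_j`, with reactions unbounded. A cubic
power emphasises load spreading across synergists while keeping the problem
smooth and strictly convex on the bounded block.

Four formulations are provided (`case = 1..4` in `freebody()`):

* **Case 1** — 18 equations. The patellofemoral joint is not explicit: each
  quadriceps element is routed through the massless patella, delivering
  `rho(theta)` newtons of patellar-tendon pull to the tibial tuberosity and
  the balancing patellofemoral contact force to the femur per newton of
  quadriceps tension; `rho` is the patellar/quadriceps tendon force ratio
  (P/Q) from the patella's sagittal-plane moment equilibrium. The effective
  upper bound of the tendon force is therefore `rho(theta)` times the summed
  quadriceps bounds, adjusted with knee flexion. Moment rows use *effective*
  moment arms: the whole rotational effect of 1 N of element tension,
  including the joint reactions it induces.
* **Case 2** — the patella becomes explicit: the patellar tendon force and
  the three patellofemoral reaction components are added as unknowns, three
  patellar force-equilibrium rows and one row enforcing
  `F_pt = sum(rho_i F_i)` are appended (22 scalar rows in this
  implementation: 18 segment rows + 3 patellar rows + the ratio row). Moment
  rows keep the hybrid effective-arm form.
* **Case 3** — fully segment-based: moment rows use plain attachment arms
  (`r x p`) and the joint reactions appear explicitly with their own moment
  arms (skew matrices of the joint-centre offsets). Cases 2 and 3 define the
  same feasible set algebraically — the reactions eliminated from case 3's
  moment rows via the force rows reproduce case 2's effective arms — and the
  test suite verifies that their solutions coincide.
* **Case 4** — the tibiofemoral contact is split into medial and lateral
  compartment contacts 2 cm either side of the joint centre along the tibial
  z-axis (193 unknowns with the full anatomy). The compartment split is
  resolved *simultaneously* with the muscle forces because the compartments
  carry moment arms in the knee's moment rows.

Moments are referenced to each segment's proximal joint centre, where the
proximal reaction has zero arm; joint contact points are fixed in the distal
segment of each joint. The inter-segmental resultants on the right-hand side
are computed by the distal-to-proximal recursion
`-S^k = m^k (a^k - g) - S^(k-1)` starting at the measured ground reaction,
with the matching moment recursion about the proximal joint centres (the
ground's action is its force at the centre of pressure plus the vertical
free moment).

## Kinematics

Segment-fixed frames are constructed from a standing calibration: y from the
distal to the proximal joint, an intermediate medial-to-lateral z from paired
landmarks, x completing the right-handed frame; origins at the proximal
joint centres (pelvis: mid-ASIS). The hip centre comes from a regression on
the inter-ASIS width (fractions −0.19, −0.30, 0.36 along the pelvis axes).
Per frame, each segment's pose is the least-squares rigid transform from its
calibration marker cloud to the observed markers, solved in closed form by
the quaternion eigen-decomposition of the cross-covariance; redundant
markers all enter the fit, and frames with fewer than three visible markers
are flagged. Angular velocity is the vector part of `2 qdot x q*` on the
hemispherised quaternion series; angular and linear accelerations are
central differences at the capture rate (one-sided at the series ends), so
differentiation tolerances scale with the squared sampling interval.

The knee flexion angle `theta` that drives the patellar model is the z-axis
Euler angle (flexion–abduction–rotation sequence) of the tibia relative to
the femur, zero at the calibration pose and positive in flexion. Patellar
posture follows quartic polynomials in `theta` (degrees in and out): the
patellar tendon's sagittal and coronal plane angles orient the tendon in the
tibial frame, placing the patellar origin at the tuberosity plus the scaled
tendon length, and patellar flexion/tilt/rotation compose with the femoral
frame as an intrinsic z–y'–x'' Euler triplet. Patellar flexion is applied as
a −z rotation so the patella follows the flexing tibia; the paper-form
polynomials only fix magnitudes, and the opposite sign makes the patella
counter-rotate and the tendon geometry degenerate. P/Q is the quotient of
the (unsigned) sagittal-plane moment arms of the quadriceps and patellar
tendon lines about the patellofemoral contact; the nominal contact then
shifts onto the line of action of the resultant tendon force so the massless
patella stays in moment equilibrium, and that shifted point is where the
patellofemoral reaction acts in cases 2–4.

Muscle paths are polylines through segment-fixed via points (frictionless
eyelets: tension is uniform, each eyelet receives the vector sum of its
adjacent edge directions), with single-cylinder wrapping where flagged:
tangent line — geodesic helix — tangent line on the configured wrap side,
the axial coordinate distributed linearly along the unwrapped length (the
global shortest path by the Minkowski inequality). The net rope load on a
wrapped cylinder is applied on the cylinder axis at the arc midpoint — exact
for planar wraps because the distributed normal is purely radial, and a
small-couple approximation when the wrap travels axially. The reaction an
element transmits across a joint equals the net force it applies distal to
that joint, which telescopes to the polyline edge crossing the joint.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `sigma_max` | 3.139e5 | N m^-2 | maximum muscle stress converting PCSA to a force bound |
| `pcsa_multiplier` | 2 | — | cadaveric cross-sections doubled for an athletic population; configuration, not a constant |
| `condyle_half_distance` | 0.02 | m | case-4 compartment contacts sit ±2 cm from the knee centre along the tibial z-axis (4 cm inter-condyle distance) |
| `cutoff` | NA | Hz | zero-phase Butterworth low-pass for markers and ground reaction; off by default because the synthetic trials are smooth and real inputs are usually pre-filtered |
| `filter_order` | 4 | — | Butterworth order before the forward–backward pass |
| solver `constraint_tol` | 1e-7 | — | equality residual on row-equilibrated scale |
| solver `cost_tol` | 1e-8 | — | relative cost change declaring convergence |
| `compression_only` | off | — | case-4 switch restricting the compartment axial (tibial +y) components to compression |

Ligament bounds are the published per-ligament values (850–4000 N,
`table5_ligament_bounds()`). Segment inertia comes from adjusted male
anthropometric fractions (mass, centre-of-mass position and radii of
gyration per segment); the pelvis is a lumped pelvis+trunk+head+arms
remainder body with a configurable centre of mass, and the patella is
massless.

## Numerical choices

* **Low-pass filtering.** The original trials were smoothed with a
  generalised cross-validated quintic spline; this package provides a
  configurable zero-phase Butterworth instead (the substitution is
  documented, and the filter is a plug-in point). The series is centred and
  padded by odd reflection before the forward–backward pass so a constant
  passes exactly and edge transients are absorbed.
* **Solver.** The unbounded reaction columns are eliminated through the left
  null space of their block (QR), leaving a strictly box-bounded convex
  program in the scaled variables `z = F/Fmax` whose cost is exactly
  `sum z^3`. An augmented Lagrangian with analytic gradients (inner solver:
  projected quasi-Newton) handles the remaining equalities; a final
  minimum-norm polish on the inactive set drives the equality residual to
  machine precision. Reactions are recovered by least squares. Rows are
  equilibrated by their norms before solving (toggle in
  `solver_control()`). Frames whose residual exceeds tolerance are flagged
  infeasible and skipped — the fit reports a solved fraction rather than
  fabricating forces, and a fit aborts if less than half the frames solve.
* **Warm starts.** Each frame starts from the previous feasible solution;
  the continuation is an accelerator only (the converged cost is verified to
  be start-independent). The default initial point is mid-bound for bounded
  columns. No randomness is involved anywhere in a fit.
* **Degenerate inputs.** Collinear calibration landmarks, fewer than three
  markers, quaternion sign flips, endpoints inside a wrapping cylinder, a
  patellar tendon with no sagittal moment arm, and zero-energy curves in the
  waveform metric all raise errors naming the offence. Small negative knee
  flexion angles (within 2 degrees, from marker noise around full extension)
  are clamped to zero before the patellar polynomials, whose calibrated
  range is 0–120 degrees (warnings outside).
* **Waveform comparison.** The magnitude/phase error decomposition is
  computed with the canonical normalised forms
  (`M = sqrt(Vcc/Vmm) - 1`, `P = acos(Vmc/sqrt(Vmm Vcc))/pi`); the energy
  integrals use trapezoidal integration after linear resampling onto a
  common grid. Composite curves re-index trials to time-to-take-off before
  averaging; take-off is the first instant the vertical ground reaction
  drops to zero after carrying load.

## The synthetic study conditions

The package is tested end to end against its own synthetic-data module, not
against recorded subjects. `make_toy_anatomy()` builds a planar-dominant
five-segment anatomy: 12 muscle elements (quadriceps group of three vasti
plus rectus femoris; soleus and tibialis anterior; paired gastrocnemius and
hamstring elements; gluteal and iliopsoas elements), 4 ligaments with
published bounds, a patellar tendon and one femoral-condyle wrapping
cylinder used by the quadriceps at deep flexion. Design features that make
the sparse set mechanically complete: paired transverse offsets give both
senses of every out-of-plane moment an actuator; the gastrocnemius pair is
crossing-oblique so differential activation provides tibial axial-rotation
authority (the patellar tendon's coronal-plane angle twists the tibia, and
nothing else in a 12-element set resists it); PCSAs are at published
magnitudes (vasti 40–59 cm², gluteal 87 cm²); and the gluteal insertion
carries a greater-trochanter-like lateral offset for frontal-plane hip
authority.

`make_jump_trial()` produces a countermovement jump: knee flexion follows a
minimum-jerk descent to 70 degrees in 0.4 s and a quadratic push-off of
0.3 s ending at 15 degrees (real jumpers leave the ground before full
extension), then a ballistic flight with the configuration frozen; the knee
angle is split between shank and thigh by a whole-body balance condition
that keeps the horizontal centre of mass stationary over the foot, and the
lumped trunk centre of mass sits mid-foot as in quiet standing. Marker
trajectories come from forward kinematics of a marker set whose labels and
placements mirror the standard capture protocol; the ground reaction force
is the whole-body Newton–Euler resultant computed from the *same* discrete
central-difference accelerations used downstream, with the centre of
pressure and the vertical free moment solved from the whole-body moment
balance about the ankle. The trial therefore satisfies the model's own
equations to machine precision before any noise is added, and it carries its
independently accumulated inter-segmental loads as an oracle attribute.

What this does and does not show: closed-loop recovery demonstrates that the
kinematic chain, load recursion, geometry and assembly are mutually
consistent and correctly implemented. It does not probe soft-tissue
artefact, marker misplacement, force-plate noise, filter interaction, or the
anatomical fidelity of a real muscle set — real data have all of these, and
the solved fractions and force magnitudes on real trials will differ. On the
toy jump the four cases solve 80–82% of frames; the infeasible remainder is
the deep-crouch band, where the 12-element set runs out of out-of-plane
authority, plus the single impulsive take-off transition frame. A model with
the full anatomy (163 elements) has far more lines of action available, and
the original study likewise reported solutions for 95.1 ± 6.2% of frames
rather than all of them. Peak contact forces of the toy (for example a total
tibiofemoral force around 10 body weights) are properties of the toy's
geometry and should not be read as physiological predictions.

The structural acceptance checks use a synthetic full-scale layout
(`make_full_layout_anatomy()`: the toy elements replicated to 163 muscle
elements plus the 14 published ligaments) purely to verify the assembled
system dimensions; it is labelled synthetic and is not anatomical data. The
real cadaveric coordinate dataset is not shipped (licensing); any dataset in
the documented CSV/JSON schema loads through `load_anatomy()` and is scaled
to the subject with `scale_anatomy()` — per-segment longitudinal factors
from joint-to-joint lengths, transverse factors defaulting to the
longitudinal one and overridable per segment, cylinder radii scaled with the
transverse factor.

## Known limitations

* Ligaments are tensile force actuators with constant bounds; forces are not
  derived from strain.
* The patellar model is not subject-specific: patellar posture and P/Q
  depend only on knee flexion.
* Single-cylinder wrapping only; no ellipsoid or mesh obstacles, no
  muscle–muscle contact. The net wrap load on the cylinder is applied on the
  axis (exact only for planar wraps).
* Binary motion-capture containers are out of scope: trials are read from
  TRC text files or the documented CSV dialect; anatomy from CSV/JSON.
* Time-normalisation across subjects, EMG processing and activation/
  contraction dynamics are out of scope: estimated forces map to fractions
  of maximum force capability only, and activation envelopes enter only as
  user-supplied curves for the waveform metric.
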