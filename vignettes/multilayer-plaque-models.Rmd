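---
title: "Multilayer thin-slice plaque models: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer thin-slice plaque models: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vesselfem)
```

## The problem

Coronary plaque stress and strain are candidate markers of plaque
vulnerability, but nearly all image-based plaque models treat the vessel
wall as a single homogeneous layer. The wall is really three mechanically
distinct layers — a stiffening intima that carries disease, a compliant
smooth-muscle media, and a collagen-jacketed adventitia — and
intravascular OCT can now resolve all three. `vesselfem` implements the
full comparison pipeline: given segmented multilayer cross-sections (or
synthetic stand-ins), it solves each slice twice, once with layer-specific
materials and once with the layers merged, and assembles the per-patient
and cohort-level stress/strain comparison statistics.

## Constitutive model

Every tissue uses a modified Mooney–Rivlin strain energy; the vessel
layers add one exponential fiber term:

$$W_{iso} = c_1(I_1-3) + c_2(I_2-3) + D_1\left[e^{D_2(I_1-3)}-1\right]$$
$$W_{aniso} = W_{iso} + \frac{K_1}{K_2}\left[e^{K_2(I_4-1)^2}-1\right],
\qquad I_4 = \lambda_\theta^2\cos^2\varphi + \lambda_z^2\sin^2\varphi$$

with $I_1, I_2$ the invariants of $C = F^TF$ and $\varphi$ the fiber angle
from the circumferential direction. The default registry
(`default_materials()`) carries the layer-specific constants (kPa where
dimensional): intima $c_1=-169.23$, $c_2=177.40$, $D_1=2.4$, $D_2=13$,
$K_1=32$, $K_2=36$; media $c_1=-67.25$, $c_2=35.01$, $D_1=17$, $D_2=2$,
$K_1=7$, $K_2=4$, $\varphi=24.9^\circ$; adventitia $c_1=-94.44$,
$c_2=102.42$, $D_1=0.8$, $D_2=10$, $K_1=10$, $K_2=40$,
$\varphi=75.3^\circ$; lipid $c_1=0.5$, $c_2=0$, $D_1=0.5$, $D_2=1.5$;
calcification $c_1=920$, $c_2=0$, $D_1=360$, $D_2=2$ (both isotropic).

Modelling decisions where the published parameter sets leave latitude:

* **Intima fiber angle.** No angle is printed for the intima;
  `vesselfem` uses $\varphi = 0$ (circumferential fibers), the convention
  of the material-curve literature the constants derive from. This is a
  package assumption, prominently flagged here.
* **Fiber families.** Fibers act as a symmetric pair at $\pm\varphi$ in
  the circumferential–axial plane, each with weight 1/2. In shear-free
  states both members give the same $I_4$, recovering the single-$I_4$
  form above; under shear the pair keeps the response symmetric.
* **Tension-only fibers.** The fiber term is active only for $I_4 > 1$,
  the standard convention that avoids fictitious compressive fiber
  support.
* **Near-incompressibility.** The finite-element stress uses the
  isochoric (distortional) invariants plus a volumetric penalty
  $\kappa(J-1)$ with $\kappa = 1000\max(|c_1|,|c_2|,D_1)$ per material
  — large enough to keep $|J-1| \lesssim 10^{-3}$ in inflation problems,
  small enough not to ill-condition the tangent. The exported uniaxial
  stress–stretch curves instead use the exact incompressible plane-stress
  protocol (the lateral in-plane stretch is solved so its stress
  vanishes), because no figure-level protocol is stated for the published
  curves; this plane-stress reading is recorded as an assumption.
* **Overflow guards.** The exponentials are guarded at exponent 50;
  deformations beyond that are outside the model's intended range and
  raise an error rather than returning astronomically large stresses.
* **A caveat on stiffness ordering.** With these constants the intima's
  fiber term ($K_2=36$) overtakes calcification in uniaxial
  circumferential stress near stretch 1.15. The intuitive ordering
  "calcification stiffer than intima stiffer than lipid" therefore holds
  only at moderate stretch (the test suite asserts it at 1.1).

## Thin-slice model and boundary conditions

Each cross-section is extruded to a 0.5 mm slab ("thin-slice" model):
cheap like a 2D model, but with a genuine 3D stress state. Boundary
conditions encode the plane-sections intent: the bottom face is fixed
axially, the top face receives a uniform prescribed axial displacement,
and three tangential point constraints on the outer ring remove the
in-plane rigid motions (the pressure load is self-equilibrated, so these
pins carry no force at equilibrium). The lumen pressure is a follower
load on the deformed surface.

Because the imaged geometry is the loaded, axially stretched in vivo
state, the computational start shape is recovered in two steps
(`axial_prestretch_factor()`, `circumferential_preshrink()`):

1. **Axial shrink–stretch (5%).** The slab is built at thickness
   $0.5/1.05$ mm and stretched back to 0.5 mm during the solve.
2. **Circumferential pre-shrink.** A single in-plane scale factor $s$
   about the lumen centroid is found by a bracketed secant/bisection
   root-find so that inflating the shrunk slice to the imaging pressure
   recovers the imaged lumen circumference to 0.5%. The lumen
   circumference is used as the matching scalar because a uniform scale
   has exactly one degree of freedom. The default bracket is
   $s \in [0.75, 1]$: compliant walls (soft media) at high systolic
   pressure genuinely need factors below 0.85. Zero imaging pressure is
   the identity map. The shrunk configuration is stress-free by
   construction; all reported stresses and strains are measured relative
   to it.

## Finite elements and numerics

* **Elements.** Trilinear hexahedra on a structured ray mesh: rays from
  the lumen centroid through the four boundary contours partition each
  layer annulus; elements whose centroid falls inside a lipid or
  calcification contour are relabelled. Meshing requires the slice to be
  star-shaped about the lumen centroid and fails loudly otherwise.
* **Locking control.** Selective reduced integration: deviatoric terms at
  the 8 Gauss points, the volumetric penalty at the element centroid only
  (mean-dilatation style). This avoids volumetric locking without a mixed
  formulation.
* **Tangent.** Consistent element tangents by forward finite differences
  of the exact analytic element residual (step $10^{-7}$), symmetrised;
  the follower-pressure tangent likewise at face level. With the exact
  residual, Newton still converges to residual norms of $10^{-8}$
  relative to the force scale (the applied load norm, or the internal
  force norm for displacement-driven cases).
* **Load stepping.** Pressure and axial stretch ramp together in 5
  increments, with automatic halving (floor 1/128 of an increment) on
  failure, regrowth after successes, and a backtracking line search.
  The line search matters because the tension-only fiber switch can make
  the residual spike transiently between iterations.
* **Stress recovery.** Gauss values are extrapolated trilinearly to
  element nodes and averaged across elements sharing a node. At the lumen
  and outer surfaces — exactly where the comparison statistics are read —
  plain averaging is first-order in steep gradients, so the package adds
  a patch recovery: along each radial element column it fits a quadratic
  in radius through the *element-mean* Gauss stresses (markedly more
  accurate than individual Gauss values near the wall), stopping at
  material changes, and evaluates at the surface. With 3 radial elements
  per layer the peak hoop stress of a three-layer cylinder at
  60–140 mmHg matches the semi-analytic incompressible oracle within 3%.
* **Strain measure.** Reported strains are principal values of the
  Green–Lagrange tensor relative to the pre-shrunk configuration; the
  stress is Cauchy stress in kPa. Neither measure is named in the
  literature this package mirrors; both choices are recorded here (the
  reported magnitudes support them).
* **Mesh convergence.** `mesh_convergence_study()` shrinks the
  characteristic element size by 10% per step (angular and radial counts
  grown by 1/0.9) until the maximum inner-wall principal stress changes
  by less than 2% between consecutive refinements.

## Verification oracle

`axisym_cylinder_oracle()` solves layered-cylinder inflation exactly
under incompressible kinematics: $r(R)=\sqrt{r_{in}^2+(R^2-R_{in}^2)/
\lambda_z}$, with the radial equilibrium ODE integrated by quadrature
through the layers and the deformed inner radius found from the outer
traction-free condition. It evaluates the same strain-energy functions but
directly in principal stretches with numerical differentiation — a code
path fully independent of the element stress routine — and anchors the
solver tests (boundary conditions, Laplace limit, hoop profiles).

## Extraction and statistics

The quarter-dividing method splits the lumen and out-wall contours into
four angular quarters about the lumen centroid (boundaries anchored at the
+x axis by default; configurable, since no anchor convention is standard)
and places 25 equal arc-step nodes per quarter on each contour
independently, pairing by (quarter, index). Equal steps *within* quarters
keep thick eccentric plaques from distorting the pairing. Cap nodes are
the lumen nodes whose pairing segment crosses a lipid contour; since no
formal cap definition is standard, pure lipid overlap is used and
calcifications do not define a cap.

Per patient, values pool over all slices (10 slices × 100 nodes = 1000
nodal values at the study scale); maxima and means feed six comparison
tables (plaque/cap/out-wall × stress/strain). Relative differences use
the single-layer value as base; summary-row differences are computed from
the cohort *averages* (this convention reproduces the bundled reference
tables' printed summary rows exactly, whereas averaging per-patient
differences does not). Across-patient spread is the sample SD (n−1).
Normality is screened with a one-sample KS test of the standardized
differences; significance uses two-sided paired t tests at α = 0.05 with
no multiplicity correction (none is applied in the reference tables
either). In the bundled out-wall stress table the mean single-layer
summary cell (51.47) disagrees slightly with the 51.74 quoted in the
source's prose; the tabulated per-patient values are authoritative here.

## The synthetic cohort generator

`generate_cohort()` emulates segmented OCT output, not OCT physics. Each
slice is built in polar coordinates: a mildly oval lumen (radius
1.0–2.0 mm), eccentric intimal thickening on a random sector (intima
0.05–0.6 mm, thick on the plaque sector in proportion to an eccentricity
draw), media 0.10–0.25 mm and adventitia 0.15–0.35 mm with smooth angular
wobble, a crescent lipid pool under a fibrous cap (arc 30–120°, cap
0.05–0.3 mm, with the configured minimum cap thickness enforced
geometrically), and a small media calcification with probability 0.25.
Systolic pressures draw uniformly from 101–175 mmHg (the bundled
reference cohort's range), or cycle through the bundled per-patient
systolic values. Generation is deterministic given
(seed, patient, slice), with a 100-attempt retry cap before failing
loudly.

What the generator does *not* emulate: segmentation noise and contour
irregularity (contours are smooth by construction; smoothing of real
contours is left to the user), layer-thickness correlations along a
pullback, bifurcations, and non-star-shaped lumens. Passing the
directional tests on synthetic cohorts therefore shows that the
*mechanical* contrast between wall treatments is real and robust across
plausible geometry, not that any specific patient's values are
reproduced: patient-specific magnitudes require the original imaged
geometries, which are not public. The bundled reference tables carry the
real-data numbers, and the pipeline reproduces their summary statistics
exactly from the per-patient values.

On synthetic cohorts the package reproduces the direction of every group
finding — higher inner-wall and cap stress and strain, lower out-wall
stress, higher out-wall strain in multilayer models. One observation
worth recording: with a 5% axial stretch the Green–Lagrange axial strain
is 0.05125, and at the out-wall the in-plane stretch of single-layer
(stiff-walled) models usually stays below it, so single-layer out-wall
maximum principal strain saturates at that axial floor — visibly so in
the reference tables, where most single-layer out-wall entries print as
0.051. Multilayer models exceed the floor because the compliant media
lets the adventitia stretch; at low imaging pressures an occasional
synthetic slice ties at the floor in both treatments.

## Problem sizes and defaults

Default meshes use 48 rays × 3 radial elements per layer × 1 slab
(432 elements) for single-slice studies; the embedded pre-shrink solves
and the cohort studies use 40 rays × 2 per layer, which preserves every
directional conclusion at a fraction of the cost. The test suite runs a
5-patient × 4-slice synthetic study; the acceptance script a 4 × 3 one.
These sizes are the package's chosen defaults for routine desk-scale
studies; all of them are arguments.

## Known limitations

* Residual stress / layer-specific opening angles are not modelled; the
  pre-shrunk state is globally stress-free.
* No fluid–structure interaction, contact, or cyclic loading; the solve
  is quasi-static at one pressure.
* Slices are independent thin slabs; no 3D continuity along the vessel.
* The uniform pre-shrink is an approximation to true inverse
  elastostatics; it matches the lumen circumference, not the pointwise
  imaged shape.
* The single-layer wall material must be chosen (nothing standard
  exists): the default is the intima parameter set for the whole wall,
  with media-for-whole-wall exercised in the test suite as a sensitivity
  companion.
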