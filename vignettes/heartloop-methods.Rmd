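---
title: "The heartloop model: growth mechanics, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The heartloop model: growth mechanics, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(heartloop)
```

## The model

The embryonic heart tube loops into a helix while both of its ends stay
put: the arterial (cranial, outflow) and venous (caudal, inflow) poles keep
an almost constant cranio-caudal separation while the tube between them
more than doubles in length. `heartloop` implements a finite-element model
of this process: an elastic cylindrical shell grows according to a
*specified growth* field, and at every step the shape that minimises the
residual-strain elastic energy under the anatomical constraints is
computed. The ingredients are:

* **Geometry.** A right circular cylinder of 6-node wedge (pentahedral)
  elements — an inner and an outer triangulated surface with a wall
  thickness. Model units are dimensionless: only ratios matter in a
  scale-free elastic growth problem. Defaults: length 1, mid-wall radius
  0.15, thickness 0.05, a 30 x 30 (circumferential x axial) grid giving
  1800 wedge elements. The frame is +z cranial, +y ventral, +x anatomical
  left; azimuth is measured from dorsal (0 deg) with the left at 90 deg.
  Note that (left, ventral, cranial) is an anatomically *left-handed*
  triple: a helix that an embryologist sees winding counter-clockwise from
  the arterial pole has negative mathematical torsion in these coordinates.
  All handedness conventions in the package go through this mapping.

* **Polarizer.** The local direction of longitudinal growth is the
  (negated, tangent-projected) gradient of a morphogen diffusing from the
  venous to the arterial pole, recomputed on the deformed geometry every
  step, so growth follows the curving tube axis. The steady diffusion
  problem is solved on the mesh's edge graph with inverse-edge-length
  weights; only the gradient direction is used, so the discretization of
  the diffusion operator is uncritical.

* **Constraints.** Both pole rings are forbidden to move along z (fixed
  pole separation). The dorsal mesocardium is two axial node lines flanking
  the dorsal midline whose nodes cannot move in y or z but may slide along
  x; this is what converts left-right asymmetric growth near a pole into
  rotation rather than translation. The attachment is released
  progressively from mid-length towards the poles (linear in time;
  defaults: release starts at step 10, half the length is free at step 45,
  the attachment is gone at step 80). The release timing is the model's
  main free parameter: the stated constraints fix only its qualitative
  course.

* **Growth programs.** Per-step fractional growth rates along the
  polarizer (longitudinal) and perpendicular to it in the wall plane
  (circumferential). The control program uses six inputs: 2.5 %/step
  longitudinal baseline everywhere; a ventral spot peaking at 5 %/step at
  mid-length until step 40; +-1.1 %/step circumferential growth (positive
  left, negative right) in a gradient from the arterial pole to mid-length
  until step 30, calibrated to rotate the arterial pole by about 25 deg; a
  venous burst peaking at 7 %/step at azimuth 270 (right side) between
  steps 30 and 60 — a right:left ratio of 2.8; and ventricle inflation of
  0.9 %/step (RV band) and 1.4 %/step (LV band), the RV rate reduced to
  0.4 %/step in a dorsal-left inhibition zone. Steps 0-9 set up the fields
  and carry zero growth.

## Growth accumulation and residual strain

Two design decisions deserve emphasis, because the verbal description of
this class of growth model underdetermines them.

**Growth rates are fractions of the initial element size.** A rate of
2.5 %/step accumulated multiplicatively over the 80 growth steps would
specify a 7.2-fold elongation, which is inconsistent with the model's own
calibration (the baseline was chosen to produce a 2.6-fold length
increase). Accumulating 2.5 % *of the original length* per step specifies
a 3.0-fold elongation, which matches that calibration once the early
constrained phase (whose growth is not realised) is accounted for.
`heartloop` therefore interprets rates as fractions of the initial element
dimension: the multiplicative increment applied to an element stretched to
lambda times its initial length is `1 + k/lambda`. The alternative
compound interpretation is available as
`scenario_config(..., growth_accumulation = "compound")`.

**Residual strain is relaxed each step.** After equilibration, the next
step's rest configuration is the equilibrated shape with the new growth
applied: growth that the constraints prevented from being realised is not
stored as standing compression. With full retention
(`strain_retention = 1`) the rest shapes compound independently of the
realised shape and the accumulated mismatch is eventually expressed after
release, overshooting the observed elongation. Dissipative stepping is
also what makes the unrealised growth of the attached phase *disappear*
rather than catch up — the mechanism behind the difference between
specified (3.0x) and realised (~2.6x) elongation.

## Elasticity

Each wedge is decomposed into tetrahedra symmetrised over all six prism
triangulations (weight 1/6 each), so the decomposition has no preferred
diagonal: the discrete energy is exactly equivariant under the sagittal
reflection, and bilaterally symmetric programs give bilaterally symmetric
shapes to solver precision. The element energy is the corotational
small-strain energy (rotation removed by polar decomposition per
tetrahedron), with Young modulus 1 and Poisson ratio 0.3; with purely
kinematic loading the shapes depend only weakly on the modulus scale.
Equilibration is a frozen-rotation Newton iteration with energy
backtracking; the sparse Cholesky factorisation is cached and updated
across steps.

The stated constraints leave rigid modes free (notably global x
translation). These are removed by mean-zero *gauge* rows enforced with
Lagrange multipliers rather than by pinning nodes: the attached dorsal
node set has zero net x displacement per step, and once the attachment has
fully broken down the pole rings have zero net lateral translation and
zero net rotation about z. Gauges are exactly mirror-symmetric and do not
tether any individual node.

## Morphometry

All measures operate on the mid-surface of the deformed mesh:

* **Axis extraction** follows the measurement procedure used on 3D
  reconstructions: cut the tube perpendicular to the local axis estimate,
  record the area centroid of the section polygon, advance. For structured
  tube meshes the stations are guided by the material ring-centroid
  polyline (the polygon centroid still replaces the guide point at every
  station); free predictor-corrector marching is used for imported
  triangulated surfaces. Sections of a coiled tube that cut several passes
  are resolved by nearest-loop selection. Tube length is the arc length of
  the centroid polyline; on analytic cylinder/arc/helix fixtures the
  recovered length is accurate to a few parts in a thousand at the default
  40 sections.

* **Pole distance** is the separation of the axis extremities projected on
  the cranio-caudal axis; **mean perimeter** is the mean equivalent-circle
  perimeter `2*sqrt(pi*A)` over 10 evenly spaced sections; the
  **transverse sector** is the angular extent of the axis about the
  superimposed endpoints in the cranial view (note that a full-turn
  analytic helix subtends 180 deg about its own chord, because the chord
  of a helix lies on the winding cylinder, not on its axis).

* **Arterial rotation** is measured as the drift of the ventral line's
  material arc-length azimuth (cumulative arc along the ring from the
  dorsal attachment, normalised to 360 deg) at the arterial end of the
  tube. The rotation produced by asymmetric circumferential growth is a
  redistribution of material around a dorsally anchored ring; the
  arc-length azimuth is the measure that corresponds to reading the
  rotation off sections relative to the dorsal mesocardium, and for an
  anchored ring with +-g circumferential asymmetry it advances by 2g
  radians per step, which is what makes 1.1 %/step over 20 steps
  correspond to ~25 deg.

* **Shape classification** uses scale- and rigid-motion-invariant metrics
  of the axis polyline: deviation from the chord (straight below 0.05),
  RMS distance to the best-fit plane over arc length (planar below 0.02),
  curvature lobes of the in-plane projection (1 lobe = C, more = flat S;
  lobes are counted only when substantial relative to the dominant lobe,
  so the short axial hooks where the tube leaves the pinned pole rings do
  not count), and the sign of the integrated discrete torsion for helix
  handedness. For simulation outputs the straightness test uses the
  frontal-plane projection (`frontal = TRUE`), so the bilaterally
  symmetric ventral bulge does not count as looping; this anatomical mode
  is deliberately not rigid-motion invariant.

## What the generator emulates, and what it does not

Synthetic inputs are of two kinds: analytic fixtures (straight cylinders,
circular arcs, circular helices of known pitch, radius and handedness)
used as oracles for the morphometry and the classifier, and the simulator
itself, whose named scenarios reproduce the study conditions (control;
minimal buckling with and without a 5 % single-pole asymmetry; free poles;
absent, persistent dorsal mesocardium; 50 % reduced left-right asymmetry;
the arterial-burst alternative; and the two parameter sweeps at 80 steps
without ventricle inflation). The model does not include the bifid atrial
region, contact with the pericardial cavity, hemodynamic loading, or
growth-mechanics feedback, and the test suite exercises reduced mesh
resolutions (typically 16 x 16) for runtime; passing tests show the
implementation realises the stated mechanics at those resolutions, not
that the mechanics captures every feature of real embryonic tissue.

## Numerical choices and limitations

Tolerances: equilibration stops when the free-node residual force
infinity-norm falls below 1e-8 (model units); trajectories are
deterministic for a fixed configuration. Problem sizes: the control run
uses the full 30 x 30 grid; sweeps and the test suite use
reduced grids (16 x 16) where the realised morphometrics are within a few
percent of the full-resolution values. Degenerate inputs (non-positive
dimensions, fewer than 3 circumferential columns, self-intersecting
fixture geometry, non-orthonormal frames, non-SPD growth tensors) are
rejected with errors.

Known limitations: the realised shapes are smoother and less strongly
differentiated across the scenarios than the biological morphologies they
model; in particular the venous end of the simulated control tube deviates
to the anatomical right rather than the left, and the quantitative
contrasts between the persistent-attachment condition and the control
(wider tube, narrower transverse sector) are weaker than the biological
mutant comparison predicts. The acceptance analysis records these
discrepancies rather than tuning them away; the elongation ratio, the
arterial rotation angle and the control helix handedness are reproduced.
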