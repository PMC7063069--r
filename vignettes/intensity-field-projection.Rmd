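---
title: "Intensity field projection: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity field projection: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifp)
```

## The problem and the model

A step-and-shoot IMRT plan is a set of beams, each delivering a 2-D fluence
map realised by MLC segments.  When the anatomy of the day differs from the
planning anatomy, the plan's apertures no longer conform to the target.
Intensity field projection (IFP) adapts the plan without re-optimisation:
the 3-D deformation vector field (DVF) between planning and daily anatomy —
normally the output of deformable image registration — is reduced to a 2-D
deformation field on each beam's isocenter plane, and the fluence is
deformed along it.

The reduction works ray by ray.  In the beam's gantry frame (origin at the
isocenter, +Z toward the source, source at $(0,0,\mathrm{SAD})$), a point
projects onto the isocenter plane through the source as
$x' = x\,\mathrm{SAD}/(\mathrm{SAD}-z)$, $y' = y\,\mathrm{SAD}/(\mathrm{SAD}-z)$.
A displacement vector projects to the difference of its projected
endpoints, so the projection is exact for the divergent-beam geometry, not
a parallel approximation.  For every fluence pixel, the ray from the source
through the pixel centre is traced through the ROI voxel lattice; the
pixel's 2-D vector is the unweighted mean of the projected displacements of
the ROI voxels the ray crosses.  Pixels whose rays miss the ROI carry no
information and are filled by a declared policy (below).

Underlying assumptions, inherited from the method itself:

* deformations are smooth and moderate — each fluence pixel's ray crosses
  tissue that moves roughly coherently, so averaging along the ray is
  meaningful;
* the adaptation is purely geometric: fluence values are transported, not
  re-weighted, so depth-dose changes from altered tissue paths are not
  compensated;
* one ray per fluence pixel is representative (a supersampling knob exists
  for sensitivity checks, default off).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `SAD` | 1000 | mm | source-axis distance of every beam |
| fluence plane | 48×48 px, 2.5 | mm | isocenter-plane pixel lattice per beam |
| projection ROI | `ptv` | — | structure whose deformation drives the warp |
| `fill_mode` (pipeline) | `nearest` | — | extension of the 2-D field beyond the ROI shadow |
| `warp_mode` | `push` | — | value transport with the deformation |
| `levels` | 10 | — | fluence quantisation levels for sequencing |
| `leaf_width` | row spacing | mm | MLC leaf pitch at the isocenter |
| `mu_per_mm` | 5e-4 | 1/mm | attenuation per mm of unit-density tissue |
| `prescription` | 60 | Gy | plan normalisation (PTV D95) |
| reposition search | radius 15, step = voxel | mm | couch-shift grid search |

Two of these deserve their rationale spelled out.

**Projection ROI = PTV, not CTV.**  The aperture of each beam is fitted to
the PTV's beam's-eye-view shadow, margin included.  If only the CTV's
deformation were projected, the margin ring of the aperture would sit over
pixels whose rays miss the CTV, receive no deformation, and stay behind
when the target moves — the safety margin would be destroyed exactly on the
leading edge where it is needed.  Projecting the PTV moves the whole
aperture coherently; for the deformations in scope (rigid or scaling motion
of the target region) the PTV deforms with the CTV, so no information is
lost.

**Uncovered pixels: `nearest` in the pipeline.**  `fill_uncovered()`
defaults to `zero` (leave pixels outside the ROI shadow undeformed), which
is the conservative reading of "fluence outside the target shadow stays as
planned".  The full replanning pipeline instead extends the field with the
nearest covered vector.  The reason is an interaction with push warping:
with a zero-filled field, pixels just outside the moving aperture edge stay
put while the edge moves into them, and the splat normalisation averages
transported aperture values with stationary zeros — the warped edge drops to
roughly half intensity and coverage is lost.  Extending the field
continuously removes the fold; pixels far from the aperture carry no
fluence, so the extension is inconsequential there.

## Fluence warping: value transport

The deformed distribution is defined by $I'(x + r_x, y + r_y) = I(x, y)$:
the intensity *value* follows the deformation.  `push` implements this with
a bilinear forward splat normalised by the accumulated weights, so a uniform
region keeps its level under expansion (the aperture grows, the monitor
units grow with it) instead of being diluted by the Jacobian as a
mass-conserving splat would do.  `pull` (inverse sampling at
$x - r_x$) is provided as the cheaper alternative; for small smooth fields
the two agree to interpolation accuracy.  `conserve_total = TRUE` rescales
the output sum to the input sum exactly, which is a plan-level MU
renormalisation decision, off by default.

## Sequencing

The method only requires that MLC and jaw data be regenerated from the
warped fluence; the decomposition algorithm is a free choice.  The
package uses uniform quantisation (`levels` levels of the per-plan maximum,
rounding to the nearest level) followed by the classical unidirectional
sweep: the $k$-th segment's left leaf edge sits at the row's $k$-th
intensity rise, the right edge at its $k$-th fall.  This is deterministic,
verifiable by brute force at small sizes, reconstructs the quantised map
*exactly* (also for non-unimodal rows), and attains the minimal-MU sweep
bound — the largest row sum of positive increments.  Delivery constraints
(interdigitation, tongue-and-groove, travel limits) are not enforced; plans
that would violate them are only flagged.

## The dose engine

The engine exists to make DVH comparisons computable and fair, not to model
transport physics: per voxel and beam,
fluence (bilinear at the voxel's divergent projection) ×
$e^{-\mu\,(\text{radiological path})}$ × $(\mathrm{SAD}/(\mathrm{SAD}-z))^2$,
summed over beams; it is exactly linear in the fluence and geometrically
faithful (Siddon-style radiological path per voxel).  There is no scatter,
no buildup, no penumbra model.  The default $\mu = 5\times10^{-4}$/mm is
deliberately small: with realistic attenuation a uniform-fluence conformal
plan has a several-percent radial dose falloff that an optimised clinical
IMRT plan would not have, and that falloff—not geometry—would then dominate
the scenario comparison.  A small $\mu$ keeps the in-field dose nearly flat,
emulating the flat target dose of an optimised plan while preserving the
attenuation and inverse-square structure the engine's tests exercise (any
$\mu$ can be passed explicitly).

Plan normalisation follows clinical convention: the reference plan is
scaled so PTV D95 equals the prescription, which leaves the CTV fully
covered (V100% = 100) with the margin as headroom.  Normalising on the CTV
itself would pin CTV V100% at exactly 95 % and make coverage comparisons a
coin flip at the threshold.

## The phantom: what it emulates, what it does not

`phantom_spec()` describes a 64×64×64, 2.5 mm lung scene: an elliptical
body, two low-density lungs (relative density 0.25), a 20 mm-radius tumour
in the right lung and a cord cylinder; CTV = tumour + 5 mm, PTV = CTV +
5 mm; five coplanar beams every 72°; 60 Gy prescription.  Daily anatomies
come from analytic deformation families — rigid translation or pure scaling
of the target inside a core radius (40 mm), cosine-tapered to zero by an
outer radius (65 mm) chosen so the displacement gradient stays below one
and the field remains invertible.  The daily scene is rasterised by testing
each voxel centre's analytically inverted position against the planning
shapes, so daily masks, daily density and the ground-truth DVF are
consistent by construction — organs in the taper zone move exactly as the
field says, and no interpolation noise enters the ground truth.

What passing tests on this phantom do **not** show about real data: there
is no CT texture or CBCT scatter, registration is bypassed entirely (the
DVF is exact, so registration error — the dominant clinical uncertainty —
is out of scope), deformations are smooth and low-dimensional, and the dose
engine omits scatter.  Results demonstrate the geometric correctness of the
projection-warp-sequence chain, not clinical dosimetric accuracy.

## Numerical choices

* Ray traversal: incremental Amanatides–Woo stepping; voxel chords below
  1e-9 mm count as grazing, not crossed.
* Field inversion: fixed point $v^{-1}(x) \leftarrow -v(x + v^{-1}(x))$,
  default 20 iterations / 0.01 mm tolerance; during iteration the field is
  sampled with edge-clamped extrapolation so constant fields invert exactly
  at the volume border (the public sampling contract — zero outside the
  grid — is unchanged).
* Volume/mask warping is backward mapping through the inverted field
  (trilinear for volumes, nearest-neighbour for masks).
* DVH point metrics interpolate linearly on the sorted voxel doses (no
  binning); volume thresholds use a 1e-9 relative tolerance so voxels
  sitting exactly at a threshold are counted stably against round-off.
* Couch-shift search is exhaustive on the voxel lattice (sub-voxel steps
  cannot change the overlap count); ties break to the smallest, then
  lexicographically smallest shift.
* Marching squares (`contourLines` at level 0.5 on the zero-padded mask)
  extracts closed polygons; even-odd scan filling supports holes; a
  one-voxel boundary band is the accepted round-trip uncertainty.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on the
default 64³ phantom (five beams, 48×48 fluence planes) and the
property-style checks on 8³–26³ lattices with seeded randomness; the
complete comparison of both deformation cases takes a few seconds on one
CPU, so the study conditions are run at full size rather than scaled down.

## Known limitations

* When the target genuinely grows, covering it requires a larger aperture:
  the adapted plan then necessarily deposits more dose in the surrounding
  lung than the (under-covering) repositioned plan.  A primary-only engine
  cannot and should not hide this trade-off; OAR sparing by IFP arises for
  motion-dominated changes, not growth.
* Collimator and couch rotations are out of scope (validated to zero);
  beams are coplanar.
* The sweep sequencer can emit more than `levels` segments for strongly
  non-unimodal rows (exactness is kept; the segment count bound holds for
  unimodal rows).
* `warp_fluence(mode = "push")` can leave unfilled pixels under extreme
  expansive fields (beyond those in scope); such pixels stay at zero and
  the dropped fraction is reported.
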