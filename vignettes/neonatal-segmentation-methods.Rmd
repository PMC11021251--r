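---
title: "Methods: neonatal T2 segmentation and surface preparation with neoseg"
author: "neoseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neonatal T2 segmentation and surface preparation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model of the data

neoseg implements the bespoke computational stages of a neonatal
T2-weighted MRI processing pipeline that feeds deformable cortical-surface
extraction: brain-mask refinement, registration-guide mask generation,
patch-based multi-atlas label fusion, rule-based label post-correction with
regions-image construction, and white-surface force-image generation. The
registrations themselves, external tissue labelling, bias correction and
the surface solver are treated as external contracts: the package consumes
and produces the volumes those tools exchange.

The intensity model throughout is the neonatal T2 contrast: unmyelinated
white matter (WM) is bright, cortical grey matter (GM) is a thin dark
stripe, and CSF is brightest. Every stage is contrast-driven, so absolute
intensity scales are irrelevant; several operators are proven (and tested)
invariant under global intensity shifts.

## Low-level operators

All 3D operators are mm-aware. Structuring elements are exact spherical
offset sets: an offset is included iff its centre-to-centre distance under
the voxel spacing is at most the radius, with no rounding, so anisotropic
voxels are handled exactly. Morphological closings are computed on a grid
padded by the element extent, which keeps the closing extensive at the
volume border. Erosion treats out-of-grid voxels as background, the usual
finite-grid convention.

Connected components are coded in voxel scan order; the component whose
first voxel comes first in scan order gets code 1. This makes every
largest-component tie-break deterministic and testable. Foreground
connectivity defaults to 26 and background to 6, the standard pairing that
avoids topological paradoxes.

The chessboard (Chebyshev) distance transform uses a two-pass chamfer with
unit weights over the 26-neighbourhood, which is exact for the L-infinity
metric; the Euclidean transform is the separable lower-envelope
squared-distance transform, exact under anisotropic spacing. Both are
validated against exhaustive brute-force minima on random small grids.

The ridge detector is the second derivative of a Gaussian along the local
image gradient direction: positive in locally dark tissue (the GM stripe),
negative in locally bright tissue (skull stripe, thin bright gyral
strands). Two numerical choices matter here:

* Derivative kernels are made DC-free after sampling, otherwise constant
  regions leak a nonzero response.
* At the exact centre line of a dark or bright sheet the gradient vanishes
  by symmetry and "along the gradient" is undefined. There the operator
  falls back to the total curvature (the Laplacian), under the same
  relative tolerance. Voxels where both the gradient and the curvature are
  below tolerance form the "locally uniform" class and return 0. The
  default tolerance is 1e-6 of the intensity range; mask-generation runs it
  at 2% (see below).

A 3D Canny detector (Gaussian-derivative gradient, trilinear non-maximum
suppression along the gradient, hysteresis by 26-connected components)
supplies the edge-voxel removal used during GM-mask generation.

K-means on intensities wraps `stats::kmeans` with k-means++-style seeding
drawn deterministically from the *sorted* values under a fixed seed, with
several restarts scored by total within-cluster sum of squares. Sorting
first makes the clustering invariant to input order; squared-distance
seeding makes it equivariant under adding a constant. Classes are reported
dark-to-bright (class 0 darkest).

The convex hull mask is computed exactly: candidate vertices are the
per-line x-extreme voxels (every hull vertex is such an endpoint), a
quickhull-style incremental hull is built over them, and voxel centres are
tested against all facets. Degenerate clouds spanning fewer than three
dimensions are returned unchanged.

## Brain-mask refinement

The initial mask is assumed over-inclusive (a conservative brain
extraction). Refinement is: 4-class K-means inside the mask with removal of
the darkest class (background), binary opening with a 4 mm sphere to
disconnect bright scalp stripes, retention of the largest connected
component, and closing with a 7 mm sphere to smooth the boundary and close
holes. "4-threshold K-means" is read as 4 classes; `k` is configurable.
When the masked intensities are degenerate (fewer distinct values than
classes) a 2-class split is attempted and, failing that, background removal
is skipped.

One boundary effect is worth knowing: a single bright non-brain voxel lying
flush against the retained surface (the root of a scalp bridge) cannot be
removed by any opening, because a ball tangent to the surface from inside
always covers it. The phantom validation therefore counts retained voxels
of the skull *stripe* (the shell and fragments, which must be zero) and
reports bridge-root remnants separately; on the shipped phantoms these
amount to two voxels per image.

Cropping uses the mask bounding box plus padding; resampling is trilinear
for intensities, nearest-neighbour for labels, with the isotropic target
either user-specified or volume-preserving (the cube root of the voxel
volume, 0.63 mm for 0.5 x 0.5 x 1.0 mm acquisitions).

## Registration-guide masks

* **Fissure mask** — voxels inside the convex hull of the brain mask but
  not in it, intersected with the warped template fissure mask dilated by
  5 mm (the dilation radius is a package default; only a coarse
  restriction is needed).
* **Approximate GM mask** — candidates are voxels with positive
  directional second derivative; Canny edge voxels are removed; candidate
  components are scored by the fraction of their 6-connected exterior
  face-neighbours lying in the slightly dilated (1 mm) coarse tissue-class
  GM label, and kept at score >= 0.2. Two defaults differ deliberately
  from the generic operator settings. First, the locally-uniform tolerance
  is raised to 2% of the intensity range: at realistic noise the *sign* of
  the second derivative in flat tissue is meaningless, and without the
  uniform class the candidate field percolates across structures, welding
  the ribbon to everything dark. Second, the Canny thresholds sit high
  (0.7/0.85 of the maximum gradient), removing only the strongest
  boundaries (brain boundary, skull gap, ventricle walls). The cortical
  ribbon is itself bounded by moderate edges and is only 3-5 voxels thick
  at working resolution, so removing those edges would excise the very
  ribbon the mask must capture; strong-edge removal instead cuts the
  candidate leakage into extracranial dark tissue.
* **Septum pellucidum guide** — from each voxel of the warped template
  seed, march laterally (away from the midline; the left side marches
  toward -x) up to 10 mm and take the first relatively dark voxel: one
  with positive Laplacian of Gaussian, or darker than the 3 mm
  box-neighbourhood mean by tau (default half the within-brain intensity
  SD).
* **Ventricle mask** — coarse tissue-class ventricle components are kept
  only when they coincide with the majority-vote lateral-ventricle labels;
  relatively dark voxels (positive LoG) and the dark periventricular
  stripe are then removed. Component filtering runs before the LoG
  exclusion.
* **Extra-cranial background** — all voxels within 3 mm outside the brain
  mask. **Skull label** — negative directional-second-derivative voxels
  (locally bright) outside the brain mask. The corpus-callosum channel is
  a passthrough of the warped majority-vote CC label.

## Label fusion

Fusion is similarity-weighted voting: for every voxel, each atlas searches
its local offsets for the atlas patch most correlated (Pearson) with the
target patch and votes for its label at the best location with weight
`max(r, 0)^beta` (`beta` = 2 by default; negative correlations never
vote). The label with the largest pooled weight wins; ties go to the
lowest code; if every weight vanishes the majority atlas label at the
voxel is used. Patch size is 2 mm, interpreted as the per-axis box
half-width (a diameter interpretation is available). The search radius is
2 mm inside the 2 mm-dilated GM mask and 1 mm elsewhere. Patches are
clipped at the volume border and correlations computed over the valid
overlap; single-sample or constant patches have similarity 0 by
convention. The correlated-error weighting of joint-fusion algorithms is
deliberately not reproduced; the implementation is plain goodness-of-fit
voting, and duplicating an atlas doubles its vote (a documented, tested
property). The fused output is written once and immediately copied to the
`*_edited` file, which is the file manual corrections should touch.

## Post-correction and the regions image

Order of operations: sentinel resolution, CSF-island reassignment,
sulcal-bank splitting, regions-image construction.

Sentinel codes 254/255 mark manually edited LH/RH WM voxels; they are
rewritten to 2/41 and protected bit-identically through every later
operation, so a manual fix survives reprocessing.

CSF components face-adjacent (6-connectivity, preventing diagonal leakage
through sulci) to a hemisphere's largest WM component become that
hemisphere's WM; components touching both main components are split
voxel-wise by chessboard distance, ties to the left. For each configured
cortical parcel pair, WM voxels in the overlap of the two parcels' 1 mm
dilations are reset to CSF; the shipped pair list is an illustrative
superior-temporal/supramarginal pair per hemisphere, and a site-specific
list can be supplied.

The regions image needed by surface extraction contains
brainstem+cerebellum, cortical GM, LH/RH WM and LH/RH lateral ventricles.
The WM composite is the hemisphere WM labels, the CC and thalamus labels
together with the voxels added by their 25-iteration unit-cross closing
(the closure bridges the midline; the label voxels themselves are included
since excluding them would leave a hole in the bridge), the subcortical
absorption set, and the twice-dilated 3rd ventricle. Composite voxels take
the hemisphere whose warped ribbon label is nearer in chessboard distance
(ties to the left, the lower code). Lateral-ventricle voxels are then
re-expressed with per-hemisphere ventricle codes on top of the assigned
hemisphere: the source description both absorbs ventricles into WM and
passes them through, and this resolution satisfies both the midline
closure and the requirement that the ventricle classes exist in the
output.

## Force images

The WM-region force is -1 (outward) on hemisphere WM, +1 (inward) on CSF
(in-brain voxels left unlabelled by the regions image) and within 2 mm of
the brain boundary, with a linear 2 mm ramp to zero elsewhere and exact
zero outside the brain; WM membership wins where the definitions overlap,
keeping the force strictly negative on WM. Magnitudes are normalised to
[-1, 1]; the consuming solver is external and no physical unit is implied.

The thin-strand force recovers bright gyral strands mislabelled as GM: it
is -1 on locally bright voxels (negative directional second derivative)
outside the current WM mask, within 2 mm of the WM boundary, and inside
the 2 mm-dilated pericalcarine mask — the restriction exists because
applying the force globally causes errors elsewhere. Its detection scale
defaults to 0.6 mm, below the voxel scale: the targets are strands about
one voxel wide, and at a 1 mm scale such a strand is averaged into its
dark surroundings. The band outside the WM label stands in for "underneath
the first WM surface" since the mesh itself is out of scope.

## The phantom and what it does (not) show

The synthetic phantom provides ground truth for every stage: two
ellipsoidal hemispheres (radii 0.36/0.40/0.34 of the grid extent), a
sinusoidally folded GM ribbon (6 folds, amplitude 0.04) with one thin
pericalcarine gyrus and one sulcal wedge separating two cortical parcels,
midline CSF lined by medial GM, lateral ventricles with a lateral
periventricular stripe (the tapetum never abuts cortex), thalami, a CC
bridge, a 3rd ventricle, dark septum slabs offset two voxels laterally
from their midline template seeds, a brainstem+cerebellum blob, a
posterior fissure notch, a bright skull shell with two sub-4 mm scalp
bridges attached at gyral crests, a smooth multiplicative bias field
(amplitude 0.05) and additive Gaussian noise (SD 3 against class means
10/30/40/50/55/70/90/100, keeping at least 3 SDs between adjacent
classes). Deep structures are positioned proportionally to the brain
radius so that dark structures stay separated by bright tissue at every
grid size, as in real anatomy. Everything is bit-reproducible from the
seed.

Atlas sets emulate residual registration error: smooth random displacement
fields (Gaussian-smoothed white noise, 8 mm smoothing) scaled so half the
volume saturates at the maximal magnitude (1 mm by default) and capped
there — normalising by the absolute maximum would leave the displacement
sub-voxel nearly everywhere and the nearest-neighbour-warped labels
identical to the truth. Corruption modes plant the error patterns the
post-correction stage reverses (a CSF pocket in deep WM, a WM-filled
sulcus between unlike parcels, an occluded thin gyrus), recording the
affected voxels so round trips can be asserted exactly.

Problem sizes used in validation: most stages run on 64-voxel cubes;
GM-mask validation uses 96, where ribbon thickness and structure
separations approach the 0.63 mm working resolution; identical-atlas
checks use 48. Ten seeds drive the skull-strip study.

Passing these tests shows that the implemented rules do what they claim on
geometry with known truth and realistic contrast ordering, noise and bias.
It does not show robustness to real-scanner artefacts (motion, ghosting,
strong bias, pathology), to registration failures larger than the emulated
1 mm residuals, or to anatomy outside the phantom's idealised topology;
the external registration and surface-extraction contracts are not
exercised at all.

## Known limitations

* The fusion stand-in ignores correlated atlas errors by design.
* The convex hull of degenerate (planar or collinear) voxel clouds is
  returned unfiltered.
* Scalp-bridge root voxels flush against the brain surface survive
  refinement (see above); they are reported, not hidden.
* The full sulcal label-pair list is site configuration; only an
  illustrative default ships.
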