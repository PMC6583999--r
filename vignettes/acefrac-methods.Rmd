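---
title: "Measuring articular fracture displacement in 3D: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring articular fracture displacement in 3D: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acefrac)
```

## The measurement problem

Acetabular fractures displace several bone fragments in several directions
at once. The two quantities surgeons care about on the joint surface are the
**step-off** — incongruity perpendicular to the articular surface — and the
**gap** — separation along it. Reading these from individual axial, coronal
or sagittal CT slices systematically underestimates oblique displacement:
a slice only ever shows the in-plane component of a 3D vector, and the
reader must also pick the slice.

`acefrac` implements a fully three-dimensional alternative:

1. **Mirror template.** The intact contralateral hemipelvis is reflected
   across the midsagittal plane, giving a patient-specific template of the
   uninjured anatomy (`build_mirror_template()`).
2. **Virtual reduction.** Each fracture fragment is rigidly registered onto
   the template with trimmed point-to-plane ICP (`reduce_fragments()`). The
   recovered transform per fragment encodes exactly how the fragment is
   displaced.
3. **Fracture lines.** In the reduced pose, each fragment's articular
   surface is identified (a band around a sphere fitted to the template
   cup) and the boundary of that surface — minus the natural acetabular rim
   — is the fracture line (`extract_fracture_lines()`), resampled at a
   uniform arc-length step.
4. **Displacement decomposition.** For a reduced-pose line point $p$ owned
   by fragment $i$ with neighbour $j$, the displaced positions are
   $T_i(p)$ and $T_j(p)$ where $T$ are the inverse reduction transforms.
   The inter-fragment displacement $d = T_i(p) - T_j(p)$ splits against
   the template's articular normal $n$ into
   step-off $= |d \cdot n|$ and gap $= \lVert d - (d \cdot n)\,n \rVert$,
   so step-off$^2$ + gap$^2$ = $\lVert d \rVert^2$ exactly
   (`displacement_profile()`). Peripheral lines (no neighbour) are measured
   against the reduced reference, $d = T_i(p) - p$.
5. **Summaries and grading.** Maximum and mean step-off and gap over all
   line points (`summarize_displacement()`), the projected **total gap
   area** (below), Matta and CT-based three-category grading, and residual
   percentages when a postoperative model is supplied.

Correspondence is *transform-based*, never nearest-neighbour between
displaced curves: because the reduction transform is known, the displaced
position of every reduced-pose point is known exactly. This is what lets a
synthetic phantom validate the pipeline against analytic ground truth.

## Total gap area

The gap of a multi-fragment fracture is poorly summarised by one number
measured somewhere along one line. The total gap area projects each
interior fracture line's two displaced copies onto a standardized plane —
through the anterior inferior iliac spine, the inferolateral foramen point
and the superior ramus prominence, viewed orthographically along the plane
normal oriented laterally (`standard_view()`) — and measures the area of
the union of the ribbons between the copies (`total_gap_area()`).

Design choices worth knowing:

* **Union, not sum**: ribbons that overlap at junctions of several fracture
  lines are counted once (polygon clipping; a rasterization fallback exists
  and agrees within `2 * raster_step * total line length`).
* **It is a gap metric**: displacement purely along the view direction
  (pure step-off) projects to a zero-width ribbon and contributes nothing.
* Interior lines only by default; `include_peripheral = TRUE` adds
  wall-edge lines measured against the reduced reference.

## The validation phantom

No public CT data accompany this method, so validation is synthetic and
exact. `make_phantom()` builds a hemispherical shell (outer radius 27 mm —
adult acetabulum scale — wall 4 mm) opening laterally, cut into 2–3
fragments by planar cuts through the apex, each displaced by a known rigid
transform; the intact side is the exact mirror image; three landmarks sit
on the rim plane. Ground truth (per-point displacement of the cut-meridian
fracture lines, their summaries) follows analytically from the applied
transforms, with no registration involved.

Two geometric details are deliberate:

* **Irregular rim.** The rim height varies with azimuth by up to 10°
  (≈ 4.7 mm), mixing the 2nd and 3rd azimuthal harmonics
  (`rim_mod_deg`). A perfectly hemispherical cup is rotationally symmetric
  about its axis, so *no* surface-registration method could recover the
  azimuthal component of a displacement — and real acetabula are strongly
  non-symmetric (saddle-shaped, notched rims). The harmonic mix matters: a
  pure 1st harmonic is absorbable by tilting the cup axis, and any single
  k-th harmonic leaves a residual k-fold symmetry that admits wrong but
  perfect-fitting registrations. With the mixed rim, the wrong fits are
  visibly worse (RMS ~0.3 mm and above versus ~0.01 mm) and multistart
  selection is unambiguous. Set `rim_mod_deg = 0` for analytic tests that
  want the pure hemisphere.
* **Flat-patch variant.** On a curved cup no translation is purely
  "tangential" at every line point, so exact decomposition checks use
  `make_flat_phantom()`, whose articular facet is a plane: normal offsets
  are pure step-off, in-plane offsets pure gap, to numerical precision.

What the phantom does *not* emulate: soft tissue and imaging noise,
comminution, cartilage (CT shows subchondral bone, not the true joint
surface), metal artefacts in postoperative scans, and genuine left–right
asymmetry. Passing the phantom validation therefore demonstrates the
correctness of the geometry and registration machinery under the stated
conditions, not clinical accuracy on real scans; bilateral asymmetry in
particular will add a patient-specific floor to the residuals that the
`rms_max` flag is designed to surface.

## Registration choices

ICP is point-to-plane (correspondences to nearest template vertices, with
area-weighted vertex normals), with an exact rigid (Rodrigues) update per
linearized solve, stopping when the trimmed RMS improves by less than
`tol = 1e-6` mm. Choices that proved load-bearing:

* **Initialization is the identity**, not principal-axes/centroid
  alignment: a fragment is registered to the *whole* cup template, and the
  centroid of a half-shell differs from that of a full cup even at the
  perfect pose, so moment-based initialization is systematically wrong for
  partial-to-whole registration. After mirroring, fragments start near the
  template anyway.
* **Centring + multistart over azimuth.** Rotation about the cup axis is
  the weakly constrained mode of any near-hemispherical joint, and a
  fragment displaced along the axis can miss the true basin entirely.
  `reduce_fragments()` therefore fits a sphere to the fragment itself,
  translates its fitted centre onto the template's articular centre, and
  restarts ICP from azimuthal rotations about the template cup axis
  (−150°…180° in 30° steps, plus the unmodified identity start), keeping
  the lowest final RMS. All starts score the *same* surface sample, so
  their RMS values are directly comparable; exploration runs on a
  1 500-point subsample, refinement on the full 5 000.
* **Trimming only at the polish stage** (`polish_trim = 0.9`). Far from the
  optimum, the worst-fitting points are exactly the rim points that carry
  the azimuthal signal, so trimming there is harmful; near the optimum the
  worst residuals are the fracture (cut) surfaces, which have no
  counterpart on the intact template, and discarding them sharpens the pose
  by an order of magnitude (to ~0.01 mm / ~0.1° on phantoms).
* A fragment whose final RMS exceeds `rms_max = 2` mm is flagged
  `unreduced` rather than silently measured: this catches non-anatomic
  template fits (severe comminution, wrong-bone input, marked bilateral
  asymmetry).

## Articular surface, normals, tolerances

The articular region is a band (`sphere_band = 2.5` mm) around a sphere
fitted to the template cup (`fit_articular()`, an algebraic fit iteratively
restricted to the inner distance cluster so it finds the concave articular
radius, not a compromise with the outer cortex). Faces belong to the region
if they lie within the band *and* face radially — which excludes fracture
surfaces and the rim annulus. Articular normals are taken from the fitted
region (radial for a sphere, constant for a plane): an analytic, smooth
normal field from the *template*, deliberately independent of the displaced
fragments whose incongruity is being measured.

Numerical conventions: step-off is unsigned in all summaries (a signed
variant, positive along the outward articular normal, travels alongside);
all coordinates are millimetres; geometric predicates use `frac_tol$geometry
= 1e-9` and registration convergence `frac_tol$registration = 1e-6`;
fracture lines are resampled at `resample_step = 0.5` mm (halving it moves
maxima by < 0.05 mm); grading bins are closed at their upper bounds
(≤ 1 / ≤ 3 / > 3 mm for Matta; ≤ 2 / ≤ 5 mm gap, ≤ 1 / ≤ 3 mm step-off,
≤ 100 / ≤ 200 mm² area for the CT criteria) so the printed integer bins
become total functions of a real-valued residual; the final three-category
grade is the category nearest the mean ordinal score with half-way ties
rounded to the worse grade.

The 2D slice emulator projects each point's step-off and gap *component
vectors* into the slice plane and maxes over slices of the stated thickness
(2 mm by default, the protocol's ceiling). Because a projection cannot
exceed the vector norm, the emulated 2D readings are never larger than
their 3D counterparts — the underestimation direction holds exactly, per
point.

## Segmentation path

When the input is a CT-like volume instead of meshes: threshold at 226 HU
(the conventional preset bone threshold; the value is configurable),
26-connected component labelling (so thin diagonal cortical contacts merge
rather than split), discard islands below 50 voxels, then extract each
fragment's surface by marching tetrahedra at the 0.5 iso-level of its
occupancy and smooth with Taubin's λ|μ filter (λ = 0.8, μ = −0.83, 40
iterations). The smoothing is not cosmetic: a raw binary iso-surface is a
voxel staircase whose area exceeds the smooth surface it samples by tens of
percent, while Taubin smoothing removes the jaggedness with almost no
volume change (phantom sphere: area within ~1%, volume within ~0.5%;
`smooth_iterations = 0` restores the raw surface). Measurements made
through the segmentation path inherit a discretization floor of roughly the
voxel spacing.

## Statistics

The agreement battery is written from first principles because its exact
conventions matter for reproducibility:

* `wilcoxon_signed_rank()` computes the *exact* two-sided p by convolving
  the signed-rank distribution over all sign assignments for n ≤ 25 nonzero
  differences — with midranks, so it remains exact under ties, which the
  classical exact tables (and `wilcox.test`) do not handle. Larger n uses
  the normal approximation with tie and continuity corrections. Zero
  differences are dropped before ranking by default (Pratt's treatment is
  the alternative).
* `spearman_rho()` is the Pearson correlation of midranks.
* `icc_a1()` is McGraw–Wong ICC(A,1) — two-way model, single measurements,
  absolute agreement — from explicit ANOVA mean squares, alongside the mean
  absolute between-rater difference. `make_rater_table()` synthesises rater
  tables with known bias and noise so the estimate can be checked against
  the variance-component prediction σ²ₛ/(σ²ₛ+σ²ₑ).

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run entirely on synthetic
phantoms: 10 end-to-end phantoms at the default 0.5 mm mesh edge for the
validation bound (about half a minute each), 20 light phantoms for the 2D
versus 3D direction, 100 random samples for the Wilcoxon oracle, and
200 simulated rater tables for the ICC calibration. These sizes were chosen
so the whole suite exercises every module at full default resolution while
staying comfortably interactive.

## Known limitations

* Rigid fragments only: plastic deformation and comminution smaller than
  the adjacency tolerance are invisible.
* The mirrored template assumes bilateral symmetry; true side differences
  bias the reference and are only surfaced, not corrected, by the RMS flag.
* Gap area is measured in projection (as defined), so gaps nearly parallel
  to the view direction are foreshortened.
* Fracture lines are derived from the articular band geometry; hairline
  cracks without surface separation in the reduced pose produce no
  boundary and hence no line.
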