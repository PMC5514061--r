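---
title: "Two-stage rigid registration and localized Allred scoring of serial sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage rigid registration and localized Allred scoring of serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialreg)
```

## The problem

Serial histology sections are consecutive 3–5 µm slices of one tissue
block, each stained with a different marker (H&E for morphology,
immunohistochemical stains such as ER or PR for protein expression).
Because sectioning destroys continuity in z, any analysis that compares
expression of several markers *at the same place in the tissue* — for
example scoring ER and PR over one annotated tumour region — first needs
the whole-slide images re-aligned. Large anatomical structures persist
across neighbouring sections while fine ones need not, so a registration
method must tolerate partial dissimilarity; and at gigapixel scale it
must be cheap.

`serialreg` implements a two-stage rigid strategy:

1. **Approximate registration** from the tissue sections' external
   boundaries alone: a boundary is a closed polygon resampled to
   `n_points = 2000` equally spaced points, represented in a Curvature
   Scale Space (CSS), and aligned by matching curvature maxima.
2. **Refinement** from internal anatomy: fat pockets and nuclei clusters
   are detected in the aligned field and registered with a rigid
   Coherent Point Drift (CPD) whose mixture terms are gated by feature
   type and by a 33 µm distance rule, followed by an optional
   phase-correlation translation correction.

Registration quality is quantified by the Chamfer distance between the
reference boundary and the registered boundary,
$D(B_{ref}, B_{reg}) = \sum_{s \in B_{ref}} \min_{t \in B_{reg}} \lVert s - t\rVert$,
reported per point (normalized) by default; the raw sum is available via
`normalize = FALSE`.

All geometry is computed in microns. A rigid transform stores a rotation
angle, rotation center and translation in micron coordinates, so one
transform is valid at every pyramid level of a slide; pixel coordinates
are 0-based with x rightward and y downward.

## Stage 1: boundary segmentation and CSS matching

**Segmentation.** Tissue is separated from glass by a local-entropy
filter (glass is near-uniform, hence low entropy) thresholded with
Otsu's method, with connected regions below 0.5 mm² dropped. The filter
window is a disc of radius 5 px at the segmentation resolution (default
8 µm/px, a low-power overview; neither value is critical, they only need
to resolve the section silhouette). Artefacts that do carry entropy —
smudges, pen marks — are removed by an SVM over rotation-invariant
uniform LBP histograms of 64×64 px windows taken at twice the
segmentation resolution: rejected windows are zeroed, and a region with
a strict majority of rejected windows is removed entirely. The LBP
comparison uses a 3-grey-level dead band so that sensor noise in flat
regions does not register as texture. The classifier is trained on
synthetic windows (`synth_training_windows()`); retraining on real
windows is a drop-in replacement.

**Boundary.** Each region is hole-filled (only the *external* boundary
matters for alignment) and its contour resampled to N points equally
spaced by arc length, counter-clockwise, starting at the contour point
with minimal (y, x) — this makes extraction bit-deterministic. The
traced pixel chain is lightly smoothed (σ ≈ 1.5 contour pixels) before
resampling to iron out the one-pixel zigzag of raster contours.

**CSS.** The boundary's x and y sequences are circularly convolved with
Gaussians of standard deviation σ (in units of boundary samples) over an
exponentially spaced schedule — by default 16 levels from σ = 2 to
σ = N/16. Exponential spacing concentrates levels where the curve still
changes; adjacent fine levels would otherwise be nearly identical.
Signed curvature is computed from circular central differences at every
scale, *without* re-parametrising by arc length after smoothing, so a
CSS column tracks the same material point across scales. The feature set
is the strict circular local maxima of signed curvature (convex
prominences); the classical zero-crossing representation is deliberately
not used because inflections along near-straight tissue edges flicker
between sections, whereas convex prominences persist.

**Matching.** Maxima of two boundaries are matched with a Hungarian
assignment over candidate circular index offsets (coarse sweep of 64
offsets, refined around the best candidates). A maximum's descriptor is
its circular position, its persistence across scales, and its curvature
magnitude; unmatched maxima absorb a dummy cost set at the 95th
percentile of pairwise costs. Because near-symmetric outlines can
produce near-tied assignments at wrong offsets, extra candidate offsets
are seeded from a coarse shape-overlap sweep and the winning candidate
is the one whose rigid fit minimizes the Chamfer distance between the
(decimated, σ-min-smoothed) boundaries. The rigid fit itself is closed
form: the rotation angle is the atan2 of summed cross and dot products
of centered pairs, which cannot produce a reflection. The matched-maxima
fit is consolidated by trimmed least squares over the dense index
correspondence implied by the offset and polished by a trimmed symmetric
nearest-neighbour descent with small-rotation restarts. These polish
steps go beyond a bare maxima fit; they were adopted because maxima on
smooth synthetic outlines localize to only a few samples, and the
restarts protect against local minima of the descent.

## Stage 2: feature detection and gated CPD

**Fat pockets** do not stain and look like glass; what distinguishes
them is the rim of connective tissue around them. A luminance threshold
is estimated from a known-empty region of the slide (mean − 2 sd), and a
bright connected component is accepted as fat only when it lies strictly
inside the tissue mask *and* its entire outer boundary ring is below the
threshold. Each pocket contributes one landmark at its centroid.

**Nuclei clusters.** The haematoxylin channel is extracted by stain
separation in optical-density space: OD vectors are estimated from the
principal plane of the OD cloud with 1%/99% angular clipping
(Macenko-style), falling back to the published Ruifrok–Johnston
reference vectors when estimation is degenerate. Nuclei are
Otsu-thresholded components of the H channel within 10–300 µm², reduced
to centroids and grouped by DBSCAN (defaults eps = 30 µm, minPts = 5).
Matching individual nuclei across sections would be hopeless — most do
not persist — so each cluster is converted to a square lattice of points
at 0.004 points/µm² (spacing 1/√0.004 ≈ 15.81 µm) filling the cluster's
region, taken here as the union of eps-radius discs around member
centroids rasterized on the lattice grid. The lattice makes *partial*
cluster overlap between sections matchable: two different clusterings of
the same nuclei field produce nearly the same point cloud.

**Gated rigid CPD.** The moving slide's features (at their positions
after approximate registration) become the centroids of an isotropic
Gaussian mixture with equal weights plus a uniform outlier component
(weight 0.1); the reference slide's features are the data. EM alternates
gated responsibilities with a closed-form weighted rigid update and a
variance re-estimate. Each mixture term is multiplied by the gate
$d(z,\tilde z)^\beta$ with
$d = \sqrt{\max(\delta^2 - \lVert z-\tilde z\rVert^2, 0)}/\delta$, zero
for feature pairs of different types, with β = 1 and δ = 33 µm: features
further apart than δ after approximate registration, or of different
types, cannot attract each other. The gate is anchored at the
post-approximate positions of *both* sets and frozen during EM. An
alternative reading lets the gate track the moving points' current EM
position; the frozen pairwise form was chosen because it makes every EM
step an exact maximization (the objective trace is then provably
monotone, which the tests assert) and because it makes completely
dissimilar feature sets fall through to the outlier component
immediately, which is precisely the intended fallback: when total
correspondence mass ends below `mass_floor = 5`, the approximate
transform is returned unchanged. σ² is initialized from the mean
pairwise variance of the clouds and floored at 10⁻⁴ µm²; EM stops at a
relative objective change of 10⁻⁶ or 100 iterations.

**Phase correction.** After CPD the aligned grey fields are compared by
phase correlation (Hann-windowed). The estimated translation is applied
only if it is below 10% of the field size in each direction — the peak
lies in the central 20% of the phase image — and at most once; larger
peaks are treated as spurious, since feature centroids can be offset
only slightly from the true structure centres.

**Acceptance of the refinement.** `register_pair()` keeps the refined
transform only when it does not worsen the boundary Chamfer distance;
otherwise the approximate result stands. This extends the method's own
"approximate is preferable" fallback from *dissimilar features* to
*non-improving refinements*. It is a deliberate deviation from a design
in which refinement output is always kept: stage 1 here ends with a
boundary-distance polish, so an unguarded refinement could only trade
boundary alignment for feature alignment, and on occasional pairs would
regress the reported metric. With the guard, case-level reports satisfy
"refined ≤ approximate" per pair by construction, and the tests verify
that the refinement still genuinely engages (and improves ground-truth
pose) on the synthetic suite.

**Case-wide registration.** `register_case()` registers each slide to
its predecessor and composes transforms toward a user-chosen reference
section, reporting approximate and refined Chamfer distances per
adjacent pair — the two-column quality table layout. A failed pair falls
back to its approximate transform and never aborts the case.

## Localized multi-IHC Allred scoring

An ROI annotated on the H&E slide is mapped through the composed chain
onto each IHC slide (rigid, so its area is preserved). Ten square FOVs
of 1000×1000 px at 0.55 µm/px (20×; half the stated 40× scan resolution
of 0.275 µm/px) are sampled uniformly inside the ROI with a seeded RNG.
Per FOV, haematoxylin and DAB are separated, nuclei detected on the
combined channel, and each nucleus called positive when its mean DAB-OD
(over its own component pixels, so background cannot dilute it) exceeds
0.15. The Allred proportion score bins the positive fraction as
0; <1%; 1–10%; 10–33%; 33–66%; >66% → 0–5, and the intensity score cuts
the mean positive DAB-OD at 0.15/0.40/0.80 → 0–3 (weak / intermediate /
strong); total = PS + IS, 0 when PS = 0, so the attainable scores are
{0, 2–8}. The scoring system names these bins but not numeric
thresholds; the OD cut-points here are package defaults, configurable in
`default_config()`. All detected nuclei are treated as tumour nuclei — a
recognised limitation; an external tumour mask can restrict the field
before scoring. A FOV with no detectable nuclei is excluded and
resampled. The slide score is the mode of the FOV scores; a tie draws
five additional FOVs, and after three unresolved rounds the higher tied
score wins (clinically conservative, configurable). For evaluation
against manual scores, 0 is remapped to 1 on both sides before the mean
absolute error so that the possible scores are equally spaced, and the
overall error is the unweighted mean of the per-stain MAEs.

## The synthetic-fixture generator

Everything above is tested without any external data against
`generate_section()` / `generate_serial_pair()` / `generate_case()` /
`generate_fov()`:

* **Outlines** are low-order random Fourier perturbations of a circle
  (harmonics 2–8, amplitude capped so the curve stays simple), radius
  800 µm in a 3 mm field — big enough to clear the 0.5 mm² segmentation
  floor and carry stable curvature maxima.
* **Content**: nuclei as 3.6–4.8 µm discs in Gaussian clusters
  (6 clusters × ~50 nuclei, sd 60 µm), fat pockets as white discs
  (45–75 µm) with a dark rim, colours through a Beer–Lambert forward
  model with the Ruifrok H/E/DAB vectors, plus mild sensor noise; IHC
  profiles plant a DAB-positive fraction and intensity, the negative
  control plants none.
* **Serial pairs** share a `persistence` fraction of structures
  (default 0.8; the rest are resampled), jitter shared structures by
  4 µm, perturb the outline with high-order radial noise of 35 µm RMS,
  and map the second section into its own frame by the inverse of the
  known true transform. The default noise levels were chosen once so
  that stage 1 alone leaves a clearly measurable residual
  (tens of µm) that is still *below* the δ = 33 µm gate. A residual far
  above δ would be self-defeating as a test condition: the gate would
  zero every correspondence and the refinement could only ever fall
  back.
* **Rendered size** is ≤ 1200² px at 2.5 µm/px so full suites run in
  minutes on one CPU; registration-only tests skip rendering and work
  on analytic boundaries and structure tables.

What the fixtures do *not* emulate: non-rigid deformation between
sections, stain variability beyond one vector set, scanner pyramid
formats, tumour/non-tumour nucleus distinction, or realistic tissue
texture (texture is stationary noise plus nuclei). Passing tests
therefore demonstrate correctness of the algorithms under rigid truth
with partial structural overlap — not clinical-grade performance on real
slides, for which the clinical evaluation data would be required.

## Numerical choices and degenerate inputs

* Squared point distances are computed difference-first to avoid the
  catastrophic cancellation of the expanded form; this matters once the
  CPD variance shrinks to its floor.
* The Hungarian solver is the O(n³) augmenting-path formulation with
  dual potentials; rectangular problems are embedded in a square matrix
  with per-feature dummy columns/rows (cost: the 95th-percentile rule).
* Assignment ties and nearest-neighbour ties break toward the lower
  index (`which.min` / first match), making runs bit-reproducible.
* Degenerate inputs error early and informatively: single-valued
  histograms in `otsu_threshold()`, repeated consecutive boundary points
  in `curvature()`, coincident sources in `fit_rigid()`, ROIs smaller
  than one FOV in `sample_fovs()`. Blank images yield an empty mask with
  a warning; a boundary with no curvature maxima at any scale falls back
  to centroid + principal-axis alignment (both axis orientations tried,
  Chamfer decides).
* `cluster_to_points()` guarantees at least one point (the centroid) per
  cluster, so a detected structure is never silently dropped.
* Scoring FOVs with zero nuclei are excluded and resampled rather than
  scored 0, mirroring how a pathologist would skip an empty field.

## Known limitations

* Rigid-only: no affine or non-rigid stage; sections with substantial
  local deformation will keep a residual the model cannot express.
* The refinement's value shows in ground-truth pose error and local
  feature alignment; measured purely by boundary Chamfer distance it is
  bounded by the guard described above.
* Stain separation assumes two dominant stains over a white background.
* The tissue/artefact classifier ships trained on synthetic appearance
  models only and should be retrained for production slide archives.
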