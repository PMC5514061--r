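# serialreg

Rigid registration of whole-slide images of **serial histology sections**,
and localized multi-IHC (Allred ER/PR) scoring on the registered stack.

Serial sections are consecutive 3–5 µm slices of one tissue block, each
stained with a different marker (H&E, ER, PR, ...). Comparing marker
expression *at the same place in the tissue* — e.g. scoring ER and PR over
one annotated tumour region — requires re-aligning the slides first, and
the alignment must tolerate the partial dissimilarity between neighbouring
sections: large structures persist, fine ones need not.

`serialreg` implements a two-stage strategy:

1. **Approximate registration** from the tissue sections' external
   boundaries. Each section is segmented (local-entropy filter + Otsu,
   with an LBP/SVM window classifier removing artefacts), its boundary
   resampled to N = 2000 equally spaced points, and represented in a
   **Curvature Scale Space**: signed curvature
   κ = (x′y″ − y′x″)/(x′² + y′²)^{3/2} at every point under Gaussian
   smoothing over an exponentially spaced scale schedule. The strict
   curvature *maxima* (stable convex prominences; not the classical zero
   crossings) of the two boundaries are matched by a Hungarian assignment
   over circular offsets and the matched points fitted with a
   least-squares rigid transform (rotation + translation only).
2. **Refinement** by a **distance-gated rigid Coherent Point Drift** on
   internal anatomy: fat pockets (bright regions fully enclosed by a dark
   connective rim) and nuclei clusters (DBSCAN over detected nuclei,
   converted to 0.004 points/µm² lattices so partially overlapping
   clusterings still match). Each CPD mixture term is weighted by
   d(z, z̃)^β with d = √max(δ² − ‖z − z̃‖², 0)/δ, zero across feature
   types, β = 1, δ = 33 µm: features further apart than δ after the
   approximate stage cannot correspond, and when too little matchable
   structure exists the approximate transform is kept. A gated
   phase-correlation translation correction (accepted only within the
   central 20% of the spectrum image) can follow.

Alignment quality is measured by the **Chamfer distance**
D(B_ref, B_reg) = Σ_{s∈B_ref} min_{t∈B_reg} ‖s − t‖ (per-point mean by
default). Composing pairwise transforms yields a case-wide registration;
regions of interest annotated on the H&E slide map through the chain onto
the IHC slides, where the **Allred score** (proportion score 0–5 +
intensity score 0–3 of DAB-positive nuclei) is computed as the mode of 10
random 1000×1000 px fields of view at 20×, with five extra FOVs on ties.

Everything is testable offline: a deterministic generator renders
tissue-section-like images (Fourier-blob silhouettes, stamped nuclei
clusters, rimmed fat pockets, Beer–Lambert stain colours) as serial pairs
and stacks with known rigid ground truth and controllable structural
persistence.

## Worked example

```r
library(serialreg)

# a synthetic serial pair with known ground truth: 15 deg, (150, -80) um
T_true <- rigid_transform(15 * pi / 180, t = c(150, -80), center = c(1500, 1500))
pr <- generate_serial_pair(serial_pair_spec(section_spec(seed = 1), T_true,
                                            boundary_noise_um = 5))

# stage 1: boundary registration
approximate_register(pr$A$boundary, pr$B$boundary)
#> rigid_transform: theta = 0.264780 rad (15.171 deg), t = (140.624, -92.269) um, center = (1460.501, 1547.390) um
```

The recovered transform differs from the planted truth by 0.17° and a
mean displacement of 2.2 µm over the section (the printed translation
differs because the rotation centers differ; the *actions* agree).
With the generator's serial-section defaults (35 µm RMS outline
difference between neighbouring sections) the second stage refines the
feature alignment and is kept when it also improves the boundary
Chamfer distance (per boundary point, µm):

```r
pr2 <- generate_serial_pair(serial_pair_spec(section_spec(seed = 2), T_true))
rp <- register_pair(pr2$A$boundary, pr2$B$boundary,
                    feature_set_from_structures(pr2$A$nuclei, pr2$A$fat),
                    feature_set_from_structures(pr2$B$nuclei, pr2$B$fat))
c(approx = rp$chamfer_approx, final = rp$chamfer_final)
#>   approx    final
#> 23.97412 23.89327
rp$refinement_accepted
#> [1] TRUE
```

Scoring a slide with a planted Allred level:

```r
cfg <- default_config(); cfg$fov_px <- 150L
slide <- generate_fov(seed = 11, n_nuclei = 700, positive_fraction = 0.5,
                      dab_od = 0.55, size_px = 520, mpp = 1)   # PS 4 + IS 2
rec <- score_slide(slide$plane,
                   roi(rbind(c(15, 15), c(505, 15), c(505, 505), c(15, 505))),
                   stain = "ER", seed = 3, config = cfg)
rec
#> score_record: annotated ER final 6 (FOVs: 6 6 6 6 6 6 6 6 6 6)
```

A thin command-line wrapper for simulation, segmentation, registration
and Chamfer evaluation lives in `inst/cli/serialreg-cli.R`.

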