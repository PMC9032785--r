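---
title: "Two-stage segmentation and diametry of great vessels in non-contrast CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage segmentation and diametry of great vessels in non-contrast CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vesselct)
```

## The problem

The pulmonary-artery to aorta diameter ratio (PA/Ao) is a radiologic marker
of pulmonary hypertension, relevant to preoperative risk assessment. On
contrast-enhanced CT both vessels are easy to delineate; on non-contrast CT
(NECT) — the scan most patients actually get — the lumen/background contrast
is a few tens of HU against comparable noise, and manual 2D caliper
measurements are unreliable. `vesselct` implements a two-stage deep-learning
pipeline for fully 3D segmentation of the aorta and pulmonary artery in
NECT, plus the downstream geometry that turns binary masks into mean 3D
diameters and the PA/Ao ratio.

## The model

**Stage 1 — contrast enhancement.** A 3D U-Net is trained image-to-image
from the non-contrast volume to its co-registered contrast-enhanced
counterpart, both windowed to $[-160, 240]$ HU and scaled to $[0,1]$. The
training loss is the convex combination

$$\mathrm{Loss}(I_{op}, I_{gt}) \;=\; \alpha\,\mathrm{MAE}(I_{op}, I_{gt})
\;+\; (1-\alpha)\,\mathrm{DSSIM}(I_{op}, I_{gt}), \qquad \alpha = 0.7,$$

where MAE is the mean absolute voxel error and DSSIM $=(1-\mathrm{SSIM})/2$
is the structural dissimilarity, computed from local SSIM statistics over a
sliding $7^3$ window with the literature stabilizers $k_1 = 0.01$,
$k_2 = 0.03$. The MAE term drives overall intensity fidelity; the DSSIM
term penalizes structural (edge/texture) mismatch that a pure $\ell_1$ loss
tolerates. With both terms on the $[0,1]$ intensity scale, $\alpha$ is a
genuine trade-off weight.

**Stage 2 — segmentation.** Two Dice-loss networks consume the stage-1
output in different ways:

* the **aorta** model is single-channel — it sees only the non-contrast
  volume, but its encoder is initialized from the trained enhancement
  encoder (transfer learning). The intuition: learning to synthesize
  contrast forces the encoder to localize vessel boundaries, which is most
  of the segmentation problem.
* the **pulmonary artery** model is a two-channel dual-encoder network: one
  encoder stream consumes the non-contrast volume (initialized from a
  single-channel segmentation pre-train), the other consumes the stage-1
  synthesized contrast image (initialized from the enhancement encoder).
  At every resolution level the two streams' feature maps are
  channel-concatenated into the skip connections of a shared decoder.
  The synthesized channel — never a real contrast scan — is also what the
  model receives at inference, so the deployed pipeline needs only the
  non-contrast acquisition.

The segmentation loss is the squared-denominator soft Dice
$\mathrm{DSC} = 2\sum p_i g_i / (\sum p_i^2 + \sum g_i^2)$, trained as
$1-\mathrm{DSC}$; on binary data it coincides with the set-cardinality form
$2|A\cap B|/(|A|+|B|)$ used for evaluation.

**Architecture.** Both stages share one 3D U-Net: per level two $3^3$
convolutions + ReLU with channel-wise (spatial) dropout, $2^3$ max-pool
downsampling, a symmetric decoder with stride-2 transposed convolutions
and skip concatenation, and a $1^3$ sigmoid head. Filters double per level.
The network, its backpropagation, the Adam optimizer and the loss gradients
(including the analytic mean-SSIM gradient) are implemented natively in
R/C++ with BLAS matrix products; every gradient path is verified against
finite differences in the test suite.

## Geometry: centerlines, cross-sections, diameters

Given a binary vessel mask, the mean 3D diameter is computed from
cross-sections perpendicular to the vessel centerline:

* **Aorta centerline** (erosion-constrained tracking): the mask is eroded
  (ball radius 2 voxels) so the search is confined to the vessel core. From
  a seed at the heart-exit end, the tracker repeatedly steps (step radius
  3 voxels) to the candidate core voxel whose step direction is most
  orthogonal to the local vessel-surface normal — estimated as the gradient
  of the Euclidean distance transform — i.e. most parallel to the wall,
  hence along the vessel. Tracking runs in both directions from the seed.
  Because erosion stops short of the vessel ends, each end is then extended
  through the full mask along the end tangent, re-centring every step on
  the cross-section centroid, until the lumen runs out.
* **PA centerline** (skeletonization): the mask is thinned to a curve
  skeleton by sequential 6-subiteration topological thinning with the
  Malandain–Bertrand simple-point test, endpoint preservation, and two
  robustness ingredients that matter in practice: candidates are processed
  in increasing distance-transform order (keeps the surviving curve
  medial), and within one subiteration no voxel adjacent to an
  already-deleted voxel may be deleted (otherwise $1\times 2$-thick
  structures "unzip" end-to-end and thin tubes vanish — a failure mode we
  also observed in a reference implementation). The skeleton adjacency
  graph is reduced to its minimum spanning tree, leaf spurs shorter than
  1.2 times the maximal inscribed radius are pruned, and junctions
  (degree-3 vertices, clustered by adjacency) become branch points. The
  main vessel is the path from the *widest* endpoint — the pulmonary trunk;
  Murray's law makes daughters thinner — to the first branch point, then
  smoothed by cubic smoothing splines against arclength (knots every 5 mm)
  and resampled at uniform 0.5 mm steps, oriented with $s=0$ at the branch
  point.
* **Sub-voxel re-centring**: both extractors finally replace each
  centerline point with the centroid of its perpendicular cross-section.
  Lattice-bound skeleton/tracker points sit up to half a voxel off the true
  axis; the section centroid of a tubular lumen recovers the axis without
  longitudinal or curvature pull. A final 3-point moving average removes
  centroid-quantization jitter that would otherwise inflate arclength.

**Diametry.** Cross-sections sample the mask on a 2D grid (default half the
voxel spacing) in the plane perpendicular to the local tangent, keep the
in-plane connected component containing the centre, and report the
equivalent-circle diameter $2\sqrt{A/\pi}$ — robust to voxelization and
exact for circular lumens. Diameters are averaged over the conventional
measurement windows: aorta 5–25 mm of arclength from the heart-exit end,
pulmonary artery 5–15 mm from the branch point toward the trunk, both
sampled every 0.4 mm. `pa_ao_ratio()` forms the final ratio.

## The phantom generator

No patient data ship with the package; a synthetic phantom generator
(`phantom_spec()`, `render_phantom()`, `generate_dataset()`) provides
paired NC/CE volumes with exact ground truth so every stage is trainable
and verifiable:

* **Geometry**: a straight tube, a half-torus arch (aorta-like), or a
  bifurcating tree (pulmonary-trunk-like; one trunk, two daughters at a
  70° opening with Murray-law radii $r_d = r_t 2^{-1/3}$). The mask is the
  exact voxel-centre membership of the analytic solid; free tube ends are
  cut flat so rendered volumes match closed-form volumes.
* **Intensities**: background 0 HU; vessel 60 HU in the non-contrast
  rendering and 300 HU in the contrast rendering. Under the $[-160,240]$ HU
  window this puts the NC vessel at 0.55 against a 0.40 background —
  deliberately faint — while the CE vessel saturates at 1.0, mirroring why
  segmenting NECT directly is hard and why a synthesized contrast channel
  helps. A Gaussian partial-volume blur of 0.5 voxel stands in for the
  scanner PSF, and i.i.d. Gaussian noise of 20 HU (≈ 0.05 normalized, i.e.
  one third of the NC edge amplitude) is added independently to both
  renderings. These values were chosen
  once as a realistic low-contrast regime.
* **Determinism**: all randomness of a sample flows from one integer seed;
  datasets regenerate bitwise-identically.

What the phantoms do *not* emulate: thoracic anatomy (ribs, lung texture,
heart chambers, neighbouring mediastinal vessels), intensity
inhomogeneity, motion, or annotation noise. Passing the desk-scale
benchmarks therefore demonstrates that the implementation learns and
measures correctly under controlled conditions — not that it reaches
clinical-grade accuracy on real NECT.

## Desk-scale benchmarks

`scaled_vessel_benchmark()` reruns the two-stage design end to end at
desk scale: 8 phantoms for the (disjoint) enhancement split and 16 for the
segmentation split (10 train / 2 validation / 4 held-out, echoing the
80/20/20-of-120 proportions), on $64^3$ grids at 1 mm spacing. The
full-scale reference schedule trains for 500 epochs at learning rate
$10^{-2}$ with decay $10^{-6}$ and spatial dropout 0.25; those remain the
package defaults
(`train_config()`, `net_config()`). The benchmark itself uses deliberately
smaller desk-scale settings, chosen once for single-CPU runtimes of a few
minutes per stage: a depth-3 U-Net with 4 base filters and no dropout,
random 32-voxel patches centred on the vessel (4 patches/volume/epoch for
enhancement, 3 for segmentation), batch size 1, and Adam at $3\times
10^{-3}$ — at these tiny batch and model sizes Adam at $10^{-2}$ is
unstable (it finds border-dependent solutions that do not transfer from
patches to whole volumes), and the ~500–900 optimizer steps the schedule
yields are what the tasks need to converge. Enhancement trains 20 epochs,
the PA pre-train 15, the segmentation stages 30. Inference is whole-volume;
masks are thresholded at 0.5 with largest-component cleanup.

`channel_ablation_benchmark()` repeats the two-channel versus
single-channel comparison on low-contrast tree phantoms ($32^3$, depth-2
nets, matched final-stage budgets) across seeded repeats; the expected
effect is the *ordering* (two-channel at least as good on average), not a
fixed margin.

## Numerical choices and edge cases

* Preprocessing standardizes volumes to 1.0 mm isotropic by default
  (`resample_volume()`), configurable: isotropic spacing is what the 3D
  diametry assumes, and 1 mm is tractable over a chest field of view.
* Axis convention: R-native column-major `(x, y, z)` arrays, matching
  NIfTI layout; VOI shapes are `c(128,128,64)` for the aorta and
  `c(96,96,32)` for the PA.
* Interpolation: trilinear for images, nearest for masks (masks stay
  binary). VOI padding value 0 — the normalized floor, i.e. clipped
  air/fat.
* MAE is implemented as a mean (a sum is available via `reduce = "sum"`);
  the mixture with DSSIM only makes sense with both terms on $[0,1]$.
* Dice smoothing: $10^{-6}$ during training (avoids 0/0 on empty early
  predictions), 0 for evaluation.
* Transferred weights are fine-tuned, never frozen. The per-level
  "combination" of the two encoders in the PA model is feature
  concatenation — concatenating *weights* of two independently trained
  nets is not well defined.
* SSIM uses uniform (unweighted) windows and only fully supported window
  positions; its analytic gradient is exercised against finite differences
  in the tests.
* The tracker's inner-product criterion uses the absolute inner product
  (a step along the vessel is orthogonal to wall normals regardless of
  sign) plus a small turn penalty (0.3 × (1 − cosine to the previous
  step)) that breaks near-ties; without it the criterion is degenerate on
  lattice candidates.
* Degenerate inputs error early with actionable messages: empty masks, a
  vessel thinner than the erosion radius, windows beyond the available
  arclength, mismatched grids, non-binary masks.
* Voxelization bias: at 1 mm spacing the voxel-centre mask of a 4.5 mm
  tube differs from the continuous volume by a few percent (the rendered
  mask is nevertheless *exactly* the analytic membership, which is what
  the tests assert). Diameter recovery is accurate to well under one voxel
  because the equivalent-diameter estimator averages hundreds of in-plane
  samples.

## Known limitations

* The hand-rolled training stack is single-threaded CPU code; it is meant
  for desk-scale experiments (minutes), not for training on real CT
  cohorts.
* Phantom realism is deliberately minimal (see above); headline DSC values
  on phantoms are not comparable to values on patient data.
* The DICOM reader covers plain explicit/implicit-VR little-endian axial
  CT series — no compressed transfer syntaxes, no multi-frame objects.
* VOI centres are taken from ground-truth centroids during training and
  from user-supplied seed points at inference; automatic vessel
  localization is out of scope.
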