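---
title: "Cerebellum sub-segmentation with cerebseg: models, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cerebellum sub-segmentation with cerebseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Volumetry of the cerebellum and its lobules is a sensitive structural
marker in degenerative ataxias and other conditions, but manual
sub-segmentation at the lobular level is prohibitively labor-intensive.
`cerebseg` implements an automated sub-segmentation pipeline for
~1 mm isotropic T1-weighted-style volumes: the cerebellum is divided into
27 disjoint structures — ten hemispheric lobules per side (I–IV, V, VI,
Crus I, Crus II, VIIb, VIIIa, VIIIb, IX, X), five vermal sub-segments
(VI–X), and left/right cerebellar white matter (CWM) — and per-structure
volumes are tabulated for downstream statistics.

The pipeline is the 2.5D multi-view design used by modern whole-brain
segmenters: a localization step extracts a fixed working crop around the
cerebellum; three independent 2D networks segment the crop slice-by-slice
along the axial, coronal, and sagittal planes, each slice presented with
its three preceding and three succeeding neighbors as a 7-channel stack
(spatial information aggregation); the per-view class-probability maps
are averaged in probability space and the argmax yields the final label
map, embedded back into the native grid. There is deliberately no
bias-field correction and no atlas registration anywhere in the path —
only a robust linear intensity rescale to [0, 1].

## The label protocol

`build_protocol()` fixes the 27-structure table with integer ids 1–27 in
a documented order (left lobules superior→inferior: 1–10; right lobules:
11–20; vermis VI–X: 21–25; left/right CWM: 26/27; background 0). The
left–right bijection `lr_swap` is an involution that fixes the five
midline vermis ids and exchanges each left structure with its right
homolog; it drives the flip augmentation and the sagittal class merging.
The protocol ships as a TSV lookup table and a viewer-compatible color
LUT (`write_protocol_tsv()`, `write_protocol_lut()`).

Two merge utilities mirror how cortex-only parcellations are combined
with a separate white-matter source: `merge_cortex_and_wm()` keeps
cortex labels wherever both sources claim a voxel (the cortex
parcellation is the richer source; the precedence is configurable via
the inputs), fills remaining white matter by hemisphere side of the
mid-sagittal plane, and resolves gap voxels — background voxels whose
26-neighborhood touches both tissue sources, or an explicit gap mask —
by assigning the gray id of the nearest gray voxel in mm, ties broken
toward the lowest id for determinism.

## The phantom generator

Everything in the package is exercisable without any imaging download
through a procedural phantom: two ellipsoidal gray-matter hemispheres
flank a midline vermis slab; each hemisphere hosts a branching
white-matter tree (random stroke segments with one child branch each,
dilated to a tube radius and clipped so a cortical clearance of gray
matter always separates WM from the pial surface). Lobules are ten
angular sectors about the left–right axis in a hemisphere-local frame;
the vermis is divided into five sectors the same way. Intensities follow
the T1 ordering background 0.1 < GM 0.5 < WM 0.8 on a [0, 1] scale, plus
additive Gaussian noise (SD expressed as a fraction of the GM mean,
default 0.1) and an optional smooth multiplicative drift built from the
same cubic polynomial basis as the bias-field augmentation.

Design notes, in the order they were decided:

* **Sector boundaries are deterministic** in the hemisphere-local frame.
  The phantom has no folia or fissure contrast, so a random angular
  phase would make lobule boundaries fundamentally unpredictable from
  the image and cap every model's achievable Dice; with deterministic
  angles the labels are a function of observable geometry, as fissures
  make them in real anatomy.
* **Subjects vary** in ellipsoid radii (±4%) and center (±1.5 mm) via
  per-subject RNG streams; both are observable from the image. RNG
  streams are keyed by (seed, subject, purpose) so adding a new output
  never perturbs existing draws, and test-retest pairs reuse one
  anatomy with two independent noise streams.
* **Atrophy** `a` shrinks the outer radii by `1 − 0.25 a`, thins the
  cortical clearance by `1 − a`, and erodes the WM branch radius by
  `1 − 0.5 a`, so gray and white matter volumes both decrease
  monotonically — matching the joint cortical/white-matter loss seen in
  cerebellar degeneration.
* The phantom emulates geometry, contrast, noise, smooth inhomogeneity,
  atrophy, and scan-rescan variability. It does **not** emulate folia,
  partial-volume effects, acquisition physics, or real anatomical shape
  variation, so passing the phantom experiments demonstrates pipeline
  correctness and trainability, not clinical-grade accuracy on MRI.

Synthetic displacement fields (`generate_displacement_field()`) stand in
for deformation fields obtained by cross-subject registration of real
scans: smoothed white-noise vector fields, tapered to zero at the grid
boundary and rescaled so the maximum magnitude is exactly the requested
`max_disp_mm`. Applying a field (`apply_displacement()`) is backward
warping — trilinear for images, nearest-neighbor for labels, so warping
can never invent a label id.

## Localization

`fit_bounding_box()` places a fixed cube (default side 128 voxels)
symmetrically around the cerebellar mask: per axis the box is centered
on the midpoint of the mask's extent, rounded down, then clamped into
the grid; grids smaller than the side are zero-padded and the padding
recorded, so the box side is exactly 128 on every axis no matter what.
Masks wider than the side trigger a containment warning but never change
the side. The box is serialized to a JSON sidecar so segmentations are
always returned in native space. Extent-midpoint centering (rather than
center of mass) guarantees symmetric containment margins.

## Augmentation

Four families, with the production defaults in
`augmentation_config()`:

* **In-slice affine**: translation uniform in ±12 mm per in-plane axis
  (simulating centroid variation left by imperfect localization), scale
  0.95–1.2, rotation ±20°, composed about the slice center as a 3×3
  homogeneous matrix and applied by backward warping (bilinear image,
  nearest-neighbor labels).
* **Left–right flip** (p = 0.5): applied volumetrically — a sagittal
  in-plane flip cannot realize a left–right mirror — with label ids
  passed through `lr_swap`, identically for all three view pipelines.
* **Bias field**: 20 coefficients of the trivariate cubic monomial basis
  (graded lexicographic order) sampled uniformly in ±0.5 on coordinates
  normalized to [−1, 1]³; the field is added to the [0, 1]-normalized
  intensities (the additive reading of "linearly superimposed"; volumes
  are normalized at load, the normalize-then-bias order is the default
  and configurable).
* **Non-linear deformation**: a static augmented set built by pairing
  displacement fields with training cases such that every case is used
  at least once, with provenance (case id, field id) carried along.

Every augmentation with identity/zero parameters is a bit-exact no-op on
labels, and label resampling is nearest-neighbor everywhere — image
interpolation is linear precisely because lossy nearest-neighbor
resampling of images discards boundary detail.

## The reference network

No deep-learning framework is part of this package's stack; the per-view
model is a compact, self-contained encoder–decoder implemented in
compiled code: per resolution level two 3×3 convolutions, 2×2
max-pooling between levels, nearest-neighbor unpooling with skip
concatenation on the way up, and a 1×1 softmax head. The default
activation is a local-competition unit (pairwise channel maximum, a
maxout) rather than ReLU; in our experiments the competitive activation
converged visibly faster at equal cost. The default configuration is
deliberately small — 2 levels, 16 base filters — so CPU training takes
minutes; `model_config()` scales levels and filters up to a faithful
architecture.

Three normalized coordinate channels (in-plane row/col and the slice
position along the view axis) are appended to the 7 intensity channels
as a positional encoding. A 2-level network's receptive field cannot
disambiguate structures that are defined by their position (angular
lobule sectors look locally identical); the coordinate channels carry
that information explicitly, which is what makes a network this small
trainable on the task at all.

The sagittal view cannot tell hemispheres apart, so the sagittal model
trains on the lateral-merged 17-class set (`merge_lateral_labels()`);
`expand_sagittal()` copies each merged probability to both lateral
classes and renormalizes, and view aggregation down-weights the sagittal
map to 0.5 by default (weights are configurable; equal weights for
axial/coronal, half for the laterally ambiguous view).

Training (`train_view()`) uses AdamW (decoupled weight decay 1e-4), a
composite loss (median-frequency-weighted cross-entropy plus soft Dice
averaged over the classes present in the target; smoothing constant
1e-6), global gradient-norm clipping (default 5; the scaled-down runs
use 2 — small-batch training of a small network on CPU is otherwise
prone to catastrophic mid-run collapses), a reduce-on-plateau schedule
monitoring validation macro Dice (multiplicative factor 0.01 after 4
stagnant epochs, with a cooldown; 0.1 is the more common convention but
0.01 is kept as the documented default), and best-validation-Dice
checkpoint selection. Loss, class weighting, and checkpoint criterion
are configurable; the defaults follow the established multi-view
segmentation lineage. Training is seed-deterministic: the compiled
backend has no nondeterministic reductions.

## Scaled-down experiments

The package ships its own desk-scale counterparts of the full
experiments (`build_toy_sets()`, `train_toy_models()`,
`evaluate_toy_models()`, `run_ablation()`). Problem sizes were chosen
once as the package's standard desk-scale configuration:

* **End-to-end run**: 40 training / 10 validation / 10 test phantoms at
  64³ with a 48-voxel working crop, 2-level 16-filter models, three
  views, 8 epochs each (batch 8, lr 2.5e-3, gradient-norm clip 2, 28
  slices sampled per volume per epoch). The cohort mixes atrophy 0 / 0.2 / 0.4 — mirroring
  a study population spanning the disease course — and every subject
  carries a random smooth intensity drift (amplitude 0.15) and noise
  SD 0.1. Working-crop boxes are jittered by up to ±3 voxels per
  subject to emulate the imprecision of a production localization
  source. Aggregated macro Dice on held-out phantoms reaches ≈ 0.85–0.9
  under this configuration.
* **Ablation**: the augmentation/pre-training ablation runs the axial
  view only (the direction of augmentation effects does not need the
  ensemble) at 48³ with a 36-voxel crop, 6 training / 2 validation / 8
  test subjects per seed, 8 epochs, three seeds, and one
  arm per family: baseline (nothing), flip, bias, affine, static
  deformation, pre-training, and everything combined. The pre-training
  pool is twice the training-pool size and deliberately domain-shifted
  (coarser white-matter trees, no drift, lower noise), the way
  atlas-derived pre-training labels miss fine WM branch detail;
  fine-tuning runs at a reduced learning rate so pretrained features
  survive, and augmentation applies to the fine-tuning stage — the
  small-data stage it exists for. Toy augmentation ranges are scaled
  to the phantom population's variability (translation ±3 mm, scale
  0.96–1.05, rotation ±5°, bias coefficients ±0.04) the same way the
  production ranges are scaled to human variability. Under these
  conditions every individual contribution improves on the baseline;
  the combined arm beats every individual augmentation arm but trails
  the pre-training arm by about 0.01 Dice — with an in-distribution
  phantom test set, clean convergence on a pool that already covers the
  test manifold is hard to beat, a gap real multi-site data closes.
* **Test-retest**: 20 phantom pairs sharing anatomy with independent
  noise, segmented with the toy ensemble; per-structure volumes are
  compared by the two-way consistency single-measure ICC.
* **Atrophy cohort**: 10 subjects per atrophy level (0 / 0.2 / 0.4);
  segmentation-derived gray-matter volume decreases across levels.

## Evaluation suite

* **Dice** `2|G∩P|/(|G|+|P|)`; two empty masks score 1 (agreement on
  absence), documented because real evaluations never score empty
  structures.
* **Volume similarity** `1 − |V_G−V_P|/(V_G+V_P)` on mm³ volumes, hence
  grid-free and usable across acquisitions without alignment; undefined
  (an error) when both masks are empty.
* **Hausdorff distances**: boundary voxels are mask voxels with a
  6-connectivity background neighbor (grid borders count); distances
  are voxel-center to voxel-center in mm; the two directed
  minimum-distance sets are pooled by union — the standard symmetric
  construction — and summarized by the maximum (HD) or the 95%
  nearest-rank percentile (HD95 ≤ HD always). Empty structures yield a
  missing-value sentinel and are excluded from macro means with a
  count.
* **ICC**: two-way consistency, single measurement (Shrout–Fleiss
  ICC(3,1)) from the ANOVA decomposition, with the 95% CI from the
  standard F-distribution bounds; exact duplicates return 1 exactly.
* **Wilcoxon signed-rank** (paired, two-sided) delegates to
  `stats::wilcox.test` with zeros dropped and the exact distribution for
  n ≤ 25 without ties; degenerate input (all differences zero) is
  rejected rather than given a p-value.
* **Outlier scan** flags values outside mean ± 2.5 SD per class.

## Numerical conventions and degenerate inputs

Argmax ties break toward the lowest class id (background first).
Probability maps are renormalized after every aggregation step and
checked to unit sum. HD95 uses the nearest-rank (ceiling) percentile.
Nearest-gray gap assignment breaks distance ties (within 1e-9 mm) toward
the lowest label id. Single-slice volumes put the slice position at 0.5.
The displacement-field taper guarantees exactly zero vectors on the grid
boundary, and a zero maximum displacement short-circuits to an all-zero
field.

## Known limitations

The phantom's lobule sectors are wedges, not folia; boundary-distance
metrics on phantoms are therefore friendlier than on real anatomy. The
reference network's coordinate channels tie it to the localization
convention — it is a reference implementation of the training and
inference machinery, not a drop-in clinical segmenter. The CPU backend
is single-threaded by design (deterministic, dependency-free), so
production-scale training (128³ crops, 70 epochs) is out of reach here;
all configuration defaults for that regime are nonetheless in place.
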