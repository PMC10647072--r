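---
title: "Tri-planar 2.5D ensemble segmentation of sinus volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-planar 2.5D ensemble segmentation of sinus volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Segmenting the maxillary sinus (MS) and the lesions inside it from dental
CBCT volumes is clinically useful but awkward for direct learning: lesions
(mucosal thickening, retention cysts, polyps — collectively "MSL") vary
enormously in size, shape and location, from rinds a few voxels thick to
masses filling most of the sinus, and annotated lesion data is scarce. The
pipeline implemented here sidesteps direct lesion segmentation: a network
simultaneously segments the **whole sinus** (MS) and its **air region**
(MSA, a strict subset of MS), and the lesion is *derived* as the voxel-wise
set difference `MSL = MS \ MSA`. Both targets are large, well-contrasted
structures that are far easier to learn than the lesion itself.

On top of this, a **2.5D multi-planar ensemble** replaces a full 3D network:
the same 2D network is trained three times, on axial, sagittal and coronal
slice stacks of the same volumes. Each trained model predicts a full volume
(slice by slice, reassembled into the canonical orientation), and the three
binary predictions are fused voxel by voxel with a voting rule:

* **unanimous** — positive iff all three planes agree (AND),
* **majority** — positive iff at least two agree,
* **affirmative** — positive iff any one is positive (OR).

The rules are nested (`unanimous ⊆ majority ⊆ affirmative`), which fixes
their precision/recall ordering: unanimous voting maximizes precision,
affirmative maximizes recall, majority balances the two. Fusion is applied
**per structure channel, before subtraction** — MS and MSA are each fused
across planes, and only then is the lesion derived. Voting on the derived
lesion directly would mix disagreements of the two parent structures.

## Canonical geometry

All volumes live in a fixed axis convention: axis 1 = left–right, axis 2 =
anterior–posterior, axis 3 = inferior–superior, so `data[, , k]` is axial
slice *k*, ordered inferior → superior. The NIfTI-1/NRRD readers reduce
whatever direction matrix a file carries to the nearest axis permutation +
flips and reorient on read; files with no orientation metadata are assumed
canonical, with a warning. Slice extraction is pure re-indexing and
`reassemble()` is its exact inverse — the property the whole 2.5D design
rests on, and the most heavily property-tested contract in the package.

## Networks and training

Four compact families are provided: `unet2d` (encoder/decoder, 2×2
max-pooling, skip concatenation, 2×2 transposed-convolution upsampling),
`unetpp2d` (nested dense skip pathways; strictly more parameters at equal
depth/width), `unet3d`, and `vnet3d` (strided-convolution downsampling,
transposed-convolution upsampling, residual blocks, additive attention
gates on the skips). Blocks are conv → batch norm → ReLU; the `backbone`
option switches the block style to residual (`resnet_style`) or dense
(`densenet_style`) variants — scaled-down stand-ins for the large published
classification backbones, whose exact architectures and pretrained weights
are out of scope.

The output head is a **per-channel sigmoid** over three channels
(background, MS, MSA) — not a softmax, because MSA ⊆ MS means the channels
overlap and are not mutually exclusive. Training minimizes the multi-label
soft Dice loss, `1 - mean_c (2Σpt + ε) / (Σp + Σt + ε)` with `ε = 1` in
numerator and denominator (the smoothing makes empty channels well-behaved
and bounds the loss in [0, 1]).

Optimization follows the reference protocol: Adam at an initial learning
rate of 0.001, halved when the monitored (validation) loss fails to improve
by a relative 1e-4 for 5 consecutive epochs; 200 epochs by default
(desk-scale runs use far fewer); batch size 8 for 2D training and 1 for
volumetric training; augmentation draws one rotation in ±20° (in-plane;
about the IS axis for volumes) and one multiplicative brightness factor in
±20% per sample per epoch, with bilinear resampling for the image, nearest
neighbour for the mask, and clipping back to [0, 1]. Every random draw —
weight initialization, shuffling, augmentation — derives from one seed, so
a training run is bit-reproducible.

Because no deep-learning framework exists in the target R stack, the
networks run on a small purpose-built engine: convolutions are evaluated in
C++ as shift-GEMMs over a zero-padded single-precision buffer (each 3×3
offset contributes one BLAS `sgemm` on a pointer-shifted view, so no im2col
matrix is materialized on the hot path), with hand-written backward passes
checked in the test suite against double-precision oracles and directional
finite differences. Single precision in the convolution kernels is a
deliberate trade: it halves memory traffic (the binding constraint on one
CPU) and its rounding noise is far below the gradient noise of SGD itself.

## The phantom generator: what it emulates, what it does not

Real CBCT with expert labels cannot ship with the package, so every stage
is exercised on synthetic sinus phantoms with exact ground truth. A phantom
is two ellipsoidal cavities (random centres, semiaxes, small rotations) in
a bright "bone" background; the air interior is dark; lesions occupy a
soft-tissue tier between the two. Lesion archetypes cover the clinically
motivated range: full and partial mucosal shells 1–3 voxels thick (built by
Chebyshev-box erosion of the sinus mask, so shell thickness is exact by
construction), polypoid blobs seeded near the sinus floor, and severe
combinations; in `mixed` mode the archetype is drawn per phantom and lesion
volume fractions span below 1% to above 40% of the sinus across a small
cohort. Gaussian noise (default sd 10 gray levels against tier gaps of 70+)
and a per-volume multiplicative contrast factor (±15%) emulate scanner
variation. Defaults were chosen once to make tier ordering
(air < soft tissue < bone) hold with margin and were not revisited.

What the phantoms do **not** emulate: real mucosal texture, bony septa,
teeth and roots, the ostium, beam hardening, scatter, or inter-patient
anatomical variability. A green end-to-end test therefore establishes that
the *pipeline machinery* — slicing, training, fusion, subtraction,
evaluation — is correct and that the networks can learn a
contrast-plus-shape task; it says nothing about clinical accuracy, and the
published patient-data performance figures are explicitly not reproduction
targets at desk scale.

## Evaluation

Volume metrics are computed from voxel confusion counts:
`JC = TP/(TP+FN+FP)`, `DSC = 2TP/(2TP+FN+FP)`, `PR = TP/(TP+FP)`,
`RC = TP/(TP+FN)`, per case, per structure (MS, MSA, MSL), per method, with
mean ± SD aggregation. Degenerate cases are defined, not raised: empty
truth met by empty prediction scores 1.0 on all metrics (a correct empty
prediction is a success); one-sided emptiness scores 0. Per-volume
identities (`DSC = 2·JC/(1+JC)`; DSC is the harmonic mean of PR and RC) are
asserted in the tests — note they hold per volume, not for averaged values.
Per-slice DSC profiles run inferior → superior along the axial axis with
the same degenerate policy. Boxplot statistics follow the Tukey 1.5·IQR
whisker convention with linearly interpolated quartiles (type 7; Tukey
hinges available behind a flag). Method comparison uses one-way ANOVA and
paired two-tailed t-tests at α = 0.05, with no multiplicity correction by
default, matching the reference protocol; both are backed by the classical
`stats` implementations and cross-checked against a sum-of-squares oracle
in the tests.

## Numerical choices and edge cases

* Resizing uses half-voxel-centre alignment (`src = (i+0.5)·scale − 0.5`),
  trilinear for intensities, nearest-neighbour for labels (half-way
  coordinates resolve consistently to the upper voxel); spacing rescales by
  the extent ratio. Identity targets are exact.
* Intensity normalization is per-volume min–max to [0, 1]; a constant
  volume maps to zeros.
* Binarization thresholds at 0.5, boundary inclusive.
* `derive_msl` is clamped set difference (`ms & !msa`), never arithmetic
  subtraction; air predicted outside the sinus is counted and reported as a
  prediction inconsistency rather than producing negative labels. No
  morphological cleanup is applied anywhere.
* Majority voting with three voters cannot tie; even voter counts are
  rejected outright rather than adopting a silent tie policy.
* Max-pooling ties break toward the earliest window position,
  deterministically.

## Known limitations

* The engine is desk-scale: a paper-scale run (256×256×192, 200 epochs,
  ResNet101/DenseNet169-sized backbones) is configuration-reachable but
  far outside a single-CPU time budget.
* Batch statistics with batch size 1 (3D training) make batch norm behave
  like instance norm; acceptable at this scale, but a known difference.
* The NIfTI/NRRD readers cover the common cases (scalar 3D grids, the
  usual dtypes, gzip, orientation as permutation+flip) and are not general
  neuroimaging I/O.
* Slice-level training ignores inter-slice context by design (pure
  single-slice 2.5D); multi-slice context windows are out of scope.
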