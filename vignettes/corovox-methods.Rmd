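---
title: "Segmenting thin vessels in 3-D CT angiography: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting thin vessels in 3-D CT angiography: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Coronary arteries occupy well under 5% of the voxels of a contrast-enhanced
cardiac CT volume, thin out to sub-voxel calibre at their distal ends, lose
contrast where the medium is unevenly distributed, and sit next to veins and
the ascending aorta whose radiodensity is almost identical. A segmentation
network therefore has to (a) preserve the faint, shallow-layer features that
encode thin structures and (b) use local context to tell a coronary vessel
from a look-alike neighbour. `corovox` implements a 3-D U-shaped network with
two components aimed at exactly these failure modes, plus everything needed
to run it end to end: HU-window preprocessing, sliding-block inference,
overlap and surface-distance metrics, and a synthetic vascular phantom
generator so the pipeline can be exercised and tested without clinical data.

## Network

The backbone is a four-level 3-D U-Net: encoder stages of widths
`base_channels * (1, 2, 4, 8)` separated by 2x2x2 max pooling, and three
decoder stages that upsample with stride-2 transposed convolutions. Each
decoder stage consumes a three-part channel concatenation: the skip-attention
output at that resolution, the raw encoder features, and the upsampled
previous decoder stage.

**Dense residual (DR) blocks.** Every stage applies
`Y = P(X) + H1(X) + H2(H1(X)) + H3(P(X) + H2(H1(X)))`, where each `H` is a
3x3x3 convolution followed by (optional instance normalisation and) ReLU and
`P` is a pointwise projection when the channel width changes (identity
otherwise). The first residual sum mirrors the classic residual block; the
third convolution then extracts deeper features and the second residual
connection sums *every* intermediate map, so shallow detail reaches the
output undamped. The plain residual block `Y = P(X) + H2(H1(X))` and the
bare two-convolution block are available for ablation.

**Local contextual transformer (LCT) skips.** On each skip connection the
encoder features `X` are embedded as queries `Q = W_q * X` (pointwise, so
each location keeps its own signature), and keys/values `K, V` through k^3
*grouped* convolutions (k = 3 by default), so each key and value summarises
its local neighbourhood. `concat(K, Q)` passes through a pointwise
convolution with ReLU to give the attention map `R1`; `R2 = R1 * V`
element-wise; a softmax yields the block output. The pointwise variant
(k = 1, ungrouped) reproduces plain self-attention for the ablation grid.

**Deep supervision.** Softmax heads are attached to the two deeper decoder
stages and to the bottleneck; their outputs are trilinearly upsampled to
input size and each contributes a Dice loss against the full-resolution
ground truth. The composite objective is `L1 + alpha * (L2 + L3 + L4)` with
`alpha` decaying over training, so early training benefits from short
gradient paths while the final objective is dominated by the
full-resolution output.

### Decisions where the design was open

* **Softmax axis in the LCT block** — taken over channels: `R2` has the same
  shape as `X` and a channel softmax preserves it without pooling. This is
  the package's choice, recorded as such.
* **Group count of the k^3 embeddings** — 4 by default (divides every level
  width of the default and desk configurations); configurable.
* **Concatenation order** into the fusion convolution is `(K, Q)`, fixed.
* **Four supervised losses vs three decoder stages** — the fourth head
  supervises the bottleneck.
* **Downsampling/upsampling operators** — 2x2x2 max pooling and stride-2
  transposed convolution, the common 3-D U-Net convention.
* **Normalisation** — the convolution unit is literally conv + ReLU; for
  training presets a per-channel *instance* normalisation is inserted
  between them. Instance norm is well defined at batch size 2 and for
  arbitrary block sizes, and needs no running statistics, which keeps
  inference deterministic. Algebraic unit tests run with normalisation off.
* **Channel widths** are nowhere published; the default is base 16 doubling
  per level, and absolute parameter counts are treated as configuration-
  dependent (only the variant *ordering* is checked).
* **Tie-breaking** — a voxel is labelled vessel only when its foreground
  probability strictly exceeds 1/2, so exact ties resolve to background.

## Preprocessing and inference

Volumes are clamped to the `[-260, 760]` HU window and mapped linearly to
`[0, 1]`; the window bounds are the conservative contrast-vessel range, and
linear min-max is the simplest deterministic rescaling. Long volumes are cut
into depth-16 blocks laid out every `stride` slices (default 8, half
overlap), with the final start clamped so the last block ends exactly at the
volume end; volumes shallower than 16 slices are replicate-padded.
Overlapping block probabilities are averaged and padding is discarded before
any metric is computed.

## Metrics

Dice, recall and precision come from voxel confusion counts; ASSD and
Hausdorff distance from the 6-connectivity boundary voxels (a foreground
voxel with at least one face-neighbour outside the mask). Distances are
Euclidean, in voxel units by default or in mm when a spacing is supplied.
The all-pairs nearest-neighbour scan *is* the normative definition; the
implementation uses exactly that scan (surfaces at the scales this package
targets are small), and the test suite holds it to an independently coded
oracle at 1e-9. Empty masks or surfaces make a metric undefined: the
low-level functions raise typed errors, and per-case aggregation reports
`NA` fields rather than absorbing degenerate predictions into a mean.

## The phantom generator

`phantom_spec()` parameterises a seeded generator of CCTA-like cases. What
it emulates, and the defaults:

* **Branching trees with decaying radius** — 2 trees (left/right
  coronary-style), 3 generations of bifurcations, root radius 2.2 voxels,
  child radius = parent x 0.75, so distal branches drop below one voxel.
* **Small foreground** — the default tree occupies roughly 1% of a
  32x64x64 volume (the tests bound it under 5%).
* **Contrast falloff** — vessel intensity 350 HU at the root, linearly
  attenuated with normalised arc length to 60% at the most distal tip
  (`distal_contrast_drop = 0.4`).
* **Distractor** — one unlabeled straight tube at 300 HU, radius 4 voxels,
  rejection-sampled so it never touches the labeled tree: a vein/aorta
  stand-in that punishes pure intensity thresholding.
* **Noise** — additive Gaussian, sd 20 HU, on a 40 HU background.

One integer seed drives three sub-streams (topology, distractor placement,
noise), so switching noise off does not move the geometry. Rasterisation
marks a voxel foreground when its centre lies within the local radius of
the centreline (swept-sphere union sampled every quarter voxel), plus a
6-connected walk along each centreline so sub-voxel branches stay
connected.

What the phantoms do *not* model: partial-volume blur, beam hardening,
cardiac anatomy and motion, scanner-dependent noise texture, annotation
noise. A network and metrics pipeline that passes the phantom tests is
demonstrably able to learn thin-tube segmentation under class imbalance and
intensity confounders; no claim is transferred to clinical data.

## Training

The published recipe is the package default: Adam with weight decay 5e-4,
batch 3, 180 epochs, learning rate 1e-5 / 1e-6 / 1e-7 on epochs [0,100),
[100,160), [160,180], and supervision weight 0.8^k stepping at epochs 40,
80, 120, 160 (intervals half-open on the left; the boundary epoch takes the
new value). `schedule_config(epochs = n)` compresses the interval
boundaries proportionally for shorter runs.

`desk_preset()` is the CPU-scale experiment used by the tests and the
acceptance script: 100 phantoms of 32x64x64 split 6:1:3, the full
dense-residual + LCT network at base width 8, 20 epochs, batch 2. Its
training samples are random 8x32x32 crops, 80% of them centred on a
foreground voxel — vessels are so sparse that uniform crops would mostly
contain background. The desk preset multiplies the scheduled learning rates
by 30 (so 3e-4 -> 3e-6): a 20-epoch run performs only ~600 optimiser
steps, and the published 1e-5 — tuned for 180 epochs at full resolution —
cannot move a freshly initialised network measurably in that budget. The
factor is the smallest of the tested ladder (x10, x30, x100) whose run
converges with margin before the first learning-rate decay step; x10
crosses the recovery threshold only around that boundary, which makes the
outcome fragile across seeds, while larger factors drift further from the
published recipe and are essentially converged within five epochs.
Validation DSC is computed after every epoch on the centre block of five
fixed validation cases, and the best-validation parameters are kept.
Problem sizes here (crop 8x32x32, five-case validation, 20 epochs) are the
package's chosen desk-scale operating point; everything scales up by
configuration.

Determinism: the case split, phantom seeds, weight initialisation, epoch
shuffling and crop sampling all derive from one master seed through
independent sub-streams, so a run is bit-reproducible on one machine.

One desk-scale finding deserves a flag. The acceptance suite compares
early-epoch validation DSC with and without deep supervision under shared
seeds and initialisation; at this scale the with-supervision runs come out
slightly *lower*. That is coherent with the mechanism: deep supervision
exists to shortcut vanishing gradients in the slow early training of a
large network at a tiny learning rate, whereas the desk network is small,
instance-normalised and trained at 3e-4 — gradient flow is already healthy,
so the coarse auxiliary Dice terms mainly bias shared features towards
blurrier maps early on. The desk tests therefore validate the machinery of
deep supervision (heads, upsampling, weighting, schedules), not its
large-scale benefit.

## Numerical notes

* Convolutions are evaluated as im2col + BLAS GEMM in compiled code, in
  double precision; pointwise convolutions skip the im2col entirely.
  Gradients of every layer are hand-derived and are held to finite
  differences and to term-by-term oracles in the test suite.
* The soft Dice loss uses smoothing constant 1e-5, keeping it defined on
  empty masks.
* Trilinear upsampling uses half-voxel centre alignment with edge
  clamping; upsampled probability fields remain probability fields because
  interpolation is convex.
* Circular padding is available on the attention block, under which it is
  exactly translation equivariant (the property tests use it).

## Limitations

* The runtime is CPU-bound R/C++; full clinical-scale inputs (16x512x512 blocks,
  180 epochs) are out of its intended range — the architecture is faithful,
  the scale is not.
* Only binary (background/vessel) segmentation and NIfTI I/O are supported;
  DICOM conversion, resampling and registration are out of scope.
* Surface distances use the brute-force scan; for very large masks a
  distance-transform implementation would be preferable.
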