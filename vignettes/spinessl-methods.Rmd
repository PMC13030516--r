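---
title: "Semi-supervised joint vertebra segmentation and identification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised joint vertebra segmentation and identification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Spinal CT analysis needs two coupled outputs per scan: a voxel-level mask of
the vertebrae (segmentation) and the anatomical level of every vertebral
instance, C1 through L5 (identification). The two tasks fail in
characteristic, coupled ways: partial field-of-view scans shift every
predicted level by a constant; adjacent vertebrae look nearly identical and
get swapped, merged, or fragmented. Dense voxel annotation is expensive, so
most of the available CT data is unlabeled.

`spinessl` implements an end-to-end semi-supervised framework for this joint
problem: a dual-branch 3D encoder--decoder trained with supervised
multi-task losses on labeled volumes and teacher--student consistency on
unlabeled volumes, followed by anatomically constrained post-processing and
instance-level evaluation. Because no external imaging data can be assumed,
the package also ships a synthetic spine-phantom generator that reproduces
the statistical structure the method relies on, so the entire pipeline is
exercised end to end on any machine.

## Model

### Architecture

The network is a dual-branch 3D U-Net:

* **Shared encoder**, four stages. Each stage applies two 3x3x3
  convolutions, each followed by instance normalization and LeakyReLU
  (slope 0.01). Stage 1 works at full resolution; stages 2--4 open with a
  stride-2 convolution, so the deepest features sit at 1/8 resolution.
  Channel widths are `base_channels * c(1, 2, 4, 8)`. This ledger (stage 1
  full-resolution, three downsamplings) is what reconciles a four-stage
  encoder with a segmentation decoder that upsamples exactly three times.
* **Bottleneck sequence operator.** The deepest feature grid is flattened
  into a cranio-caudal-major sequence (in-plane positions fastest, depth
  slowest) and passed through one of three interchangeable operators:
  a *gated diagonal state-space scan* (the default; input-dependent
  per-channel decay and output gate, linear time in sequence length), a
  standard scaled dot-product *self-attention* block (quadratic), or the
  *identity*. The state-space block is implemented from its contract --
  shape-preserving, O(1) per step in sequence length -- rather than from any
  particular published kernel; `bottleneck_flops()` exposes the analytic
  operation counts that the tests use to verify the linear-vs-quadratic
  contract. The operator can also be placed after every encoder stage
  (`bottleneck_placement = "all_encoder_stages"`), an ablation axis.
* **Segmentation decoder**: three upsampling steps (nearest-neighbour x2
  followed by a convolution block) with skip-feature concatenation, purely
  convolutional, producing single-channel foreground logits at full
  resolution plus deep-supervision heads at 1/2 and 1/4 resolution.
* **Identification decoder**: one upsampling step from 1/8 to 1/4
  resolution with the 1/4-scale skip, two convolution blocks each followed
  by a channel-then-spatial attention block (CBAM recipe: global avg+max
  pooling through a shared two-layer bottleneck MLP and a sigmoid channel
  gate, then a 2-map channel-pooled convolution and a sigmoid spatial
  gate), and a 1x1x1 head with K channels (default K = 24, C1..L5). The
  decoder predicts, per class, a heatmap whose spatial softmax is the
  predicted distribution of that vertebra's centroid. Attention placement
  is configurable (`none`, `id_only`, `both`); the default keeps the
  segmentation decoder attention-free to protect boundary fidelity.

One open question the sources leave is how many upsampling steps the
identification path takes from 1/8 to 1/4; a single step is used. Encoder
channel widths are likewise not published; `base_channels` is exposed and
defaults to 16 (8 in the desk-scale tests, < 2M parameters).

Because no deep-learning framework is available in this R stack, the
package carries its own reverse-mode autodiff tape (`R/autodiff.R`) over a
small set of tensor operations, with the 3D convolutions implemented as
blocked im2col + BLAS kernels in C++. Every operation's gradient is tested
against central finite differences.

### Losses

Supervised term, per labeled patch:

* Segmentation: at each of the three scales, an equal-weighted sum of soft
  Dice (smoothing `eps = 1e-6`) and binary cross-entropy on the sigmoid of
  the head's logits, aggregated with scale weights `ws` summing to 1. The
  default `ws = (4/7, 2/7, 1/7)` realizes "larger weight at higher
  resolution" with dyadic decay; the exact values are not published and are
  configurable.
* Identification: (i) a KL divergence between the target Gaussian heatmap
  (sigma = 2.0 voxels on the 1/4 grid, each present channel normalized to
  sum to 1) and the per-channel spatial softmax of the predicted logits,
  averaged over present classes; and (ii) an instance-consistency term, the
  mean over ground-truth vertebrae of `1 - Dice` between per-instance voxel
  sets at 1/4 resolution, which penalizes merging and fragmentation. The
  two identification terms are combined with fixed weights `kl_inst_mix =
  c(1, 1)`; a dynamic reweighting is mentioned in the source material
  without a formula, so the fixed mix is the default and the knob is
  exposed. The identification block is weighted by `alpha_cls` (default 1,
  unpublished) against the segmentation loss.

The printed instance-consistency definition operates on hard (argmax)
instance maps and is therefore not differentiable; `spinessl` exports it
exactly as defined for evaluation and testing, and backpropagates a soft
surrogate during training (per-voxel class softmax restricted to the
ground-truth foreground, soft Dice per instance). At the optimum the two
coincide.

Consistency term, per unlabeled volume: the EMA teacher sees a weakly
augmented (geometry-only) view; the student sees the same geometry plus
strong photometric corruption, so teacher predictions align voxel-wise with
student inputs. Pseudo-labels are confidence-filtered:

* Segmentation: pseudo-mask = teacher probability > 0.5, kept on voxels
  where the probability is confidently foreground (`p > tau_seg(t)`) *or*
  confidently background (`p < 1 - tau_seg(t)`); the symmetric rule is an
  interpretation -- the printed rule thresholds foreground probability
  only, but "high-confidence voxels" plainly includes confident
  background, and the empty-background alternative starves the loss early
  in the ramp. Binary cross-entropy on student logits over that set.
* Identification: teacher heatmap logits pass through a temperature-0.5
  class softmax; the argmax is the pseudo-class, kept where the maximum
  confidence exceeds `tau_cls(t)` and the voxel is teacher foreground (the
  1/4-resolution deep-supervision head supplies the foreground mask).
  Cross-entropy per class over its retained voxels, weighted by
  inverse-frequency class weights `wk` normalized so `sum(wk) = K`, summed
  over classes. Per-class averaging order is not printed; the package
  averages within a class, then applies `wk` and sums.

Both consistency losses are defined as 0 on empty retained sets so the
early ramp is numerically stable.

### Schedules

With `E_cons = 40`, `E_ramp = 80`, `total = 100` epochs:

* consistency weight `lambda(t)`: 0 before `E_cons`, then
  `min(1, (t - E_cons) / (E_ramp - E_cons))`, fixed at 1 afterwards;
* `tau_cls(t)`: 0.30 -> 0.55 linearly over the same window, clamped;
* `tau_seg(t)`: 0.50 -> 0.90 linearly, clamped.

`scale_schedule()` rescales all epoch constants proportionally so shorter
runs keep the 40:40:20 warm-up:ramp:stable split -- the desk-scale tests
use 12 epochs (5 warm-up, 5 ramp, 2 stable).

The teacher is initialized as an exact copy of the student when consistency
starts and is thereafter updated after every student step by
`theta_ema <- 0.99 * theta_ema + 0.01 * theta_student`; it never receives
gradients. Optimization is SGD with momentum 0.9 and learning rate 0.01,
no decay (only the initial rate and momentum are published; a decay hook
would be a one-line change in `sgd_update`). Labeled and unlabeled steps
interleave 1:1 per iteration once consistency is active (the interleaving
ratio is unpublished; 1:1 is the default and configurable).

## Augmentation

Weak (geometry-only): flips with probability 0.5 on each in-plane axis and
0.25 on the cranio-caudal axis, then an in-plane rotation uniform on
[-22.5, +22.5] degrees -- bilinear for intensities, nearest-neighbour for
labels, flips always before rotation for reproducibility. Strong
(photometric-only): RandAugment-style, 1--3 operations drawn per call from
{intensity scale/shift, gamma, Gaussian/salt-and-pepper/Poisson/speckle
noise, Gaussian blur, 3x3x3 median, unsharp masking, slice-wise CLAHE},
never moving voxels and never touching labels. The magnitude ranges (gamma
[0.7, 1.5], additive noise sd [0.01, 0.1] and so on; see
`?strong_policy`) are design choices -- the source's parameter table is not
available -- and all are configurable. CLAHE runs per axial slice through
`EBImage::clahe` with the tile grid scaled to the slice (slices under
16 px are passed through unchanged; the clip limit uses EBImage's
multiples-of-uniform scale, range [1, 3]).

Labeled pairs share one geometry record between volume and mask; the full
strong pipeline is applied to the volume with probability 0.5, otherwise a
mild global scaling from [0.95, 1.05] with probability 0.5.

## Inference and post-processing

Sliding-window inference (default 50% overlap, mean fusion of
probabilities -- the overlap and fusion rule are unpublished design
choices) stitches the full-resolution foreground probability and the
per-class heatmap distributions. Then:

1. threshold at 0.5 (strictly greater; exact ties are background);
2. 26-connected component labeling, components below `min_fragment` voxels
   removed (default 200 at 1 mm^3; the connectivity and floor are
   unpublished -- both configurable);
3. per-class heatmap peaks (ties to the lowest linear index) become
   predicted centroids; classes whose peak is below 10% of the volume's
   maximum peak are called absent;
4. every foreground voxel joins its nearest centroid (Euclidean; ties to
   the more cranial centroid), and each instance takes the majority id of
   its voxels with that id's peak value as confidence;
5. sequence continuity: final ids must increase by exactly 1 down the
   cranio-caudally sorted instances. The instance with the highest
   confidence anchors the run and keeps its raw id; everything else is
   renumbered around it, which resolves duplicates (confidence first, then
   spatial order) and fills gaps superior-to-inferior. The run is shifted
   if it would leave 1..24, and caudal extras beyond 24 are flagged
   unassigned. The anchor rule is the package's resolution of an
   under-determined prescription ("shift or fill from superior to
   inferior") and is verified against an enumeration oracle in the tests.

## Evaluation

`dice_global()` is the standard overlap Dice (both-empty defined as 1).
Instance identification accuracy counts a ground-truth vertebra as correct
only if it is matched one-to-one to a predicted component with IoU at
least `tau_iou` *and* that component's final id equals the ground-truth
level; the matching maximizes total IoU (Hungarian algorithm, verified
against exhaustive enumeration for up to 5x5 problems). `tau_iou` defaults
to 0.5 -- the conventional instance-detection threshold; no value is
published, so every report states the value used. `region_report()`
stratifies by cervical (1--7), thoracic (8--19), lumbar (20--24).

## The synthetic phantom and what it does (not) show

`phantom_spec()` describes a miniature spine: a cranio-caudal stack of
axis-aligned ellipsoidal "vertebral bodies" (in-plane semi-axis 3.5 mm,
cranio-caudal semi-axis 2.8 mm, 3 mm gaps) of bright bone-like intensity
(400 HU) on a darker background (-50 HU) with additive Gaussian noise
(sd 25 HU), on a (48, 24, 24) voxel grid at 1 mm spacing. Body positions
are deterministic given the spec, so an anatomical level always sits at
the same depth, and field-of-view truncation removes extreme bodies
without moving the rest. Defaults were chosen once: large enough that
every component (patching, augmentation, both decoders, consistency
training, post-processing, matching) is exercised with realistic failure
modes -- adjacency merging, index shifts under truncation, photometric
corruption -- and small enough that the full six-run semi-supervised
versus fully-supervised study completes in minutes on one CPU. The
12-epoch desk-scale study uses 8 labeled + 12 unlabeled phantoms, batch
size 1, 10 steps per epoch, `base_channels = 8`, and held-out noiseless
phantoms for validation/testing; `min_fragment` is lowered to 50 voxels at
evaluation because the miniature bodies hold only ~140 voxels.

What passing phantoms shows: the optimization machinery descends, the
teacher--student loop is stable, pseudo-label filtering behaves, the
post-processing recovers exact instance maps from oracle-grade outputs,
and identification is learnable when level is a deterministic function of
position. What it does not show: performance on real CT -- no bone
texture, no arches/processes, no curvature or pathology, and real
vertebra identity is not a pure function of scanner position. Numbers from
phantom runs are smoke-level evidence about the implementation, not about
clinical accuracy.

## Numerical choices

* Dice smoothing `eps = 1e-6`; CE probabilities clamped to
  `[1e-7, 1 - 1e-7]`; class-softmax probabilities floored at `1e-12` in
  logs.
* Instance-norm epsilon `1e-5`; He-style initialization scaled for
  LeakyReLU; biases zero, IN gain 1.
* Exact-tie rules are all documented and tested: probability exactly at
  the binarization threshold is background; equal heatmap maxima take the
  lowest linear index; equidistant voxels join the more cranial centroid;
  equal anchor confidences take the more cranial instance.
* Empty sets: empty consistency masks give loss 0; a volume with no
  predicted centroids leaves the foreground unassigned with a warning;
  both-empty Dice is 1.
* All randomness is seeded (`with_seed` restores global RNG state); a
  fixed spec/seed reproduces phantoms, augmentations, initializations and
  training trajectories bit-for-bit on one machine.

## Known limitations

* CPU-only and desk-scale: the network is intentionally small; nothing
  here is tuned for benchmark-scale CT.
* The hard instance-consistency loss is reported but its gradient comes
  from the soft surrogate described above.
* The state-space block is a minimal gated scan satisfying the published
  contract (shape-preserving, linear-time), not a reimplementation of any
  specific selective-scan kernel.
* Transitional anatomy (e.g. S1) is outside the default 24-label protocol;
  the extended label set is configurable but unscored.
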