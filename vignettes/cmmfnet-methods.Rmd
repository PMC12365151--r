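---
title: "Methods: multimodal contrastive fusion for lung adenocarcinoma subtyping"
author: "cmmfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal contrastive fusion for lung adenocarcinoma subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lung adenocarcinoma is staged into three subtypes of increasing
invasiveness — adenocarcinoma in situ (AIS, with the rare precursor AAH
folded in), minimally invasive adenocarcinoma (MIA) and invasive
adenocarcinoma (IA). On CT the subtypes differ in lesion size, density
(ground-glass versus solid) and margin irregularity, but the differences
are subtle, and radiologists routinely combine the image with the
patient's clinical record. `cmmfnet` implements a three-modality deep
classifier for this task together with everything needed to exercise it
without clinical data: preprocessing, a synthetic lesion-phantom world,
and cross-validated training and evaluation.

## Model

Three inputs per lesion: a small CT crop $\mathcal I^S$ ($32^3$ voxels at
1 mm), a large crop $\mathcal I^L$ ($128\times128\times32$), each with the
lesion's crop-relative bounding box $\mathcal B$, and the encoded clinical
vector $\mathcal C \in \mathbb R^{1\times l}$.

**CT encoder (CTE).** A 3D vision transformer. The crop is cut into
non-overlapping $p^3$ patches ($p = 8$ by default, giving
$\lceil w/p\rceil \lceil h/p\rceil \lceil d/p\rceil$ tokens: 64 and 1024
for the two scales), each flattened and linearly embedded into
$\mathbb R^D$ ($D = 768$). The six box coordinates $(x,y,z,w,h,d)$ are
linearly embedded as one extra token occupying position 0, a learnable
positional table is added, and the sequence passes through 12 pre-norm
transformer blocks (multi-head self-attention with
$\mathrm{softmax}(QK^\top/\sqrt{d_k})V$, $d_k = D/m$, $m = 12$ heads, then
a GELU MLP of width $4D$). The token mean of the final layer is the
modality feature $f \in \mathbb R^{1\times D}$. Two design points decided
here:

* "averaged across the channel dimension" is read as the mean over the
  *token* axis — averaging over $D$ would collapse the embedding;
* there is **no** extra layer norm after the last block: the contract that
  zeroed attention/MLP output projections reduce the encoder to the mean
  of embedded-plus-positional tokens pins the residual path exactly, and
  the pre-norm blocks already normalize internally.

The two scales use two independent encoders by default (`share_cte = TRUE`
shares all weights except the positional tables, whose lengths differ).

**Clinical encoder (CLE).** Each scalar entry $j$ of $\mathcal C$ scales a
learned row $E_j \in \mathbb R^D$ (plus a learned bias row and a
positional row), giving an $l \times D$ sheet that is flattened and
linearly projected to $f^C \in \mathbb R^{1\times D}$. The flatten-plus-
linear reading (rather than pooling) preserves field identity.

**Contrastive alignment.** Features are L2-normalized,
$z = f / \lVert f\rVert$, and temperature-scaled cosine logits formed for
both image–clinical pairs: $l_1 = \alpha\, z_1 z_2^\top$,
$l_2 = \alpha\, z_3 z_2^\top$ with $\alpha = \exp(\log\frac1{0.07})$. The
log-scale is a learnable parameter initialized at $\log(1/0.07)$ (freeze
with `freeze_temperature = TRUE`). Each pair contributes a symmetric
cross-entropy: rows of $l$ against the matching-pair index plus rows of
$l^\top$ against the same index, halved and batch-averaged. The original
formulation writes cross-entropy against "the true label", but the logits form an
$N\times N$ image–clinical similarity matrix, so the matching-pair target
is the only shape-consistent reading; a supervised variant with
same-class positives is available via `contrastive_targets = "class"`.

**Fusion (DFF).** The *raw* (un-normalized) features are stacked into
$F = (f^S\; f^C\; f^L)^\top \in \mathbb R^{B\times3\times D}$ — the
normalized $z$'s live only on the contrastive pathway, per the two-pathway
description. Phase 1 applies $n$ residual transformer blocks over the
three modality tokens ($n = 2$ by default). The original formulation
is ambiguous on a feed-forward sub-block inside each block; the FFN is
included by default (`ffn = FALSE` gives the attention-only block). The
final normalization admits two readings, an L2 norm or layer
normalization; per-token layer norm without affine is the default
(`phase1_norm = "l2"` for the other reading). Phase 2 is channel
attention: each modality row is pooled to its mean (AP) and max (MP) over
$D$, both statistics pass through a shared two-layer map
$\sigma(W_2\,\mathrm{ReLU}(W_1\,\cdot))$ with reduction ratio $r$
($W_1 \in \mathbb R^{(3/r)\times 3}$), and the row is rescaled by the
*sum* of the two sigmoid gates (not the sigmoid of a sum), giving a multiplier
in $(0,2)$ that equals 1 at zero weights. With only three channels,
$r = 1$ is the default (the only value besides 3 giving an integer hidden
width above 1). A linear head on the flattened $3D$ stack yields the
class logits.

One consequence worth knowing: because Phase 1 ends in a per-token layer
norm, the average-pooled statistic entering the channel attention is
identically zero, so the AP gate is constant at $\sigma(0)$-level until
$W_1, W_2$ move; the MP gate carries the channel signal. The `"l2"`
normalization avoids this if it matters.

**Objective.** The total loss is
$L = \omega\,(L_{SC} + L_{LC}) + (1-\omega)\,L_{\text{focal}}$ with the
dynamic weight $\omega = L_c / (L_c + L_f)$ recomputed each step from the
current *detached* loss values (no gradient flows through $\omega$; when
every term is zero, the initial weight 0.5 is used). Substituting
$\omega$ gives the closed form $(L_c^2 + L_f^2)/(L_c + L_f)$, which the
tests assert. The focal loss is
$-\frac1N\sum \alpha_t (1-p_t)^\gamma \log p_t$ with $\gamma = 0.25$ (the
method's value — deliberately far below the canonical 2) and $\alpha_t$
inversely proportional to the training-fold class frequencies, normalized
so a balanced fold gives all-ones.

## Preprocessing

* Volumes are trilinearly resampled to 1 mm isotropic
  (shape $= \mathrm{round}(\text{shape}\cdot s / t)$, corner-aligned
  mapping, boundary clamped), then windowed to $[-1000, 400]$ HU and
  rescaled to $[0,1]$.
* Crops are centred on the (possibly fractional) box center; out-of-volume
  voxels are padded with 0, the post-windowing value of air — the natural
  fill for a lung field.
* Boxes convert to crop-relative coordinates by dividing by the crop
  shape (0-based voxel indices, center+size), clamped to $[0,1]$ when a
  lesion overflows its crop; the voxel round-trip is exact to 0.5 voxel.
* Augmentation: each axis is mirrored independently with probability 0.5,
  training samples only; the box center reflects ($c \mapsto 1-c$), and
  labels and clinical vectors are never touched.
* Clinical records: numeric fields are z-scored with statistics computed
  on the **training fold only** (population convention, divisor $n$);
  categoricals are one-hot against the training vocabulary, with unseen
  categories encoded as an all-zero group plus a warning.

## The synthetic world

The generator emulates the subtype narrative with closed-form lesions so
every claim is testable: class mixture $(0.224, 0.241, 0.535)$ — the
merged cohort proportions of AIS/MIA/IA; mean radii 4 / 7 / 11 mm (each
case draws uniformly within ±15% of its class mean, so the class radius
ranges are disjoint and a noise-free dataset is separable by size alone);
intensities 0.35 / 0.55 / 0.80 on the HU window (HU
$= 1400\,I - 1000$, spanning ground-glass to solid); spiculation
amplitudes 0 / 0.15 / 0.35 applied as a radial harmonic perturbation
$r(\theta,\varphi) = r_0(1 + a\sin 2\theta\cos 3\varphi)$. Lesions are
spheres in millimetre space embedded in a $-900$ HU lung field at the
default anisotropic spacing $(0.8, 0.8, 1.25)$ mm, so isotropic
resampling is genuinely exercised; Gaussian intensity noise (sd 0.05 of
the window by default) is added everywhere. Lesion centers sit on voxel
cell boundaries, which makes the tight support box of an unperturbed
sphere equal $\lceil 2r_0/s\rceil$ voxels per axis in the aligned case;
for arbitrary radii any voxelization is within one voxel of $2r_0/s$, and
the tests assert the exact index-arithmetic count. The clinical schema
(age, sex, smoking, nodule diameter, a marker level) shifts with class,
and the nodule diameter is tied to the *sampled* radius, giving a true
cross-modal correlation for the contrastive objective to exploit. What
the phantoms do **not** model: vasculature and parenchymal texture,
pleural attachment, partial-volume effects, multi-lesion cases, scanner
noise spectra. A green learning-sanity test therefore establishes that
the architecture, gradients and training loop work — not clinical
performance.

## Training and evaluation

Adam with learning rate $10^{-4}$, weight decay $10^{-3}$, betas
$(0.9, 0.99)$; per-epoch exponential decay with factor 0.99; batch size
24; 500 epochs at paper scale, 30 by desk default — the budget is a config
value, not a code change. Stratified five-fold cross-validation deals each
shuffled class round-robin over the folds (per-fold counts within one
sample of proportionality); each fold trains an independently initialized
model, the clinical encoder is refit on each training split, and the
best-validation-accuracy epoch is kept (our model-selection rule; any
fixed rule would do). Metrics: accuracy, macro precision/recall/F1 in percent with
undefined per-class values counted as 0, and macro one-vs-rest AUC with
midrank ties (constant scores give exactly 0.5) — both conventions are
forced by the degenerate all-majority baseline row that the tests
reproduce (71.01 / 23.67 / 33.33 / 27.68 / 50.00 on a 49-of-69 majority
split). Both pooled-prediction and per-fold mean±sd metrics are reported,
since either convention is defensible. A classic paired t-test on
per-fold metrics (dof $n-1$, error on zero difference variance) supports
variant comparisons.

### Desk-scale learning sanity

The acceptance experiment trains a reduced model — embedding 64, depth 2,
4 heads, one fusion layer, and patch size 16 (8 and 128 tokens for the two
crops) — on 120 noise-free phantoms with learning rate $10^{-3}$,
compensating the 30-versus-500-epoch desk budget; both choices were fixed
before measuring. Folds stop early once validation accuracy reaches 1.0,
which cannot change the selected checkpoint under best-accuracy selection.
On this separable world the pooled five-fold accuracy reaches 100% (the
criterion asks for ≥ 90%) in a few minutes on one CPU.

## Numerical choices and degenerate inputs

* Softmax rows are max-shifted before exponentiation; attention rows sum
  to 1 within $10^{-6}$ by construction and by test.
* Layer norm uses $\varepsilon = 10^{-5}$; the no-affine variant used at
  the end of Phase 1 leaves tokens with mean 0 and population variance 1.
* $p_t$ is clamped to $[10^{-12}, 1 - 10^{-12}]$ inside the focal loss so
  the $\gamma < 1$ gradient stays finite as $p_t \to 1$.
* Zero-norm vectors are rejected by the normalizers rather than silently
  regularized; both-zero losses fall back to $\omega = 0.5$ with a
  warning.
* Every backward pass is verified against central finite differences of
  the detached-weight objective (relative error $\sim 10^{-8}$ in the
  development checks, $10^{-4}$ tolerance in the shipped tests).
* Weight init: truncated normal (sd 0.02) for embedding/positional
  tables, fan-in-scaled normal elsewhere, zero biases.

## Limitations

* No DICOM input (no R DICOM reader in the supported environment);
  volumes enter as NIfTI-1 via the package's own minimal reader/writer,
  which handles single-frame 3D images, the common scalar dtypes and
  axis-aligned geometry only.
* The network is pure R: correct and exhaustively gradient-checked, but
  desk-scale — paper-scale training (D = 768, depth 12, 500 epochs) is
  expressible in the same configs yet far outside a CPU budget.
* Phantoms are closed-form, not photorealistic; see above for what a
  green test does and does not establish.
* Clinical encoders assume a fixed field schema; transferring weights
  across datasets with different fields is out of scope.
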