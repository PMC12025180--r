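---
title: "Multi-condition FAZ segmentation by knowledge distillation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-condition FAZ segmentation by knowledge distillation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The foveal avascular zone (FAZ) is the capillary-free region at the center of
the fovea. Its area and shape change measurably in diabetic retinopathy (DR),
age-related macular degeneration (AMD), Alzheimer's disease (ALZ) and other
conditions, which makes automated FAZ segmentation in en face OCTA images a
useful quantitative biomarker pipeline. The practical obstacle is data:
clinical OCTA cohorts are small and imbalanced across conditions, and
transformer-style segmentation models overfit small datasets.

`fazkd` implements a segmentation architecture built around three ideas:

1. **Inductive biases in attention.** Each self-attention block receives two
   additive pre-softmax score matrices besides the usual content scores
   $q_i \cdot k_j / \sqrt{d}$: a *positional* score matrix that depends only
   on the absolute patch locations (parameterized low-rank, $P_h = U_h
   V_h^\top$), and a *Gaussian locality* kernel
   $L_{ij} = \exp\!\big(-(x_i-x_j)^2/\sigma_x - (y_i-y_j)^2/\sigma_y\big)$
   with learnable per-head axes, entering the softmax in log form. Both
   pathways have far fewer weights than content attention; an L1 penalty on
   the content scores pushes the model toward them.
2. **Sparse-autoencoder feed-forwards.** The transformer MLP is replaced by
   an overcomplete hidden layer (expansion factor $\times$ embedding dim,
   ReLU) with an L1 activity penalty, so few units stay active.
3. **Knowledge distillation across conditions.** One shared encoder feeds a
   condition-conditioned *base* decoder and one *teacher* decoder per
   condition. All are trained simultaneously; at test time only the base
   model is used. The base decoder receives a one-hot condition code,
   projected per stage and added to every patch embedding.

## Architecture

The encoder alternates strided 3×3 convolutions (halving resolution,
doubling-ish channels) with transformer blocks; a token-wise two-layer fully
connected network forms the bottleneck. The decoder mirrors this with 2×2
stride-2 transposed convolutions; each decoder stage first adds the
condition embedding (base only), then integrates the same-scale encoder skip
features by cross-attention (decoder tokens are queries, skip tokens are
keys/values, output added residually), then applies a self-attention block
and SAE feed-forward. A 1×1 convolution plus sigmoid yields per-pixel
probabilities at input resolution.

Choices the description above leaves open, and how this package resolves
them:

- **Where the bias matrices are added.** All three score matrices are summed
  *pre-softmax*; post-softmax addition would break row normalization. The
  Gaussian kernel enters as its logarithm, which is numerically exact and
  stable.
- **Tokens per stage.** Each stage tokenizes its feature map over the
  downsampled grid with a configurable patch size; shallow stages attend
  over many small patches, deep stages over few larger ones. Patch size 1 is
  the conceptual default; the desk-scale preset uses (4, 2) so attention
  matrices stay small.
- **$\sigma$ granularity.** Per-head scalars by default; a per-head,
  per-query-patch variant is available (`sigma_per_patch = TRUE`). Scales
  are reparameterized through a softplus, so positivity survives arbitrary
  gradient steps.
- **Cross-attention biases.** The positional and locality biases live in the
  self-attention blocks, where query and key grids coincide; skip
  cross-attention uses content scores only.
- **Positional matrix.** A full $n^2$ learnable matrix is quadratic in
  patches; rank-8 (default) factors over absolute positions keep it linear.
- **Condition injection.** Decoder only; the encoder is condition-blind so
  its features can be shared by the teachers. An optional extra one-hot slot
  supports condition-agnostic prediction.
- **Downsampling.** Strided convolution by default; stride-1 convolution
  plus 2×2 max pooling is a config flag.
- **Head counts.** The single-condition model uses 8 heads at full scale;
  the multi-condition variant can reasonably be run wider (e.g. 16) to
  capture relationships across datasets. Head count is a config choice
  (`n_heads`), default 8.

## Losses

Every supervised term is the hybrid loss
$L = c_1 L_{BCE} + c_2 L_{Dice}$ with $c_1 = 1$, $c_2 = \tfrac12$ and the
smoothed soft Dice loss
$L_{Dice} = 1 - (2\sum Y \odot \hat Y + \delta_1)/(\sum (Y + \hat Y) +
\delta_2)$, $\delta_1 = \delta_2 = 1$. For condition $j$ the distillation
loss is
$\alpha L(\hat Y_{base}, Y) + \beta L(\hat Y_{teacher_j}, Y) + \gamma
L(\hat Y_{base}, \hat Y_{teacher_j})$ with $\alpha = 1 > \beta = \tfrac12 >
\gamma = \tfrac14$: ground truth dominates the teacher comparison, and the
base model dominates the teacher. The $\gamma$ term uses the teacher's
real-valued probability map as target; gradients flow through both networks
(a stop-gradient variant is a flag).

The total training loss additionally evaluates the base decoder at every
*mask depth* $i = 0..n_{stages}$ — depth $i$ zeroes the skip connections
into the $i$ shallowest decoder stages — weighted $a_i = 2^{-i}$, so each
term outweighs the sum of all deeper-masked ones. Masking forces the deeper
(smaller) layers to carry compressed representations that already explain
the output. The mask is tied to the base-decoder branch — the teacher and
comparison terms are evaluated at full depth only — because teachers exist
per condition and the point of masking is to compress the *base* network's
representations; masking the teachers as well would multiply the number of
forward passes without serving that goal.

L1 penalties: post-softmax attention rows sum to one, so an L1 penalty there
is constant; the penalty is applied to the *pre-softmax content scores*
(positional and locality pathways are deliberately exempt) and to the SAE
hidden activations. Each attention/SAE evaluation in the training graph
contributes $\lambda \cdot \text{mean}|\cdot|$; because the depth-masked
loss runs the base decoder at several depths, every evaluation is penalized.
All pixel losses are means, not sums, so loss scales are
resolution-independent.

## Training protocol

Adam (learning rate $10^{-4}$ at full scale), batch 10, 500 epochs, with
random shifts, rotations, flips, intensity jitter and additive Gaussian
noise; geometric transforms are applied identically to image and mask
(nearest-neighbour for masks), photometric ones to the image only. The
augmentation magnitudes are not pinned by the protocol; the defaults (shift
≤ 8 px, rotation ≤ 15°, flip 0.5, ±10% jitter, noise sd 0.02) are
config-exposed. Multi-condition training cycles the conditions in a fixed
order, one condition-epoch (a full pass over that condition's training
split — conditions have unequal sizes) at a time; one optimizer covers all
parameters, and parameters outside the active graph (inactive teachers)
receive no update, which makes gradient routing exact and testable. No
learning-rate schedule and no weight decay.

Inter-modality pretraining uses a photocoagulation-style fundus
segmentation set as plain supervised segmentation (the PC data has no
conditions, so no distillation terms), and the checkpoint warm-starts FAZ
training. With two annotators per image, training can draw
$\lambda \sim U(0,1)$ per sample and use $\lambda m_1 + (1-\lambda) m_2$ as
the target together with the interpolated condition-annotator code; the
endpoints reproduce single-annotator training exactly.

## Evaluation

Dice index $2|A \cap B|/(|A|+|B|)$ on masks binarized at 0.5 (the threshold
is a package choice; empty-vs-empty is defined as 1, which cannot occur
with the synthetic defaults). Two-fold cross-validation halves each
condition at *patient* level with one seeded partition reused everywhere,
trains on one half, tests on the other, swaps, and averages. Because small
test sets make per-epoch scores noisy, the reported number is the mean test
Dice over the final 100 epochs. Comparisons between model variants use a
paired t-test and paired Cohen's $d_z$ over those final-window per-epoch
scores. Per-epoch metrics are autocorrelated, so the paired t-test's
independence assumption is optimistic; the protocol is mirrored as stated
rather than corrected, and the caveat applies to any p-values produced this
way. $d_z$ (mean/sd of paired differences, sign preserved) is used because
it is the variant consistent with the paired test.

## Synthetic data

No public OCTA FAZ cohort with per-condition labels and dual annotations is
bundled; the generator replaces it with a controllable emulation:

- **FAZ shapes** are star-convex radial-harmonic curves $r(\theta) =
  \max(1, R + \sum_{k=2}^{5} A_k \cos(k\theta + \phi_k))$, $R \sim
  N(\mu_c, \sigma_c)$, harmonic amplitudes proportional to a per-condition
  irregularity; zero irregularity gives a disk, larger values give the
  enlarged, irregular shapes seen in disease.
- **Vessel texture** comes from recursive biased random walks started at
  the image border with branching, lightly blurred; intensity inside the
  FAZ is suppressed to background level, as the FAZ is capillary-free.
  Additive Gaussian speckle (sd 0.05 by default) is applied last.
- **Annotators** apply a signed disc dilation/erosion bias plus smooth
  boundary jitter (thresholding the signed distance transform at a smooth
  Gaussian random field), emulating systematic inter-annotator differences.
- **Cohort structure**: four conditions with 17/33/31/21 eyes (102 total),
  patients owning 1–2 eyes so cross-validation can split at patient level;
  the per-condition morphology (Healthy → DR: radius fraction 0.140 →
  0.185 of the image side, irregularity 0.08 → 0.45, vessel density 0.90 →
  0.55) is illustrative — no per-condition FAZ statistics are published for
  the motivating cohort, so these profiles are a design choice, chosen once
  to give visible, ordered condition differences.
- **Photocoagulation set**: 298 fundus-like images (radial gradient +
  vessel texture) with 1–30 bright elliptical lesion blobs; the mask is the
  blob union.

All randomness flows from one named seed through deterministic
seed-derivation; datasets are byte-reproducible.

What passing tests on this generator do *not* show: real OCTA speckle
statistics, device artifacts, signal dropout, or the deep vascular complex'
appearance. The synthetic task is easier than clinical segmentation — the
FAZ is always the central dark region — so absolute Dice values here do not
transfer to clinical data; the tests establish correctness of the losses,
attention mechanisms, routing and protocol, and qualitative properties such
as the distillation benefit under imbalance.

## Numerical engine and problem sizes

No neural-network or automatic-differentiation library is a dependency: the
package carries a compact tape-based reverse-mode engine over dense
matrices (`R/autograd.R`) with compiled kernels (RcppArmadillo) for row
gather/scatter — which expresses im2col convolution, patchify, transposed
convolution and upsampling — and for the fused multi-head attention with
both bias pathways. Every hand-derived backward pass is checked against
central finite differences in the test suite (relative error ≤ 2e-4 at
h = 1e-6).

The documented full-scale preset (256×256, dims 128/256/512, 8 heads) is
not trained in the tests. The desk-scale preset used throughout —
`tiny_model_config()`: 64×64 inputs, 2 stages, dims 16/32, 4 heads, patch
sizes (4, 2), SAE expansion 2, positional rank 4, Adam 2e-3 — trains to
held-out Dice ≈ 0.9 on the easiest synthetic condition in 200 steps
(minutes on one CPU). Problem sizes in the tests (40 train/20 test per
condition for single-condition runs; 16 per common condition and 8 for the
rare one in the distillation comparison; 12–60 epochs) were chosen as the
smallest sizes at which the studied effects are stable across seeds.
Degenerate inputs are defined rather than left to chance: sampled FAZ radii
≤ 0 are clamped to 1 px with a warning, annotations that empty a mask
return a 1-px centroid mask with a warning, zero-variance paired tests are
errors rather than NaN, and probabilities are clipped at 1e-7 inside the
cross-entropy.

One measurement deserves a caveat: "does pretraining help at step 0 of
fine-tuning?" is degenerate under this generator when measured by binarized
Dice, because the photocoagulation task (bright lesions) has polarity
opposite to the FAZ (dark hole) — a pretrained model's initial prediction
avoids the FAZ entirely while random-init speckle can overlap it by chance.
The tests therefore assert the warm start where it is actually visible: at
an identical short fine-tuning budget the pretrained model reaches a lower
training loss than random initialization.

## Known limitations

- 2D en face images only; no volumetric OCTA, no DVC layer.
- The engine is single-threaded CPU code built for desk-scale models; the
  full-scale preset is architecture-complete but not practical to train
  here.
- Base and teacher networks are compared at the output level (at several
  mask depths), not feature map against feature map; a per-layer feature
  loss would be a natural extension but is out of scope here.
- Synthetic condition profiles are illustrative, not calibrated to any
  clinical cohort; reported synthetic Dice values are not clinical claims.
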