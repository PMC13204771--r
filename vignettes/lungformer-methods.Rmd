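---
title: "Methods: multi-slice transformer classification and report generation for lung CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-slice transformer classification and report generation for lung CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Thoracic CT interpretation distinguishes three principal clinical categories
— no malignancy, small-cell lung carcinoma (SCLC), and non-small-cell lung
carcinoma (NSCLC) — and produces a structured free-text report. Radiologists
do neither from a single image: they read a run of adjacent axial slices and
then verbalise what they saw. `lungformer` reproduces that two-stage
workflow as a single differentiable pipeline operating on five axial slices
per patient.

**Per-slice encoding.** Each slice is lung-windowed, resized to 224×224 and
replicated to three channels, then split into 196 non-overlapping 16×16
patches. Patches are linearly projected to D = 768, a CLS token is
prepended, and a learnable positional embedding (197×768) is added. Twelve
pre-norm transformer blocks follow — each sublayer is
`x + Sublayer(LayerNorm(x))`, attention has 12 heads of width 64, the MLP
expands 4× with GELU — and a final LayerNorm closes the encoder. The final
LayerNorm is not stated explicitly by the architecture's published
description; it is included because (a) it is the standard composition of
this encoder family and (b) the published trainable-parameter figure for
the encoder (85.80 M) is reproduced exactly only with it. This
inference-by-count is verified by the test suite and the acceptance script.

**Cross-slice aggregation (LQAP).** The five per-slice sequences are
concatenated along the token axis (985×768). A bank of 197 trainable latent
queries (Xavier-uniform initialised) attends over the concatenation:

$$Z' = \mathrm{MHA}(\mathrm{LN}(Q_{lat}), \mathrm{LN}(X), \mathrm{LN}(X)) + Q_{lat},
\qquad Z = \mathrm{MLP}(\mathrm{LN}(Z')) + Z'.$$

Three points here are deliberate and parameter-count-verified:

* query, key and value inputs pass through **independent** LayerNorm
  modules even though keys and values receive the same tensor;
* the residual adds the **raw** queries, not their normalised form — the
  formulation adds $Q_{lat}$, not $\mathrm{LN}(Q_{lat})$;
* the attention projections carry biases; without them the published
  7.24 M / 7.09 M figures for the two pooling blocks are unreachable.

Because attention is a weighted sum over an unordered key set, the pooled
context is invariant to permuting the five slice blocks; the test suite
checks this at 1e-5. A second, structurally identical block with a single
class query pools the 197-token context to one 768-vector.

**Classification head.** `LN → Linear(768→256) → GELU → Linear(256→3)` with
softmax cross-entropy. The hidden width is not part of the published
accounting; 256 was chosen as the smallest power of two that keeps the head
far below one million parameters, it is config-exposed, and it is excluded
from the parameter-accounting checks.

**Report decoder.** A GPT-2-geometry decoder (50,257-token id space, 1024
learned positions, 12 blocks, 12 heads, weight-tied LM head) is extended
with a cross-attention sublayer in every block: text supplies the queries,
the 197-token LQAP context supplies keys and values. LayerNorm is applied on
the query path only — keys and values are the raw context — which is again
what the 152.81 M decoder accounting requires. Teacher forcing computes all
next-token logits in one causal-masked pass; the language loss is the
token-mean cross-entropy (whether the original formulation averages or sums
per sequence is unstated; token-mean is adopted because it decouples the
loss scale from report length). Inference is greedy from `<|endoftext|>`
(id 50256 serves as both BOS and EOS, the standard single-special-token
convention) until EOS or 64 tokens; temperature/top-k sampling is
config-exposed but off by default since no sampling scheme is specified for
the original system.

**Joint objective.** `L_total = L_cls + λ·L_report` with λ = 0.3, Adam
(betas 0.9/0.999, eps 1e-8, no weight decay — unstated upstream, so the
optimizer defaults are used and exposed), a one-cycle schedule (peak 1e-4
for the full-size profile, 30 % cosine warm-up from peak/25, cosine
annealing to peak/25/1e4 — the div factors are the de-facto defaults of the
schedule and are config-exposed), batch 16, at most 100 epochs, early
stopping after 5 non-improving validation epochs, best-checkpoint selection
on validation total loss.

# Explainability

Grad-CAM is adapted to the transformer encoder. For slice $i$ and class
$c$, the gradient of the logit $y^c$ with respect to each head's attention
probabilities in the **final** encoder block is obtained by
backpropagation through the head and both pooling blocks;
$\alpha_k = \tfrac1Z\sum_{u,v} \partial y^c / \partial A^{k}_{uv}$ averages
it spatially, and the map is $\mathrm{ReLU}(\sum_k \alpha_k A^k)$ over the
CLS-query row of the 196 patch tokens, reshaped row-major to 14×14,
bilinearly upsampled and min-max normalised per slice.

The published description is ambiguous here: its equations operate on
attention maps while the surrounding prose describes reshaping token
*embeddings* to a 14×14×D grid. The two are never reconciled upstream; this
implementation follows the equations (attention probabilities, CLS row) and
records the discrepancy. Two numerical choices are pinned: an all-negative
combined map ReLUs to an all-zero, explicitly flagged "degenerate" map
rather than being renormalised, and the Pointing Game breaks ties at the
first maximal pixel in row-major order.

Saliency validation binarises the top 20 % activation quantile (ties
included, so the mask can exceed 20 % by the tied pixels) and scores IoU,
Dice and Pointing-Game hits against lesion boxes rescaled into the map
frame with floor/ceil coverage rounding. `Dice = 2·IoU/(1+IoU)` holds
identically and is property-tested.

# Preprocessing choices

* **Windowing**: linear map of level ± width/2 (defaults −600/1500 HU, the
  standard lung parenchyma window) onto 0..255 with clamping. The rounding
  rule is not stated upstream; round-half-even is pinned for cross-platform
  reproducibility (−600 HU maps to 127.5 and rounds to 128).
* **Resize**: bilinear with half-pixel centres, no corner alignment, no
  antialiasing. This dialect is pinned because cached fixtures must be
  bit-stable; it matches the most common library default.
* **Scaling**: divide by 255, then per-channel standardisation with the
  pretrained backbone's published statistics (0.485/0.456/0.406 means,
  0.229/0.224/0.225 SDs). Normalisation is unstated upstream and therefore
  config-exposed.
* **Reports**: fixture reports carry machine-readable `[section]` tags in
  eight fixed categories; only the `[parenchyma]` section feeds the
  decoder. A report without the requested section yields an empty, flagged
  result — never a silent drop.
* **Tokenizer**: the decoder contract is the 50,257-id GPT-2 BPE space
  shared by both languages. The packaged default is a byte-level encoder
  into ids 0..255 of that same space (id 50256 = `<|endoftext|>`), which
  keeps the vocabulary contract with zero external files; a vocabulary JSON
  can override it. Real BPE merges are neither shipped nor required by any
  test.
* Slice selection on real data consumes externally supplied (radiologist-
  chosen) indices; the tool never auto-detects lesions.

# The synthetic cohort generator

The clinical dataset that motivated this architecture (767 patients,
248 SCLC / 263 NSCLC / 256 Normal, five slices each, eight-sentence
bilingual reports, lesion boxes) is not publicly deposited. The generator
emulates its *statistical structure* so every downstream stage is testable:

* background parenchyma at −800 HU with Gaussian noise (SD 25 HU, a
  realistic emphysema-to-normal parenchymal spread), clamped to the 12-bit
  CT range [−1024, 3071];
* SCLC-like: one compact, near-homogeneous blob (intensity jitter SD
  10 HU) centred in the middle of the field of view — a central/hilar
  analogue;
* NSCLC-like: three overlapping Gaussian lobes near the lateral periphery
  with strong internal heterogeneity (SD 40 HU) — a peripheral, irregular
  analogue;
* blobs are anisotropic Gaussian fields thresholded at half-maximum
  (cheap, smooth-edged, controllable); lesion HU is drawn from
  [−20, 80] HU, the soft-tissue range that contrasts sharply under the
  lung window;
* malignant slice levels are the five contiguous levels bracketing the
  maximal-area slice; Normal patients get five evenly spaced depths — a
  stand-in for the anatomy-defined landmark levels (apex, arch, carina,
  lower-lobe bronchus, diaphragm) used clinically, with no claim of
  equivalence;
* the report's parenchyma sentence is filled from the rendered blob:
  location descriptor, long-axis size in mm measured from the index-slice
  bounding box (1 mm/px default spacing), and a margin descriptor.

Default volumes are small (48–64 px in-plane, 16–32 slices) so tests are
fast; 224-px generation is a parameter away. Determinism is strict: each
patient's RNG stream is a pure function of (cohort seed, class, index), so
cohorts are reproducible and order-independent, and the manifest hash is a
pure function of the spec.

What the generator does **not** emulate — and hence what passing tests do
not show about clinical data: anatomy (airways, vessels, pleura), scanner
and reconstruction effects, multi-lesion or metastatic disease, report
style variation beyond the template slots, and any real correlation between
image texture and histology. Tests on this cohort validate the mechanics
and the learnability of an encoded class signal (a logistic probe on mean
windowed intensity separates Normal from malignant at >0.9 accuracy by
construction), not clinical performance.

# Profiles and problem sizes

Two first-class profiles share every structural relationship:

| | base | tiny |
|---|---|---|
| input / patch | 224 / 16 (196+1 tokens) | 32 / 16 (4+1 tokens) |
| width D / heads | 768 / 12 | 64 / 4 |
| encoder / decoder layers | 12 / 12 | 2 / 2 |
| latent queries | 197 | 5 |
| vocabulary | 50,257 | 257 (byte-level ids) |
| parameters | 253.1 M | ~0.43 M |

The tiny profile keeps the latent-query count equal to the per-slice token
count (the structural-consistency rule of the full model), five slices, and
weight tying. The package's own verification runs use: gradient checks and
property suites at the tiny profile; one base-profile forward pass and the
full parameter accounting; a 200-step joint-training smoke run on 8
synthetic patients and a 300-step single-pair decoder overfit (both seeded,
at peak learning rate 1e-3, the conventional Adam rate for sub-million-
parameter models). These sizes are the package's choices for routine
verification, not statements about training the full model, which the
trainer supports unchanged at the base profile.

# Numerical notes and degenerate inputs

* LayerNorm uses eps 1e-5; GELU is the exact Gaussian-CDF form.
* All backward passes are hand-written and were validated against central
  finite differences at the tiny profile (relative error ~1e-5 across all
  parameter groups).
* Dropout (0.1 on attention probabilities, MLP and residual branches, and
  the decoder embedding) is active only in training mode; every
  determinism test and Grad-CAM run uses evaluation mode.
* Stratified splitting rounds per-class test and validation counts
  half-up and gives the remainder to train; with 256/248/263 patients at
  70/20/10 this reproduces a 77-patient test set of 26/25/26 — the
  arithmetic the published split protocol implies. An empty class warns
  and contributes nothing.
* A constant saliency map binarises to an empty mask with a degeneracy
  flag; a constant upsampled map normalises to zero rather than 0/0.
* Metric denominators of zero (a class never predicted, a single-class
  truth vector for AUC) yield `NA` plus a warning — undefined is reported
  as undefined, never as 0.
* Caption metrics tokenize by lowercasing and splitting punctuation,
  independently of the model's BPE ids. ROUGE-L uses the balanced
  F-measure (β = 1) and METEOR the standard constants (α = 0.9, γ = 0.5,
  exponent 3) because the published formula fragments for both are
  incomplete; METEOR's alignment is the longest-common-subsequence
  (monotone) alignment, a documented simplification of the minimum-chunk
  matching. CIDEr is the plain tf-idf consensus variant (not CIDEr-D)
  with uniform n-gram weights and reference-corpus idf.

# Known limitations

* The synthetic cohort cannot reproduce any of the clinical headline
  numbers (accuracies, caption scores, saliency overlap values); those
  require the original protected dataset and GPU-scale training. What the
  package reproduces exactly are the structural and arithmetic facts:
  shapes, parameter accounting, split sizes, and the metric engine's
  worked examples.
* Training the base profile in R is possible but slow (one CPU forward
  pass is ~10–60 s); the implementation favours transparency over speed
  and has no GPU path.
* The byte-level default tokenizer yields longer sequences than true BPE
  for the same text; generated-report quality at the tiny profile is a
  mechanism check, not a language-quality result.
* Loading published pretrained checkpoints is supported only through the
  documented name/shape-matching interface (`load_pretrained_lm()`), with
  cross-attention always trained from scratch; no download is performed.
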