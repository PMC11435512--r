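---
title: "Cache-based few-shot classification with vlcache: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cache-based few-shot classification with vlcache}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlcache)
```

## The problem and the model family

Few-shot crop-disease classification asks for a C-way decision when only K
labeled images per class are available (K between 1 and 16). With a frozen
vision–language encoder pair, a test image embedding `f` can be scored
against text-derived class weights `W_C` without any training (`f W_Cᵀ`,
the zero-shot term), and the few labeled images can be exploited through a
key–value cache: their embeddings `F` are the keys, one-hot labels `L` the
values, and a test image borrows label evidence from nearby keys.

`vlcache` implements three nested predictors:

1. **Zero-shot**: `R_fW = logitScale · f W_Cᵀ`. With unit rows on both
   sides this is a cosine classifier with logits in `[-s, s]`.
2. **Cache-blended (training-free)**: a prior-refinement (PR) step keeps
   the E most discriminative channels; on those channels the cache affinity
   `R_f'F' = exp(-β (1 - f′F′ᵀ))` and the per-row cache scores
   `R_F'W' = exp(γ · KL)` reweight the one-hot values, giving
   `logits = R_fW + α R_f'F' (diag(R_F'W') L)`.
3. **Trained branch**: per-class residuals `Res ∈ R^{C×E}` added to both
   the classifier weights (zero-padded to D channels) and the cache keys
   (broadcast over each class's K rows), learnable cache scores, and a
   squeeze-and-excitation (SE) gate over the channels of `W_C`. The cache
   itself stays frozen.

The classifier weights are built from a *prompt bank*: M free-text
descriptions per class, encoded and fused by intra-class cross-attention
(`S = XXᵀ`, row-softmax, weighted rows averaged and renormalized). The
descriptions are grounded in the images themselves: per class,
representative images are selected by K-means over cheap color/texture
features and captioned through a pluggable backend.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `alpha` | cache-vs-zero-shot balance | searched | ≥ 0; 0 disables the cache term exactly |
| `beta` | affinity sharpness | searched | > 0; affinities live in `[e^{-2β}, 1]` for unit rows |
| `gamma` | cache-score strength | searched | any sign; + up-weights rows the zero-shot classifier finds hard, 0 gives an unweighted cache |
| `logitScale` | cosine temperature | 1 | the core math is temperature-agnostic; a real encoder adapter would supply its learned value |
| `E` | refined channels | D/2 | 1 ≤ E ≤ D; E = D makes refinement a no-op |
| `M` | prompts per class | 10 | the bank validates `|T_i| = M` per class |
| `r` | SE reduction ratio | 32 | hidden width `max(1, floor(D/r))`, clamped with a warning |
| `epochs`, `lr`, `batchSize` | training loop | 30, 1e-3, 256 | AdamW, cosine decay to 0, no warmup; effective batch is `min(256, C·K)` |
| `weightDecay` | AdamW decoupled decay | 0.01 | the conventional AdamW default |

The default grid (`defaultParamGrid()`) is 8 log-spaced α in [0.1, 5],
6 evenly spaced β in [1, 10] and γ ∈ {0, ±0.1, ±0.5, ±1}; ties in
validation accuracy resolve toward the smallest α, then β, then |γ|, so the
search result is independent of enumeration order.

## Decisions made where the design was open

* **PR selection rule.** The refinement step needs a concrete
  per-channel criterion; this package scores channel d by the mean squared
  pairwise difference of the classifier-weight rows,
  `S_d = Σ_{i≠j}(W[i,d] − W[j,d])² / (C(C−1))`, and keeps the top E (ties
  to the lower index). Masked features are **renormalized** so `1 − cos`
  stays in [0, 2] and the affinity bounds survive masking.
* **KL direction and smoothing.** The cache score compares the smoothed
  one-hot label `q = (L + ε)/(1 + Cε)`, ε = 1e-6, against the row's softmax
  prediction as `KL(q ‖ p)` — finite for any prediction, and equal to
  `−log p_true` up to smoothing. The score uses the positive sign,
  `exp(+γ·KL)`; γ may be set negative to flip the weighting, and the grid
  covers both signs.
* **Softmax axis and scaling in the fusion.** Attention weights are
  row-wise over `S_i` (each prompt attends over all prompts); no `1/√D`
  scaling by default (a `scaled` switch exists). The fused `a_i` is
  renormalized to unit length so `W_C` acts as a cosine classifier; a
  `normalize = FALSE` escape hatch is provided, as is the plain-average
  fusion mode used as the ensemble baseline.
* **SE squeeze axis.** The squeeze is the per-channel mean of `W_C` over
  classes, giving a D-vector `y`; a literal single-scalar pooling is
  selectable (`pool = "scalar"`) for audit, but with one scalar the gate
  could not re-rank channels, so the vector reading is the default.
* **Training initialization.** `Res = 0`, cache scores at their
  training-free KL values, `W1` seeded Gaussian (sd `1/√D`), `W2 = 0`.
  Because `σ(0) = 0.5`, the fresh model is exactly the training-free
  predictor with its zero-shot term halved — a pure positive rescale whose
  behaviour is analytically checkable, and the loss/gradients at epoch 0
  are well defined. SE matrices are trained jointly with the residuals and
  scores (they are declared learnable). The loss is cross-entropy on the
  final logits.
* **Representative selection.** Features are z-scored within the class
  before K-means so 0–255 color does not drown the O(1) texture features;
  zero-variance dimensions are dropped per class. k equals
  `min(M, class size)` — one representative (the item nearest each
  centroid, ties to the lowest index) per cluster, so M controls coverage.
  `stats::kmeans` with 10 seeded random restarts provides the clustering.
  GLCM features use ITU-R 601 luma, 8 gray levels, distance 1, angles
  {0°, 45°, 90°, 135°} averaged, and the 4-feature Haralick set (contrast,
  correlation, energy, homogeneity); correlation on a constant image is
  0/0 and is defined as 1. All of these are arguments, not constants.
* **Prompt padding.** When a class has fewer representatives than M, the
  captions cycle; surplus captions are truncated to M.
* **Argmax ties** resolve to the lowest class index everywhere
  (`which.max`), and reported accuracies are percentages.

## What the synthetic fixtures emulate — and what they do not

`makeClassPrototypes` places C unit prototypes (orthonormal when C ≤ D);
image and prompt embeddings are `normalize(prototype + noise·N(0, I))` —
an approximate von-Mises–Fisher cloud with a single interpretable dial.
As noise → 0 the fixture becomes perfectly separable and every mode must
reach accuracy 100 exactly; the suite enforces this. The toy images give
each class a mean-preserving stripe texture (distinct period) over a
distinct base color, so color/GLCM clustering has planted structure to
recover. The mock encoder hashes content to a deterministic unit vector,
optionally anchored near the class prototype.

What this does **not** emulate: the anisotropic, heavy-tailed geometry of
real CLIP embeddings, correlated errors between image and text encoders,
class imbalance, or photorealistic leaf pathology. Passing tests therefore
certify the *mechanics* (formulas, shapes, invariances, determinism,
optimization behaviour), not field performance on real crop imagery — for
that, a real encoder adapter and a real captioner must be plugged into the
`EncoderBackend`/captioner contracts.

## Numerical choices and degenerate inputs

* Unit-norm is enforced defensively (`l2normalize`) at every producer;
  rows with norm < 1e-12 are an error rather than silently rescaled.
* Row-softmax subtracts the row max before exponentiation.
* Non-finite cache scores (|γ|·KL overflowing) raise an error naming γ.
* `C < 2`, empty classes, insufficient shots, dimension mismatches and
  empty captions all fail with validation errors naming the offender.
* Problem sizes in the tests and the acceptance script (C = 4, D = 16–32,
  M = 3, K ≤ 4, pools of 40–60 items per class, 50 random oracle
  instances) were chosen as the smallest sizes at which every code path —
  refinement, both cache terms, batching, the SE gate — is exercised with
  non-trivial shapes.

## Known limitations

* The captioner mock produces templated sentences; prompt *quality*
  effects cannot be studied offline.
* `runExperiment`'s image-directory mode uses the unanchored hash encoder
  by default, which yields chance-level accuracy by construction — it
  validates plumbing, not recognition.
* Training is CPU-only, full-batch for typical shot counts; very large
  C·K would want minibatching beyond the simple permutation scheme used
  here.
* The package reports accuracy only; calibration and per-class recall are
  out of scope.
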