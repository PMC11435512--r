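# vlcache

Few-shot image classification with vision–language caches, in R.

Crop-disease image collections are expensive to label: new diseases, new
crops and new imaging conditions appear faster than large labeled sets can
be assembled. Frozen vision–language encoders (CLIP-style) offer a way out —
a test image can be classified by comparing its embedding against text-derived
class weights — and a small *key–value cache* of the few labeled images
available per class can sharpen those predictions without any encoder
fine-tuning. `vlcache` implements this whole adapter family as a reusable,
fully offline-testable package: the training-free cache pipeline, a
prompt-ensemble fusion step that builds the class weights from several
generated descriptions per class, and a lightweight training branch that
learns per-class residuals under a squeeze-and-excitation channel gate. It is
aimed at researchers experimenting with few-shot adapters on top of frozen
encoders, and at anyone who wants a transparent, oracle-tested reference
implementation of this model family.

## The model

Let `f ∈ R^D` be a unit-norm test-image embedding, `W_C ∈ R^{C×D}` the
per-class classifier weights, and `F ∈ R^{CK×D}`, `L ∈ R^{CK×C}` the cache of
K labeled embeddings per class with one-hot labels.

**Classifier weights from prompt ensembles.** Each class i has M textual
descriptions, encoded as `X_i ∈ R^{M×D}`. They are fused by intra-class
cross-attention:

    S_i = X_i X_iᵀ,   A = softmax(S_i)  (row-wise),
    a_i = mean(A X_i),  renormalized to unit length,

and stacked into `W_C = [a_1; …; a_C]`. With M = 1 this is the identity; a
plain-average mode is included as the ensemble baseline. The descriptions
themselves come from a prompt bank: per class, representative images are
picked by K-means on mean-color + GLCM texture features, captioned through a
pluggable backend (a deterministic mock ships with the package; the query
template is `"Can you help me describe this [CLASS] leaf?"`), and stored as
JSON.

**Training-free logits.** A prior-refinement step keeps the E most
class-discriminative embedding channels (mask `′`). The prediction combines
the three pairwise relations among test feature, class weights and cache:

    R_fW   = f W_Cᵀ                        (zero-shot term, full D)
    R_f'F' = exp(−β (1 − f′ F′ᵀ))          (cache affinity, refined channels)
    R_F'W' = exp(γ · KL(L ‖ softmax(F′ W_C′ᵀ)))   (per-row cache scores)

    logits = R_fW + α · R_f'F' (diag(R_F'W') L)

With α = 0 this is exactly the zero-shot classifier; with γ = 0 the cache is
unweighted; the unrefined, unscored variant (`tipAdapterLogits`) is the
classic cache-adapter baseline. α, β, γ are searched on a validation split.

**Training branch.** Keeping F and L frozen, the trained variant learns
per-class residuals `Res ∈ R^{C×E}` (padded into `W` and broadcast onto
`F′`), the CK cache scores, and a squeeze-and-excitation gate
`λ = σ(W₂ ReLU(W₁ y))` over the channels of `W_C` (y = per-channel mean,
reduction ratio r). Training minimizes cross-entropy of the resulting logits
over the shot set with AdamW and a cosine schedule (defaults: 30 epochs,
lr 1e-3, batch 256, r = 32); gradients are analytic.

## Worked example

Everything below is synthetic: class prototypes on the unit sphere, image
and prompt embeddings scattered around them (noise sd 0.35), split 8:1:1 per
class, hyperparameters searched on the validation partition.

```r
library(vlcache)
cfg <- list(mode = "vlcd", shots = c(1, 4, 16), seed = 7, nClasses = 4,
            dim = 16, promptsPerClass = 3, noiseScale = 0.35, perClass = 60,
            grid = "default")
runExperiment(cfg)
#>   mode  K seed val_acc test_acc  alpha beta gamma
#> 1 vlcd  1    7   83.33    79.17 0.1749    1   1.0
#> 2 vlcd  4    7   83.33    79.17 0.3058    1   1.0
#> 3 vlcd 16    7   79.17    79.17 0.1000    1   0.5

cfg$mode <- "zeroshot"
runExperiment(cfg)
#>       mode  K seed val_acc test_acc alpha beta gamma
#> 1 zeroshot NA    7   79.17    79.17    NA   NA    NA
```

Each row is one experiment: `val_acc` is the accuracy (%) on the full
validation partition under the best grid point (`alpha`, `beta`, `gamma`),
`test_acc` the accuracy on the held-out test partition with those
parameters. Here the cache lifts the zero-shot classifier from 79.2% to
83.3% on validation at 1 and 4 shots while matching it on the 24-item test
partition, whose size quantizes accuracy in steps of ~4 points; the search
settles on small α (the cache term assists rather than dominates).
On the noiseless fixture every mode reaches exactly 100 at every K (that
invariant is enforced by the test suite).

A thin CLI over the same functions ships at `inst/cli/vlcd.R`
(`Rscript inst/cli/vlcd.R experiment --config cfg.json --out results.csv`,
plus subcommands `fixtures`, `features`, `reps`, `prompts`, `encode`,
`fuse`, `cache`, `refine`, `eval`, `train`).

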