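Package: vlcache
Title: Few-Shot Image Classification with Vision-Language Caches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Training-free and lightweight-training few-shot image
    classification built on frozen vision-language encoders. Implements
    key-value cache models with prior refinement of embedding channels and
    trilateral-relation logits, cross-attention fusion of per-class prompt
    ensembles into classifier weights, representative-image selection by
    K-means on mean-color and gray-level co-occurrence texture features,
    and a training branch with squeeze-and-excitation channel attention
    plus learnable class residuals and cache scores. Ships deterministic
    synthetic fixtures (class-structured unit embeddings, prompt banks,
    textured toy images) and mock encoder/captioner backends so the whole
    pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
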