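## Synthetic fixtures: class-structured unit embeddings, prompt embeddings,
## textured toy images, and deterministic mock backends. These are the
## offline stand-ins for a real image collection + frozen encoder pair, so
## the whole pipeline runs without any pretrained model.

#' Generate well-separated unit class prototypes
#'
#' Draws C deterministic unit vectors in R^D to anchor a synthetic class
#' structure. For C <= D the prototypes are orthonormal (QR of a seeded
#' Gaussian matrix); otherwise normalized Gaussian rows with rejection of
#' near-duplicates.
#'
#' @param spec A [SyntheticSpec-class].
#' @return C x D matrix of unit rows with pairwise cosine similarity < 1.
#' @examples
#' P <- makeClassPrototypes(syntheticSpec(3, dim = 8, seed = 7))
#' rowSums(P^2)
#' @export
makeClassPrototypes <- function(spec) {
  validObject(spec)
  C <- spec@nClasses; D <- spec@dim
  if (C > 2^D) stop("cannot place ", C, " distinct prototypes in dimension ", D)
  withSeed(subSeed(spec@seed, "prototypes"), {
    if (C <= D) {
      G <- matrix(rnorm(D * C), nrow = D, ncol = C)
      Q <- qr.Q(qr(G))[, seq_len(C), drop = FALSE]
      # fix signs so the decomposition is unambiguous
      sgn <- sign(Q[1L, ]); sgn[sgn == 0] <- 1
      P <- t(Q * rep(sgn, each = D))
    } else {
      P <- l2normalize(matrix(rnorm(C * D), nrow = C))
      repeat {
        G <- P %*% t(P); diag(G) <- -Inf
        bad <- which(apply(G, 1L, max) > 1 - 1e-6)
        if (!length(bad)) break
        P[bad, ] <- l2normalize(matrix(rnorm(length(bad) * D), ncol = D))
      }
    }
    dimnames(P) <- NULL
    P
  })
}

#' Generate labeled class-structured embeddings
#'
#' K rows per class, each `normalize(prototype + noiseScale * N(0, I))`,
#' emitted class-major (all rows of class 1 first). With `noiseScale = 0`
#' every row equals its prototype, giving an analytically separable fixture.
#'
#' @param spec A [SyntheticSpec-class]; `shotsPerClass` rows per class unless
#'   `perClass` overrides it.
#' @param prototypes C x D unit matrix from [makeClassPrototypes()].
#' @param perClass Optional override of rows per class.
#' @return A [LabeledEmbeddingSet-class], class-major.
#' @export
makeSyntheticEmbeddings <- function(spec, prototypes, perClass = NULL) {
  validObject(spec)
  C <- spec@nClasses; D <- spec@dim
  K <- if (is.null(perClass)) spec@shotsPerClass else as.integer(perClass)
  stopifnot(nrow(prototypes) == C, ncol(prototypes) == D)
  withSeed(subSeed(spec@seed, "embeddings"), {
    rows <- matrix(0, nrow = C * K, ncol = D)
    for (c in seq_len(C)) {
      noise <- matrix(rnorm(K * D, sd = 1), nrow = K)
      block <- rep(1, K) %o% prototypes[c, ] + spec@noiseScale * noise
      rows[(c - 1L) * K + seq_len(K), ] <- l2normalize(block)
    }
    labeledEmbeddingSet(rows, rep(seq_len(C), each = K),
                        syntheticClassNames(C))
  })
}

#' Generate per-class prompt embeddings around the prototypes
#'
#' For each class, M unit rows `normalize(prototype + noiseScale * N(0, I))`
#' with noise independent of the image-embedding noise; emulates the text
#' encoder applied to a class's prompt ensemble.
#'
#' @inheritParams makeSyntheticEmbeddings
#' @return List of C matrices, each M x D with unit rows.
#' @export
makeSyntheticPromptEmbeddings <- function(spec, prototypes) {
  validObject(spec)
  C <- spec@nClasses; D <- spec@dim; M <- spec@promptsPerClass
  stopifnot(nrow(prototypes) == C, ncol(prototypes) == D)
  withSeed(subSeed(spec@seed, "prompt-embeddings"), {
    lapply(seq_len(C), function(c) {
      noise <- matrix(rnorm(M * D), nrow = M)
      l2normalize(rep(1, M) %o% prototypes[c, ] + spec@noiseScale * noise)
    })
  })
}

syntheticClassNames <- function(C) sprintf("class%02d", seq_len(C))

## Default appearance table: base colors kept in [60, 195] so the +/- delta
## stripe modulation never clips, and stripe periods that divide the image
## width so the modulation is exactly mean-preserving.
.syntheticPalette <- function(C) {
  hues <- (seq_len(C) - 1L) / C
  base <- t(vapply(hues, function(h) {
    60 + 135 * c(abs(h - 0.5) * 2, h, 1 - h)
  }, numeric(3)))
  round(base)
}

#' Generate small textured toy images with class-distinct statistics
#'
#' Each class gets a distinct base RGB color and a distinct vertical stripe
#' period; stripes modulate the base by +/- `delta` with equal area, so with
#' `noise = 0` the mean color of every image equals the class base color
#' exactly. Optional uniform pixel noise is added and clipped to 0..255.
#'
#' @param nClasses Number of classes.
#' @param perClass Images per class.
#' @param size `c(H, W)` with H, W >= 16; W must be divisible by `2*period`.
#' @param seed Integer seed.
#' @param noise Integer amplitude of uniform pixel noise (0 disables).
#' @param periods Stripe half-periods per class (recycled); defaults to
#'   `2^((class - 1) %% 4)`.
#' @param delta Stripe modulation amplitude.
#' @return List with `images` (list of H x W x 3 numeric arrays in 0..255,
#'   each carrying a `classIndex` attribute), `labels`, `classNames`.
#' @export
makeSyntheticImages <- function(nClasses, perClass, size = c(32L, 32L),
                                seed = 1L, noise = 8L, periods = NULL,
                                delta = 40) {
  stopifnotScalarCount(nClasses, "nClasses", 2L)
  stopifnotScalarCount(perClass, "perClass", 1L)
  H <- as.integer(size[1L]); W <- as.integer(size[2L])
  if (H < 16L || W < 16L) stop("images must be at least 16 x 16")
  if (is.null(periods)) periods <- 2L^((seq_len(nClasses) - 1L) %% 4L)
  periods <- rep_len(as.integer(periods), nClasses)
  if (any(W %% (2L * periods) != 0L)) {
    stop("image width must be divisible by 2*period for every class")
  }
  base <- .syntheticPalette(nClasses)
  withSeed(subSeed(seed, "images"), {
    images <- vector("list", nClasses * perClass)
    labels <- integer(nClasses * perClass)
    idx <- 0L
    for (c in seq_len(nClasses)) {
      stripe <- rep(rep(c(1, -1), each = periods[c]), length.out = W)
      pattern <- matrix(stripe, nrow = H, ncol = W, byrow = TRUE)
      for (j in seq_len(perClass)) {
        img <- array(0, dim = c(H, W, 3L))
        for (ch in 1:3) img[, , ch] <- base[c, ch] + delta * pattern
        if (noise > 0) {
          img <- img + array(sample.int(2L * noise + 1L, H * W * 3L,
                                        replace = TRUE) - noise - 1L,
                             dim = c(H, W, 3L))
          img <- pmin(pmax(img, 0), 255)
        }
        idx <- idx + 1L
        attr(img, "classIndex") <- c
        images[[idx]] <- img
        labels[idx] <- c
      }
    }
    list(images = images, labels = labels,
         classNames = syntheticClassNames(nClasses))
  })
}

## Deterministic pseudo-random unit vector from a content hash.
hashUnitVector <- function(item, D) {
  withSeed(hashContent(item), l2normalize(rnorm(D)))
}

#' Deterministic mock encoder backend
#'
#' Stands in for a frozen vision-language encoder pair. In plain mode every
#' input is mapped to a content-hash-seeded pseudo-random unit vector
#' (identical input, identical output). In anchored mode an input associated
#' with class c is mapped to `normalize(prototype_c + noiseScale * n)` where
#' `n` is hash-seeded noise: images carry their class in a `classIndex`
#' attribute (as produced by [makeSyntheticImages()]), and texts are matched
#' by the longest class name they contain.
#'
#' @param dim Output dimension D (ignored when `prototypes` given).
#' @param prototypes Optional C x D unit matrix enabling anchored mode.
#' @param classNames Class names used to anchor text inputs.
#' @param noiseScale Anchored-mode noise std (0 returns the prototype).
#' @return An [EncoderBackend-class].
#' @export
mockEncoderBackend <- function(dim = 16L, prototypes = NULL,
                               classNames = NULL, noiseScale = 0) {
  anchored <- !is.null(prototypes)
  if (anchored) dim <- ncol(prototypes)
  stopifnotScalarCount(dim, "dim", 2L)
  D <- as.integer(dim)

  anchor <- function(classIdx, item) {
    if (noiseScale == 0) return(prototypes[classIdx, ])
    n <- withSeed(hashContent(item), rnorm(D))
    l2normalize(prototypes[classIdx, ] + noiseScale * n)
  }
  encImage <- function(image) {
    if (is.null(image) || length(image) == 0L) stop("empty image input")
    ci <- attr(image, "classIndex")
    if (anchored && !is.null(ci)) anchor(ci, image) else hashUnitVector(image, D)
  }
  encText <- function(text) {
    if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
      stop("empty text input")
    }
    if (anchored && !is.null(classNames)) {
      hits <- which(vapply(classNames, function(nm) grepl(nm, text, fixed = TRUE),
                           logical(1)))
      if (length(hits)) {
        ci <- hits[which.max(nchar(classNames[hits]))]
        return(anchor(ci, text))
      }
    }
    hashUnitVector(text, D)
  }
  new("EncoderBackend", dim = D, encodeImage = encImage,
      encodeText = encText,
      name = if (anchored) "mock-anchored" else "mock-hash")
}
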