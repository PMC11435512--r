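#' SyntheticSpec: parameters of the synthetic embedding fixture
#'
#' Describes a class-structured synthetic embedding problem: `nClasses` unit
#' prototypes in `dim` dimensions, `shotsPerClass` image embeddings and
#' `promptsPerClass` prompt embeddings per class, each generated as
#' prototype + isotropic Gaussian noise (sd `noiseScale`) renormalized to the
#' unit sphere. Identical spec + seed gives bit-identical outputs.
#'
#' @slot nClasses Number of classes C (>= 2).
#' @slot shotsPerClass Few-shot count K per class (>= 1).
#' @slot dim Embedding dimension D (>= 2).
#' @slot promptsPerClass Prompt texts per class M (>= 1).
#' @slot noiseScale Std of the isotropic perturbation before renormalization.
#' @slot seed Integer RNG seed.
#' @export
setClass("SyntheticSpec", representation(
  nClasses = "integer", shotsPerClass = "integer", dim = "integer",
  promptsPerClass = "integer", noiseScale = "numeric", seed = "integer"
), validity = function(object) {
  msg <- character()
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@dim < 2L) msg <- c(msg, "dim must be >= 2")
  if (object@shotsPerClass < 1L) msg <- c(msg, "shotsPerClass must be >= 1")
  if (object@promptsPerClass < 1L) msg <- c(msg, "promptsPerClass must be >= 1")
  if (object@noiseScale < 0) msg <- c(msg, "noiseScale must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticSpec
#'
#' @param nClasses,shotsPerClass,dim,promptsPerClass,noiseScale,seed See
#'   [SyntheticSpec-class].
#' @return A [SyntheticSpec-class] object.
#' @examples
#' syntheticSpec(nClasses = 3, shotsPerClass = 4, dim = 16)
#' @export
syntheticSpec <- function(nClasses, shotsPerClass = 1L, dim = 16L,
                          promptsPerClass = 10L, noiseScale = 0.1,
                          seed = 1L) {
  new("SyntheticSpec", nClasses = as.integer(nClasses),
      shotsPerClass = as.integer(shotsPerClass), dim = as.integer(dim),
      promptsPerClass = as.integer(promptsPerClass),
      noiseScale = as.numeric(noiseScale), seed = as.integer(seed))
}

#' LabeledEmbeddingSet: unit-norm feature rows with class labels
#'
#' Container for encoder output: an N x D matrix whose rows have unit L2 norm,
#' an integer label per row (1-based, in `1..length(classNames)`), and the
#' class names. When used as a cache source the rows are class-major
#' (all of class 1 first, then class 2, ...).
#'
#' @slot features N x D numeric matrix, unit rows.
#' @slot labels Integer vector of length N with values in 1..C.
#' @slot classNames Character vector of C class names.
#' @export
setClass("LabeledEmbeddingSet", representation(
  features = "matrix", labels = "integer", classNames = "character"
), validity = function(object) {
  msg <- character()
  n <- sqrt(rowSums(object@features^2))
  if (any(abs(n - 1) > .UNIT_TOL)) msg <- c(msg, "feature rows must be unit norm")
  if (length(object@labels) != nrow(object@features)) {
    msg <- c(msg, "one label per feature row required")
  }
  C <- length(object@classNames)
  if (any(object@labels < 1L | object@labels > C)) {
    msg <- c(msg, "labels must lie in 1..length(classNames)")
  }
  if (!all(seq_len(C) %in% object@labels)) {
    msg <- c(msg, "every class needs at least one row")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn LabeledEmbeddingSet-class Constructor.
#' @param features,labels,classNames See slots.
#' @export
labeledEmbeddingSet <- function(features, labels, classNames) {
  new("LabeledEmbeddingSet", features = features,
      labels = as.integer(labels), classNames = as.character(classNames))
}

#' CacheModel: frozen key-value memory of few-shot training embeddings
#'
#' Keys are the CK unit-norm training embeddings (class-major: the K rows of
#' class 1 first), values the matching one-hot label rows. The cache is frozen
#' at construction; the training branch only learns offsets around it.
#'
#' @slot keys CK x D matrix of unit rows, class-major.
#' @slot values CK x C one-hot matrix.
#' @slot classNames Character vector of C class names.
#' @slot shots Integer K, rows per class.
#' @export
setClass("CacheModel", representation(
  keys = "matrix", values = "matrix", classNames = "character",
  shots = "integer"
), validity = function(object) {
  msg <- character()
  C <- length(object@classNames)
  K <- object@shots
  if (nrow(object@keys) != C * K) msg <- c(msg, "keys must have C*K rows")
  if (!identical(dim(object@values), c(C * K, C))) {
    msg <- c(msg, "values must be (C*K) x C")
  }
  rs <- rowSums(object@values)
  one <- apply(object@values, 1L, function(r) sum(r == 1) == 1 && all(r %in% c(0, 1)))
  if (any(abs(rs - 1) > 0) || !all(one)) msg <- c(msg, "value rows must be one-hot")
  expected <- rep(seq_len(C), each = K)
  if (nrow(object@values) == length(expected) && all(one)) {
    got <- apply(object@values, 1L, which.max)
    if (!identical(as.integer(got), expected)) {
      msg <- c(msg, "value rows must be class-major (class 1 block first)")
    }
  }
  nrm <- sqrt(rowSums(object@keys^2))
  if (any(abs(nrm - 1) > .UNIT_TOL)) msg <- c(msg, "key rows must be unit norm")
  if (length(msg)) msg else TRUE
})

#' ChannelMask: the refined embedding channels
#'
#' Strictly increasing subset of channel indices (1-based) selected by the
#' prior-refinement step and applied consistently to test features, classifier
#' weights and cache keys.
#'
#' @slot indices Strictly increasing integers in 1..dim.
#' @slot dim Full embedding dimension D.
#' @export
setClass("ChannelMask", representation(indices = "integer", dim = "integer"),
  validity = function(object) {
    msg <- character()
    i <- object@indices
    if (length(i) < 1L || length(i) > object@dim) {
      msg <- c(msg, "need 1 <= E <= D channels")
    }
    if (anyDuplicated(i)) msg <- c(msg, "duplicate channel indices")
    if (is.unsorted(i, strictly = TRUE)) msg <- c(msg, "indices must be strictly increasing")
    if (any(i < 1L | i > object@dim)) msg <- c(msg, "indices out of range")
    if (length(msg)) msg else TRUE
  })

#' TrilateralParams: scalars of the cache-blended logits
#'
#' `alpha` balances the cache term against the zero-shot term, `beta` sharpens
#' the exponential cache affinity, `gamma` scales the KL-based cache-row
#' scores (sign as printed: positive up-weights rows the zero-shot classifier
#' finds hard), and `logitScale` is the cosine-logit temperature.
#'
#' @slot alpha Balance factor, >= 0.
#' @slot beta Affinity smoothing scalar, > 0.
#' @slot gamma KL smoothing factor (any sign).
#' @slot logitScale Cosine logit temperature, > 0.
#' @export
setClass("TrilateralParams", representation(
  alpha = "numeric", beta = "numeric", gamma = "numeric",
  logitScale = "numeric"
), validity = function(object) {
  msg <- character()
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (object@beta <= 0) msg <- c(msg, "beta must be > 0")
  if (object@logitScale <= 0) msg <- c(msg, "logitScale must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrilateralParams-class Constructor.
#' @param alpha,beta,gamma,logitScale See slots.
#' @export
trilateralParams <- function(alpha = 1, beta = 5.5, gamma = 0.1,
                             logitScale = 1) {
  new("TrilateralParams", alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma), logitScale = as.numeric(logitScale))
}

#' ClassifierWeights: per-class text-derived weight rows
#'
#' One fused D-dimensional row per class, used as a cosine classifier against
#' image embeddings. `fusion` records how the rows were built ("attention",
#' "average" or "external").
#'
#' @slot weights C x D matrix.
#' @slot classNames Character vector of C class names.
#' @slot normalized Logical; TRUE when rows are unit norm.
#' @slot fusion Provenance of the fusion ("attention", "average", "external").
#' @export
setClass("ClassifierWeights", representation(
  weights = "matrix", classNames = "character", normalized = "logical",
  fusion = "character"
), validity = function(object) {
  msg <- character()
  if (nrow(object@weights) != length(object@classNames)) {
    msg <- c(msg, "one weight row per class name required")
  }
  if (object@normalized) {
    n <- sqrt(rowSums(object@weights^2))
    if (any(abs(n - 1) > .UNIT_TOL)) {
      msg <- c(msg, "normalized=TRUE but rows are not unit norm")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PromptBank: per-class textual descriptions
#'
#' For each class an ordered list of M non-empty prompt strings with a
#' provenance tag each ("mock", "external-captioner" or "user-supplied").
#'
#' @slot classNames Character vector of C class names.
#' @slot prompts List of C character vectors, each of length M.
#' @slot provenance List of C character vectors matching `prompts`.
#' @slot M Prompts per class.
#' @export
setClass("PromptBank", representation(
  classNames = "character", prompts = "list", provenance = "list",
  M = "integer"
), validity = function(object) {
  msg <- character()
  C <- length(object@classNames)
  if (length(object@prompts) != C || length(object@provenance) != C) {
    msg <- c(msg, "prompts and provenance need one entry per class")
  }
  for (i in seq_len(C)) {
    p <- object@prompts[[i]]
    if (length(p) != object@M) {
      msg <- c(msg, sprintf("class '%s' has %d prompts, expected M=%d",
                            object@classNames[i], length(p), object@M))
    }
    if (any(!nzchar(trimws(p)))) {
      msg <- c(msg, sprintf("class '%s' has empty prompt(s)", object@classNames[i]))
    }
    if (length(object@provenance[[i]]) != length(p)) {
      msg <- c(msg, sprintf("class '%s': provenance length mismatch",
                            object@classNames[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' EncoderBackend: uniform image/text encoder contract
#'
#' A frozen encoder pair mapping images and strings to unit-norm D-vectors.
#' The package ships deterministic mock backends; any object honouring the
#' contract (determinism, unit norm, fixed D) can be substituted.
#'
#' @slot dim Output dimension D.
#' @slot encodeImage Function(image array) -> unit D-vector.
#' @slot encodeText Function(character scalar) -> unit D-vector.
#' @slot name Backend identifier.
#' @export
setClass("EncoderBackend", representation(
  dim = "integer", encodeImage = "function", encodeText = "function",
  name = "character"
))

#' SEModule: squeeze-and-excitation gate over classifier-weight channels
#'
#' Two linear maps around a ReLU: `W1` squeezes the D channel means to
#' `max(1, floor(D/r))` hidden units, `W2` expands back to D, and a sigmoid
#' yields per-channel gates in (0,1).
#'
#' @slot W1 H x D matrix (H = max(1, floor(D/r))).
#' @slot W2 D x H matrix.
#' @slot r Reduction ratio.
#' @export
setClass("SEModule", representation(W1 = "matrix", W2 = "matrix",
                                    r = "integer"),
  validity = function(object) {
    H <- nrow(object@W1)
    if (!identical(dim(object@W2), c(ncol(object@W1), H))) {
      "W2 must be D x H with H = nrow(W1)"
    } else TRUE
  })

#' TrainState: learnable parameters of the training branch
#'
#' Class residuals on the refined channels, the learnable cache-row scores,
#' and the SE gate weights. The cache keys/values themselves stay frozen.
#'
#' @slot residuals C x E matrix of class residuals.
#' @slot cacheScores Length-CK numeric vector of learnable cache scores.
#' @slot se [SEModule-class] gate.
#' @slot useSE Logical; FALSE reproduces the no-gate baseline path.
#' @slot epoch Epochs trained so far.
#' @slot seed Seed the state was initialized/trained with.
#' @export
setClass("TrainState", representation(
  residuals = "matrix", cacheScores = "numeric", se = "SEModule",
  useSE = "logical", epoch = "integer", seed = "integer"
))

#' FewShotSplit: per-class train/validation/test partition
#'
#' Disjoint, exhaustive per-class partition of item indices (default ratio
#' 8:1:1), from which K-shot subsets are drawn.
#'
#' @slot train,validation,test Lists of integer index vectors, one per class.
#' @slot classNames Character vector of class names.
#' @slot seed Seed used for the shuffle.
#' @export
setClass("FewShotSplit", representation(
  train = "list", validation = "list", test = "list",
  classNames = "character", seed = "integer"
))

## ---- accessors ----

#' Accessors for vlcache containers
#'
#' @param x A package container object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
#' @rdname accessors
#' @export
setMethod("classNames", "LabeledEmbeddingSet", function(x) x@classNames)
#' @rdname accessors
#' @export
setMethod("classNames", "CacheModel", function(x) x@classNames)
#' @rdname accessors
#' @export
setMethod("classNames", "ClassifierWeights", function(x) x@classNames)
#' @rdname accessors
#' @export
setMethod("classNames", "PromptBank", function(x) x@classNames)

#' @rdname accessors
#' @export
embeddings <- function(x) {
  stopifnot(is(x, "LabeledEmbeddingSet"))
  x@features
}

#' @rdname accessors
#' @export
embeddingLabels <- function(x) {
  stopifnot(is(x, "LabeledEmbeddingSet"))
  x@labels
}

#' @rdname accessors
#' @export
cacheKeys <- function(x) { stopifnot(is(x, "CacheModel")); x@keys }

#' @rdname accessors
#' @export
cacheValues <- function(x) { stopifnot(is(x, "CacheModel")); x@values }

#' @rdname accessors
#' @export
weightMatrix <- function(x) { stopifnot(is(x, "ClassifierWeights")); x@weights }

#' @rdname accessors
#' @export
maskIndices <- function(x) { stopifnot(is(x, "ChannelMask")); x@indices }

#' @rdname accessors
#' @export
promptTexts <- function(x) { stopifnot(is(x, "PromptBank")); x@prompts }

## ---- show methods ----

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: C=%d classes, K=%d shots, D=%d, M=%d prompts, noise=%g, seed=%d\n",
    object@nClasses, object@shotsPerClass, object@dim,
    object@promptsPerClass, object@noiseScale, object@seed))
})

setMethod("show", "LabeledEmbeddingSet", function(object) {
  cat(sprintf("LabeledEmbeddingSet: %d x %d unit embeddings, %d classes\n",
              nrow(object@features), ncol(object@features),
              length(object@classNames)))
})

setMethod("show", "CacheModel", function(object) {
  cat(sprintf("CacheModel: C=%d classes x K=%d shots, D=%d (keys frozen)\n",
              length(object@classNames), object@shots, ncol(object@keys)))
})

setMethod("show", "ChannelMask", function(object) {
  cat(sprintf("ChannelMask: E=%d of D=%d channels\n",
              length(object@indices), object@dim))
})

setMethod("show", "TrilateralParams", function(object) {
  cat(sprintf("TrilateralParams: alpha=%g beta=%g gamma=%g logitScale=%g\n",
              object@alpha, object@beta, object@gamma, object@logitScale))
})

setMethod("show", "ClassifierWeights", function(object) {
  cat(sprintf("ClassifierWeights: %d x %d (%s fusion%s)\n",
              nrow(object@weights), ncol(object@weights), object@fusion,
              if (object@normalized) ", unit rows" else ""))
})

setMethod("show", "PromptBank", function(object) {
  cat(sprintf("PromptBank: %d classes x M=%d prompts\n",
              length(object@classNames), object@M))
})

setMethod("show", "EncoderBackend", function(object) {
  cat(sprintf("EncoderBackend '%s': D=%d\n", object@name, object@dim))
})

setMethod("show", "TrainState", function(object) {
  cat(sprintf(
    "TrainState: Res %d x %d, %d cache scores, SE %s, epoch %d\n",
    nrow(object@residuals), ncol(object@residuals),
    length(object@cacheScores), if (object@useSE) "on" else "off",
    object@epoch))
})

setMethod("show", "FewShotSplit", function(object) {
  cat(sprintf("FewShotSplit: %d classes, %d/%d/%d items (train/val/test)\n",
              length(object@classNames),
              sum(lengths(object@train)), sum(lengths(object@validation)),
              sum(lengths(object@test))))
})
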