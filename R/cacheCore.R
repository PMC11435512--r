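## Training-free inference core: key-value cache construction, zero-shot
## cosine logits, prior refinement of embedding channels, exponential cache
## affinity, KL-based cache-row scores, and the trilateral combination
##
##   logits = R_fW + alpha * R_f'F' (diag(R_F'W') L)
##
## where f is the test embedding, W the (text-derived) classifier weights,
## F/L the cache keys/values, and primes denote the refined-channel views.

#' Build a key-value cache from a labeled embedding set
#'
#' Takes the first K rows of each class (in the set's row order), stacks them
#' class-major as keys, and pairs them with one-hot value rows.
#'
#' @param train A [LabeledEmbeddingSet-class].
#' @param K Shots per class; every class must have at least K rows.
#' @return A [CacheModel-class] with CK keys.
#' @export
buildCache <- function(train, K) {
  stopifnot(is(train, "LabeledEmbeddingSet"))
  stopifnotScalarCount(K, "K", 1L)
  validObject(train)
  C <- length(train@classNames)
  keyRows <- integer(0)
  for (c in seq_len(C)) {
    idx <- which(train@labels == c)
    if (length(idx) < K) {
      stop(sprintf("class '%s' has only %d rows, need K=%d",
                   train@classNames[c], length(idx), K))
    }
    keyRows <- c(keyRows, idx[seq_len(K)])
  }
  FF <- train@features[keyRows, , drop = FALSE]
  L <- matrix(0, nrow = C * K, ncol = C)
  L[cbind(seq_len(C * K), rep(seq_len(C), each = K))] <- 1
  new("CacheModel", keys = FF, values = L, classNames = train@classNames,
      shots = as.integer(K))
}

#' Zero-shot cosine logits
#'
#' `logitScale * f W^T`: cosine similarity between test embeddings and the
#' per-class classifier-weight rows.
#'
#' @param f Unit D-vector or N x D matrix of unit rows.
#' @param W A [ClassifierWeights-class] or C x D matrix.
#' @param logitScale Cosine-logit temperature (default 1).
#' @return N x C logit matrix.
#' @export
zeroShotLogits <- function(f, W, logitScale = 1) {
  Wm <- if (is(W, "ClassifierWeights")) W@weights else W
  fm <- if (is.matrix(f)) f else matrix(f, nrow = 1L)
  if (ncol(fm) != ncol(Wm)) stop("dimension mismatch between f and W")
  logitScale * fm %*% t(Wm)
}

#' Rank embedding channels by inter-class dispersion and keep the top E
#'
#' The prior-refinement criterion scores channel d by the mean squared
#' pairwise difference of the classifier-weight rows on that channel,
#' `S_d = sum_{i != j} (W[i,d] - W[j,d])^2 / (C (C-1))`, and keeps the E
#' highest-scoring channels (ties broken toward the lower index). This
#' dispersion score is this package's concrete selection rule for the
#' refinement step.
#'
#' @param W A [ClassifierWeights-class] or C x D matrix.
#' @param E Number of channels to keep, 1 <= E <= D.
#' @return A [ChannelMask-class].
#' @export
refineChannels <- function(W, E) {
  Wm <- if (is(W, "ClassifierWeights")) W@weights else W
  D <- ncol(Wm); C <- nrow(Wm)
  stopifnotScalarCount(E, "E", 1L)
  if (E > D) stop("E must be <= D")
  # sum_{i,j} (w_i - w_j)^2 = 2 C sum w^2 - 2 (sum w)^2, diagonal terms are 0
  s <- (2 * C * colSums(Wm^2) - 2 * colSums(Wm)^2) / (C * (C - 1))
  ord <- order(-s, seq_len(D))
  new("ChannelMask", indices = sort(as.integer(ord[seq_len(E)])),
      dim = as.integer(D))
}

#' Restrict embeddings to masked channels (renormalized)
#'
#' Applies a [ChannelMask-class] to a vector or matrix of embeddings and, by
#' default, renormalizes rows to unit length so the (1 - cosine) affinity
#' stays in \[0, 2\].
#'
#' @param x Vector (length D) or matrix (N x D).
#' @param mask A [ChannelMask-class].
#' @param renormalize Renormalize after masking (default TRUE).
#' @return Masked (and renormalized) vector or matrix with E columns.
#' @export
maskEmbeddings <- function(x, mask, renormalize = TRUE) {
  stopifnot(is(mask, "ChannelMask"))
  if (is.matrix(x)) {
    if (ncol(x) != mask@dim) stop("mask dimension mismatch")
    m <- x[, mask@indices, drop = FALSE]
    if (renormalize) l2normalize(m) else m
  } else {
    if (length(x) != mask@dim) stop("mask dimension mismatch")
    m <- x[mask@indices]
    if (renormalize) l2normalize(m) else m
  }
}

#' Exponential cache affinity
#'
#' `exp(-beta * (1 - f' F'^T))` between masked test embeddings and masked
#' cache keys; entries lie in `[exp(-2 beta), 1]` for unit rows.
#'
#' @param fMasked Unit E-vector or N x E matrix of unit rows.
#' @param FMasked CK x E matrix of unit rows (masked cache keys).
#' @param beta Smoothing scalar, > 0.
#' @return N x CK affinity matrix.
#' @export
cacheAffinity <- function(fMasked, FMasked, beta) {
  if (beta <= 0) stop("beta must be > 0")
  fm <- if (is.matrix(fMasked)) fMasked else matrix(fMasked, nrow = 1L)
  if (ncol(fm) != ncol(FMasked)) stop("dimension mismatch")
  exp(-beta * (1 - fm %*% t(FMasked)))
}

#' KL-based cache-row scores
#'
#' For each cache row, the zero-shot prediction on refined channels,
#' `p = softmax(logitScale * F' W'^T)`, is compared with the (smoothed)
#' one-hot label `q` by `d = KL(q || p)`, and the row's score is
#' `exp(gamma * d)`. With the printed positive sign, rows the zero-shot
#' classifier finds hard are up-weighted; `gamma = 0` gives all-ones
#' (unweighted cache). Smoothing is additive: `q = (L + eps) / (1 + C eps)`.
#'
#' @param FMasked CK x E masked cache keys (unit rows).
#' @param WMasked C x E masked classifier weights (unit rows).
#' @param L CK x C one-hot value matrix.
#' @param gamma KL smoothing factor (any sign).
#' @param logitScale Cosine-logit temperature (default 1).
#' @param eps Label-smoothing constant (default 1e-6).
#' @return Length-CK numeric score vector.
#' @export
cacheScores <- function(FMasked, WMasked, L, gamma, logitScale = 1,
                        eps = 1e-6) {
  stopifnot(nrow(FMasked) == nrow(L), nrow(WMasked) == ncol(L))
  P <- softmaxRows(logitScale * FMasked %*% t(WMasked))
  Q <- (L + eps) / (1 + ncol(L) * eps)
  d <- rowSums(Q * (log(Q) - log(P)))
  s <- exp(gamma * d)
  if (any(!is.finite(s))) stop("non-finite cache score; gamma too large")
  as.numeric(s)
}

#' Trilateral cache-blended logits (training-free)
#'
#' The full training-free prediction: full-dimension zero-shot term plus the
#' alpha-weighted, score-reweighted cache term on refined channels,
#' `R_fW + alpha * R_f'F' (diag(R_F'W') L)`. With `alpha = 0` this reduces
#' exactly to [zeroShotLogits()]; with `gamma = 0` the cache is unweighted;
#' with a full mask the refined views equal the originals.
#'
#' @param f Unit D-vector or N x D matrix (test embeddings).
#' @param W A [ClassifierWeights-class] or C x D matrix.
#' @param cache A [CacheModel-class].
#' @param mask A [ChannelMask-class].
#' @param params A [TrilateralParams-class].
#' @return N x C logit matrix.
#' @export
vlcdLogits <- function(f, W, cache, mask, params) {
  stopifnot(is(cache, "CacheModel"), is(mask, "ChannelMask"),
            is(params, "TrilateralParams"))
  validObject(params)
  Wm <- if (is(W, "ClassifierWeights")) W@weights else W
  fm <- if (is.matrix(f)) f else matrix(f, nrow = 1L)
  R_fW <- zeroShotLogits(fm, Wm, params@logitScale)
  if (params@alpha == 0) return(R_fW)
  fMasked <- maskEmbeddings(fm, mask)
  FMasked <- maskEmbeddings(cache@keys, mask)
  WMasked <- maskEmbeddings(Wm, mask)
  aff <- cacheAffinity(fMasked, FMasked, params@beta)
  sc <- cacheScores(FMasked, WMasked, cache@values, params@gamma,
                    params@logitScale)
  R_fW + params@alpha * aff %*% (sc * cache@values)
}

#' Cache-blended logits without refinement or scores (baseline)
#'
#' The plain cache-adapter combination `R_fW + alpha * exp(-beta (1 - f F^T)) L`
#' on full-dimension features, without channel refinement or cache-row
#' scores.
#'
#' @inheritParams vlcdLogits
#' @return N x C logit matrix.
#' @export
tipAdapterLogits <- function(f, W, cache, params) {
  stopifnot(is(cache, "CacheModel"), is(params, "TrilateralParams"))
  validObject(params)
  Wm <- if (is(W, "ClassifierWeights")) W@weights else W
  fm <- if (is.matrix(f)) f else matrix(f, nrow = 1L)
  R_fW <- zeroShotLogits(fm, Wm, params@logitScale)
  if (params@alpha == 0) return(R_fW)
  aff <- exp(-params@beta * (1 - fm %*% t(cache@keys)))
  R_fW + params@alpha * aff %*% cache@values
}
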