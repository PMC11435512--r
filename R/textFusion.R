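## Cross-attention fusion of a class's M prompt embeddings into one
## classifier-weight row. Each prompt attends over all prompts of its class
## via the self-similarity matrix, the attention-weighted embeddings are
## averaged, and the result is (optionally) renormalized so the stacked
## weight matrix acts as a cosine classifier.

#' Fuse one class's prompt embeddings by intra-class cross-attention
#'
#' Computes `S = X X^T`, `A = softmax(S)` row-wise, `AW = A X`, and returns
#' the column mean of `AW` (renormalized to unit length by default). With a
#' single prompt this is the identity. `mode = "average"` replaces the
#' attention by a plain mean of the rows — the average-ensemble baseline.
#'
#' @param X M x D matrix of unit prompt embeddings for one class.
#' @param normalize Renormalize the fused vector to unit length
#'   (default TRUE).
#' @param mode `"attention"` (default) or `"average"`.
#' @param scaled If TRUE, divide the attention scores by `sqrt(D)` before the
#'   softmax (off by default; the unscaled form is the reference).
#' @param details If TRUE, also return the attention intermediates as a list
#'   `(S, A, AW, a)`.
#' @return Length-D fused vector (or the intermediates list).
#' @export
intraClassAttention <- function(X, normalize = TRUE,
                                mode = c("attention", "average"),
                                scaled = FALSE, details = FALSE) {
  mode <- match.arg(mode)
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (nrow(X) < 1L || any(!is.finite(X))) stop("prompt matrix must be non-empty and finite")
  S <- A <- AW <- NULL
  a <- if (mode == "average") {
    colMeans(X)
  } else {
    S <- X %*% t(X)
    if (scaled) S <- S / sqrt(ncol(X))
    A <- softmaxRows(S)
    AW <- A %*% X
    colMeans(AW)
  }
  if (normalize) a <- l2normalize(a)
  if (details) list(S = S, A = A, AW = AW, a = a) else a
}

#' Stack per-class fused prompt embeddings into classifier weights
#'
#' Row i of the result is `intraClassAttention(XList[[i]])`; class order is
#' preserved.
#'
#' @param XList List of C matrices (M_i x D each, unit rows).
#' @param classNames Optional class names (defaults to `class01`, ...).
#' @inheritParams intraClassAttention
#' @return A [ClassifierWeights-class] (C x D).
#' @export
buildClassifierWeights <- function(XList, classNames = NULL,
                                   normalize = TRUE,
                                   mode = c("attention", "average"),
                                   scaled = FALSE) {
  mode <- match.arg(mode)
  if (!length(XList)) stop("need at least one class")
  D <- ncol(XList[[1L]])
  if (!all(vapply(XList, ncol, integer(1)) == D)) {
    stop("all classes must share the embedding dimension D")
  }
  W <- do.call(rbind, lapply(XList, intraClassAttention,
                             normalize = normalize, mode = mode,
                             scaled = scaled))
  if (is.null(classNames)) classNames <- syntheticClassNames(length(XList))
  new("ClassifierWeights", weights = W, classNames = as.character(classNames),
      normalized = normalize, fusion = mode)
}
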