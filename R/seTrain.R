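## Training-required branch: a squeeze-and-excitation gate over the
## classifier-weight channels, learnable per-class residuals applied to both
## the (gated) classifier weights and the cache keys on the refined
## channels, and learnable cache-row scores. The cache keys/values stay
## frozen; only Res (C x E), the CK cache scores and the SE matrices W1/W2
## receive gradient updates. Gradients are analytic (the model is a shallow
## composition of linear maps, ReLU/sigmoid and an exponential kernel), and
## the optimizer is AdamW with a cosine learning-rate schedule.

#' Construct an SE (squeeze-and-excitation) gate module
#'
#' Hidden width is `max(1, floor(D / r))`. `W1` is seeded Gaussian scaled by
#' `1/sqrt(D)`; `W2` starts at zero so the initial gate is sigmoid(0) = 0.5
#' everywhere — a pure rescale of the classifier weights, making the fresh
#' state analytically checkable.
#'
#' @param D Embedding dimension.
#' @param r Reduction ratio (default 32).
#' @param seed Integer seed for the `W1` init.
#' @return An [SEModule-class].
#' @export
seModule <- function(D, r = 32L, seed = 1L) {
  stopifnotScalarCount(D, "D", 2L)
  stopifnotScalarCount(r, "r", 1L)
  H <- floor(D / r)
  if (H < 1L) {
    warning("reduction ratio ", r, " leaves no hidden unit for D = ", D,
            "; clamping hidden width to 1")
    H <- 1L
  }
  W1 <- withSeed(subSeed(seed, "se-W1"),
                 matrix(rnorm(H * D, sd = 1 / sqrt(D)), nrow = H))
  new("SEModule", W1 = W1, W2 = matrix(0, nrow = D, ncol = H),
      r = as.integer(r))
}

#' SE-gated classifier weights
#'
#' Squeeze: per-channel mean of the weight rows over the class axis (a
#' D-vector; `pool = "scalar"` collapses further to the literal single
#' scalar mean, selectable for audit). Excite:
#' `lambda = sigmoid(W2 relu(W1 y))`, a per-channel gate in (0,1).
#' The gated weights `W_att = W * lambda` (broadcast over classes) are
#' returned with `lambda` attached as attribute `"lambda"`.
#'
#' @param W A [ClassifierWeights-class] or C x D matrix.
#' @param se An [SEModule-class].
#' @param pool `"channel"` (default) or `"scalar"`.
#' @return C x D gated weight matrix with attribute `lambda`.
#' @export
seForward <- function(W, se, pool = c("channel", "scalar")) {
  pool <- match.arg(pool)
  Wm <- if (is(W, "ClassifierWeights")) W@weights else W
  D <- ncol(Wm)
  stopifnot(ncol(se@W1) == D)
  y <- colMeans(Wm)
  if (pool == "scalar") y <- rep(mean(Wm), D)
  h <- pmax(as.numeric(se@W1 %*% y), 0)
  lambda <- 1 / (1 + exp(-as.numeric(se@W2 %*% h)))
  Watt <- Wm * rep(lambda, each = nrow(Wm))
  attr(Watt, "lambda") <- lambda
  Watt
}

#' Pad class residuals into full-dimension classifier weights
#'
#' `Pad(Res)` places residual column j at full channel `mask[j]` and zero
#' elsewhere; the result is added to the (gated) classifier weights.
#'
#' @param Watt C x D (gated) classifier-weight matrix.
#' @param Res C x E residual matrix.
#' @param mask A [ChannelMask-class] with E indices.
#' @return C x D matrix `Watt + Pad(Res)`.
#' @export
applyResidualsText <- function(Watt, Res, mask) {
  stopifnot(is(mask, "ChannelMask"))
  if (ncol(Res) != length(mask@indices) || nrow(Res) != nrow(Watt) ||
      ncol(Watt) != mask@dim) {
    stop("residual / mask / weight shapes are inconsistent")
  }
  out <- Watt
  out[, mask@indices] <- out[, mask@indices] + Res
  attr(out, "lambda") <- NULL
  out
}

#' Broadcast class residuals onto masked cache keys
#'
#' `Expand(Res)` repeats each class's residual row K times (class-major
#' cache order) and adds it elementwise to the masked keys.
#'
#' @param FMasked CK x E masked cache-key matrix, class-major.
#' @param Res C x E residual matrix.
#' @return CK x E matrix `FMasked + Expand(Res)`.
#' @export
applyResidualsCache <- function(FMasked, Res) {
  CK <- nrow(FMasked); C <- nrow(Res)
  if (CK %% C != 0L) stop("cache rows are not a multiple of the class count")
  if (ncol(FMasked) != ncol(Res)) stop("residual width must match masked keys")
  K <- CK %/% C
  FMasked + Res[rep(seq_len(C), each = K), , drop = FALSE]
}

#' Initialize the training state
#'
#' Residuals start at zero, the learnable cache scores at their KL-based
#' training-free values, `W1` seeded and `W2` zero (gate 0.5). With this
#' state the model's argmax behaviour is a rescaled version of the
#' training-free predictor.
#'
#' @param W A [ClassifierWeights-class] or C x D matrix.
#' @param cache A [CacheModel-class].
#' @param mask A [ChannelMask-class].
#' @param params A [TrilateralParams-class].
#' @param r SE reduction ratio (default 32).
#' @param seed Integer seed.
#' @param useSE Enable the SE gate (default TRUE; FALSE is the plain
#'   residual-training baseline path).
#' @return A [TrainState-class].
#' @export
newTrainState <- function(W, cache, mask, params, r = 32L, seed = 1L,
                          useSE = TRUE) {
  Wm <- if (is(W, "ClassifierWeights")) W@weights else W
  C <- nrow(Wm); E <- length(mask@indices)
  FMasked <- maskEmbeddings(cache@keys, mask)
  WMasked <- maskEmbeddings(Wm, mask)
  sc <- cacheScores(FMasked, WMasked, cache@values, params@gamma,
                    params@logitScale)
  new("TrainState", residuals = matrix(0, C, E), cacheScores = sc,
      se = seModule(ncol(Wm), r = r, seed = seed), useSE = useSE,
      epoch = 0L, seed = as.integer(seed))
}

#' Trainable scalar count of a state
#'
#' `C*E` residuals + `CK` cache scores + (with SE) the `2 * D * H` entries
#' of W1 and W2.
#'
#' @param state A [TrainState-class].
#' @return Integer number of trainable scalars.
#' @export
countTrainableParams <- function(state) {
  n <- length(state@residuals) + length(state@cacheScores)
  if (state@useSE) n <- n + length(state@se@W1) + length(state@se@W2)
  as.integer(n)
}

## Shared forward pass over a batch; returns intermediates for the backward
## pass. X: B x D unit rows.
.vlcdtForward <- function(X, Wm, state, cache, mask, params) {
  s <- params@logitScale
  Watt <- if (state@useSE) seForward(Wm, state@se) else Wm
  lambda <- attr(Watt, "lambda")
  Weff <- applyResidualsText(Watt, state@residuals, mask)
  Z <- s * X %*% t(Weff)
  FMasked <- maskEmbeddings(cache@keys, mask)
  Feff <- applyResidualsCache(FMasked, state@residuals)
  Xm <- maskEmbeddings(X, mask)
  Aff <- exp(-params@beta * (1 - Xm %*% t(Feff)))
  cacheTerm <- params@alpha * Aff %*% (state@cacheScores * cache@values)
  list(logits = Z + cacheTerm, Z = Z, Aff = Aff, Xm = Xm,
       lambda = lambda, Watt = Watt, Weff = Weff, Feff = Feff)
}

#' Logits of the training branch
#'
#' `R_fW` uses the SE-gated, residual-padded classifier weights; the cache
#' affinity uses the residual-expanded masked keys; the cache term is
#' weighted by the learnable cache scores.
#'
#' @param f Unit D-vector or N x D matrix.
#' @param W A [ClassifierWeights-class] or C x D matrix.
#' @param state A [TrainState-class].
#' @param cache A [CacheModel-class].
#' @param mask A [ChannelMask-class].
#' @param params A [TrilateralParams-class].
#' @return N x C logit matrix.
#' @export
vlcdtLogits <- function(f, W, state, cache, mask, params) {
  Wm <- if (is(W, "ClassifierWeights")) W@weights else W
  fm <- if (is.matrix(f)) f else matrix(f, nrow = 1L)
  .vlcdtForward(fm, Wm, state, cache, mask, params)$logits
}

## Cross-entropy loss and analytic gradients for one batch.
.vlcdtLossGrad <- function(X, y, Wm, state, cache, mask, params) {
  B <- nrow(X); C <- nrow(Wm); s <- params@logitScale
  fw <- .vlcdtForward(X, Wm, state, cache, mask, params)
  P <- softmaxRows(fw$logits)
  Y <- matrix(0, B, C); Y[cbind(seq_len(B), y)] <- 1
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y)], 1e-300)))
  G <- (P - Y) / B

  gradWeff <- s * t(G) %*% X                      # C x D
  gradResText <- gradWeff[, mask@indices, drop = FALSE]

  gradW1 <- gradW2 <- NULL
  if (state@useSE) {
    gradLambda <- colSums(gradWeff * Wm)          # D
    u <- gradLambda * fw$lambda * (1 - fw$lambda)
    ypool <- colMeans(Wm)
    pre <- as.numeric(state@se@W1 %*% ypool)
    h <- pmax(pre, 0)
    gradW2 <- u %o% h                             # D x H
    gradh <- as.numeric(t(state@se@W2) %*% u)
    gradpre <- gradh * (pre > 0)
    gradW1 <- gradpre %o% ypool                   # H x D
  }

  Gc <- G %*% t(cache@values)                     # B x CK: G[i, class(k)]
  gradAff <- params@alpha * Gc * rep(state@cacheScores, each = B)
  gradScores <- params@alpha * colSums(fw$Aff * Gc)
  gradFeff <- params@beta * t(gradAff * fw$Aff) %*% fw$Xm   # CK x E
  gradResCache <- t(cache@values) %*% gradFeff              # C x E
  gradRes <- gradResText + gradResCache

  acc <- 100 * mean(argmaxRows(fw$logits) == y)
  list(loss = loss, acc = acc, gradRes = gradRes, gradScores = gradScores,
       gradW1 = gradW1, gradW2 = gradW2)
}

## Minimal AdamW step on a flat list of parameter arrays.
.adamwStep <- function(theta, grad, mbuf, vbuf, t, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, wd = 0.01) {
  for (nm in names(theta)) {
    if (is.null(grad[[nm]])) next
    mbuf[[nm]] <- beta1 * mbuf[[nm]] + (1 - beta1) * grad[[nm]]
    vbuf[[nm]] <- beta2 * vbuf[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- mbuf[[nm]] / (1 - beta1^t)
    vhat <- vbuf[[nm]] / (1 - beta2^t)
    theta[[nm]] <- theta[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + wd * theta[[nm]])
  }
  list(theta = theta, m = mbuf, v = vbuf)
}

#' Train the residual + SE branch
#'
#' Minimizes the cross-entropy of [vlcdtLogits()] over the few-shot training
#' embeddings with AdamW and a cosine learning-rate decay (no warmup),
#' touching only the residuals, cache scores and SE matrices; cache keys and
#' values are frozen and bit-identical after training. Deterministic per
#' seed.
#'
#' @param trainSet A [LabeledEmbeddingSet-class] (the shot set).
#' @param W A [ClassifierWeights-class] or C x D matrix.
#' @param cache A [CacheModel-class].
#' @param mask A [ChannelMask-class].
#' @param params A [TrilateralParams-class].
#' @param epochs Training epochs (default 30).
#' @param lr Peak learning rate (default 1e-3).
#' @param batchSize Maximum batch size (default 256; the effective batch is
#'   `min(batchSize, nrow(trainSet))`).
#' @param r SE reduction ratio (default 32).
#' @param seed Integer seed (state init + batch shuffling).
#' @param useSE Enable the SE gate (default TRUE).
#' @param valSet Optional [LabeledEmbeddingSet-class] scored each epoch.
#' @param weightDecay AdamW decoupled weight decay (default 0.01).
#' @return List with `state` (trained [TrainState-class]) and `metrics`
#'   (data frame: epoch, lr, train_loss, train_acc, val_acc).
#' @export
trainVLCDT <- function(trainSet, W, cache, mask, params, epochs = 30L,
                       lr = 1e-3, batchSize = 256L, r = 32L, seed = 1L,
                       useSE = TRUE, valSet = NULL, weightDecay = 0.01) {
  stopifnot(is(trainSet, "LabeledEmbeddingSet"))
  validObject(trainSet)
  if (nrow(trainSet@features) == 0L) stop("empty training set")
  Wm <- if (is(W, "ClassifierWeights")) W@weights else W
  state <- newTrainState(Wm, cache, mask, params, r = r, seed = seed,
                         useSE = useSE)
  X <- trainSet@features; y <- trainSet@labels
  N <- nrow(X); B <- min(as.integer(batchSize), N)

  theta <- list(Res = state@residuals, scores = state@cacheScores)
  if (useSE) theta <- c(theta, list(W1 = state@se@W1, W2 = state@se@W2))
  zeros <- lapply(theta, function(p) p * 0)
  mbuf <- zeros; vbuf <- zeros

  asState <- function(th, epoch) {
    se <- state@se
    if (useSE) { se@W1 <- th$W1; se@W2 <- th$W2 }
    new("TrainState", residuals = th$Res, cacheScores = th$scores, se = se,
        useSE = useSE, epoch = as.integer(epoch), seed = as.integer(seed))
  }

  metrics <- vector("list", epochs)
  t <- 0L
  withSeed(subSeed(seed, "train-shuffle"), {
    for (ep in seq_len(epochs)) {
      lrEp <- lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
      perm <- if (N > B) sample.int(N) else seq_len(N)
      lossSum <- 0; accSum <- 0; nb <- 0L
      for (start in seq(1L, N, by = B)) {
        bi <- perm[start:min(start + B - 1L, N)]
        st <- asState(theta, ep - 1L)
        lg <- .vlcdtLossGrad(X[bi, , drop = FALSE], y[bi], Wm, st, cache,
                             mask, params)
        t <- t + 1L
        grads <- list(Res = lg$gradRes, scores = lg$gradScores,
                      W1 = lg$gradW1, W2 = lg$gradW2)
        upd <- .adamwStep(theta, grads, mbuf, vbuf, t, lrEp,
                          wd = weightDecay)
        theta <- upd$theta; mbuf <- upd$m; vbuf <- upd$v
        lossSum <- lossSum + lg$loss * length(bi)
        accSum <- accSum + lg$acc * length(bi)
        nb <- nb + length(bi)
      }
      valAcc <- NA_real_
      if (!is.null(valSet)) {
        st <- asState(theta, ep)
        vl <- vlcdtLogits(valSet@features, Wm, st, cache, mask, params)
        valAcc <- accuracy(vl, valSet@labels)
      }
      metrics[[ep]] <- data.frame(epoch = ep, lr = lrEp,
                                  train_loss = lossSum / nb,
                                  train_acc = accSum / nb,
                                  val_acc = valAcc)
    }
  })
  list(state = asState(theta, epochs), metrics = do.call(rbind, metrics))
}
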