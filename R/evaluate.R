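## Few-shot experiment harness: per-class 8:1:1 splitting, K-shot sampling,
## accuracy, exhaustive hyperparameter search on the validation partition,
## and end-to-end experiment orchestration over the synthetic fixture or an
## image directory.

#' Split items into per-class train/validation/test partitions
#'
#' Shuffles each class independently and partitions it by `ratios`
#' (default 8:1:1) with proportional floors, guaranteeing at least one item
#' per partition. Deterministic per seed; partitions are disjoint and
#' exhaustive per class.
#'
#' @param labels Integer class label per item (1..C).
#' @param classNames Optional class names.
#' @param ratios Length-3 positive weights for train/validation/test.
#' @param seed Integer seed.
#' @return A [FewShotSplit-class].
#' @export
makeSplit <- function(labels, classNames = NULL, ratios = c(8, 1, 1),
                      seed = 1L) {
  labels <- as.integer(labels)
  C <- max(labels)
  if (is.null(classNames)) classNames <- syntheticClassNames(C)
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  tr <- vector("list", C); va <- vector("list", C); te <- vector("list", C)
  withSeed(subSeed(seed, "split"), {
    for (c in seq_len(C)) {
      idx <- which(labels == c)
      n <- length(idx)
      if (n < 3L) stop(sprintf("class '%s' has %d items; need at least 3",
                               classNames[c], n))
      idx <- idx[sample.int(n)]
      nva <- max(1L, floor(n * ratios[2L] / sum(ratios)))
      nte <- max(1L, floor(n * ratios[3L] / sum(ratios)))
      ntr <- n - nva - nte
      tr[[c]] <- sort(idx[seq_len(ntr)])
      va[[c]] <- sort(idx[ntr + seq_len(nva)])
      te[[c]] <- sort(idx[ntr + nva + seq_len(nte)])
    }
  })
  new("FewShotSplit", train = tr, validation = va, test = te,
      classNames = as.character(classNames), seed = as.integer(seed))
}

#' Sample K shots per class from the train partition
#'
#' Draws exactly K indices per class without replacement from the split's
#' train partition; deterministic per seed.
#'
#' @param split A [FewShotSplit-class].
#' @param K Shots per class.
#' @param seed Integer seed.
#' @return Integer vector of C*K item indices, class-major.
#' @export
sampleShots <- function(split, K, seed = 1L) {
  stopifnot(is(split, "FewShotSplit"))
  stopifnotScalarCount(K, "K", 1L)
  withSeed(subSeed(seed, paste0("shots-", K)), {
    unlist(lapply(seq_along(split@train), function(c) {
      pool <- split@train[[c]]
      if (length(pool) < K) {
        stop(sprintf("class '%s' has only %d training items, need K=%d",
                     split@classNames[c], length(pool), K))
      }
      if (length(pool) == K) pool else sort(pool[sample.int(length(pool), K)])
    }))
  })
}

#' Classification accuracy as a percentage
#'
#' `100 * mean(argmax(logits) == label)`; argmax ties break toward the
#' lowest class index.
#'
#' @param logits N x C logit matrix.
#' @param labels Integer labels (1..C), length N.
#' @return Accuracy percentage in \[0, 100\].
#' @export
accuracy <- function(logits, labels) {
  if (!is.matrix(logits)) logits <- matrix(logits, nrow = 1L)
  if (nrow(logits) == 0L) stop("empty logits")
  if (nrow(logits) != length(labels)) stop("one label per logit row required")
  100 * mean(argmaxRows(logits) == as.integer(labels))
}

#' Default hyperparameter grid
#'
#' 8 log-spaced `alpha` in \[0.1, 5\], 6 evenly spaced `beta` in \[1, 10\],
#' `gamma` in 0, +/-0.1, +/-0.5, +/-1. `"small"` is a 12-point subset for
#' quick runs.
#'
#' @param size `"default"` or `"small"`.
#' @return Data frame with columns alpha, beta, gamma.
#' @export
defaultParamGrid <- function(size = c("default", "small")) {
  size <- match.arg(size)
  if (size == "small") {
    expand.grid(alpha = c(0.5, 2), beta = c(1, 5.5), gamma = c(0, 0.1, -0.1))
  } else {
    expand.grid(alpha = exp(seq(log(0.1), log(5), length.out = 8)),
                beta = seq(1, 10, length.out = 6),
                gamma = c(0, 0.1, -0.1, 0.5, -0.5, 1, -1))
  }
}

#' Exhaustive hyperparameter search
#'
#' Scores every grid row with `scoreFun(params)` (validation accuracy) and
#' returns the best. Ties break deterministically toward the smallest
#' `alpha`, then `beta`, then `|gamma|`, so the result is invariant to grid
#' enumeration order.
#'
#' @param grid Data frame with columns alpha, beta, gamma (and optionally
#'   logitScale).
#' @param scoreFun Function([TrilateralParams-class]) -> validation accuracy.
#' @return List with `params` (best [TrilateralParams-class]), `valAcc`, and
#'   `table` (the scored grid).
#' @export
gridSearch <- function(grid, scoreFun) {
  if (nrow(grid) == 0L) stop("empty parameter grid")
  if (is.null(grid$logitScale)) grid$logitScale <- 1
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    scoreFun(trilateralParams(grid$alpha[i], grid$beta[i], grid$gamma[i],
                              grid$logitScale[i]))
  }, numeric(1))
  ord <- order(-scores, grid$alpha, grid$beta, abs(grid$gamma))
  best <- ord[1L]
  list(params = trilateralParams(grid$alpha[best], grid$beta[best],
                                 grid$gamma[best], grid$logitScale[best]),
       valAcc = scores[best],
       table = cbind(grid, val_acc = scores))
}

## Subset a LabeledEmbeddingSet by row indices.
subsetEmbeddings <- function(set, idx) {
  labeledEmbeddingSet(set@features[idx, , drop = FALSE], set@labels[idx],
                      set@classNames)
}

## Assemble the classifier weights for a given mode.
.weightsForMode <- function(mode, XList, classNames) {
  fusion <- switch(mode,
    zeroshot = "attention", vlcd = "attention", vlcdt = "attention",
    tip = "average", ape = "average")
  buildClassifierWeights(XList, classNames, mode = fusion)
}

#' Run a few-shot experiment end to end
#'
#' Orchestrates the full protocol: build (or load) the data, split each
#' class 8:1:1, fuse prompt embeddings into classifier weights, and for each
#' requested shot count build the cache, search the hyperparameter grid on
#' the full validation partition and report accuracy on the full test
#' partition. Modes: `"zeroshot"` (no cache), `"tip"` (average-fused
#' weights, unrefined unweighted cache), `"ape"` (average-fused weights,
#' refined + scored cache), `"vlcd"` (attention-fused weights, refined +
#' scored cache) and `"vlcdt"` (as vlcd plus the trained residual/SE
#' branch).
#'
#' `config` is a list with fields: `mode`; `shots` (integer vector);
#' `seed`; fixture fields `nClasses`, `dim`, `promptsPerClass`,
#' `noiseScale`, `perClass` (pool size per class); `E` (refined channels);
#' `grid` (`"default"`, `"small"`, or a data frame); and for vlcdt `epochs`,
#' `lr`, `r`, `useSE`, `weightDecay`. Alternatively `imageDir` (+ `M`,
#' `backend`) replaces the fixture fields: images are read from a
#' directory-per-class tree, representatives are selected, captioned with
#' the mock captioner and everything is encoded with the given (default
#' mock) backend.
#'
#' @param config Named list, see Details.
#' @return Data frame with one row per (mode, K): val/test accuracy and the
#'   chosen alpha, beta, gamma.
#' @export
runExperiment <- function(config) {
  mode <- match.arg(config$mode, c("zeroshot", "tip", "ape", "vlcd", "vlcdt"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  shots <- if (is.null(config$shots)) c(1L, 2L, 4L) else as.integer(config$shots)
  if (mode == "zeroshot") shots <- NA_integer_

  if (!is.null(config$imageDir)) {
    data <- readImageDir(config$imageDir)
    backend <- if (is.null(config$backend)) mockEncoderBackend(
      if (is.null(config$dim)) 16L else config$dim) else config$backend
    feats <- imageFeatureTable(data$images)
    M <- if (is.null(config$M)) 3L else as.integer(config$M)
    reps <- selectRepresentatives(feats, data$labels, M, seed = seed)
    bank <- generatePrompts(mockCaptioner(), data$images, reps,
                            data$classNames, M = M)
    XList <- encodePromptBank(backend, bank)
    pool <- labeledEmbeddingSet(encodeImageBatch(backend, data$images),
                                data$labels, data$classNames)
  } else {
    spec <- syntheticSpec(
      nClasses = if (is.null(config$nClasses)) 4L else config$nClasses,
      shotsPerClass = 1L,
      dim = if (is.null(config$dim)) 16L else config$dim,
      promptsPerClass = if (is.null(config$promptsPerClass)) 3L else
        config$promptsPerClass,
      noiseScale = if (is.null(config$noiseScale)) 0.1 else config$noiseScale,
      seed = seed)
    protos <- makeClassPrototypes(spec)
    perClass <- if (is.null(config$perClass)) 40L else as.integer(config$perClass)
    pool <- makeSyntheticEmbeddings(spec, protos, perClass = perClass)
    XList <- makeSyntheticPromptEmbeddings(spec, protos)
  }

  W <- .weightsForMode(mode, XList, pool@classNames)
  E <- if (is.null(config$E)) max(1L, ncol(W@weights) %/% 2L) else
    as.integer(config$E)
  mask <- refineChannels(W, E)
  split <- makeSplit(pool@labels, pool@classNames, seed = seed)
  val <- subsetEmbeddings(pool, unlist(split@validation))
  test <- subsetEmbeddings(pool, unlist(split@test))
  grid <- config$grid
  if (is.null(grid)) grid <- "small"
  if (is.character(grid)) grid <- defaultParamGrid(grid)

  rows <- lapply(shots, function(K) {
    if (mode == "zeroshot") {
      valAcc <- accuracy(zeroShotLogits(val@features, W), val@labels)
      testAcc <- accuracy(zeroShotLogits(test@features, W), test@labels)
      return(data.frame(mode = mode, K = NA_integer_, seed = seed,
                        val_acc = valAcc, test_acc = testAcc,
                        alpha = NA_real_, beta = NA_real_, gamma = NA_real_))
    }
    shotIdx <- sampleShots(split, K, seed = seed)
    shotSet <- subsetEmbeddings(pool, shotIdx)
    cache <- buildCache(shotSet, K)
    logitFun <- switch(mode,
      tip = function(x, p) tipAdapterLogits(x, W, cache, p),
      ape = , vlcd = function(x, p) vlcdLogits(x, W, cache, mask, p),
      vlcdt = NULL)
    if (mode %in% c("tip", "ape", "vlcd")) {
      gs <- gridSearch(grid, function(p) {
        accuracy(logitFun(val@features, p), val@labels)
      })
      testAcc <- accuracy(logitFun(test@features, gs$params), test@labels)
      p <- gs$params
      data.frame(mode = mode, K = K, seed = seed, val_acc = gs$valAcc,
                 test_acc = testAcc, alpha = p@alpha, beta = p@beta,
                 gamma = p@gamma)
    } else {
      gs <- gridSearch(grid, function(p) {
        accuracy(vlcdLogits(val@features, W, cache, mask, p), val@labels)
      })
      fit <- trainVLCDT(
        shotSet, W, cache, mask, gs$params,
        epochs = if (is.null(config$epochs)) 30L else config$epochs,
        lr = if (is.null(config$lr)) 1e-3 else config$lr,
        r = if (is.null(config$r)) 32L else config$r,
        seed = seed,
        useSE = if (is.null(config$useSE)) TRUE else config$useSE,
        weightDecay = if (is.null(config$weightDecay)) 0.01 else
          config$weightDecay)
      valAcc <- accuracy(vlcdtLogits(val@features, W, fit$state, cache,
                                     mask, gs$params), val@labels)
      testAcc <- accuracy(vlcdtLogits(test@features, W, fit$state, cache,
                                      mask, gs$params), test@labels)
      p <- gs$params
      data.frame(mode = mode, K = K, seed = seed, val_acc = valAcc,
                 test_acc = testAcc, alpha = p@alpha, beta = p@beta,
                 gamma = p@gamma)
    }
  })
  do.call(rbind, rows)
}
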