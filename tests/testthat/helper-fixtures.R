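## Shared fixture builders for the test suite.

## Anchored synthetic problem: embeddings and prompt embeddings share class
## prototypes, so the optimal classifier is known analytically.
anchoredFixture <- function(C = 4, D = 16, M = 3, K = 2, noise = 0,
                            seed = 11, perClass = NULL) {
  spec <- syntheticSpec(C, K, D, promptsPerClass = M, noiseScale = noise,
                        seed = seed)
  protos <- makeClassPrototypes(spec)
  pool <- makeSyntheticEmbeddings(spec, protos,
                                  perClass = if (is.null(perClass)) K else perClass)
  XList <- makeSyntheticPromptEmbeddings(spec, protos)
  W <- buildClassifierWeights(XList, classNames(pool))
  list(spec = spec, protos = protos, pool = pool, XList = XList, W = W)
}

## Random problem instance for oracle-equivalence sweeps; nothing anchored.
randomInstance <- function(seed) {
  set.seed(seed)
  C <- sample(2:4, 1); K <- sample(1:3, 1); D <- sample(4:16, 1)
  E <- sample(1:min(8, D), 1); M <- sample(1:4, 1)
  XList <- lapply(seq_len(C), function(i) {
    m <- matrix(rnorm(M * D), nrow = M)
    m / sqrt(rowSums(m^2))
  })
  W <- buildClassifierWeights(XList)
  feats <- matrix(rnorm(C * K * D), nrow = C * K)
  feats <- feats / sqrt(rowSums(feats^2))
  train <- labeledEmbeddingSet(feats, rep(seq_len(C), each = K),
                               sprintf("class%02d", seq_len(C)))
  cache <- buildCache(train, K)
  mask <- refineChannels(W, E)
  params <- trilateralParams(alpha = runif(1, 0.1, 3),
                             beta = runif(1, 1, 8),
                             gamma = runif(1, -0.5, 0.5),
                             logitScale = runif(1, 0.5, 2))
  f <- rnorm(D); f <- f / sqrt(sum(f^2))
  H <- max(1L, D %/% 4L)
  W1 <- matrix(rnorm(H * D, sd = 1 / sqrt(D)), nrow = H)
  W2 <- matrix(rnorm(D * H, sd = 0.5), nrow = D)
  Res <- matrix(rnorm(C * E, sd = 0.1), nrow = C)
  scores <- exp(rnorm(C * K, sd = 0.3))
  list(C = C, K = K, D = D, E = E, M = M, XList = XList, W = W,
       cache = cache, mask = mask, params = params, f = f,
       W1 = W1, W2 = W2, Res = Res, scores = scores)
}

## Toy image set with two planted sub-clusters inside each class: the pools
## of generator classes (2c-1, 2c) are merged into observed class c.
subClusteredImages <- function(nSuper = 2, perSub = 3, seed = 5) {
  raw <- makeSyntheticImages(2 * nSuper, perSub, seed = seed, noise = 4)
  list(images = raw$images,
       labels = ((raw$labels - 1L) %/% 2L) + 1L,
       subLabels = raw$labels,
       classNames = sprintf("super%02d", seq_len(nSuper)))
}
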