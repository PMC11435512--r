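test_that("class prototypes are unit, distinct and deterministic", {
  spec <- syntheticSpec(4, 1, 4, seed = 1)
  P <- makeClassPrototypes(spec)
  expect_equal(dim(P), c(4L, 4L))
  expect_true(all(abs(sqrt(rowSums(P^2)) - 1) < 1e-6))
  # exhaustive pairwise dot products
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(oracleDot(P[i, ], P[j, ]), 1 - 1e-6)
  }
  spec2 <- syntheticSpec(3, 1, 8, seed = 7)
  expect_identical(makeClassPrototypes(spec2), makeClassPrototypes(spec2))
  P2 <- makeClassPrototypes(syntheticSpec(2, 1, 2, seed = 0))
  expect_false(isTRUE(all.equal(P2[1, ], P2[2, ])))
  expect_error(syntheticSpec(1, 1, 4), "nClasses")
})

test_that("prototypes stay distinct when C exceeds D", {
  P <- makeClassPrototypes(syntheticSpec(7, 1, 3, seed = 2))
  G <- P %*% t(P); diag(G) <- 0
  expect_lt(max(G), 1 - 1e-6)
})

test_that("synthetic embeddings honour the noise model and ordering", {
  spec0 <- syntheticSpec(3, 4, 8, noiseScale = 0, seed = 3)
  P <- makeClassPrototypes(spec0)
  setz <- makeSyntheticEmbeddings(spec0, P)
  expect_equal(embeddingLabels(setz), rep(1:3, each = 4))  # class-major
  for (i in seq_len(nrow(embeddings(setz)))) {
    expect_equal(embeddings(setz)[i, ], P[embeddingLabels(setz)[i], ],
                 tolerance = 1e-12)
  }
  specN <- syntheticSpec(3, 50, 16, noiseScale = 0.1, seed = 3)
  PN <- makeClassPrototypes(specN)
  sN <- makeSyntheticEmbeddings(specN, PN)
  expect_true(all(abs(sqrt(rowSums(embeddings(sN)^2)) - 1) < 1e-6))
  # exhaustive pairwise cosines: within-class mean must beat between-class
  F <- embeddings(sN); lab <- embeddingLabels(sN)
  wi <- c(); be <- c()
  for (i in seq_len(nrow(F) - 1)) for (j in (i + 1):nrow(F)) {
    cs <- oracleDot(F[i, ], F[j, ])
    if (lab[i] == lab[j]) wi <- c(wi, cs) else be <- c(be, cs)
  }
  expect_gt(mean(wi), mean(be))
})

test_that("prompt embeddings sit around their class prototype", {
  spec <- syntheticSpec(3, 1, 8, promptsPerClass = 3, noiseScale = 0, seed = 4)
  P <- makeClassPrototypes(spec)
  X <- makeSyntheticPromptEmbeddings(spec, P)
  for (c in 1:3) for (m in 1:3) {
    expect_equal(X[[c]][m, ], P[c, ], tolerance = 1e-12)
  }
  spec1 <- syntheticSpec(2, 1, 8, promptsPerClass = 1, noiseScale = 0.2, seed = 4)
  P1 <- makeClassPrototypes(spec1)
  X1 <- makeSyntheticPromptEmbeddings(spec1, P1)
  expect_equal(dim(X1[[1]]), c(1L, 8L))
  expect_equal(sqrt(sum(X1[[1]]^2)), 1, tolerance = 1e-6)
  # exhaustive cosine dominance at small noise
  spec05 <- syntheticSpec(4, 1, 16, promptsPerClass = 5, noiseScale = 0.05,
                          seed = 9)
  P05 <- makeClassPrototypes(spec05)
  X05 <- makeSyntheticPromptEmbeddings(spec05, P05)
  for (c in 1:4) {
    own <- mean(vapply(1:5, function(m) oracleDot(X05[[c]][m, ], P05[c, ]),
                       numeric(1)))
    for (o in setdiff(1:4, c)) {
      other <- mean(vapply(1:5, function(m) oracleDot(X05[[c]][m, ], P05[o, ]),
                           numeric(1)))
      expect_gt(own, other)
    }
  }
})

test_that("toy images have exact class colors, distinct textures, and are deterministic", {
  imgs <- makeSyntheticImages(2, 1, size = c(32, 32), seed = 1, noise = 0,
                              periods = c(2, 8))
  base <- vlcache:::.syntheticPalette(2)
  for (c in 1:2) {
    expect_equal(unname(computeColorFeatures(imgs$images[[c]])),
                 unname(base[c, ]), tolerance = 1e-12)
  }
  # GLCM contrast at distance 1, 0 deg differs between stripe periods,
  # verified by direct co-occurrence counting
  con <- vapply(1:2, function(c) {
    q <- vlcache:::.grayQuantize(imgs$images[[c]], 8L)
    oracleGlcm(q, 8L, dx = 1L, dy = 0L)[["contrast"]]
  }, numeric(1))
  expect_gt(abs(con[1] - con[2]), 1e-8)
  a <- makeSyntheticImages(3, 2, seed = 42)
  b <- makeSyntheticImages(3, 2, seed = 42)
  expect_identical(a, b)
})

test_that("mock encoder is deterministic, unit-norm and anchorable", {
  be <- mockEncoderBackend(8)
  v1 <- be@encodeText("a tomato leaf")
  v2 <- be@encodeText("a tomato leaf")
  expect_identical(v1, v2)
  expect_equal(sqrt(sum(v1^2)), 1, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(v1, be@encodeText("a grape leaf"))))
  expect_error(be@encodeText(""), "empty")
  P <- makeClassPrototypes(syntheticSpec(3, 1, 8, seed = 2))
  anc <- mockEncoderBackend(prototypes = P,
                            classNames = c("apple scab", "rust", "healthy"),
                            noiseScale = 0)
  expect_equal(anc@encodeText("A rust leaf with spots."), P[2, ],
               tolerance = 1e-12)
  img <- makeSyntheticImages(2, 1, seed = 1)$images[[1]]
  expect_equal(anc@encodeImage(img), P[1, ], tolerance = 1e-12)
})

test_that("noise -> 0 gives perfect nearest-prototype separability", {
  spec <- syntheticSpec(5, 10, 16, noiseScale = 0, seed = 6)
  P <- makeClassPrototypes(spec)
  s <- makeSyntheticEmbeddings(spec, P)
  pred <- apply(embeddings(s) %*% t(P), 1, which.max)
  expect_equal(pred, embeddingLabels(s))
})
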