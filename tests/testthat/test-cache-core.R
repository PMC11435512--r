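test_that("cache construction is class-major with one-hot values", {
  fx <- anchoredFixture(C = 2, D = 8, M = 2, K = 1, noise = 0, seed = 1)
  cache <- buildCache(fx$pool, 1)
  expect_equal(dim(cacheKeys(cache)), c(2L, 8L))
  expect_equal(cacheValues(cache), diag(2))
  expect_true(all(rowSums(cacheValues(cache)) == 1))

  # K=2 selection from a larger pool matches a per-class head-selection loop
  fx3 <- anchoredFixture(C = 3, D = 8, M = 2, K = 2, noise = 0.2, seed = 2,
                         perClass = 5)
  cache3 <- buildCache(fx3$pool, 2)
  F <- embeddings(fx3$pool); lab <- embeddingLabels(fx3$pool)
  want <- NULL
  for (c in 1:3) {
    idx <- which(lab == c)[1:2]
    want <- rbind(want, F[idx, ])
  }
  expect_identical(cacheKeys(cache3), want)
  expect_error(buildCache(fx3$pool, 9), "class01")
})

test_that("zero-shot logits are scaled cosine similarities", {
  f <- c(0, 1, 0)
  expect_equal(as.numeric(zeroShotLogits(f, diag(3))), c(0, 1, 0))
  expect_equal(which.max(zeroShotLogits(f, diag(3))), 2L)
  set.seed(3)
  W <- l2normalize(matrix(rnorm(3 * 8), 3))
  fr <- l2normalize(rnorm(8))
  lg <- zeroShotLogits(fr, W, logitScale = 2.5)
  expect_true(all(abs(lg) <= 2.5 + 1e-12))
  expect_equal(as.numeric(lg), oracleZeroShot(fr, W, 2.5), tolerance = 1e-12)
  expect_error(zeroShotLogits(fr[1:5], W), "mismatch")
})

test_that("channel refinement ranks by inter-class dispersion", {
  # rows differing only on channel 3: E=1 must pick it
  W <- matrix(0.5, 3, 4); W[, 3] <- c(-1, 0, 1)
  expect_equal(maskIndices(refineChannels(W, 1)), 3L)
  sc <- oracleDispersion(W)
  expect_equal(which.max(sc), 3L)

  set.seed(4)
  Wr <- l2normalize(matrix(rnorm(4 * 12), 4))
  for (E in c(1, 5, 12)) {
    got <- maskIndices(refineChannels(Wr, E))
    want <- sort(order(-oracleDispersion(Wr), seq_len(12))[seq_len(E)])
    expect_equal(got, as.integer(want))
  }
  expect_error(refineChannels(Wr, 13), "E")
})

test_that("a full mask leaves downstream logits unchanged", {
  fx <- anchoredFixture(C = 3, D = 8, M = 2, K = 2, noise = 0.2, seed = 5)
  cache <- buildCache(fx$pool, 2)
  full <- refineChannels(fx$W, 8)
  expect_equal(maskIndices(full), 1:8)
  p <- trilateralParams(alpha = 1.3, beta = 4, gamma = 0.2)
  f <- embeddings(fx$pool)
  # masked views with the full mask are the originals (rows already unit)
  expect_equal(maskEmbeddings(cacheKeys(cache), full), cacheKeys(cache),
               tolerance = 1e-12)
  lg <- vlcdLogits(f, fx$W, cache, full, p)
  W <- weightMatrix(fx$W)
  aff <- cacheAffinity(f, cacheKeys(cache), 4)
  sc <- cacheScores(cacheKeys(cache), W, cacheValues(cache), 0.2)
  want <- zeroShotLogits(f, W) + 1.3 * aff %*% (sc * cacheValues(cache))
  expect_equal(lg, want, tolerance = 1e-12)
})

test_that("cache affinity has the exponential closed form and bounds", {
  v <- l2normalize(c(1, 1, 0, 0))
  FM <- unname(rbind(v, l2normalize(c(0, 0, 1, 1))))
  aff <- unname(cacheAffinity(v, FM, beta = 3))
  expect_equal(aff[1, 1], 1)            # identical row: exp(0)
  expect_equal(aff[1, 2], exp(-3))      # orthogonal row: exp(-beta)
  set.seed(6)
  FM2 <- l2normalize(matrix(rnorm(6 * 4), 6))
  f2 <- l2normalize(rnorm(4))
  got <- cacheAffinity(f2, FM2, 5.5)
  expect_equal(as.numeric(got), oracleAffinityRow(f2, FM2, 5.5),
               tolerance = 1e-12)
  expect_true(all(got >= exp(-2 * 5.5) - 1e-12 & got <= 1 + 1e-12))
  expect_error(cacheAffinity(f2, FM2, 0), "beta")
})

test_that("KL cache scores reduce and match the scalar loop", {
  set.seed(7)
  Fm <- l2normalize(matrix(rnorm(6 * 5), 6))
  Wm <- l2normalize(matrix(rnorm(3 * 5), 3))
  L <- matrix(0, 6, 3); L[cbind(1:6, rep(1:3, each = 2))] <- 1
  expect_equal(cacheScores(Fm, Wm, L, gamma = 0), rep(1, 6))
  got <- cacheScores(Fm, Wm, L, gamma = 0.7)
  expect_equal(got, oracleCacheScores(Fm, Wm, L, 0.7), tolerance = 1e-10)
  # when the prediction already equals the smoothed one-hot, the score is 1
  Lrow <- matrix(c(1, 0, 0), 1)
  Wid <- diag(3)
  Fsharp <- matrix(c(1, 0, 0), 1)
  s <- cacheScores(Fsharp, Wid, Lrow, gamma = 1, logitScale = 60)
  expect_equal(s, 1, tolerance = 1e-4)
  expect_error(cacheScores(Fm, Wm, L, gamma = 1e6), "gamma")
})

test_that("trilateral logits reduce, separate and match the scalar oracle", {
  fx <- anchoredFixture(C = 4, D = 16, M = 3, K = 2, noise = 0, seed = 8)
  cache <- buildCache(fx$pool, 2)
  mask <- refineChannels(fx$W, 8)
  # alpha = 0: exact zero-shot reduction
  p0 <- trilateralParams(alpha = 0)
  expect_identical(vlcdLogits(embeddings(fx$pool), fx$W, cache, mask, p0),
                   zeroShotLogits(embeddings(fx$pool), weightMatrix(fx$W)))
  # noise-0 fixture: every prototype classifies to its own class
  p <- trilateralParams(alpha = 1, beta = 5.5, gamma = 0.1)
  lg <- vlcdLogits(fx$protos, fx$W, cache, mask, p)
  expect_equal(unname(apply(lg, 1, which.max)), 1:4)

  for (seed in 1:6) {
    inst <- randomInstance(seed + 100)
    got <- vlcdLogits(inst$f, inst$W, inst$cache, inst$mask, inst$params)
    want <- oracleVlcdLogits(inst$f, weightMatrix(inst$W),
                             cacheKeys(inst$cache), cacheValues(inst$cache),
                             maskIndices(inst$mask), inst$params@alpha,
                             inst$params@beta, inst$params@gamma,
                             inst$params@logitScale)
    expect_equal(as.numeric(got), want, tolerance = 1e-10)
  }
})

test_that("the unrefined cache baseline reduces and matches its oracle", {
  fx <- anchoredFixture(C = 3, D = 8, M = 2, K = 1, noise = 0, seed = 9)
  cache <- buildCache(fx$pool, 1)
  p0 <- trilateralParams(alpha = 0)
  expect_identical(tipAdapterLogits(fx$protos, fx$W, cache, p0),
                   zeroShotLogits(fx$protos, weightMatrix(fx$W)))
  p <- trilateralParams(alpha = 2, beta = 5)
  lg <- tipAdapterLogits(fx$protos, fx$W, cache, p)
  expect_equal(unname(apply(lg, 1, which.max)), 1:3)
  for (seed in 1:4) {
    inst <- randomInstance(seed + 200)
    got <- tipAdapterLogits(inst$f, inst$W, inst$cache, inst$params)
    want <- oracleTipLogits(inst$f, weightMatrix(inst$W),
                            cacheKeys(inst$cache), cacheValues(inst$cache),
                            inst$params@alpha, inst$params@beta,
                            inst$params@logitScale)
    expect_equal(as.numeric(got), want, tolerance = 1e-12)
  }
})

test_that("the cache contribution grows linearly in alpha", {
  inst <- randomInstance(300)
  base <- vlcdLogits(inst$f, inst$W, inst$cache, inst$mask,
                     trilateralParams(0, inst$params@beta, inst$params@gamma,
                                      inst$params@logitScale))
  l1 <- vlcdLogits(inst$f, inst$W, inst$cache, inst$mask,
                   trilateralParams(1, inst$params@beta, inst$params@gamma,
                                    inst$params@logitScale))
  l2 <- vlcdLogits(inst$f, inst$W, inst$cache, inst$mask,
                   trilateralParams(2, inst$params@beta, inst$params@gamma,
                                    inst$params@logitScale))
  contrib <- l1 - base
  expect_true(all(contrib > 0))  # affinities and scores are positive
  expect_equal(l2 - base, 2 * contrib, tolerance = 1e-12)
})
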