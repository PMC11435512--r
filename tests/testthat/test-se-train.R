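test_that("the SE gate scales channels by sigmoid weights in (0,1)", {
  set.seed(1)
  W <- l2normalize(matrix(rnorm(3 * 8), 3))
  se <- seModule(8, r = 4, seed = 1)  # W2 = 0 at init
  Watt <- seForward(W, se)
  expect_equal(unclass(Watt)[1:3, ], 0.5 * W, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(Watt, "lambda"), rep(0.5, 8))
  # uniform positive scaling preserves every argmax
  f <- l2normalize(rnorm(8))
  expect_equal(which.max(zeroShotLogits(f, Watt)),
               which.max(zeroShotLogits(f, W)))

  se@W2 <- matrix(rnorm(8 * 2), 8)
  Watt2 <- seForward(W, se)
  lam <- attr(Watt2, "lambda")
  expect_true(all(lam > 0 & lam < 1))
  # scalar loop: pool, two matvecs, sigmoid, scale (D=4, r=2)
  W4 <- l2normalize(matrix(rnorm(2 * 4), 2))
  se4 <- seModule(4, r = 2, seed = 3)
  se4@W2 <- matrix(rnorm(4 * 2), 4)
  o <- oracleSEForward(W4, se4@W1, se4@W2)
  g <- seForward(W4, se4)
  expect_equal(attr(g, "lambda"), o$lambda, tolerance = 1e-12)
  expect_equal(unclass(g)[1:2, ], o$Watt, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a too-aggressive reduction ratio clamps the hidden width", {
  expect_warning(se <- seModule(8, r = 32, seed = 1), "clamping")
  expect_equal(nrow(se@W1), 1L)
})

test_that("residual padding places columns at the masked channels", {
  mask <- new("ChannelMask", indices = c(2L, 4L), dim = 4L)
  Watt <- matrix(0, 2, 4)
  Res <- rbind(c(5, 7), c(-1, 2))
  out <- applyResidualsText(Watt, Res, mask)
  expect_equal(out, rbind(c(0, 5, 0, 7), c(0, -1, 0, 2)))
  set.seed(4)
  W <- matrix(rnorm(3 * 6), 3)
  m6 <- new("ChannelMask", indices = c(1L, 3L, 6L), dim = 6L)
  R <- matrix(rnorm(9), 3)
  expect_equal(applyResidualsText(W, R, m6),
               oraclePadResiduals(W, R, c(1, 3, 6)), tolerance = 1e-15)
  expect_equal(applyResidualsText(W, matrix(0, 3, 3), m6), W,
               ignore_attr = TRUE)
  expect_error(applyResidualsText(W, R[, 1:2], m6), "inconsistent")
})

test_that("residual expansion broadcasts class rows onto the cache blocks", {
  Fm <- matrix(1, 4, 3)
  Res <- rbind(c(1, 2, 3), c(10, 20, 30))
  out <- applyResidualsCache(Fm, Res)
  expect_equal(out[1, ], c(2, 3, 4))
  expect_equal(out[2, ], c(2, 3, 4))
  expect_equal(out[3, ], c(11, 21, 31))
  expect_equal(out[4, ], c(11, 21, 31))
  expect_equal(oracleExpandResiduals(Fm, Res), out)
  expect_equal(applyResidualsCache(out, -Res), Fm, tolerance = 1e-15)
  expect_equal(applyResidualsCache(Fm, matrix(0, 2, 3)), Fm)
  expect_error(applyResidualsCache(matrix(1, 5, 3), Res), "multiple")
})

test_that("training-branch logits agree with the scalar oracle", {
  for (seed in 1:4) {
    inst <- randomInstance(seed + 400)
    se <- seModule(inst$D, r = 4, seed = seed)
    se@W1 <- inst$W1[seq_len(nrow(se@W1)), , drop = FALSE]
    se@W2 <- inst$W2[, seq_len(ncol(se@W2)), drop = FALSE]
    state <- new("TrainState", residuals = inst$Res,
                 cacheScores = inst$scores, se = se, useSE = TRUE,
                 epoch = 0L, seed = 1L)
    got <- vlcdtLogits(inst$f, inst$W, state, inst$cache, inst$mask,
                       inst$params)
    want <- oracleVlcdtLogits(inst$f, weightMatrix(inst$W),
                              cacheKeys(inst$cache),
                              cacheValues(inst$cache),
                              maskIndices(inst$mask), inst$Res, inst$scores,
                              se@W1, se@W2, inst$params@alpha,
                              inst$params@beta, inst$params@logitScale)
    expect_equal(as.numeric(got), want, tolerance = 1e-10)
  }
})

test_that("a fresh state reproduces the training-free decisions", {
  fx <- anchoredFixture(C = 4, D = 16, M = 3, K = 3, noise = 0.15, seed = 20,
                        perClass = 8)
  cache <- buildCache(fx$pool, 3)
  mask <- refineChannels(fx$W, 8)
  p <- trilateralParams(alpha = 1, beta = 5.5, gamma = 0.1)
  st <- newTrainState(fx$W, cache, mask, p, r = 4, seed = 2)
  expect_true(all(st@residuals == 0))
  expect_equal(st@cacheScores,
               cacheScores(maskEmbeddings(cacheKeys(cache), mask),
                           maskEmbeddings(weightMatrix(fx$W), mask),
                           cacheValues(cache), 0.1))
  ltrain <- vlcdtLogits(embeddings(fx$pool), fx$W, st, cache, mask, p)
  lfree <- vlcdLogits(embeddings(fx$pool), fx$W, cache, mask, p)
  expect_equal(unname(apply(ltrain, 1, which.max)),
               unname(apply(lfree, 1, which.max)))
  # alpha = 0 with zero residuals and W2 = 0: zero-shot decisions
  p0 <- trilateralParams(alpha = 0)
  st0 <- newTrainState(fx$W, cache, mask, p0, r = 4, seed = 2)
  l0 <- vlcdtLogits(embeddings(fx$pool), fx$W, st0, cache, mask, p0)
  expect_equal(unname(apply(l0, 1, which.max)),
               unname(apply(zeroShotLogits(embeddings(fx$pool),
                                           weightMatrix(fx$W)), 1,
                            which.max)))
})

test_that("analytic gradients match finite differences", {
  inst <- randomInstance(500)
  se <- seModule(inst$D, r = 4, seed = 5)
  se@W2 <- matrix(rnorm(length(se@W2), sd = 0.3), nrow(se@W2))
  state <- new("TrainState", residuals = inst$Res,
               cacheScores = inst$scores, se = se, useSE = TRUE,
               epoch = 0L, seed = 1L)
  X <- rbind(inst$f, l2normalize(rnorm(inst$D)))
  y <- c(1L, min(2L, inst$C))
  W <- weightMatrix(inst$W)
  lossAt <- function(st) {
    lg <- vlcdtLogits(X, W, st, inst$cache, inst$mask, inst$params)
    P <- exp(lg - apply(lg, 1, max)); P <- P / rowSums(P)
    -mean(log(P[cbind(1:2, y)]))
  }
  g <- vlcache:::.vlcdtLossGrad(X, y, W, state, inst$cache, inst$mask,
                                inst$params)
  h <- 1e-6
  # a few entries of every parameter group
  for (ij in list(c(1, 1), c(inst$C, inst$E))) {
    st2 <- state; st2@residuals[ij[1], ij[2]] <- st2@residuals[ij[1], ij[2]] + h
    st3 <- state; st3@residuals[ij[1], ij[2]] <- st3@residuals[ij[1], ij[2]] - h
    expect_equal(g$gradRes[ij[1], ij[2]], (lossAt(st2) - lossAt(st3)) / (2 * h),
                 tolerance = 1e-4)
  }
  for (k in c(1L, length(state@cacheScores))) {
    st2 <- state; st2@cacheScores[k] <- st2@cacheScores[k] + h
    st3 <- state; st3@cacheScores[k] <- st3@cacheScores[k] - h
    expect_equal(g$gradScores[k], (lossAt(st2) - lossAt(st3)) / (2 * h),
                 tolerance = 1e-4)
  }
  st2 <- state; st2@se@W2[2, 1] <- st2@se@W2[2, 1] + h
  st3 <- state; st3@se@W2[2, 1] <- st3@se@W2[2, 1] - h
  expect_equal(g$gradW2[2, 1], (lossAt(st2) - lossAt(st3)) / (2 * h),
               tolerance = 1e-4)
  st2 <- state; st2@se@W1[1, 2] <- st2@se@W1[1, 2] + h
  st3 <- state; st3@se@W1[1, 2] <- st3@se@W1[1, 2] - h
  expect_equal(g$gradW1[1, 2], (lossAt(st2) - lossAt(st3)) / (2 * h),
               tolerance = 1e-4)
})

test_that("training is deterministic, freezes the cache and counts its parameters", {
  fx <- anchoredFixture(C = 4, D = 32, M = 3, K = 4, noise = 0.05, seed = 30)
  cache <- buildCache(fx$pool, 4)
  mask <- refineChannels(fx$W, 16)
  p <- trilateralParams(alpha = 1, beta = 5.5, gamma = 0.1)
  keys0 <- cacheKeys(cache); vals0 <- cacheValues(cache)

  # learning rate 0: parameters bit-identical to the initial state
  fit0 <- trainVLCDT(fx$pool, fx$W, cache, mask, p, epochs = 3, lr = 0,
                     r = 32, seed = 7)
  st0 <- newTrainState(fx$W, cache, mask, p, r = 32, seed = 7)
  expect_identical(fit0$state@residuals, st0@residuals)
  expect_identical(fit0$state@cacheScores, st0@cacheScores)
  expect_identical(fit0$state@se@W1, st0@se@W1)

  fitA <- trainVLCDT(fx$pool, fx$W, cache, mask, p, epochs = 5, seed = 7)
  fitB <- trainVLCDT(fx$pool, fx$W, cache, mask, p, epochs = 5, seed = 7)
  expect_identical(fitA$metrics, fitB$metrics)
  expect_identical(fitA$state@residuals, fitB$state@residuals)

  expect_identical(cacheKeys(cache), keys0)
  expect_identical(cacheValues(cache), vals0)

  # trainable scalars: C*E + CK + 2*D*floor(D/r)
  expect_equal(countTrainableParams(fitA$state),
               4L * 16L + 16L + 2L * 32L * 1L)
  fitNoSE <- trainVLCDT(fx$pool, fx$W, cache, mask, p, epochs = 2, seed = 7,
                        useSE = FALSE)
  expect_equal(countTrainableParams(fitNoSE$state), 4L * 16L + 16L)
  expect_no_error(trainVLCDT(fx$pool, fx$W, cache, mask, p, epochs = 0))
})

test_that("training converges on a separable anchored fixture", {
  fx <- anchoredFixture(C = 4, D = 32, M = 3, K = 4, noise = 0.05, seed = 31)
  cache <- buildCache(fx$pool, 4)
  mask <- refineChannels(fx$W, 16)
  p <- trilateralParams(alpha = 1, beta = 5.5, gamma = 0.1)
  fit <- trainVLCDT(fx$pool, fx$W, cache, mask, p, epochs = 30, r = 32,
                    seed = 3)
  m <- fit$metrics
  expect_lt(m$train_loss[30], m$train_loss[1])
  expect_equal(m$train_acc[30], 100)
})
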