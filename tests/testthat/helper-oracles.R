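## Independent scalar-loop oracles: every quantity is recomputed with plain
## for-loops and scalar accumulation, no matrix products, so the vectorized
## implementation is checked against genuinely independent arithmetic.

oracleNorm <- function(v) {
  acc <- 0
  for (x in v) acc <- acc + x * x
  sqrt(acc)
}

oracleUnit <- function(v) {
  n <- oracleNorm(v)
  out <- numeric(length(v))
  for (d in seq_along(v)) out[d] <- v[d] / n
  out
}

oracleDot <- function(a, b) {
  acc <- 0
  for (d in seq_along(a)) acc <- acc + a[d] * b[d]
  acc
}

oracleSoftmaxRow <- function(v) {
  m <- v[1L]
  for (x in v) if (x > m) m <- x
  e <- numeric(length(v)); s <- 0
  for (j in seq_along(v)) { e[j] <- exp(v[j] - m); s <- s + e[j] }
  for (j in seq_along(v)) e[j] <- e[j] / s
  e
}

## Cross-attention fusion intermediates for one class.
oracleAttention <- function(X, normalize = TRUE) {
  M <- nrow(X); D <- ncol(X)
  S <- matrix(0, M, M)
  for (i in seq_len(M)) for (j in seq_len(M)) S[i, j] <- oracleDot(X[i, ], X[j, ])
  A <- matrix(0, M, M)
  for (i in seq_len(M)) A[i, ] <- oracleSoftmaxRow(S[i, ])
  AW <- matrix(0, M, D)
  for (i in seq_len(M)) for (d in seq_len(D)) {
    acc <- 0
    for (j in seq_len(M)) acc <- acc + A[i, j] * X[j, d]
    AW[i, d] <- acc
  }
  a <- numeric(D)
  for (d in seq_len(D)) {
    acc <- 0
    for (i in seq_len(M)) acc <- acc + AW[i, d]
    a[d] <- acc / M
  }
  if (normalize) a <- oracleUnit(a)
  list(S = S, A = A, AW = AW, a = a)
}

oracleZeroShot <- function(f, W, s = 1) {
  C <- nrow(W)
  out <- numeric(C)
  for (c in seq_len(C)) out[c] <- s * oracleDot(f, W[c, ])
  out
}

oracleMaskRenorm <- function(v, idx) {
  m <- numeric(length(idx))
  for (j in seq_along(idx)) m[j] <- v[idx[j]]
  oracleUnit(m)
}

## Per-channel inter-class dispersion score.
oracleDispersion <- function(W) {
  C <- nrow(W); D <- ncol(W)
  s <- numeric(D)
  for (d in seq_len(D)) {
    acc <- 0
    for (i in seq_len(C)) for (j in seq_len(C)) {
      if (i != j) acc <- acc + (W[i, d] - W[j, d])^2
    }
    s[d] <- acc / (C * (C - 1))
  }
  s
}

oracleAffinityRow <- function(fm, Fm, beta) {
  CK <- nrow(Fm)
  out <- numeric(CK)
  for (k in seq_len(CK)) out[k] <- exp(-beta * (1 - oracleDot(fm, Fm[k, ])))
  out
}

oracleCacheScores <- function(Fm, Wm, L, gamma, s = 1, eps = 1e-6) {
  CK <- nrow(Fm); C <- nrow(Wm)
  out <- numeric(CK)
  for (k in seq_len(CK)) {
    z <- numeric(C)
    for (c in seq_len(C)) z[c] <- s * oracleDot(Fm[k, ], Wm[c, ])
    p <- oracleSoftmaxRow(z)
    d <- 0
    for (c in seq_len(C)) {
      q <- (L[k, c] + eps) / (1 + C * eps)
      d <- d + q * (log(q) - log(p[c]))
    }
    out[k] <- exp(gamma * d)
  }
  out
}

## Full training-free trilateral logits for one test vector.
oracleVlcdLogits <- function(f, W, Fkeys, L, maskIdx, alpha, beta, gamma,
                             s = 1) {
  C <- nrow(W); CK <- nrow(Fkeys)
  RfW <- oracleZeroShot(f, W, s)
  if (alpha == 0) return(RfW)
  fm <- oracleMaskRenorm(f, maskIdx)
  Fm <- matrix(0, CK, length(maskIdx))
  for (k in seq_len(CK)) Fm[k, ] <- oracleMaskRenorm(Fkeys[k, ], maskIdx)
  Wm <- matrix(0, C, length(maskIdx))
  for (c in seq_len(C)) Wm[c, ] <- oracleMaskRenorm(W[c, ], maskIdx)
  aff <- oracleAffinityRow(fm, Fm, beta)
  sc <- oracleCacheScores(Fm, Wm, L, gamma, s)
  out <- numeric(C)
  for (c in seq_len(C)) {
    acc <- 0
    for (k in seq_len(CK)) acc <- acc + aff[k] * sc[k] * L[k, c]
    out[c] <- RfW[c] + alpha * acc
  }
  out
}

oracleTipLogits <- function(f, W, Fkeys, L, alpha, beta, s = 1) {
  C <- nrow(W); CK <- nrow(Fkeys)
  RfW <- oracleZeroShot(f, W, s)
  out <- numeric(C)
  for (c in seq_len(C)) {
    acc <- 0
    for (k in seq_len(CK)) {
      acc <- acc + exp(-beta * (1 - oracleDot(f, Fkeys[k, ]))) * L[k, c]
    }
    out[c] <- RfW[c] + alpha * acc
  }
  out
}

## SE gate: pool, two matvecs, sigmoid, per-channel scale.
oracleSEForward <- function(W, W1, W2) {
  C <- nrow(W); D <- ncol(W); H <- nrow(W1)
  y <- numeric(D)
  for (d in seq_len(D)) {
    acc <- 0
    for (c in seq_len(C)) acc <- acc + W[c, d]
    y[d] <- acc / C
  }
  h <- numeric(H)
  for (i in seq_len(H)) {
    acc <- 0
    for (d in seq_len(D)) acc <- acc + W1[i, d] * y[d]
    h[i] <- max(acc, 0)
  }
  lambda <- numeric(D)
  for (d in seq_len(D)) {
    acc <- 0
    for (i in seq_len(H)) acc <- acc + W2[d, i] * h[i]
    lambda[d] <- 1 / (1 + exp(-acc))
  }
  Watt <- matrix(0, C, D)
  for (c in seq_len(C)) for (d in seq_len(D)) Watt[c, d] <- W[c, d] * lambda[d]
  list(lambda = lambda, Watt = Watt)
}

oraclePadResiduals <- function(Watt, Res, maskIdx) {
  out <- Watt
  for (c in seq_len(nrow(Res))) for (j in seq_along(maskIdx)) {
    out[c, maskIdx[j]] <- out[c, maskIdx[j]] + Res[c, j]
  }
  out
}

oracleExpandResiduals <- function(Fm, Res) {
  CK <- nrow(Fm); C <- nrow(Res); K <- CK %/% C
  out <- Fm
  for (k in seq_len(CK)) {
    c <- ((k - 1L) %/% K) + 1L
    for (j in seq_len(ncol(Fm))) out[k, j] <- out[k, j] + Res[c, j]
  }
  out
}

## Training-branch logits for one test vector.
oracleVlcdtLogits <- function(f, W, Fkeys, L, maskIdx, Res, scores, W1, W2,
                              alpha, beta, s = 1, useSE = TRUE) {
  C <- nrow(W); CK <- nrow(Fkeys)
  se <- if (useSE) oracleSEForward(W, W1, W2) else list(Watt = W)
  Weff <- oraclePadResiduals(se$Watt, Res, maskIdx)
  RfW <- oracleZeroShot(f, Weff, s)
  fm <- oracleMaskRenorm(f, maskIdx)
  Fm <- matrix(0, CK, length(maskIdx))
  for (k in seq_len(CK)) Fm[k, ] <- oracleMaskRenorm(Fkeys[k, ], maskIdx)
  Feff <- oracleExpandResiduals(Fm, Res)
  out <- numeric(C)
  for (c in seq_len(C)) {
    acc <- 0
    for (k in seq_len(CK)) {
      aff <- exp(-beta * (1 - oracleDot(fm, Feff[k, ])))
      acc <- acc + aff * scores[k] * L[k, c]
    }
    out[c] <- RfW[c] + alpha * acc
  }
  out
}

## Direct co-occurrence counting for GLCM verification (one offset).
oracleGlcm <- function(gray, levels, dx, dy) {
  H <- nrow(gray); W <- ncol(gray)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    r2 <- r + dy; c2 <- cc + dx
    if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W) {
      a <- gray[r, cc] + 1L; b <- gray[r2, c2] + 1L
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  P <- counts / sum(counts)
  contrast <- 0; energy <- 0; homog <- 0
  mu_i <- 0; mu_j <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels)) {
    contrast <- contrast + (i - j)^2 * P[i, j]
    energy <- energy + P[i, j]^2
    homog <- homog + P[i, j] / (1 + (i - j)^2)
    mu_i <- mu_i + (i - 1) * P[i, j]
    mu_j <- mu_j + (j - 1) * P[i, j]
  }
  v_i <- 0; v_j <- 0; cov <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels)) {
    v_i <- v_i + (i - 1 - mu_i)^2 * P[i, j]
    v_j <- v_j + (j - 1 - mu_j)^2 * P[i, j]
    cov <- cov + (i - 1 - mu_i) * (j - 1 - mu_j) * P[i, j]
  }
  correlation <- if (v_i < 1e-24 || v_j < 1e-24) 1 else
    cov / sqrt(v_i * v_j)
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homog)
}
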