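## Mean-color + GLCM texture features per image, and K-means selection of
## M representative images per class on the combined (z-scored) features.
## Color and texture are the stable, intuitive cues for leaf-disease imagery,
## which is why this cheap classical pipeline suffices to pick the images
## worth captioning.

#' Per-channel mean color of an 8-bit RGB image
#'
#' @param image H x W x 3 numeric array on the 0..255 scale.
#' @return Named numeric vector `c(r, g, b)` of channel means.
#' @examples
#' img <- array(c(255, 0, 0), dim = c(4, 4, 3))
#' @export
computeColorFeatures <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop("expected an H x W x 3 image array")
  }
  if (prod(dim(image)) == 0L) stop("empty image")
  c(r = mean(image[, , 1L]), g = mean(image[, , 2L]), b = mean(image[, , 3L]))
}

## ITU-R 601 luma, quantized to `levels` equal-width bins over 0..255.
.grayQuantize <- function(image, levels) {
  g <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
  q <- floor(g / 256 * levels)
  q[q >= levels] <- levels - 1L
  q  # values in 0..levels-1
}

## Symmetric, normalized gray-level co-occurrence matrix for one offset.
.glcmMatrix <- function(q, levels, dx, dy) {
  H <- nrow(q); W <- ncol(q)
  rows <- seq_len(H); cols <- seq_len(W)
  r2 <- rows + dy; c2 <- cols + dx
  keepR <- rows[r2 >= 1L & r2 <= H]; keepC <- cols[c2 >= 1L & c2 <= W]
  if (!length(keepR) || !length(keepC)) {
    stop("image smaller than the requested GLCM displacement")
  }
  a <- q[keepR, keepC, drop = FALSE]
  b <- q[keepR + dy, keepC + dx, drop = FALSE]
  counts <- matrix(0, levels, levels)
  tab <- table(factor(a, levels = 0:(levels - 1L)),
               factor(b, levels = 0:(levels - 1L)))
  counts <- counts + tab + t(tab)   # symmetric pairs
  counts / sum(counts)
}

.haralick <- function(P) {
  levels <- nrow(P)
  i <- matrix(0:(levels - 1L), levels, levels)
  j <- t(i)
  contrast <- sum((i - j)^2 * P)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + (i - j)^2))
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  correlation <- if (sd_i < 1e-12 || sd_j < 1e-12) {
    1  # constant image: degenerate 0/0, defined as perfectly correlated
  } else {
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
  }
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity)
}

#' GLCM texture features of an 8-bit RGB image
#'
#' Converts to ITU-R 601 luma, quantizes to `levels` gray levels, builds a
#' symmetric normalized co-occurrence matrix per (distance, angle), computes
#' contrast, correlation, energy and homogeneity, and averages each over the
#' angle set (and distances).
#'
#' @param image H x W x 3 numeric array on the 0..255 scale.
#' @param levels Number of gray levels (>= 2); default 8.
#' @param distances Integer pixel displacements; default 1.
#' @param angles Angles in degrees; default `c(0, 45, 90, 135)`.
#' @return Named numeric vector
#'   `c(contrast, correlation, energy, homogeneity)`.
#' @export
computeGlcmFeatures <- function(image, levels = 8L, distances = 1L,
                                angles = c(0, 45, 90, 135)) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop("expected an H x W x 3 image array")
  }
  if (levels < 2L) stop("levels must be >= 2")
  q <- .grayQuantize(image, as.integer(levels))
  if (min(dim(q)) <= max(distances)) {
    stop("image smaller than the maximum GLCM distance")
  }
  feats <- vapply(distances, function(d) {
    per <- vapply(angles, function(ang) {
      # image convention: x right (columns), y down (rows); 0 deg is
      # horizontal, 90 deg vertical
      rad <- ang * pi / 180
      dx <- as.integer(round(cos(rad))) * d
      dy <- as.integer(round(-sin(rad))) * d
      .haralick(.glcmMatrix(q, as.integer(levels), dx, dy))
    }, numeric(4))
    rowMeans(per)
  }, numeric(4))
  rowMeans(matrix(feats, nrow = 4L,
                  dimnames = list(c("contrast", "correlation", "energy",
                                    "homogeneity"), NULL)))
}

#' Combined color + texture feature table for a set of images
#'
#' @param images List of H x W x 3 arrays.
#' @param ... Passed to [computeGlcmFeatures()].
#' @return Data frame with columns r, g, b, contrast, correlation, energy,
#'   homogeneity; one row per image.
#' @export
imageFeatureTable <- function(images, ...) {
  rows <- lapply(images, function(im) {
    c(computeColorFeatures(im), computeGlcmFeatures(im, ...))
  })
  as.data.frame(do.call(rbind, rows))
}

## z-score columns, dropping zero-variance dimensions for this class.
.zscoreDrop <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  keep <- which(sdv > 1e-12)
  if (!length(keep)) return(matrix(0, nrow(X), 1L))
  scale(X[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
}

#' Select M representative images per class by K-means
#'
#' Within each class, the combined color/texture features are z-scored
#' (zero-variance dimensions dropped), clustered with K-means into
#' `k = min(M, class size)` clusters, and the image nearest each centroid
#' (Euclidean; ties broken by the lowest index) is returned. Classes with at
#' most M images are returned whole.
#'
#' @param features Matrix or data frame of per-image feature rows (e.g. from
#'   [imageFeatureTable()]).
#' @param labels Integer class label per row (1..C).
#' @param M Representatives per class.
#' @param seed Seed for the K-means initialization (10 restarts).
#' @return List of C integer vectors of row indices into `features`,
#'   ascending, no duplicates.
#' @export
selectRepresentatives <- function(features, labels, M, seed = 1L) {
  stopifnotScalarCount(M, "M", 1L)
  X <- as.matrix(features)
  labels <- as.integer(labels)
  C <- max(labels)
  if (!all(seq_len(C) %in% labels)) stop("empty class in representative selection")
  withSeed(subSeed(seed, "kmeans"), {
    lapply(seq_len(C), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) <= M) return(idx)
      Z <- .zscoreDrop(X[idx, , drop = FALSE])
      k <- min(M, nrow(unique(Z)))
      if (k < 2L) {
        # single cluster: the image nearest the class feature mean
        d2 <- rowSums((Z - rep(1, nrow(Z)) %o% colMeans(Z))^2)
        near <- idx[order(d2, idx)][1L]
        extra <- setdiff(idx, near)[seq_len(min(M, length(idx)) - 1L)]
        return(sort(c(near, extra[!is.na(extra)])))
      }
      km <- kmeans(Z, centers = k, nstart = 10L, iter.max = 100L)
      used <- integer(0)
      for (ctr in seq_len(k)) {
        d2 <- rowSums((Z - rep(1, nrow(Z)) %o% km$centers[ctr, ])^2)
        ord <- order(d2, idx)  # lowest index at equal distance
        cand <- setdiff(idx[ord], used)
        used <- c(used, cand[1L])
      }
      # distinct-representative count may fall short of M when feature rows
      # repeat; top up with the lowest unused indices
      if (length(used) < M) {
        used <- c(used, setdiff(idx, used)[seq_len(M - length(used))])
      }
      sort(used)
    })
  })
}
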