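#' @importFrom stats rnorm runif kmeans sd setNames
#' @importFrom methods new validObject is slot
#' @importFrom utils head write.csv read.csv read.table
NULL

## Internal numeric helpers shared across modules.

.UNIT_TOL <- 1e-6

#' Normalize vectors or matrix rows to unit L2 length
#'
#' Embedding geometry throughout the package assumes unit-norm rows, so every
#' producer funnels through this helper.
#'
#' @param x A numeric vector or matrix (rows are normalized).
#' @return Object of the same shape with unit L2 rows.
#' @examples
#' l2normalize(c(3, 4))
#' @export
l2normalize <- function(x) {
  if (is.matrix(x)) {
    n <- sqrt(rowSums(x^2))
    if (any(n < 1e-12)) {
      stop("cannot normalize: row(s) ", paste(which(n < 1e-12), collapse = ", "),
           " have (near-)zero norm")
    }
    x / n
  } else {
    n <- sqrt(sum(x^2))
    if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
    x / n
  }
}

## Row-wise softmax, numerically stabilised.
softmaxRows <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

## Evaluate `expr` under a fixed RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Deterministic content hash onto [0, 2^31 - 2]; used to seed the mock
## encoder/captioner. Polynomial rolling hash over the flattened content,
## computed in doubles (exact: intermediate values stay far below 2^53).
hashContent <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L || !nzchar(trimws(x))) {
      stop("mock hash input must be one non-empty string")
    }
    vals <- utf8ToInt(x)
  } else if (is.numeric(x) || is.array(x)) {
    vals <- as.numeric(x)
    if (length(vals) == 0L) stop("mock hash input must be non-empty")
    vals <- round(vals * 8) %% 4096
  } else {
    stop("unsupported input type for content hash")
  }
  p <- 2147483629
  h <- 17
  # fold in position-weighted moments rather than looping over every element
  idx <- seq_along(vals)
  h <- (h * 31 + sum(vals) %% p) %% p
  h <- (h * 31 + sum(vals * (idx %% 64)) %% p) %% p
  h <- (h * 31 + sum(vals^2 %% 97) %% p) %% p
  h <- (h * 31 + length(vals)) %% p
  as.integer(h)
}

## Derive a reproducible sub-seed from a base seed and a stream label.
subSeed <- function(seed, label) {
  (as.integer(seed) %% 100000L) * 10007L %% 2147483629L +
    hashContent(paste0("stream:", label)) %% 99991L
}

## argmax with lowest-index tie-break (which.max's contract, made explicit).
argmaxRows <- function(logits) {
  if (!is.matrix(logits)) logits <- matrix(logits, nrow = 1L)
  apply(logits, 1L, which.max)
}

stopifnotScalarCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x)) {
    stop(name, " must be a single integer >= ", min)
  }
}
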