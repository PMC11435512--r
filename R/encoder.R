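## Batch encoding through an EncoderBackend. The wrapper renormalizes
## defensively so the cosine-geometry assumptions of the cache math hold for
## any backend honouring the contract approximately.

#' Encode a batch of images
#'
#' @param backend An [EncoderBackend-class].
#' @param images List of image arrays.
#' @return N x D matrix of unit rows, row order matching the input.
#' @export
encodeImageBatch <- function(backend, images) {
  stopifnot(is(backend, "EncoderBackend"))
  if (!length(images)) stop("empty image batch")
  rows <- lapply(seq_along(images), function(i) {
    v <- tryCatch(backend@encodeImage(images[[i]]), error = function(e) {
      stop("backend failed on image ", i, ": ", conditionMessage(e))
    })
    if (length(v) != backend@dim) {
      stop("backend returned wrong dimension for image ", i)
    }
    v
  })
  l2normalize(do.call(rbind, rows))
}

#' Encode every prompt of a prompt bank
#'
#' @param backend An [EncoderBackend-class].
#' @param bank A [PromptBank-class].
#' @return List of C matrices, each M x D with unit rows; row j of matrix i
#'   encodes prompt j of class i.
#' @export
encodePromptBank <- function(backend, bank) {
  stopifnot(is(backend, "EncoderBackend"), is(bank, "PromptBank"))
  validObject(bank)
  lapply(seq_along(bank@classNames), function(i) {
    rows <- lapply(seq_along(bank@prompts[[i]]), function(j) {
      v <- tryCatch(backend@encodeText(bank@prompts[[i]][j]),
                    error = function(e) {
        stop(sprintf("backend failed on class '%s' prompt %d: %s",
                     bank@classNames[i], j, conditionMessage(e)))
      })
      if (length(v) != backend@dim) {
        stop(sprintf("backend returned wrong dimension for class '%s' prompt %d",
                     bank@classNames[i], j))
      }
      v
    })
    l2normalize(do.call(rbind, rows))
  })
}
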