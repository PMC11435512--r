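## Prompt bank: per-class query construction, captioning of representative
## images through a pluggable backend, and JSON round-tripping. The shipped
## captioner is a deterministic mock that summarizes the image's measured
## color/texture so downstream fusion sees class-correlated text offline;
## a live vision-language captioner can be dropped in behind the same
## function contract.

#' Build the per-class captioning query
#'
#' Substitutes the class name into the fixed query template used to elicit a
#' leaf description from a vision-language captioner.
#'
#' @param className Non-empty class name string.
#' @return The query string.
#' @examples
#' buildQuery("grape leaf blight")
#' @export
buildQuery <- function(className) {
  if (!is.character(className) || length(className) != 1L ||
      !nzchar(trimws(className))) {
    stop("class name must be a non-empty string")
  }
  sprintf("Can you help me describe this %s leaf?", className)
}

#' Deterministic mock captioner
#'
#' Returns a captioner `function(image, query)` that emits a sentence
#' embedding the class name (parsed from the query) together with a
#' quantized summary of the image's mean color and GLCM contrast, so the
#' generated text is correlated with the image's class without any external
#' model.
#'
#' @return A captioner function.
#' @export
mockCaptioner <- function() {
  function(image, query) {
    cls <- sub("^Can you help me describe this (.*) leaf\\?$", "\\1", query)
    col <- round(computeColorFeatures(image))
    glcm <- computeGlcmFeatures(image)
    sprintf(paste0("A %s leaf with mean color (%d, %d, %d), ",
                   "texture contrast %.1f and homogeneity %.2f."),
            cls, col[1L], col[2L], col[3L], glcm[["contrast"]],
            glcm[["homogeneity"]])
  }
}

#' Generate a prompt bank from representative images
#'
#' Captions each class's representative images in order with
#' `captioner(image, buildQuery(className))`. If a class has fewer than M
#' representatives the captions are padded by cycling through the
#' representatives again; more than M are truncated. A captioner failure on
#' one image is recorded and the image skipped; a class whose every caption
#' fails is an error.
#'
#' @param captioner Function(image, query) -> string.
#' @param images List of image arrays (the full collection).
#' @param reps List of per-class integer indices into `images`, e.g. from
#'   [selectRepresentatives()].
#' @param classNames Character vector of class names.
#' @param M Prompts per class (default 10).
#' @return A [PromptBank-class].
#' @export
generatePrompts <- function(captioner, images, reps, classNames, M = 10L) {
  stopifnotScalarCount(M, "M", 1L)
  C <- length(classNames)
  stopifnot(length(reps) == C)
  prompts <- vector("list", C)
  prov <- vector("list", C)
  for (i in seq_len(C)) {
    q <- buildQuery(classNames[i])
    caps <- character(0)
    for (idx in reps[[i]]) {
      cap <- tryCatch(captioner(images[[idx]], q), error = function(e) {
        warning(sprintf("captioner failed on class '%s' image %d: %s",
                        classNames[i], idx, conditionMessage(e)))
        NA_character_
      })
      if (!is.na(cap) && nzchar(trimws(cap))) caps <- c(caps, cap)
    }
    if (!length(caps)) {
      stop("no usable captions for class '", classNames[i], "'")
    }
    prompts[[i]] <- rep_len(caps, M)   # cycle to pad, truncate past M
    prov[[i]] <- rep("mock", M)
  }
  new("PromptBank", classNames = as.character(classNames),
      prompts = prompts, provenance = prov, M = as.integer(M))
}

#' Save / load a prompt bank as JSON
#'
#' The JSON schema is
#' `{"M": int, "classes": [{"name", "prompts", "provenance"}, ...]}`.
#' Loading validates the schema and reports the offending class by name;
#' classes whose prompt counts disagree with M are an error (normalize the
#' bank explicitly before saving).
#'
#' @param bank A [PromptBank-class].
#' @param path File path.
#' @return `savePromptBank` returns `path` invisibly; `loadPromptBank`
#'   returns the bank.
#' @export
savePromptBank <- function(bank, path) {
  validObject(bank)
  payload <- list(
    M = bank@M,
    classes = lapply(seq_along(bank@classNames), function(i) {
      list(name = bank@classNames[i], prompts = bank@prompts[[i]],
           provenance = bank@provenance[[i]])
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname savePromptBank
#' @export
loadPromptBank <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (is.null(payload$M) || is.null(payload$classes)) {
    stop("prompt bank JSON must contain 'M' and 'classes'")
  }
  M <- as.integer(payload$M)
  nms <- character(0); prompts <- list(); prov <- list()
  for (cls in payload$classes) {
    if (is.null(cls$name) || is.null(cls$prompts)) {
      stop("prompt bank entry missing 'name' or 'prompts'",
           if (!is.null(cls$name)) paste0(" for class '", cls$name, "'") else "")
    }
    p <- as.character(unlist(cls$prompts))
    if (length(p) != M) {
      stop(sprintf("class '%s' has %d prompts but bank declares M=%d",
                   cls$name, length(p), M))
    }
    nms <- c(nms, cls$name)
    prompts <- c(prompts, list(p))
    pv <- if (is.null(cls$provenance)) rep("user-supplied", M) else
      as.character(unlist(cls$provenance))
    prov <- c(prov, list(pv))
  }
  new("PromptBank", classNames = nms, prompts = prompts, provenance = prov,
      M = M)
}
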