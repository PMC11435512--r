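## Plain-text I/O: embedding matrices as TSV with a JSON sidecar, image
## collections as a directory-per-class tree of PNGs, channel masks and
## experiment configs as JSON. Everything round-trips losslessly and is
## byte-stable for identical inputs.

#' Save / load an embedding matrix (TSV + JSON sidecar)
#'
#' The matrix is written as a headerless tab-separated table at full double
#' precision (17 significant digits), with a `<path>.json` sidecar recording
#' shape, optional labels/class names and the producing backend.
#'
#' @param x Numeric matrix (rows are embeddings).
#' @param path Output TSV path; the sidecar is written at `<path>.json`.
#' @param labels Optional integer labels, one per row.
#' @param classNames Optional class names.
#' @param backend Optional backend name string.
#' @return `saveEmbeddings` returns `path` invisibly. `loadEmbeddings`
#'   returns the matrix with the sidecar fields attached as attributes
#'   (`labels`, `classNames`, `backend`).
#' @export
saveEmbeddings <- function(x, path, labels = NULL, classNames = NULL,
                           backend = NULL) {
  stopifnot(is.matrix(x))
  lines <- apply(x, 1L, function(r) paste(sprintf("%.17g", r),
                                          collapse = "\t"))
  writeLines(lines, path)
  side <- list(rows = nrow(x), cols = ncol(x))
  if (!is.null(labels)) side$labels <- as.integer(labels)
  if (!is.null(classNames)) side$classNames <- as.character(classNames)
  if (!is.null(backend)) side$backend <- backend
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveEmbeddings
#' @export
loadEmbeddings <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  x <- as.matrix(read.table(path, sep = "\t", header = FALSE,
                            colClasses = "numeric"))
  dimnames(x) <- NULL
  if (!identical(dim(x), c(as.integer(side$rows), as.integer(side$cols)))) {
    stop("embedding file shape disagrees with its sidecar")
  }
  attr(x, "labels") <- side$labels
  attr(x, "classNames") <- side$classNames
  attr(x, "backend") <- side$backend
  x
}

#' Write an image collection as a directory-per-class PNG tree
#'
#' @param images List of H x W x 3 arrays on the 0..255 scale.
#' @param labels Integer class label per image.
#' @param classNames Class names (become directory names).
#' @param dir Output directory.
#' @return Character vector of written file paths, invisibly.
#' @export
writeImageDir <- function(images, labels, classNames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(images))
  counter <- integer(length(classNames))
  for (i in seq_along(images)) {
    cl <- labels[i]
    counter[cl] <- counter[cl] + 1L
    sub <- file.path(dir, classNames[cl])
    dir.create(sub, showWarnings = FALSE)
    paths[i] <- file.path(sub, sprintf("img%04d.png", counter[cl]))
    png::writePNG(aperm(array(images[[i]] / 255, dim = dim(images[[i]])),
                        c(1, 2, 3)), paths[i])
  }
  invisible(paths)
}

#' Read a directory-per-class PNG tree
#'
#' Subdirectory names become class names (sorted); files within a class are
#' read in sorted order. Each image carries its `classIndex` attribute so
#' anchored mock backends can use it.
#'
#' @param dir Directory containing one subdirectory per class.
#' @return List with `images`, `labels`, `classNames`, `paths`.
#' @export
readImageDir <- function(dir) {
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stop("no class subdirectories under ", dir)
  images <- list(); labels <- integer(0); paths <- character(0)
  for (c in seq_along(classes)) {
    files <- sort(list.files(file.path(dir, classes[c]), pattern = "\\.png$",
                             full.names = TRUE))
    for (fp in files) {
      px <- png::readPNG(fp)
      if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
      img <- px[, , 1:3, drop = FALSE] * 255
      dim(img) <- c(dim(px)[1:2], 3L)
      attr(img, "classIndex") <- c
      images <- c(images, list(img))
      labels <- c(labels, c)
      paths <- c(paths, fp)
    }
  }
  list(images = images, labels = labels, classNames = classes, paths = paths)
}

#' Save / load a channel mask as JSON
#'
#' @param mask A [ChannelMask-class].
#' @param path JSON path.
#' @return `saveChannelMask` returns `path` invisibly; `loadChannelMask`
#'   returns the mask.
#' @export
saveChannelMask <- function(mask, path) {
  jsonlite::write_json(list(dim = mask@dim, indices = mask@indices), path,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname saveChannelMask
#' @export
loadChannelMask <- function(path) {
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ChannelMask", indices = as.integer(side$indices),
      dim = as.integer(side$dim))
}

#' Read an experiment config file (JSON)
#'
#' @param path JSON config path.
#' @return Named list suitable for [runExperiment()].
#' @export
readExperimentConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$shots)) cfg$shots <- as.integer(cfg$shots)
  cfg
}
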