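# Image, mask, weight-map and manifest I/O.
#
# Images are 8-bit RGB PNG or TIFF; masks and boundary maps are single-channel
# 8-bit PNG with {0, 255} encoding {0, 1}; weight maps are 32-bit float TIFF;
# the dataset manifest is a TSV with columns
# path_image, path_mask, path_boundary, split (paths relative to the manifest).

#' Read an RGB image
#'
#' Reads a PNG or TIFF image and returns an `H x W x 3` numeric array with
#' values in `[0, 1]`. Grayscale images are replicated across channels and an
#' alpha channel, if present, is dropped.
#'
#' @param path file path (`.png`, `.tif` or `.tiff`).
#' @return numeric array `H x W x 3`.
#' @export
read_image <- function(path) {
  x <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (is.matrix(x)) x <- array(rep(x, 3), c(dim(x), 3L))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 1) x <- array(rep(x, 3), c(dim(x)[1:2], 3L))
  x
}

#' Write an RGB image
#'
#' @param x numeric array `H x W x 3` in `[0, 1]`.
#' @param path output path; format chosen by extension (PNG or TIFF).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  x <- clamp(x, 0, 1)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(x, path, bits.per.sample = 8L)
  else png::writePNG(x, path)
  invisible(path)
}

#' Read a binary mask or boundary map
#'
#' Reads a single-channel PNG/TIFF whose pixel values 0/255 encode 0/1 and
#' returns an integer 0/1 matrix.
#'
#' @param path file path.
#' @return integer matrix of 0s and 1s.
#' @export
read_mask <- function(path) {
  x <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  m <- matrix(as.integer(x > 0.5), nrow(x), ncol(x))
  m
}

#' Write a binary mask or boundary map
#'
#' @param mask 0/1 matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stop_if_not_binary(mask, "mask")
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a weight map as 32-bit TIFF
#'
#' Static pixel-weight maps can exceed 1, so they are stored as 32-bit TIFF
#' samples normalized by the map's maximum, with the scale recorded on a
#' second one-pixel page; [read_weight_map()] restores the original values
#' (relative round-trip error below 1e-9).
#'
#' @param w numeric matrix of non-negative weights.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_weight_map <- function(w, path) {
  scale <- max(w, 1)
  # page 1: normalized map; page 2: 1x1 page holding 1/scale (weights are
  # always >= 1, so 1/scale lies in (0, 1])
  tiff::writeTIFF(list(w / scale, matrix(1 / scale, 1, 1)), path,
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a weight map written by [write_weight_map()]
#'
#' @param path `.tif` path.
#' @return numeric matrix.
#' @export
read_weight_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  x <- pages[[1]]
  scale <- if (length(pages) > 1) 1 / pages[[2]][1, 1] else 1
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.numeric(x), nrow(x), ncol(x)) * scale
}

#' Read a dataset manifest
#'
#' @param path path to a TSV manifest with columns `path_image`, `path_mask`,
#'   `path_boundary`, `split`; file paths are interpreted relative to the
#'   manifest's directory.
#' @return data frame with absolute paths and a `split` column.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("path_image", "path_mask", "path_boundary", "split")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (col in c("path_image", "path_mask", "path_boundary"))
    m[[col]] <- file.path(base, m[[col]])
  m
}

write_manifest <- function(m, path) {
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single-file archives holding a format version tag, the
#' model configuration and all parameter tensors.
#'
#' @param model a `myoseg_net` model (see [build_model()]).
#' @param path checkpoint path (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "myoseg_net"))
  saveRDS(list(version = "myoseg-checkpoint-1",
               config = model$config, par = model$par), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$version, "myoseg-checkpoint-1"))
    stop("not a myoseg checkpoint: ", path)
  structure(list(config = x$config, par = x$par), class = "myoseg_net")
}
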