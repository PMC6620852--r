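# Arbitrary-size and whole-slide prediction, single pass or memory-bounded
# tiles with overlap-averaged blending, plus overlay export.

#' Predict a probability map for an image of arbitrary size
#'
#' Runs the fused network head over the image. With `tile_size = NULL` the
#' image is processed in a single forward pass when no side exceeds 2048 px;
#' larger images are automatically tiled (default tile 1024). Tiles overlap
#' by `overlap` pixels and probabilities are averaged in the overlapped
#' bands, which bounds boundary artifacts at tile joints; the output always
#' has the input's spatial size.
#'
#' @param model a `myoseg_net` (or `myoseg` fit; see [myoseg()]).
#' @param image numeric `H x W x 3` array in `[0, 1]`.
#' @param tile_size tile side in pixels, or `NULL` for automatic choice.
#' @param overlap tile overlap in pixels; must be `< tile_size / 2`.
#' @return probability matrix of the input's size.
#' @export
predict_image <- function(model, image, tile_size = NULL, overlap = 64) {
  if (inherits(model, "myoseg")) model <- model$model
  stopifnot(inherits(model, "myoseg_net"))
  H <- dim(image)[1]; W <- dim(image)[2]
  auto <- is.null(tile_size)
  if (auto && max(H, W) > 2048) tile_size <- 1024
  if (is.null(tile_size)) return(forward(model, image)$fused_map)
  if (tile_size < 32) stop("tile_size must be at least 32 px", call. = FALSE)
  if (!auto && overlap >= tile_size / 2)
    stop("overlap must be smaller than tile_size / 2", call. = FALSE)
  if (tile_size >= H && tile_size >= W)
    return(forward(model, image)$fused_map)
  starts <- function(n, tile) {
    if (tile >= n) return(0L)
    s <- seq(0L, n - tile, by = max(1L, tile - overlap))
    if (s[length(s)] != n - tile) s <- c(s, n - tile)
    as.integer(s)
  }
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  for (r0 in starts(H, min(tile_size, H))) {
    for (c0 in starts(W, min(tile_size, W))) {
      ri <- r0 + seq_len(min(tile_size, H))
      ci <- c0 + seq_len(min(tile_size, W))
      p <- forward(model, image[ri, ci, , drop = FALSE])$fused_map
      acc[ri, ci] <- acc[ri, ci] + p
      cnt[ri, ci] <- cnt[ri, ci] + 1
    }
  }
  acc / cnt
}

#' Save a colour overlay of labelled fibres
#'
#' Alpha-blends a distinct colour per fibre label over the image and writes
#' the result as RGB PNG. The palette is drawn deterministically from
#' `seed`. With zero fibres the written image equals the input.
#'
#' @param image numeric `H x W x 3` array in `[0, 1]`.
#' @param labels integer label matrix (0 = background).
#' @param out_path output PNG path.
#' @param alpha blend weight of the colour mask in `[0, 1]`.
#' @param seed integer seed for the palette permutation.
#' @return `out_path`, invisibly.
#' @export
save_overlay <- function(image, labels, out_path, alpha = 0.45, seed = 1) {
  stopifnot(all(dim(image)[1:2] == dim(labels)))
  k <- max(labels)
  out <- image
  if (k > 0) {
    pal <- with_seed(seed, {
      hues <- (seq_len(k) - 1) / k
      grDevices::col2rgb(grDevices::hsv(sample(hues), 0.85, 0.95)) / 255
    })
    for (ch in 1:3) {
      plane <- out[, , ch]
      colvec <- c(0, pal[ch, ])[labels + 1L]
      sel <- labels > 0
      plane[sel] <- (1 - alpha) * plane[sel] + alpha * colvec[sel]
      out[, , ch] <- plane
    }
  }
  write_image(out, out_path)
  invisible(out_path)
}
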