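# Hierarchically connected encoder / multi-decoder network.
#
# Encoder: VGG-16-style stack (fully connected layers removed): 5 blocks of
# 3x3 conv + ReLU with 2x2/stride-2 max-pooling between blocks. One decoder
# taps the last conv activation of every block (i.e. just before each
# max-pool). Decoder i applies a 3x3 conv to `decoder_channels`, then (i-1)
# refinement steps of [stride-2 4x4 learnable deconvolution, 3x3 conv+ReLU],
# then a 3x3 conv to one channel; its score map is cropped to the input size.
# The M one-channel score maps are concatenated into an M-channel map and
# merged by a 1x1 convolution; a sigmoid is applied to every decoder map and
# to the fused map.
#
# Parameters are kept in a flat named list (`model$par`) so that gradient
# accumulation and SGD updates are simple elementwise maps. Naming:
#   e{b}.{l}.w / .b        encoder block b, conv layer l
#   d{i}.tap.w / .b        decoder i tap conv
#   d{i}.s{j}.dc.w / .b    decoder i refinement step j, deconvolution
#   d{i}.s{j}.cv.w / .b    decoder i refinement step j, conv
#   d{i}.out.w / .b        decoder i 1-channel score conv
#   fuse.w / fuse.b        1x1 fusion conv
# Conv weights are (k*k*cin x cout) matrices (kernel offset fastest, input
# channel slowest); deconv weights are (16*cin x cout) matrices with row
# index ci + cin*(a + 4*b). See src/ops.cpp.

VGG16_WIDTHS <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                     c(512, 512, 512), c(512, 512, 512))

#' Model configuration
#'
#' Describes the encoder/decoder architecture. The defaults reproduce the
#' full-size network (VGG-16 encoder widths, 5 decoders, 64 decoder
#' channels). `width_multiplier` scales every channel count (floored at 1)
#' and exists so that desk-scale variants can be trained in minutes; it does
#' not change the layer structure.
#'
#' @param width_multiplier channel scaling factor in `(0, 1]`.
#' @param decoder_channels internal decoder width before scaling.
#' @param n_decoders number of decoders `M`; must equal the number of
#'   encoder blocks.
#' @param encoder_widths list of per-block conv widths before scaling.
#' @return an object of class `myoseg_config`.
#' @export
model_config <- function(width_multiplier = 1, decoder_channels = 64,
                         n_decoders = 5, encoder_widths = VGG16_WIDTHS) {
  stopifnot(width_multiplier > 0, width_multiplier <= 1,
            decoder_channels >= 1, n_decoders >= 1)
  if (n_decoders != length(encoder_widths))
    stop("n_decoders must equal the number of encoder blocks (",
         length(encoder_widths), ")", call. = FALSE)
  sc <- function(w) pmax(1L, as.integer(round(w * width_multiplier)))
  structure(list(
    encoder_widths = lapply(encoder_widths, sc),
    decoder_channels = sc(decoder_channels),
    n_decoders = as.integer(n_decoders),
    width_multiplier = width_multiplier),
    class = "myoseg_config")
}

#' @export
print.myoseg_config <- function(x, ...) {
  cat("<myoseg_config>\n")
  cat("  encoder blocks:",
      paste(vapply(x$encoder_widths, function(w) paste(w, collapse = "-"),
                   ""), collapse = " | "), "\n")
  cat(sprintf("  decoders: %d (width %d), width multiplier %g\n",
              x$n_decoders, x$decoder_channels, x$width_multiplier))
  invisible(x)
}

he_init <- function(k, cin, cout) {
  matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

# 4x4 stride-2 bilinear upsampling kernel, identity across channels.
bilinear_deconv_init <- function(cin, cout) {
  h <- c(0.25, 0.75, 0.75, 0.25)
  w <- matrix(0, 16 * cin, cout)
  for (a in 0:3) for (b in 0:3) {
    rows <- seq_len(min(cin, cout)) + cin * (a + 4 * b)
    w[cbind(rows, seq_len(min(cin, cout)))] <- h[a + 1] * h[b + 1]
  }
  w
}

#' Build a model
#'
#' Allocates and initializes all parameters: He-normal for convolutions,
#' bilinear-interpolation identity for deconvolutions, zero biases.
#' Deterministic given `seed`.
#'
#' @param config a [model_config()].
#' @param seed integer seed for the random initialization.
#' @return an object of class `myoseg_net` with elements `config` and `par`
#'   (flat named list of parameter tensors).
#' @export
build_model <- function(config = model_config(), seed = 1) {
  stopifnot(inherits(config, "myoseg_config"))
  M <- config$n_decoders
  dc <- config$decoder_channels
  par <- list()
  with_seed(seed, {
    cin <- 3L
    for (b in seq_len(M)) {
      for (l in seq_along(config$encoder_widths[[b]])) {
        cout <- config$encoder_widths[[b]][l]
        par[[sprintf("e%d.%d.w", b, l)]] <- he_init(3, cin, cout)
        par[[sprintf("e%d.%d.b", b, l)]] <- numeric(cout)
        cin <- cout
      }
    }
    for (i in seq_len(M)) {
      tin <- config$encoder_widths[[i]][length(config$encoder_widths[[i]])]
      par[[sprintf("d%d.tap.w", i)]] <- he_init(3, tin, dc)
      par[[sprintf("d%d.tap.b", i)]] <- numeric(dc)
      if (i > 1) for (j in seq_len(i - 1)) {
        par[[sprintf("d%d.s%d.dc.w", i, j)]] <- bilinear_deconv_init(dc, dc)
        par[[sprintf("d%d.s%d.dc.b", i, j)]] <- numeric(dc)
        par[[sprintf("d%d.s%d.cv.w", i, j)]] <- he_init(3, dc, dc)
        par[[sprintf("d%d.s%d.cv.b", i, j)]] <- numeric(dc)
      }
      par[[sprintf("d%d.out.w", i)]] <- he_init(3, dc, 1)
      par[[sprintf("d%d.out.b", i)]] <- numeric(1)
    }
    par[["fuse.w"]] <- matrix(rnorm(M, sd = sqrt(2 / M)), M, 1)
    par[["fuse.b"]] <- numeric(1)
  })
  structure(list(config = config, par = par), class = "myoseg_net")
}

#' @export
print.myoseg_net <- function(x, ...) {
  np <- sum(vapply(x$par, length, 0L))
  cat(sprintf(
    "<myoseg_net> %d encoder conv layers, %d decoders, %s parameters\n",
    sum(lengths(x$config$encoder_widths)), x$config$n_decoders,
    format(np, big.mark = ",")))
  invisible(x)
}

#' Number of encoder conv layers
#' @param model a `myoseg_net`.
#' @return integer count.
#' @export
n_encoder_convs <- function(model) {
  sum(lengths(model$config$encoder_widths))
}

#' Load pretrained encoder weights
#'
#' Copies encoder conv weights/biases from `weights_source` (a named list
#' using this package's parameter names, or a checkpoint path) into the
#' encoder; decoder and fusion parameters are untouched. Layer shapes must
#' match exactly. With `weights_source = NULL` the model is returned
#' unchanged with a warning.
#'
#' @param model a `myoseg_net`.
#' @param weights_source named list of tensors, a checkpoint path, or `NULL`.
#' @return the model, with attribute `tensors_loaded` giving the number of
#'   parameter tensors copied.
#' @export
load_pretrained_encoder <- function(model, weights_source = NULL) {
  stopifnot(inherits(model, "myoseg_net"))
  if (is.null(weights_source)) {
    warning("no pretrained weights given; encoder left at random init")
    attr(model, "tensors_loaded") <- 0L
    return(model)
  }
  src <- if (is.character(weights_source)) load_model(weights_source)$par
         else weights_source
  enc_names <- grep("^e[0-9]+\\.", names(model$par), value = TRUE)
  n <- 0L
  for (nm in enc_names) {
    if (is.null(src[[nm]])) next
    if (!identical(dim(model$par[[nm]]), dim(src[[nm]])) ||
        length(model$par[[nm]]) != length(src[[nm]]))
      stop(sprintf(
        "shape mismatch for encoder layer '%s': have %s, source has %s",
        nm, paste(dim(model$par[[nm]]) %||% length(model$par[[nm]]),
                  collapse = "x"),
        paste(dim(src[[nm]]) %||% length(src[[nm]]), collapse = "x")),
        call. = FALSE)
    model$par[[nm]] <- src[[nm]]
    n <- n + 1L
  }
  attr(model, "tensors_loaded") <- n
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Padding bookkeeping: pad H, W up to multiples of 32 by reflection, original
# placed with centred offsets. Returns the padded array plus the crop window.
pad_to_stride <- function(x, stride = 32L) {
  H <- dim(x)[1]; W <- dim(x)[2]
  Hp <- as.integer(ceiling(H / stride) * stride)
  Wp <- as.integer(ceiling(W / stride) * stride)
  top <- (Hp - H) %/% 2L; left <- (Wp - W) %/% 2L
  xp <- pad_reflect(x, top, Hp - H - top, left, Wp - W - left)
  list(x = xp, H = H, W = W, Hp = Hp, Wp = Wp, top = top, left = left)
}

#' Forward pass
#'
#' Runs the network on one RGB image of arbitrary size (at least 32 px per
#' side). Internally the image is reflect-padded to multiples of 32 and every
#' score map is cropped back, so all returned maps have exactly the input's
#' spatial size. One forward pass only; deterministic for fixed parameters.
#'
#' @param model a `myoseg_net`.
#' @param image numeric `H x W x 3` array in `[0, 1]`.
#' @param train logical; if `TRUE` the returned object carries the
#'   activation cache needed by the backward pass.
#' @return an object of class `myoseg_bundle`: list with `decoder_maps`
#'   (list of `M` probability matrices), `fused_map` (probability matrix),
#'   the corresponding logit maps, and (if `train`) `cache`.
#' @export
forward <- function(model, image, train = FALSE) {
  stopifnot(inherits(model, "myoseg_net"))
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("`image` must be an H x W x 3 array", call. = FALSE)
  if (d[1] < 32 || d[2] < 32)
    stop("image smaller than one receptive stride (32 px) per side",
         call. = FALSE)
  cfg <- model$config; par <- model$par
  M <- cfg$n_decoders
  pd <- pad_to_stride(image - 0.5)
  x <- pd$x
  enc_in <- vector("list", M); enc_act <- vector("list", M)
  pool_idx <- vector("list", M); pool_dim <- vector("list", M)
  taps <- vector("list", M)
  for (b in seq_len(M)) {
    nl <- length(cfg$encoder_widths[[b]])
    enc_in[[b]] <- vector("list", nl); enc_act[[b]] <- vector("list", nl)
    for (l in seq_len(nl)) {
      enc_in[[b]][[l]] <- x
      pre <- cpp_conv_fwd(x, par[[sprintf("e%d.%d.w", b, l)]],
                          par[[sprintf("e%d.%d.b", b, l)]], 3L)
      x <- relu(pre)
      enc_act[[b]][[l]] <- x
    }
    taps[[b]] <- x
    if (b < M) {
      pool_dim[[b]] <- dim(x)[1:2]
      p <- cpp_pool_fwd(x)
      pool_idx[[b]] <- p$idx
      x <- p$y
    }
  }
  dec <- vector("list", M)
  logits <- vector("list", M)
  rows <- pd$top + seq_len(pd$H); cols <- pd$left + seq_len(pd$W)
  for (i in seq_len(M)) {
    ci <- list()
    tpre <- cpp_conv_fwd(taps[[i]], par[[sprintf("d%d.tap.w", i)]],
                         par[[sprintf("d%d.tap.b", i)]], 3L)
    a <- relu(tpre)
    ci$tap_act <- a
    if (i > 1) {
      ci$steps <- vector("list", i - 1)
      for (j in seq_len(i - 1)) {
        s <- list(dc_in = a)
        up <- cpp_deconv_fwd(a, par[[sprintf("d%d.s%d.dc.w", i, j)]],
                             par[[sprintf("d%d.s%d.dc.b", i, j)]])
        s$dc_out <- up
        cpre <- cpp_conv_fwd(up, par[[sprintf("d%d.s%d.cv.w", i, j)]],
                             par[[sprintf("d%d.s%d.cv.b", i, j)]], 3L)
        a <- relu(cpre)
        s$cv_act <- a
        ci$steps[[j]] <- s
      }
    }
    ci$score_in <- a
    score <- cpp_conv_fwd(a, par[[sprintf("d%d.out.w", i)]],
                          par[[sprintf("d%d.out.b", i)]], 3L)
    ci$score_dim <- dim(score)
    logits[[i]] <- score[rows, cols, 1]
    dec[[i]] <- ci
  }
  concat <- array(0, c(pd$H, pd$W, M))
  for (i in seq_len(M)) concat[, , i] <- logits[[i]]
  fpre <- cpp_conv_fwd(concat, par[["fuse.w"]], par[["fuse.b"]], 1L)
  fused_logit <- fpre[, , 1]
  out <- list(decoder_maps = lapply(logits, sigmoid),
              fused_map = sigmoid(fused_logit),
              decoder_logits = logits, fused_logit = fused_logit)
  if (train)
    out$cache <- list(pd = pd, enc_in = enc_in, enc_act = enc_act,
                      pool_idx = pool_idx, pool_dim = pool_dim,
                      taps = taps, dec = dec, concat = concat,
                      rows = rows, cols = cols)
  class(out) <- "myoseg_bundle"
  out
}

#' @export
print.myoseg_bundle <- function(x, ...) {
  cat(sprintf("<myoseg_bundle> %d decoder maps + fused map, %d x %d\n",
              length(x$decoder_maps), nrow(x$fused_map), ncol(x$fused_map)))
  invisible(x)
}

# Backward pass: given per-head gradients w.r.t. the (cropped) logit maps,
# returns gradients for every parameter tensor (same names as model$par).
# dlogit_dec: list of M (H x W) matrices; dlogit_fused: (H x W) matrix.
backward <- function(model, bundle, dlogit_dec, dlogit_fused) {
  cfg <- model$config; par <- model$par; cache <- bundle$cache
  if (is.null(cache)) stop("bundle was produced with train = FALSE")
  M <- cfg$n_decoders
  pd <- cache$pd
  g <- list()
  # fusion head
  r <- cpp_conv_bwd(cache$concat, par[["fuse.w"]],
                    array(dlogit_fused, c(pd$H, pd$W, 1L)), 1L)
  g[["fuse.w"]] <- r$dw; g[["fuse.b"]] <- r$db
  dconcat <- r$dx
  dtap <- vector("list", M)
  for (i in seq_len(M)) {
    dscore_crop <- dlogit_dec[[i]] + dconcat[, , i]
    dscore <- array(0, cache$dec[[i]]$score_dim)
    dscore[cache$rows, cache$cols, 1] <- dscore_crop
    ci <- cache$dec[[i]]
    r <- cpp_conv_bwd(ci$score_in, par[[sprintf("d%d.out.w", i)]], dscore, 3L)
    g[[sprintf("d%d.out.w", i)]] <- r$dw
    g[[sprintf("d%d.out.b", i)]] <- r$db
    da <- r$dx
    if (i > 1) for (j in rev(seq_len(i - 1))) {
      s <- ci$steps[[j]]
      da <- da * (s$cv_act > 0)
      r <- cpp_conv_bwd(s$dc_out, par[[sprintf("d%d.s%d.cv.w", i, j)]], da, 3L)
      g[[sprintf("d%d.s%d.cv.w", i, j)]] <- r$dw
      g[[sprintf("d%d.s%d.cv.b", i, j)]] <- r$db
      r2 <- cpp_deconv_bwd(s$dc_in, par[[sprintf("d%d.s%d.dc.w", i, j)]],
                           r$dx)
      g[[sprintf("d%d.s%d.dc.w", i, j)]] <- r2$dw
      g[[sprintf("d%d.s%d.dc.b", i, j)]] <- r2$db
      da <- r2$dx
    }
    da <- da * (ci$tap_act > 0)
    r <- cpp_conv_bwd(cache$taps[[i]], par[[sprintf("d%d.tap.w", i)]], da, 3L)
    g[[sprintf("d%d.tap.w", i)]] <- r$dw
    g[[sprintf("d%d.tap.b", i)]] <- r$db
    dtap[[i]] <- r$dx
  }
  # encoder: gradients accumulate from the decoder taps and the pooling path
  dact <- dtap[[M]]
  for (b in rev(seq_len(M))) {
    nl <- length(cfg$encoder_widths[[b]])
    for (l in rev(seq_len(nl))) {
      dpre <- dact * (cache$enc_act[[b]][[l]] > 0)
      r <- cpp_conv_bwd(cache$enc_in[[b]][[l]],
                        par[[sprintf("e%d.%d.w", b, l)]], dpre, 3L)
      g[[sprintf("e%d.%d.w", b, l)]] <- r$dw
      g[[sprintf("e%d.%d.b", b, l)]] <- r$db
      dact <- r$dx
    }
    if (b > 1) {
      dd <- cache$pool_dim[[b - 1]]
      dact <- cpp_pool_bwd(cache$pool_idx[[b - 1]], dact, dd[1], dd[2]) +
        dtap[[b - 1]]
    }
  }
  # bias gradients arrive as n x 1 matrices; keep them plain vectors so
  # updates preserve parameter shapes
  for (nm in names(g))
    if (endsWith(nm, ".b")) g[[nm]] <- as.vector(g[[nm]])
  g
}
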