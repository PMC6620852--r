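# Top-level fitting interface in the classic modelling idiom: one fitting
# function returning a classed object with print/summary/predict/plot
# methods, composed from the exported building blocks.

#' Fit a muscle-fibre segmentation network
#'
#' Builds a model from `config`, optionally initializes the encoder from
#' pretrained weights, and runs the two-stage training procedure (stage 1:
#' fibre-boundary detection; stage 2: fibre-mask fine-tuning) on the given
#' dataset manifest.
#'
#' @param manifest manifest data frame or path to a manifest TSV (see
#'   [make_dataset()] / [read_manifest()]).
#' @param config a [model_config()].
#' @param schedule1,schedule2 [training_schedule()]s for the two stages.
#' @param crops_per_image,crop_size cropping parameters; see [make_crops()].
#' @param eta1,epsilon,eta2 loss parameters; see [static_weight_map()] and
#'   [switch_mask()].
#' @param switch_warmup per-stage switch warm-up; see [train_stage()].
#' @param pretrained optional encoder weight source; see
#'   [load_pretrained_encoder()].
#' @param skip_stage1 ablation flag: train on masks only.
#' @param seed integer seed driving initialization, cropping and shuffling.
#' @param verbose print training progress.
#' @return an object of class `myoseg`: list with `model` (the trained
#'   `myoseg_net`), `config`, `history` (per-iteration losses, column
#'   `stage`), `seed` and `call`.
#' @examples
#' \donttest{
#' dir <- tempfile()
#' make_dataset(8, size_range = c(96, 96), out_dir = dir, seed = 1,
#'              fiber_diameter_range = c(24, 40))
#' fit <- myoseg(file.path(dir, "manifest.tsv"),
#'               config = model_config(width_multiplier = 0.125),
#'               schedule1 = training_schedule(1, lr = 2e-4,
#'                                             max_iterations = 20),
#'               schedule2 = training_schedule(2, lr = 1e-4,
#'                                             max_iterations = 20),
#'               crops_per_image = 4, crop_size = 64, seed = 1)
#' img <- read_image(read_manifest(file.path(dir, "manifest.tsv"))$path_image[8])
#' p <- predict(fit, img)
#' }
#' @export
myoseg <- function(manifest, config = model_config(),
                   schedule1 = training_schedule(1),
                   schedule2 = training_schedule(2),
                   crops_per_image = 30, crop_size = 300,
                   eta1 = 5, epsilon = 10, eta2 = 0.6, switch_warmup = 0,
                   pretrained = NULL, skip_stage1 = FALSE, seed = 1,
                   verbose = FALSE) {
  cl <- match.call()
  model <- build_model(config, seed = seed)
  if (!is.null(pretrained))
    model <- load_pretrained_encoder(model, pretrained)
  res <- run_two_stage(model, manifest, schedule1, schedule2,
                       crops_per_image = crops_per_image,
                       crop_size = crop_size, eta1 = eta1,
                       epsilon = epsilon, eta2 = eta2,
                       switch_warmup = switch_warmup, seed = seed,
                       skip_stage1 = skip_stage1, verbose = verbose)
  hist <- rbind(
    if (!is.null(res$history1))
      cbind(res$history1, stage = 1L),
    cbind(res$history2, stage = 2L))
  structure(list(model = res$model, config = config, history = hist,
                 seed = seed, call = cl), class = "myoseg")
}

#' @export
print.myoseg <- function(x, ...) {
  cat("Two-stage muscle-fibre segmentation fit\n\nCall:\n  ")
  print(x$call)
  cat("\n")
  print(x$model)
  st <- split(x$history, x$history$stage)
  for (s in names(st))
    cat(sprintf("  stage %s: %d iterations, final loss/px %.5f\n", s,
                nrow(st[[s]]), st[[s]]$loss[nrow(st[[s]])]))
  invisible(x)
}

#' @export
summary.myoseg <- function(object, ...) {
  np <- sum(vapply(object$model$par, length, 0L))
  st <- split(object$history, object$history$stage)
  cat("Two-stage muscle-fibre segmentation fit\n")
  print(object$config)
  cat(sprintf("  parameters: %s\n", format(np, big.mark = ",")))
  for (s in names(st)) {
    h <- st[[s]]
    cat(sprintf(
      "  stage %s: %d iterations, loss/px %.5f -> %.5f, gated %.3f -> %.3f\n",
      s, nrow(h), h$loss[1], h$loss[nrow(h)],
      h$excluded_fraction[1], h$excluded_fraction[nrow(h)]))
  }
  invisible(object)
}

#' Predict from a fitted segmentation model
#'
#' @param object a `myoseg` fit.
#' @param image numeric `H x W x 3` array in `[0, 1]`.
#' @param type `"prob"` for the fused probability map, `"labels"` for
#'   thresholded, labelled fibres.
#' @param threshold,min_area labelling parameters for `type = "labels"`.
#' @param tile_size,overlap tiling parameters; see [predict_image()].
#' @param ... unused.
#' @return probability matrix or integer label matrix.
#' @export
predict.myoseg <- function(object, image, type = c("prob", "labels"),
                           threshold = 0.5, min_area = 30,
                           tile_size = NULL, overlap = 64, ...) {
  type <- match.arg(type)
  p <- predict_image(object$model, image, tile_size, overlap)
  if (type == "prob") p else binarize_and_label(p, threshold, min_area)
}

#' Plot the training loss history
#'
#' @param x a `myoseg` fit.
#' @param ... passed to [plot()].
#' @export
plot.myoseg <- function(x, ...) {
  h <- x$history
  off <- c(0, cumsum(tapply(h$iteration, h$stage, max) + 1))
  it <- h$iteration + off[as.integer(factor(h$stage))]
  plot(it, h$loss, type = "l", xlab = "iteration (stages concatenated)",
       ylab = "loss per pixel", ...)
  if (length(unique(h$stage)) > 1)
    graphics::abline(v = off[2] - 0.5, lty = 2, col = "grey50")
  invisible(x)
}

#' @export
coef.myoseg <- function(object, ...) object$model$par
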