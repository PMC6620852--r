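# Augmentation (random cropping) and the two-stage training procedure.
#
# Stage 1 trains the network to detect fibre boundaries (boundary-map
# targets); stage 2 fine-tunes the same parameters on the fibre masks.
# Optimization is SGD with momentum; the learning rate of stage 1 is divided
# by 10 every 1e4 iterations. Static weight maps are computed per crop from
# the stage's own target with the same machinery (the weighting formulation
# is target-agnostic).

#' Training schedule
#'
#' Hyper-parameters of one training stage. Defaults: learning rate `1e-6`
#' for stage 1 and `1e-7` for stage 2, divided by 10 every `1e4` iterations,
#' momentum 0.9, minibatch size 2. Iteration budgets default to `2e4`
#' (stage 1) and `1e4` (stage 2) and should be overridden for desk-scale
#' runs.
#'
#' @param stage 1 (boundary pretext) or 2 (mask fine-tuning).
#' @param lr base learning rate; `NULL` uses the stage default.
#' @param lr_decay_every iterations between learning-rate divisions.
#' @param lr_decay_factor division factor.
#' @param momentum SGD momentum.
#' @param batch_size minibatch size (>= 1).
#' @param max_iterations iteration budget.
#' @return an object of class `training_schedule`.
#' @export
training_schedule <- function(stage, lr = NULL, lr_decay_every = 1e4,
                              lr_decay_factor = 10, momentum = 0.9,
                              batch_size = 2,
                              max_iterations = if (stage == 1) 2e4 else 1e4) {
  stopifnot(stage %in% c(1, 2), batch_size >= 1, max_iterations >= 0,
            momentum >= 0, momentum < 1)
  if (is.null(lr)) lr <- if (stage == 1) 1e-6 else 1e-7
  stopifnot(lr > 0)
  structure(list(stage = as.integer(stage), lr = lr,
                 lr_decay_every = lr_decay_every,
                 lr_decay_factor = lr_decay_factor, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations)),
            class = "training_schedule")
}

#' Learning rate at a given iteration
#'
#' @param schedule a [training_schedule()].
#' @param iteration 0-based iteration counter.
#' @return the learning rate in effect for that iteration.
#' @export
schedule_lr <- function(schedule, iteration) {
  schedule$lr / schedule$lr_decay_factor^(iteration %/% schedule$lr_decay_every)
}

#' Random training crops
#'
#' Samples `crops_per_image` random crop windows of `crop_size` pixels from
#' every training image in the manifest. The crop table is lazy: it records
#' the window coordinates, and [get_crop()] materializes the aligned image,
#' target and per-crop static weight map on demand. Images smaller than
#' `crop_size` are reflect-padded (a warning is logged once per such image).
#' Deterministic given `seed`.
#'
#' @param manifest manifest data frame or path (see [read_manifest()]).
#' @param crops_per_image crops per training image (default 30).
#' @param crop_size crop side length in pixels (default 300).
#' @param seed integer seed.
#' @return an object of class `crop_set`: a data frame with columns `image`,
#'   `row0`, `col0` (0-based offsets in the padded canvas), with the
#'   manifest and geometry attached as attributes.
#' @export
make_crops <- function(manifest, crops_per_image = 30, crop_size = 300,
                       seed = 1) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(crops_per_image >= 1, crop_size >= 1)
  train <- manifest[manifest$split == "train", , drop = FALSE]
  if (nrow(train) == 0) stop("manifest has no training images")
  dims <- matrix(0L, nrow(train), 2)
  for (i in seq_len(nrow(train))) {
    # masks are single-channel and cheapest to read for geometry
    m <- read_mask(train$path_mask[i])
    dims[i, ] <- dim(m)
  }
  undersized <- dims[, 1] < crop_size | dims[, 2] < crop_size
  if (any(undersized))
    warning(sprintf(
      "%d training image(s) smaller than crop_size %d: reflect-padding",
      sum(undersized), crop_size))
  with_seed(seed, {
    rows <- vector("list", nrow(train))
    for (i in seq_len(nrow(train))) {
      Hp <- max(dims[i, 1], crop_size); Wp <- max(dims[i, 2], crop_size)
      rows[[i]] <- data.frame(
        image = i,
        row0 = sample.int(Hp - crop_size + 1L, crops_per_image,
                          replace = TRUE) - 1L,
        col0 = sample.int(Wp - crop_size + 1L, crops_per_image,
                          replace = TRUE) - 1L)
    }
    crops <- do.call(rbind, rows)
    attr(crops, "manifest") <- train
    attr(crops, "dims") <- dims
    attr(crops, "crop_size") <- as.integer(crop_size)
    attr(crops, "seed") <- seed
    class(crops) <- c("crop_set", "data.frame")
    crops
  })
}

# Cache environment for decoded images/targets, keyed by training image index.
crop_cache <- function() new.env(parent = emptyenv())

load_train_image <- function(crops, i, cache) {
  key <- as.character(i)
  if (!is.null(cache[[key]])) return(cache[[key]])
  man <- attr(crops, "manifest")
  cs <- attr(crops, "crop_size")
  img <- read_image(man$path_image[i])
  msk <- read_mask(man$path_mask[i])
  bnd <- read_mask(man$path_boundary[i])
  H <- dim(img)[1]; W <- dim(img)[2]
  if (H < cs || W < cs) {
    bot <- max(0L, cs - H); rgt <- max(0L, cs - W)
    img <- pad_reflect(img, 0L, bot, 0L, rgt)
    msk <- pad_reflect(msk, 0L, bot, 0L, rgt)
    bnd <- pad_reflect(bnd, 0L, bot, 0L, rgt)
  }
  val <- list(image = img, mask = msk, boundary = bnd)
  cache[[key]] <- val
  val
}

#' Materialize one training crop
#'
#' Slices the aligned image and target crop and computes the static weight
#' map of the crop's target (class balance over the crop, boundary-proximity
#' term with `eta1`, `epsilon`).
#'
#' @param crops a `crop_set` from [make_crops()].
#' @param i crop index (row of the crop table).
#' @param target `"mask"` or `"boundary"`: which ground truth the crop
#'   carries as `y`.
#' @param eta1,epsilon static weight-map parameters; see
#'   [static_weight_map()].
#' @param cache optional environment used to memoize decoded images.
#' @return list with `x` (image crop, `crop_size^2 x 3`), `y` (binary target
#'   crop) and `w` (static weight map of `y`).
#' @export
get_crop <- function(crops, i, target = c("mask", "boundary"), eta1 = 5,
                     epsilon = 10, cache = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(crops, "crop_set"), i >= 1, i <= nrow(crops))
  if (is.null(cache)) cache <- crop_cache()
  rec <- crops[i, ]
  dat <- load_train_image(crops, rec$image, cache)
  cs <- attr(crops, "crop_size")
  ri <- rec$row0 + seq_len(cs); ci <- rec$col0 + seq_len(cs)
  y <- if (target == "mask") dat$mask[ri, ci] else dat$boundary[ri, ci]
  list(x = dat$image[ri, ci, , drop = FALSE], y = y,
       w = static_weight_map(y, eta1, epsilon))
}

#' Train one stage
#'
#' SGD with momentum over shuffled minibatches of materialized crops.
#' Gradients are averaged over the minibatch; the per-head losses use the
#' dynamic switch computed from the fused map. The loss history records the
#' per-pixel mean loss for monitoring. Training aborts with a diagnostic
#' error if the loss becomes non-finite.
#'
#' @param model a `myoseg_net`.
#' @param crops a `crop_set`.
#' @param schedule a [training_schedule()]; stage 1 pairs with
#'   `target_kind = "boundary"`, stage 2 with `"mask"`.
#' @param target_kind `"boundary"` or `"mask"`.
#' @param seed integer seed for shuffling.
#' @param eta1,epsilon,eta2 loss parameters.
#' @param switch_warmup number of initial iterations during which the
#'   dynamic switch is disabled (gate all-ones). From a random
#'   initialization the network can briefly be confidently wrong everywhere,
#'   and an always-on gate would then excise exactly the pixels that carry
#'   the corrective gradient; the warm-up lets the network become broadly
#'   calibrated before the gate starts discounting suspect annotations.
#' @param verbose print progress every 50 iterations.
#' @return list with `model` (trained) and `history` (data frame with
#'   columns `iteration`, `lr`, `loss`, `loss_fused`, `excluded_fraction`).
#' @export
train_stage <- function(model, crops, schedule,
                        target_kind = c("boundary", "mask"), seed = 1,
                        eta1 = 5, epsilon = 10, eta2 = 0.6,
                        switch_warmup = 0, verbose = FALSE) {
  target_kind <- match.arg(target_kind)
  stopifnot(inherits(model, "myoseg_net"), inherits(crops, "crop_set"),
            inherits(schedule, "training_schedule"))
  expected <- if (schedule$stage == 1) "boundary" else "mask"
  if (target_kind != expected)
    stop(sprintf("schedule stage %d pairs with target_kind '%s'",
                 schedule$stage, expected), call. = FALSE)
  n_iter <- schedule$max_iterations
  if (n_iter == 0)
    return(list(model = model,
                history = data.frame(iteration = integer(), lr = numeric(),
                                     loss = numeric(), loss_fused = numeric(),
                                     excluded_fraction = numeric())))
  M <- model$config$n_decoders
  cache <- crop_cache()
  vel <- lapply(model$par, function(p) p * 0)
  hist_loss <- numeric(n_iter); hist_fused <- numeric(n_iter)
  hist_lr <- numeric(n_iter); hist_excl <- numeric(n_iter)
  with_seed(seed, {
    order_pool <- sample.int(nrow(crops))
    pos <- 1L
    next_batch <- function() {
      b <- integer(0)
      while (length(b) < schedule$batch_size) {
        if (pos > length(order_pool)) {
          order_pool <<- sample.int(nrow(crops))
          pos <<- 1L
        }
        take <- min(schedule$batch_size - length(b),
                    length(order_pool) - pos + 1L)
        b <- c(b, order_pool[pos:(pos + take - 1L)])
        pos <<- pos + take
      }
      b
    }
    for (it in seq_len(n_iter) - 1L) {
      lr <- schedule_lr(schedule, it)
      batch <- next_batch()
      acc <- NULL
      bl <- 0; bf <- 0; be <- 0
      for (idx in batch) {
        cr <- get_crop(crops, idx, target_kind, eta1, epsilon, cache)
        bundle <- forward(model, cr$x, train = TRUE)
        gate <- if (it < switch_warmup)
          matrix(1L, nrow(cr$y), ncol(cr$y)) else NULL
        rep_ <- total_loss(bundle, cr$y, cr$w, eta2, switch = gate)
        if (!is.finite(rep_$total))
          stop(sprintf(
            "non-finite loss at iteration %d (crop %d, target '%s')",
            it, idx, target_kind), call. = FALSE)
        s <- rep_$switch
        dd <- lapply(bundle$decoder_maps,
                     function(P) weighted_bce_grad(P, cr$y, cr$w, s))
        df <- weighted_bce_grad(bundle$fused_map, cr$y, cr$w, s)
        g <- backward(model, bundle, dd, df)
        acc <- if (is.null(acc)) g else Map(`+`, acc, g)
        bl <- bl + rep_$total; bf <- bf + rep_$fused
        be <- be + rep_$excluded_fraction
      }
      nb <- length(batch)
      npx <- length(cr$y) * (M + 1)
      hist_loss[it + 1L] <- bl / nb / npx
      hist_fused[it + 1L] <- bf / nb / length(cr$y)
      hist_lr[it + 1L] <- lr
      hist_excl[it + 1L] <- be / nb
      # step on the per-pixel mean gradient (summed over heads) so the
      # learning rate is independent of the crop area
      gsc <- nb * length(cr$y)
      for (nm in names(model$par)) {
        vel[[nm]] <- schedule$momentum * vel[[nm]] - lr * acc[[nm]] / gsc
        model$par[[nm]] <- model$par[[nm]] + vel[[nm]]
      }
      if (verbose && (it %% 50 == 0 || it == n_iter - 1L))
        message(sprintf("iter %5d  lr %.2g  loss/px %.5f  gated %.3f",
                        it, lr, hist_loss[it + 1L], hist_excl[it + 1L]))
    }
  })
  list(model = model,
       history = data.frame(iteration = seq_len(n_iter) - 1L, lr = hist_lr,
                            loss = hist_loss, loss_fused = hist_fused,
                            excluded_fraction = hist_excl))
}

#' Two-stage training
#'
#' Runs stage 1 (boundary-map pretext) and stage 2 (mask fine-tuning) on the
#' crops drawn from a manifest, handing the stage-1 parameters to stage 2
#' unchanged. Stage 1 can be skipped (`skip_stage1 = TRUE`) for the
#' mask-only ablation, in which case stage 2 starts from the given model and
#' a message is logged.
#'
#' @param model a `myoseg_net` (random or encoder-pretrained init).
#' @param manifest manifest data frame or path.
#' @param schedule1,schedule2 [training_schedule()]s for the two stages.
#' @param crops_per_image,crop_size cropping parameters; see [make_crops()].
#' @param eta1,epsilon,eta2 loss parameters.
#' @param switch_warmup per-stage switch warm-up; see [train_stage()].
#' @param seed integer seed driving cropping and shuffling.
#' @param skip_stage1 ablation flag: train on masks only.
#' @param verbose print progress.
#' @return list with `model`, `history1`, `history2`.
#' @export
run_two_stage <- function(model, manifest,
                          schedule1 = training_schedule(1),
                          schedule2 = training_schedule(2),
                          crops_per_image = 30, crop_size = 300,
                          eta1 = 5, epsilon = 10, eta2 = 0.6,
                          switch_warmup = 0, seed = 1,
                          skip_stage1 = FALSE, verbose = FALSE) {
  crops <- make_crops(manifest, crops_per_image, crop_size, seed = seed)
  h1 <- NULL
  if (skip_stage1) {
    message("skipping stage 1 (mask-only ablation)")
  } else {
    s1 <- train_stage(model, crops, schedule1, "boundary", seed = seed + 1L,
                      eta1 = eta1, epsilon = epsilon, eta2 = eta2,
                      switch_warmup = switch_warmup, verbose = verbose)
    model <- s1$model
    h1 <- s1$history
  }
  s2 <- train_stage(model, crops, schedule2, "mask", seed = seed + 2L,
                    eta1 = eta1, epsilon = epsilon, eta2 = eta2,
                    switch_warmup = switch_warmup, verbose = verbose)
  list(model = s2$model, history1 = h1, history2 = s2$history)
}
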