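test_that("the learning-rate schedule decays by tens", {
  s1 <- training_schedule(1)
  expect_equal(s1$lr, 1e-6)
  expect_equal(s1$momentum, 0.9)
  expect_equal(s1$batch_size, 2L)
  expect_equal(schedule_lr(s1, 0), 1e-6)
  expect_equal(schedule_lr(s1, 9999), 1e-6)
  expect_equal(schedule_lr(s1, 10000), 1e-7)
  expect_equal(schedule_lr(s1, 20000), 1e-8)
  expect_equal(training_schedule(2)$lr, 1e-7)
  expect_error(training_schedule(3))
})

test_that("crop tables are seeded, aligned and complete", {
  man <- small_dataset()
  crops <- make_crops(man, crops_per_image = 6, crop_size = 48, seed = 5)
  expect_s3_class(crops, "crop_set")
  expect_equal(nrow(crops), 8 * 6)   # 8 training images
  crops2 <- make_crops(man, crops_per_image = 6, crop_size = 48, seed = 5)
  expect_identical(crops[, c("image", "row0", "col0")],
                   crops2[, c("image", "row0", "col0")])
  # materialized crops are exactly crop_size with aligned channels
  cache <- myoseg:::crop_cache()
  for (i in c(1, 17, 48)) {
    cr <- get_crop(crops, i, "mask", cache = cache)
    expect_equal(dim(cr$x), c(48, 48, 3))
    expect_equal(dim(cr$y), c(48, 48))
    expect_equal(dim(cr$w), c(48, 48))
    expect_true(all(cr$y %in% c(0, 1)))
    expect_true(all(cr$w > 0))
  }
  # boundary crops come from the boundary map and stay exclusive of the mask
  cm <- get_crop(crops, 3, "mask", cache = cache)
  cb <- get_crop(crops, 3, "boundary", cache = cache)
  expect_false(any(cm$y == 1 & cb$y == 1))
  # undersized images are reflect-padded with a warning
  expect_warning(make_crops(man, 2, crop_size = 200, seed = 1),
                 "reflect-padding")
})

test_that("zero iterations leave the model untouched", {
  man <- small_dataset()
  crops <- make_crops(man, 2, 48, seed = 1)
  m <- build_model(model_config(width_multiplier = 0.05), seed = 4)
  r <- train_stage(m, crops, training_schedule(2, max_iterations = 0),
                   "mask", seed = 1)
  expect_identical(r$model$par, m$par)
  expect_equal(nrow(r$history), 0)
})

test_that("stage pairing is enforced", {
  man <- small_dataset()
  crops <- make_crops(man, 2, 48, seed = 1)
  m <- build_model(model_config(width_multiplier = 0.05), seed = 4)
  expect_error(train_stage(m, crops, training_schedule(1, max_iterations = 1),
                           "mask", seed = 1), "pairs with")
  expect_error(train_stage(m, crops, training_schedule(2, max_iterations = 1),
                           "boundary", seed = 1), "pairs with")
})

test_that("short training decreases the smoothed loss and is reproducible", {
  man <- small_dataset()
  crops <- make_crops(man, 2, 64, seed = 2)   # 16 crops
  cfg <- model_config(width_multiplier = 0.125)
  m <- build_model(cfg, seed = 4)
  sch <- training_schedule(2, lr = 1e-3, max_iterations = 200)
  r <- train_stage(m, crops, sch, "mask", seed = 6, switch_warmup = 1e9)
  sm <- function(x) mean(x)
  first <- sm(r$history$loss[1:20])
  last <- sm(r$history$loss[181:200])
  expect_lt(last, first)
  expect_true(all(is.finite(r$history$loss)))
  # identical rerun: same loss history bit for bit
  r2 <- train_stage(m, crops, sch, "mask", seed = 6, switch_warmup = 1e9)
  expect_identical(r$history$loss, r2$history$loss)
  # parameter count unchanged by training
  expect_identical(lapply(r$model$par, dim), lapply(m$par, dim))
})

test_that("two-stage hands parameters over unchanged and supports ablation", {
  man <- small_dataset()
  cfg <- model_config(width_multiplier = 0.05)
  m <- build_model(cfg, seed = 9)
  # stage-2 budget of zero: the two-stage result is exactly the stage-1 model
  r <- run_two_stage(m, man,
                     training_schedule(1, lr = 1e-3, max_iterations = 5),
                     training_schedule(2, lr = 1e-3, max_iterations = 0),
                     crops_per_image = 2, crop_size = 48, seed = 3,
                     switch_warmup = 1e9)
  s1 <- train_stage(m, make_crops(man, 2, 48, seed = 3),
                    training_schedule(1, lr = 1e-3, max_iterations = 5),
                    "boundary", seed = 4, switch_warmup = 1e9)
  expect_identical(r$model$par, s1$model$par)
  # ablation flag skips stage 1 with a message
  expect_message(
    r2 <- run_two_stage(m, man,
                        training_schedule(1, lr = 1e-3, max_iterations = 5),
                        training_schedule(2, lr = 1e-3, max_iterations = 2),
                        crops_per_image = 2, crop_size = 48, seed = 3,
                        switch_warmup = 1e9, skip_stage1 = TRUE),
    "skipping stage 1")
  expect_null(r2$history1)
})
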