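test_that("default architecture matches the declared structure", {
  cfg <- model_config()
  expect_equal(cfg$n_decoders, 5)
  m <- build_model(cfg, seed = 1)
  expect_equal(n_encoder_convs(m), 13)
  # decoder i contains exactly i-1 deconvolution layers
  for (i in 1:5) {
    ndc <- sum(grepl(sprintf("^d%d\\.s[0-9]+\\.dc\\.w$", i),
                     names(m$par)))
    expect_equal(ndc, i - 1)
  }
  # fusion merges a 5-channel concatenation
  expect_equal(nrow(m$par[["fuse.w"]]), 5)
  # config with mismatched decoder count is rejected
  expect_error(model_config(n_decoders = 4), "must equal")
})

test_that("width multiplier scales channels without changing structure", {
  cfg <- model_config(width_multiplier = 0.125)
  expect_equal(cfg$encoder_widths[[1]], c(8L, 8L))
  expect_equal(cfg$encoder_widths[[5]], c(64L, 64L, 64L))
  expect_equal(cfg$decoder_channels, 8L)
  m <- build_model(cfg, seed = 2)
  expect_equal(n_encoder_convs(m), 13)
  # extreme multipliers floor at one channel
  expect_true(all(model_config(width_multiplier = 0.001)$encoder_widths[[1]] >= 1))
})

test_that("forward preserves arbitrary input sizes and is deterministic", {
  m <- build_model(model_config(width_multiplier = 0.125), seed = 1)
  x <- array(runif(97 * 133 * 3), c(97, 133, 3))
  b <- forward(m, x)
  expect_equal(dim(b$fused_map), c(97, 133))
  for (p in b$decoder_maps) expect_equal(dim(p), c(97, 133))
  expect_true(all(b$fused_map > 0 & b$fused_map < 1))
  expect_identical(forward(m, x)$fused_map, b$fused_map)
  expect_error(forward(m, array(0.5, c(16, 64, 3))), "receptive stride")
  expect_error(forward(m, matrix(0, 64, 64)))
})

test_that("gradients agree with central differences, including shared layers", {
  set.seed(42)
  m <- tiny_model()
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  Y <- matrix(rbinom(32 * 32, 1, 0.5), 32, 32)
  W <- matrix(runif(32 * 32, 0.5, 3), 32, 32)
  b <- forward(m, x, train = TRUE)
  s <- switch_mask(b$fused_map, Y, 0.99)
  dd <- lapply(b$decoder_maps, function(P) weighted_bce_grad(P, Y, W, s))
  df <- weighted_bce_grad(b$fused_map, Y, W, s)
  g <- myoseg:::backward(m, b, dd, df)
  h <- 1e-5
  # e1.2.w feeds both decoder-1 and the pooling path: its finite-difference
  # gradient checks that gradients accumulate over both consumers
  for (nm in c("e1.2.w", "e2.1.w", "d1.tap.w", "d2.s1.dc.w", "d2.s1.cv.w",
               "d2.out.w", "fuse.w", "e1.1.b", "fuse.b")) {
    p <- m$par[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- m
      m2$par[[nm]][i] <- p[i] + h
      lp <- loss_via_forward(m2, x, Y, W)
      m2$par[[nm]][i] <- p[i] - h
      lm <- loss_via_forward(m2, x, Y, W)
      fd <- (lp - lm) / (2 * h)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("analytic grad %s[%d]", nm, i))
    }
  }
  # the shared layer's gradient is the sum of the per-head path gradients
  gd <- myoseg:::backward(m, b, dd, matrix(0, 32, 32))
  gf <- myoseg:::backward(m, b,
                          lapply(dd, function(d) d * 0), df)
  expect_equal(g[["e1.2.w"]], gd[["e1.2.w"]] + gf[["e1.2.w"]],
               tolerance = 1e-10)
})

test_that("pretrained encoder loading copies matching tensors only", {
  m <- build_model(model_config(width_multiplier = 1, decoder_channels = 2,
                                n_decoders = 2,
                                encoder_widths = list(c(4, 4), c(6, 6))),
                   seed = 1)
  donor <- build_model(model_config(width_multiplier = 1,
                                    decoder_channels = 2, n_decoders = 2,
                                    encoder_widths = list(c(4, 4), c(6, 6))),
                       seed = 99)
  enc <- donor$par[grep("^e", names(donor$par))]
  m2 <- load_pretrained_encoder(m, enc)
  expect_equal(attr(m2, "tensors_loaded"), 8L)  # 4 conv layers: w + b each
  expect_identical(m2$par[["e1.1.w"]], donor$par[["e1.1.w"]])
  expect_identical(m2$par[["d1.tap.w"]], m$par[["d1.tap.w"]])
  # full default model: 13 conv layers -> 26 tensors
  big <- build_model(model_config(width_multiplier = 0.125), seed = 1)
  donor_big <- build_model(model_config(width_multiplier = 0.125), seed = 5)
  expect_equal(attr(load_pretrained_encoder(
    big, donor_big$par[grep("^e", names(donor_big$par))]),
    "tensors_loaded"), 26L)
  # width mismatch is a named error
  narrow <- build_model(model_config(width_multiplier = 0.25), seed = 1)
  expect_error(load_pretrained_encoder(big, narrow$par[grep("^e", names(narrow$par))]),
               "shape mismatch")
  # no source: warning, unchanged
  expect_warning(m3 <- load_pretrained_encoder(m), "no pretrained")
  expect_equal(attr(m3, "tensors_loaded"), 0L)
  expect_identical(m3$par, m$par)
})

test_that("checkpoints round-trip through disk", {
  m <- tiny_model()
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$par, m$par)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(forward(m2, x)$fused_map, forward(m, x)$fused_map)
})
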