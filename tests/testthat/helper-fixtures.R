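# Shared fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

# A tiny two-block network for fast structural/gradient tests.
tiny_config <- function() {
  model_config(width_multiplier = 1, decoder_channels = 4, n_decoders = 2,
               encoder_widths = list(c(4, 4), c(6, 6)))
}

tiny_model <- function(seed = 3) build_model(tiny_config(), seed = seed)

# Small on-disk synthetic dataset (8 train + 2 test images, 96 px).
small_dataset <- function() {
  if (is.null(.fx$small_manifest)) {
    dir <- file.path(tempdir(), "myoseg-small-ds")
    make_dataset(10, c(96, 96), dir, seed = 42,
                 fiber_diameter_range = c(24, 40))
    .fx$small_manifest <- file.path(dir, "manifest.tsv")
  }
  .fx$small_manifest
}

# Total loss recomputed through forward() only, for finite differencing.
loss_via_forward <- function(model, x, Y, W, eta2 = 0.99) {
  b <- forward(model, x)
  s <- switch_mask(b$fused_map, Y, eta2)
  sum(vapply(b$decoder_maps, function(P) weighted_bce(P, Y, W, s), 0)) +
    weighted_bce(b$fused_map, Y, W, s)
}
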