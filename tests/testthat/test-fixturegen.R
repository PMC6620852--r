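test_that("layouts are seeded, packed, and disjoint", {
  # single fibre: label-0 margin all around
  L1 <- generate_layout(1, 64, 64, 2, seed = 5)
  expect_equal(L1$n_fibers, 1)
  expect_true(all(L1$label_image[1, ] == 0))
  expect_true(all(L1$label_image[64, ] == 0))
  expect_true(all(L1$label_image[, 1] == 0))
  expect_true(all(L1$label_image[, 64] == 0))

  # seeded determinism
  expect_identical(generate_layout(12, 128, 96, 3, seed = 9)$label_image,
                   generate_layout(12, 128, 96, 3, seed = 9)$label_image)

  # pairwise disjointness by exhaustive pixel-set intersection
  L <- generate_layout(20, 256, 256, 3, seed = 7)
  pix <- lapply(seq_len(L$n_fibers),
                function(k) which(L$label_image == k))
  for (a in seq_along(pix)) for (b in seq_along(pix)) {
    if (a < b) expect_length(intersect(pix[[a]], pix[[b]]), 0)
  }
  # every fibre 8-connected (one component each)
  for (k in seq_len(L$n_fibers)) {
    comp <- bf_label8(matrix(as.integer(L$label_image == k), 256, 256))
    expect_equal(max(comp), 1)
  }
  # touching fibres separated by a label-0 band: no fibre pixel has an
  # 8-neighbour from a different fibre
  lab <- L$label_image
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    a <- lab[(1 + max(0, di)):(256 + min(0, di)),
             (1 + max(0, dj)):(256 + min(0, dj))]
    b <- lab[(1 - min(0, di)):(256 - max(0, di)),
             (1 - min(0, dj)):(256 - max(0, dj))]
    expect_false(any(a > 0 & b > 0 & a != b))
  }
})

test_that("impossible packings fail loudly", {
  expect_error(generate_layout(5000, 64, 64, 3, seed = 1), "cannot pack")
  expect_error(generate_layout(0, 64, 64, 3, seed = 1))
})

test_that("mask and boundary map are exclusive and reproducible", {
  L <- generate_layout(15, 160, 160, 3, seed = 11)
  m <- layout_mask(L); b <- layout_boundary(L)
  expect_false(any(m == 1 & b == 1))
  expect_true(all(m %in% c(0, 1)) && all(b %in% c(0, 1)))
})

test_that("rendering is seeded and honours the boundary break rate", {
  L <- generate_layout(15, 160, 160, 3, seed = 11)
  flat <- stain_params(hue_jitter = 0, brightness_jitter = 0,
                       texture_noise = 0, boundary_break_rate = 0,
                       nuclei_density = 0)
  img <- render_image(L, flat, seed = 2)
  expect_identical(img, render_image(L, flat, seed = 2))
  # with all jitter off the image is a function of the labels:
  # band pixels carry exactly the boundary colour
  bnd <- which(layout_boundary(L) == 1)
  for (ch in 1:3)
    expect_true(all(img[, , ch][bnd] == flat$boundary_color[ch]))

  # rate 1: no boundary-coloured pixels remain between fibres
  broke <- render_image(L, stain_params(hue_jitter = 0,
                                        brightness_jitter = 0,
                                        texture_noise = 0,
                                        boundary_break_rate = 1,
                                        nuclei_density = 0), seed = 2)
  same_as_bnd <- broke[, , 1][bnd] == flat$boundary_color[1] &
    broke[, , 2][bnd] == flat$boundary_color[2] &
    broke[, , 3][bnd] == flat$boundary_color[3]
  expect_false(any(same_as_bnd))

  # rate 0.3: recoloured count inside the binomial 99% interval
  part <- render_image(L, stain_params(hue_jitter = 0,
                                       brightness_jitter = 0,
                                       texture_noise = 0,
                                       boundary_break_rate = 0.3,
                                       nuclei_density = 0), seed = 4)
  changed <- sum(part[, , 1][bnd] != flat$boundary_color[1] |
                 part[, , 2][bnd] != flat$boundary_color[2] |
                 part[, , 3][bnd] != flat$boundary_color[3])
  B <- length(bnd)
  ci <- qbinom(c(0.005, 0.995), B, 0.3)
  expect_gte(changed, ci[1])
  expect_lte(changed, ci[2])
})

test_that("datasets are written with a correct split and are byte-stable", {
  d1 <- file.path(tempdir(), "myoseg-ds-a")
  d2 <- file.path(tempdir(), "myoseg-ds-b")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- make_dataset(10, c(64, 72), d1, seed = 3,
                     fiber_diameter_range = c(20, 32))
  m2 <- make_dataset(10, c(64, 72), d2, seed = 3,
                     fiber_diameter_range = c(20, 32))
  expect_equal(nrow(m1), 10)
  expect_equal(sum(m1$split == "train"), 8)
  expect_equal(sum(m1$split == "test"), 2)
  expect_true(all(file.exists(file.path(d1, m1$path_image))))
  expect_true(all(file.exists(file.path(d1, m1$path_mask))))
  expect_true(all(file.exists(file.path(d1, m1$path_boundary))))
  # byte-identical rerun: manifest and one image/mask pair
  expect_identical(readBin(file.path(d1, "manifest.tsv"), "raw", 1e6),
                   readBin(file.path(d2, "manifest.tsv"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, m1$path_image[1]), "raw", 1e6),
                   readBin(file.path(d2, m2$path_image[1]), "raw", 1e6))
  # mask and boundary maps on disk are exclusive binary maps
  mk <- read_mask(file.path(d1, m1$path_mask[1]))
  bd <- read_mask(file.path(d1, m1$path_boundary[1]))
  expect_false(any(mk == 1 & bd == 1))
})
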