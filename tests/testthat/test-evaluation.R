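test_that("binarization and labelling match a flood-fill oracle", {
  set.seed(31)
  P <- matrix(runif(30 * 30), 30, 30)
  lab <- binarize_and_label(P, 0.5, min_area = 0)
  want <- bf_label8(matrix(as.integer(P >= 0.5), 30, 30))
  # same partition (labels may renumber): compare co-membership via sizes
  expect_equal(lab > 0, want > 0)
  for (k in seq_len(max(want)))
    expect_equal(length(unique(lab[want == k])), 1)
  # threshold limits
  expect_equal(max(binarize_and_label(P, 0, min_area = 1)) >= 1, TRUE)
  expect_equal(max(binarize_and_label(P, 1 + 1e-9)), 0)
  # min_area filters small components
  Q <- matrix(0, 10, 10); Q[2, 2] <- 1; Q[6:9, 6:9] <- 1
  expect_equal(max(binarize_and_label(Q, 0.5, min_area = 2)), 1)
  expect_equal(max(binarize_and_label(Q, 0.5, min_area = 1)), 2)
})

test_that("per-image metrics follow the stated formulas", {
  # exact prediction
  gt <- matrix(0L, 20, 20); gt[3:8, 3:8] <- 1L; gt[12:18, 12:18] <- 2L
  m <- image_metrics(gt, gt)
  expect_equal(m$precision, 1); expect_equal(m$recall, 1)
  expect_equal(m$f1, 1); expect_equal(m$n_fibres, 2)

  # one 100-px fibre, one 80-px prediction fully inside: P=1, R=0.8, F1=8/9
  gt1 <- matrix(0L, 20, 20); gt1[5:14, 5:14] <- 1L
  pr1 <- matrix(0L, 20, 20); pr1[5:14, 5:12] <- 1L
  m1 <- image_metrics(pr1, gt1)
  expect_equal(m1$precision, 1)
  expect_equal(m1$recall, 0.8)
  expect_equal(m1$f1, 8 / 9)

  # no overlapping prediction: zeros
  pr0 <- matrix(0L, 20, 20); pr0[1:2, 18:20] <- 1L
  m0 <- image_metrics(pr0, gt1)
  expect_equal(c(m0$precision, m0$recall, m0$f1), c(0, 0, 0))

  # permutation invariance of the label ids
  perm <- gt
  perm[gt == 1L] <- 7L; perm[gt == 2L] <- 4L
  mp <- image_metrics(perm, gt)
  expect_equal(c(mp$precision, mp$recall, mp$f1), c(1, 1, 1))

  # random case equals the brute-force recomputation
  set.seed(17)
  for (rep in 1:5) {
    gtr <- bf_label8(matrix(rbinom(400, 1, 0.45), 20, 20))
    prr <- bf_label8(matrix(rbinom(400, 1, 0.45), 20, 20))
    if (max(gtr) == 0) next
    got <- image_metrics(prr, gtr)
    want <- bf_metrics(prr, gtr)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f1, want$f1)
  }

  # nested predictions: recall non-decreasing with predicted area
  small <- matrix(0L, 20, 20); small[6:9, 6:9] <- 1L
  big <- matrix(0L, 20, 20); big[5:12, 5:12] <- 1L
  expect_lte(image_metrics(small, gt1)$recall,
             image_metrics(big, gt1)$recall)

  # zero ground-truth fibres: sentinel with warning
  expect_warning(mz <- image_metrics(gt1, matrix(0L, 20, 20)),
                 "zero ground-truth")
  expect_true(is.na(mz$f1))
})

test_that("FT/DT summaries match exhaustive grid recomputation", {
  set.seed(41)
  grid <- seq(0, 1, by = 0.1)
  maps <- list(); gts <- list()
  for (i in 1:3) {
    L <- generate_layout(6, 64, 64, 3, seed = 50 + i)
    gts[[i]] <- L$label_image
    # noisy probability map correlated with the mask, different sharpness
    # per image so the best thresholds differ
    p <- layout_mask(L) * runif(1, 0.5, 0.9) +
      matrix(runif(64 * 64, 0, 0.35), 64, 64)
    maps[[i]] <- pmin(p, 1)
  }
  ev <- ft_dt_summary(maps, gts, thresholds = grid, min_area = 5)

  # exhaustive recomputation
  f1 <- matrix(0, 3, length(grid))
  pm <- f1; rm_ <- f1
  for (i in 1:3) for (j in seq_along(grid)) {
    met <- image_metrics(binarize_and_label(maps[[i]], grid[j], 5), gts[[i]])
    f1[i, j] <- met$f1; pm[i, j] <- met$precision; rm_[i, j] <- met$recall
  }
  jft <- which.max(colMeans(f1))
  expect_equal(ev$ft_threshold, grid[jft])
  expect_equal(unname(ev$ft["f1", "mean"]), mean(f1[, jft]))
  expect_equal(unname(ev$ft["precision", "sd"]), sd(pm[, jft]))
  jdt <- apply(f1, 1, which.max)
  expect_equal(unname(ev$dt["f1", "mean"]),
               mean(f1[cbind(1:3, jdt)]))
  expect_equal(unname(ev$dt["recall", "mean"]),
               mean(rm_[cbind(1:3, jdt)]))

  # DT never below FT on mean F1
  expect_gte(ev$dt["f1", "mean"], ev$ft["f1", "mean"])

  # single image: FT and DT coincide
  ev1 <- ft_dt_summary(maps[1], gts[1], thresholds = grid, min_area = 5)
  expect_equal(ev1$ft, ev1$dt)

  # report writing
  f <- tempfile(fileext = ".tsv")
  write_eval_report(ev, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$mode), c("FT", "DT"))
})
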