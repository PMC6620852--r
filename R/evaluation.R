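# Per-fibre precision/recall/F1 with fixed-threshold (FT) and
# dynamic-threshold (DT) reporting.
#
# A probability map is binarized at a threshold and 8-connected components of
# at least `min_area` pixels become predicted fibres S. Each ground-truth
# fibre G is matched to the predicted region maximizing |S ∩ G| (ties to the
# lower label id); per fibre, precision = |S∩G|/|S| and recall = |S∩G|/|G|
# (0 without any overlapping prediction). Image-level precision/recall are
# fibre means and F1 = 2PR/(P+R) is computed from those means. FT reports
# metrics at the single grid threshold maximizing mean F1 across the test
# set; DT picks the best-F1 threshold per image, so DT mean F1 >= FT mean F1
# by construction.

#' Binarize a probability map into labelled fibres
#'
#' @param P probability matrix.
#' @param t threshold in `[0, 1]`; pixels with `P >= t` are foreground.
#' @param min_area minimum component area in pixels; smaller 8-connected
#'   components are discarded.
#' @return integer label matrix (0 = background, 1..K = predicted fibres,
#'   labelled consecutively in first-encounter order).
#' @export
binarize_and_label <- function(P, t, min_area = 30) {
  stopifnot(t >= 0, min_area >= 0)
  fg <- matrix(as.integer(P >= t), nrow(P), ncol(P))
  lab <- cpp_label8(fg)
  if (max(lab) == 0) return(lab)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_area)
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

#' Per-fibre metrics for one image
#'
#' @param pred_labels integer label matrix of predicted fibres.
#' @param gt_labels integer label matrix of ground-truth fibres.
#' @return an object of class `fiber_metrics`: list with `precision`,
#'   `recall`, `f1` (image-level, fibre-averaged), `n_fibres` and the
#'   per-fibre table. With zero ground-truth fibres, a sentinel with `NA`
#'   metrics is returned with a warning.
#' @export
image_metrics <- function(pred_labels, gt_labels) {
  stopifnot(all(dim(pred_labels) == dim(gt_labels)))
  gt_ids <- sort(unique(gt_labels[gt_labels > 0]))
  if (length(gt_ids) == 0) {
    warning("image has zero ground-truth fibres; metrics undefined")
    return(structure(list(precision = NA_real_, recall = NA_real_,
                          f1 = NA_real_, n_fibres = 0L, per_fibre = NULL),
                     class = "fiber_metrics"))
  }
  pred_area <- if (max(pred_labels) > 0)
    tabulate(pred_labels[pred_labels > 0], nbins = max(pred_labels))
  else integer(0)
  pf <- matrix(0, length(gt_ids), 2, dimnames = list(NULL, c("p", "r")))
  for (k in seq_along(gt_ids)) {
    sel <- gt_labels == gt_ids[k]
    garea <- sum(sel)
    preds <- pred_labels[sel]
    preds <- preds[preds > 0]
    if (length(preds) > 0) {
      tab <- tabulate(preds)
      s <- which.max(tab)        # ties resolved to the lower label id
      inter <- tab[s]
      pf[k, "p"] <- inter / pred_area[s]
      pf[k, "r"] <- inter / garea
    }
  }
  p <- mean(pf[, "p"]); r <- mean(pf[, "r"])
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(precision = p, recall = r, f1 = f1,
                 n_fibres = length(gt_ids),
                 per_fibre = data.frame(gt = gt_ids, precision = pf[, "p"],
                                        recall = pf[, "r"])),
            class = "fiber_metrics")
}

#' @export
print.fiber_metrics <- function(x, ...) {
  cat(sprintf("<fiber_metrics> P %.3f  R %.3f  F1 %.3f  (%d fibres)\n",
              x$precision, x$recall, x$f1, x$n_fibres))
  invisible(x)
}

#' Fixed- and dynamic-threshold test-set summary
#'
#' Evaluates every probability map over a threshold grid. FT: the single
#' threshold maximizing mean F1 over the test set, metrics reported at it.
#' DT: per-image best-F1 threshold, metrics averaged over images. Reports
#' mean and standard deviation over images for precision, recall and F1 in
#' both modes. Images with zero ground-truth fibres are excluded with a
#' warning.
#'
#' @param prob_maps list of probability matrices (one per test image).
#' @param gt_labels list of ground-truth label matrices, same length.
#' @param thresholds threshold grid covering `[0, 1]`; default 0.01 steps.
#' @param min_area minimum predicted-fibre area; see [binarize_and_label()].
#' @return an object of class `fiber_eval`: list with `ft_threshold`, `ft`
#'   and `dt` (each a 2 x 3 matrix of mean/sd for precision, recall, f1),
#'   `per_image` (long data frame: image, mode, threshold, precision,
#'   recall, f1, n_fibres) and `thresholds`.
#' @export
ft_dt_summary <- function(prob_maps, gt_labels,
                          thresholds = seq(0, 1, by = 0.01), min_area = 30) {
  stopifnot(length(prob_maps) == length(gt_labels), length(prob_maps) >= 1,
            min(thresholds) <= 0 + 1e-9, max(thresholds) >= 1 - 1e-9)
  keep <- vapply(gt_labels, function(g) any(g > 0), TRUE)
  if (!all(keep)) {
    warning(sprintf("excluding %d image(s) with zero ground-truth fibres",
                    sum(!keep)))
    prob_maps <- prob_maps[keep]; gt_labels <- gt_labels[keep]
  }
  if (length(prob_maps) == 0) stop("no evaluable test images")
  ni <- length(prob_maps); nt <- length(thresholds)
  P <- matrix(0, ni, nt); R <- matrix(0, ni, nt); F1 <- matrix(0, ni, nt)
  NF <- integer(ni)
  for (i in seq_len(ni)) {
    for (j in seq_len(nt)) {
      lab <- binarize_and_label(prob_maps[[i]], thresholds[j], min_area)
      m <- image_metrics(lab, gt_labels[[i]])
      P[i, j] <- m$precision; R[i, j] <- m$recall; F1[i, j] <- m$f1
      NF[i] <- m$n_fibres
    }
  }
  ft_j <- which.max(colMeans(F1))
  dt_j <- apply(F1, 1, which.max)
  pick <- function(mat, j_img) mat[cbind(seq_len(ni), j_img)]
  msd <- function(x) c(mean = mean(x), sd = sd(x))
  ft <- rbind(precision = msd(P[, ft_j]), recall = msd(R[, ft_j]),
              f1 = msd(F1[, ft_j]))
  dt <- rbind(precision = msd(pick(P, dt_j)), recall = msd(pick(R, dt_j)),
              f1 = msd(pick(F1, dt_j)))
  per_image <- rbind(
    data.frame(image = seq_len(ni), mode = "FT",
               threshold = thresholds[ft_j], precision = P[, ft_j],
               recall = R[, ft_j], f1 = F1[, ft_j], n_fibres = NF),
    data.frame(image = seq_len(ni), mode = "DT",
               threshold = thresholds[dt_j], precision = pick(P, dt_j),
               recall = pick(R, dt_j), f1 = pick(F1, dt_j), n_fibres = NF))
  structure(list(ft_threshold = thresholds[ft_j], ft = ft, dt = dt,
                 per_image = per_image, thresholds = thresholds),
            class = "fiber_eval")
}

#' @export
print.fiber_eval <- function(x, ...) {
  fmt <- function(m) sprintf("P %.3f±%.3f  R %.3f±%.3f  F1 %.3f±%.3f",
                             m["precision", 1], m["precision", 2],
                             m["recall", 1], m["recall", 2],
                             m["f1", 1], m["f1", 2])
  cat(sprintf("<fiber_eval> FT (t = %.2f): %s\n             DT:            %s\n",
              x$ft_threshold, fmt(x$ft), fmt(x$dt)))
  invisible(x)
}

#' Write a per-image evaluation report
#'
#' @param x a `fiber_eval` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path) {
  stopifnot(inherits(x, "fiber_eval"))
  write.table(x$per_image, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
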