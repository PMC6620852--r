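# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately written as direct transcriptions of the definitions
# (exhaustive loops), not as alternative fast algorithms.

# Exhaustive Euclidean distance to the nearest feature pixel.
bf_distance <- function(feat) {
  H <- nrow(feat); W <- ncol(feat)
  pts <- which(feat == 1, arr.ind = TRUE)
  out <- matrix(Inf, H, W)
  if (nrow(pts) == 0) return(out)
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- sqrt(min((pts[, 1] - i)^2 + (pts[, 2] - j)^2))
  out
}

# Contour pixels by exhaustive neighbourhood scan: mask pixels with a
# 4-neighbour (inside the image) of value 0.
bf_contour <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] != 1) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ni <- i + d[1]; nj <- j + d[2]
      if (ni >= 1 && ni <= H && nj >= 1 && nj <= W && mask[ni, nj] == 0)
        out[i, j] <- TRUE
    }
  }
  out
}

# Flood-fill 8-connected labelling (queue-based, plain R).
bf_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni < 1 || ni > H || nj < 1 || nj > W) next
        if (mask[ni, nj] != 0 && lab[ni, nj] == 0) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# Direct recomputation of per-fibre precision/recall/F1 from the stated
# formulas: each ground-truth fibre G matched to the predicted region S with
# maximal |S intersect G| (ties to lower id), per-fibre P = |S∩G|/|S|,
# R = |S∩G|/|G|, image values are fibre means, F1 from the means.
bf_metrics <- function(pred, gt) {
  ids <- sort(unique(gt[gt > 0]))
  ps <- c(); rs <- c()
  for (g in ids) {
    inter_best <- 0; s_best <- NA
    for (s in sort(unique(pred[pred > 0]))) {
      inter <- sum(pred == s & gt == g)
      if (inter > inter_best) { inter_best <- inter; s_best <- s }
    }
    if (inter_best == 0) { ps <- c(ps, 0); rs <- c(rs, 0) }
    else {
      ps <- c(ps, inter_best / sum(pred == s_best))
      rs <- c(rs, inter_best / sum(gt == g))
    }
  }
  p <- mean(ps); r <- mean(rs)
  list(precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}
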