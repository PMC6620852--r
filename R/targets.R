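# Training targets and the static part of the pixelwise weight-assigning
# function: class-balance term times a boundary-proximity term
#   W_i = C(Y_i)^{-1} * exp(max(epsilon - Omega_i, 0) / eta1)
# where Omega_i is the Euclidean distance of pixel i to the nearest fibre
# contour pixel. The exponential factor equals e^(epsilon/eta1) on the
# contour, decays monotonically with distance, and is exactly 1 for
# Omega_i >= epsilon. The third, dynamic term of the weight function (the
# prediction-gated switch) depends on the network output and lives in
# switch_mask().

# Contour pixels: mask pixels with at least one 4-neighbour of value 0
# inside the image (the image border itself does not create contour).
contour4 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  up    <- rbind(mask[1, , drop = FALSE], mask[-H, , drop = FALSE])
  down  <- rbind(mask[-1, , drop = FALSE], mask[H, , drop = FALSE])
  left  <- cbind(mask[, 1, drop = FALSE], mask[, -W, drop = FALSE])
  right <- cbind(mask[, -1, drop = FALSE], mask[, W, drop = FALSE])
  mask == 1 & (up == 0 | down == 0 | left == 0 | right == 0)
}

#' Derive a boundary map from a fibre mask
#'
#' Marks every pixel whose Euclidean distance to the morphological contour of
#' a fibre region is strictly less than `thickness`. With `thickness = 1`
#' this is exactly the set of contour pixels (mask pixels with a 4-neighbour
#' of the opposite class); larger thickness dilates the contour
#' isotropically, and the result is pixelwise monotone in `thickness`.
#'
#' @param mask binary 0/1 matrix (fibre interior = 1).
#' @param thickness boundary half-width in pixels (>= 1).
#' @return integer 0/1 matrix; all-zero if `mask` has no contour.
#' @export
derive_boundary_map <- function(mask, thickness = 1) {
  stop_if_not_binary(mask, "mask")
  stopifnot(thickness >= 1)
  ct <- contour4(mask)
  if (!any(ct)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- sqrt(cpp_sqedt(matrix(as.integer(ct), nrow(mask), ncol(mask))))
  matrix(as.integer(d < thickness), nrow(mask), ncol(mask))
}

#' Euclidean distance to the nearest fibre contour
#'
#' Exact per-pixel Euclidean distance (pixel centres, squared-distance
#' transform computed exactly) to the nearest contour pixel of `mask`.
#' Contour pixels themselves have distance 0. If the mask has no contour
#' (empty or all-ones), all distances are `Inf`, which downstream weighting
#' treats as "beyond epsilon".
#'
#' @param mask binary 0/1 matrix.
#' @return numeric matrix of distances (possibly `Inf`).
#' @export
distance_to_boundary <- function(mask) {
  stop_if_not_binary(mask, "mask")
  ct <- contour4(mask)
  if (!any(ct)) return(matrix(Inf, nrow(mask), ncol(mask)))
  sqrt(cpp_sqedt(matrix(as.integer(ct), nrow(mask), ncol(mask))))
}

#' Per-class balancing weights
#'
#' Inverse label frequencies over the given crop: the weight of class `c` is
#' `1 / max(freq(c), floor)`. The floor keeps the weight of an absent class
#' finite (it is never applied to any pixel in that case).
#'
#' @param Y binary 0/1 matrix.
#' @param floor lower bound on the frequency (default `1e-6`).
#' @return named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
class_balance <- function(Y, floor = 1e-6) {
  stop_if_not_binary(Y, "Y")
  f1 <- mean(Y == 1)
  c("0" = 1 / max(1 - f1, floor), "1" = 1 / max(f1, floor))
}

#' Static pixel weight map
#'
#' Computes the static (prediction-independent) part of the weight-assigning
#' function: `W_i = C(Y_i)^{-1} * exp(max(epsilon - Omega_i, 0) / eta1)`,
#' where `C(Y_i)` is the label frequency of pixel i's class over the crop and
#' `Omega_i` its distance to the nearest fibre contour. On the contour the
#' exponential factor is `e^(epsilon/eta1)`; at distance `>= epsilon` it is
#' exactly 1, so far-from-boundary pixels carry the pure class-balance
#' weight.
#'
#' @param Y binary 0/1 target matrix.
#' @param eta1 exponential sharpness (> 0); default 5.
#' @param epsilon distance cutoff in pixels (> 0); default 10.
#' @return numeric matrix of positive weights with attributes `eta1` and
#'   `epsilon`.
#' @export
static_weight_map <- function(Y, eta1 = 5, epsilon = 10) {
  stop_if_not_binary(Y, "Y")
  stopifnot(eta1 > 0, epsilon > 0)
  omega <- distance_to_boundary(Y)
  cb <- class_balance(Y)
  cinv <- matrix(cb[as.character(Y)], nrow(Y), ncol(Y))
  w <- cinv * exp(pmax(epsilon - omega, 0) / eta1)
  attr(w, "eta1") <- eta1
  attr(w, "epsilon") <- epsilon
  w
}
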