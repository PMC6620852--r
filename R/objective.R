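# Spatially weighted cross-entropy objective with deep supervision.
#
# Every head (M decoder maps + fused map) carries the same weighted
# binary cross-entropy; the total loss is their unweighted sum. Pixel weights
# combine the precomputed static map (class balance x boundary proximity)
# with a dynamic switch that removes pixels whose ground-truth label the
# network contradicts with high confidence: such pixels keep their forward
# value but contribute neither loss nor gradient.

#' Dynamic switch mask
#'
#' Returns 1 where `|Y_i - P_i| < eta2` and 0 elsewhere. A gated pixel (0) is
#' one whose annotation the network contradicts with probability margin at
#' least `eta2`; its loss and gradient are suppressed, reflecting that thin,
#' broken fibre boundaries make pixel-exact annotation unreliable. `eta2`
#' must exceed 0.5 to mean "the opposite label with high probability"; the
#' default is 0.6.
#'
#' @param P probability matrix in `(0, 1)`.
#' @param Y binary 0/1 matrix.
#' @param eta2 switch threshold in `(0, 1]`.
#' @return integer 0/1 matrix.
#' @export
switch_mask <- function(P, Y, eta2 = 0.6) {
  stopifnot(eta2 > 0, eta2 <= 1, all(dim(P) == dim(Y)))
  matrix(as.integer(abs(Y - P) < eta2), nrow(Y), ncol(Y))
}

#' Weighted binary cross-entropy
#'
#' Computes `-sum_i W_i * s_i * [1(Y_i=1) log P_i + 1(Y_i=0) log(1 - P_i)]`
#' (sum reduction). Probabilities are clamped to `[1e-7, 1 - 1e-7]` before
#' the log. Pixels with `s_i = 0` contribute exactly zero to the value and to
#' the gradient; [weighted_bce_grad()] gives the analytic gradient with
#' respect to the pre-sigmoid logits, `W * s * (P - Y)`.
#'
#' @param P probability matrix.
#' @param Y binary 0/1 matrix.
#' @param W non-negative weight matrix (use `1` for plain cross-entropy).
#' @param switch 0/1 gating matrix; `NULL` means no gating.
#' @return scalar loss (sum over pixels).
#' @export
weighted_bce <- function(P, Y, W = 1, switch = NULL) {
  stopifnot(all(dim(P) == dim(Y)))
  if (is.null(switch)) switch <- 1
  Pc <- clamp(P, 1e-7, 1 - 1e-7)
  -sum(W * switch * (Y * log(Pc) + (1 - Y) * log(1 - Pc)))
}

#' @rdname weighted_bce
#' @export
weighted_bce_grad <- function(P, Y, W = 1, switch = NULL) {
  if (is.null(switch)) switch <- 1
  W * switch * (P - Y)
}

#' Joint multi-head loss
#'
#' Applies the weighted cross-entropy identically to each of the `M` decoder
#' probability maps and to the fused map; the total is their unweighted sum.
#' The dynamic switch is computed once from the fused map and applied to all
#' heads, keeping the heads' supervision consistent.
#'
#' @param bundle a `myoseg_bundle` from [forward()].
#' @param Y binary 0/1 target matrix matching the bundle's spatial size.
#' @param W static weight map (see [static_weight_map()]), or `1`.
#' @param eta2 switch threshold; see [switch_mask()].
#' @param switch optional 0/1 matrix overriding the gate (e.g. all-ones to
#'   disable gating during a warm-up); `NULL` computes it from the fused map.
#' @return an object of class `loss_report`: list with `per_decoder` (M
#'   scalars), `fused`, `total` (their sum), `excluded_fraction` (fraction of
#'   pixels gated off) and `switch` (the gate used).
#' @export
total_loss <- function(bundle, Y, W = 1, eta2 = 0.6, switch = NULL) {
  stopifnot(inherits(bundle, "myoseg_bundle"),
            all(dim(bundle$fused_map) == dim(Y)))
  s <- if (is.null(switch)) switch_mask(bundle$fused_map, Y, eta2)
       else switch
  per_dec <- vapply(bundle$decoder_maps,
                    function(P) weighted_bce(P, Y, W, s), 0)
  fused <- weighted_bce(bundle$fused_map, Y, W, s)
  structure(list(per_decoder = per_dec, fused = fused,
                 total = sum(per_dec) + fused,
                 excluded_fraction = mean(s == 0), switch = s),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf(
    "<loss_report> total %.4g (fused %.4g; decoders %s); %.1f%% pixels gated\n",
    x$total, x$fused, paste(sprintf("%.3g", x$per_decoder), collapse = ", "),
    100 * x$excluded_fraction))
  invisible(x)
}
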