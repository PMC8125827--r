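BCE_EPS <- 1e-7

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a); db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop_invalid("shapes of the two inputs differ")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Binary cross-entropy loss
#'
#' Mean over all elements of `-(t*log(p) + (1-t)*log(1-p))`, with `p` clamped
#' to `[1e-7, 1 - 1e-7]` so the loss stays finite for saturated predictions.
#' Used as the segmentation loss (prediction vs ground truth) and the DAE
#' reconstruction loss (reconstruction vs clean mask).
#'
#' @param p Probability map (values in `[0, 1]`).
#' @param t Binary target of the same shape.
#' @return Non-negative scalar.
#' @export
#' @examples
#' bce_loss(matrix(0.5, 4, 4), matrix(c(0, 1), 4, 4))  # log(2)
bce_loss <- function(p, t) {
  check_same_shape(p, t)
  pc <- pmin(pmax(p, BCE_EPS), 1 - BCE_EPS)
  -mean(t * log(pc) + (1 - t) * log(1 - pc))
}

#' Embedding (latent-coupling) loss
#'
#' Mean squared error between the segmentation encoder's latent features `h`
#' and the DAE encoder's latent features `z`. How its gradient is routed
#' (to the segmentation encoder only, or to both encoders) is decided by the
#' training step's `routing_mode`, not by this function.
#'
#' @param h,z Latent feature arrays of identical shape.
#' @return Non-negative scalar.
#' @export
embedding_loss <- function(h, z) {
  check_same_shape(h, z)
  mean((h - z)^2)
}

#' Soft Dice loss
#'
#' `1 - (2*sum(p*t) + s) / (sum(p) + sum(t) + s)` with smoothing `s`. Used by
#' the reconstruction-regularised baseline as segmentation and reconstruction
#' loss.
#'
#' @param p Probability map.
#' @param t Binary target of the same shape.
#' @param smooth Smoothing constant `s` (default 1).
#' @return Scalar in `[0, 1]` (up to smoothing).
#' @export
dice_loss <- function(p, t, smooth = 1) {
  check_same_shape(p, t)
  1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
}

#' Combine the three loss components
#'
#' @param L_SEG,L_DAE,L_E Finite scalar loss components.
#' @param lambda Non-negative weight of the embedding loss.
#' @return A `loss_bundle` with `L_Total = L_SEG + L_DAE + lambda * L_E`
#'   (exact floating-point identity).
#' @export
total_loss <- function(L_SEG, L_DAE, L_E, lambda = 1) {
  vals <- c(L_SEG = L_SEG, L_DAE = L_DAE, L_E = L_E, lambda = lambda)
  if (any(!is.finite(vals))) rlang::abort("non-finite loss component",
                                          class = "anatseg_numeric_error")
  structure(list(L_SEG = L_SEG, L_DAE = L_DAE, L_E = L_E, lambda = lambda,
                 L_Total = L_SEG + L_DAE + lambda * L_E),
            class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf("L_SEG=%.5f L_DAE=%.5f L_E=%.5f (lambda=%.3g) L_Total=%.5f\n",
              x$L_SEG, x$L_DAE, x$L_E, x$lambda, x$L_Total))
  invisible(x)
}

# --- analytic gradients used by the training steps -------------------------

# d(BCE)/d(logit) with p = sigmoid(logit): (p - t) / n
bce_dlogits <- function(p, t) (p - t) / length(p)

# d(Dice)/d(p): -(2 t D - N) / D^2 with N = 2*sum(pt)+s, D = sum(p)+sum(t)+s
dice_dprob <- function(p, t, smooth = 1) {
  N <- 2 * sum(p * t) + smooth
  D <- sum(p) + sum(t) + smooth
  -(2 * t * D - N) / D^2
}

# d(MSE)/d(h) for embedding_loss
mse_dh <- function(h, z) 2 * (h - z) / length(h)
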