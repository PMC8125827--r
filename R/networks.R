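# Network construction and manual forward/backward passes.
#
# A network is a named list of layers; each layer holds its weights as the
# matrix layout expected by the C++ kernels ((k*k*in) x out for convolutions,
# (4*out) x in for the 2x2 stride-2 transposed convolution). Backward passes
# mirror the forwards exactly and are validated against finite differences in
# the test suite. Parameter groups (encoder vs decoder) are identified by
# layer name prefix, which is what the gradient-routing contract and the
# optimizer rely on.

new_conv_layer <- function(in_ch, out_ch, k, relu) {
  fan_in <- k * k * in_ch
  lim <- sqrt(6 / fan_in)                      # Kaiming-uniform, fan-in mode
  list(type = "conv", k = k, in_ch = in_ch, out_ch = out_ch, relu = relu,
       W = matrix(runif(fan_in * out_ch, -lim, lim), fan_in, out_ch),
       b = rep(0, out_ch))
}

new_deconv_layer <- function(in_ch, out_ch, relu) {
  lim <- sqrt(6 / in_ch)
  list(type = "deconv", k = 2, in_ch = in_ch, out_ch = out_ch, relu = relu,
       W = matrix(runif(4 * out_ch * in_ch, -lim, lim), 4 * out_ch, in_ch),
       b = rep(0, out_ch))
}

#' Build the U-Net segmentation network
#'
#' Encoder: `depth` blocks of (conv3x3, conv3x3, maxpool2x2) with ReLU;
#' bottleneck: two conv3x3 producing the latent feature map `h`; decoder:
#' mirrored blocks of (deconv2x2, skip concatenation, conv3x3, conv3x3);
#' head: conv1x1 + sigmoid giving a one-channel probability map at input
#' resolution. Weights use seeded Kaiming-uniform initialisation; no batch
#' normalisation.
#'
#' @param spec A [network_spec()] with `skip_connections = TRUE`.
#' @param seed Integer seed for weight initialisation.
#' @return An `anatseg_network` of kind `"seg"`, exposing the encoder
#'   `f_SEG` (image to latent `h`) and decoder `g_SEG` (latent to probability
#'   map) through [net_forward()].
#' @export
build_segmentation_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  if (!spec$skip_connections)
    stop_invalid("segmentation network requires skip_connections = TRUE")
  ch <- spec$base_kernels * 2^(seq_len(spec$depth) - 1)
  layers <- list()
  with_seed(seed, {
    prev <- 1L
    for (d in seq_len(spec$depth)) {
      layers[[sprintf("enc%d_conv1", d)]] <- new_conv_layer(prev, ch[d], 3, TRUE)
      layers[[sprintf("enc%d_conv2", d)]] <- new_conv_layer(ch[d], ch[d], 3, TRUE)
      prev <- ch[d]
    }
    layers[["bott_conv1"]] <- new_conv_layer(prev, spec$bottleneck_kernels, 3, TRUE)
    layers[["bott_conv2"]] <- new_conv_layer(spec$bottleneck_kernels,
                                             spec$bottleneck_kernels, 3, TRUE)
    prev <- spec$bottleneck_kernels
    for (d in rev(seq_len(spec$depth))) {
      layers[[sprintf("dec%d_deconv", d)]] <- new_deconv_layer(prev, ch[d], TRUE)
      layers[[sprintf("dec%d_conv1", d)]] <- new_conv_layer(2 * ch[d], ch[d], 3, TRUE)
      layers[[sprintf("dec%d_conv2", d)]] <- new_conv_layer(ch[d], ch[d], 3, TRUE)
      prev <- ch[d]
    }
    layers[["out_conv"]] <- new_conv_layer(prev, 1L, 1, FALSE)
  })
  structure(list(kind = "seg", spec = spec, layers = layers),
            class = "anatseg_network")
}

#' Build the denoising autoencoder
#'
#' Encoder: `depth` blocks of a single conv3x3 + maxpool2x2; bottleneck: one
#' conv3x3 producing the latent `z`; decoder: per block a deconv2x2 (keeping
#' channels) followed by a conv3x3 halving them; head: conv1x1 + sigmoid. No
#' skip connections, so all information must pass through the latent space.
#'
#' @param spec A [network_spec()] with `skip_connections = FALSE`.
#' @param seed Integer seed for weight initialisation.
#' @return An `anatseg_network` of kind `"dae"` (encoder `f_DAE`, decoder
#'   `g_DAE`).
#' @export
build_dae <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$skip_connections)
    stop_invalid("DAE requires skip_connections = FALSE")
  ch <- spec$base_kernels * 2^(seq_len(spec$depth) - 1)
  layers <- list()
  with_seed(seed, {
    prev <- 1L
    for (d in seq_len(spec$depth)) {
      layers[[sprintf("enc%d_conv", d)]] <- new_conv_layer(prev, ch[d], 3, TRUE)
      prev <- ch[d]
    }
    layers[["z_conv"]] <- new_conv_layer(prev, spec$bottleneck_kernels, 3, TRUE)
    prev <- spec$bottleneck_kernels
    for (d in rev(seq_len(spec$depth))) {
      layers[[sprintf("dec%d_deconv", d)]] <- new_deconv_layer(prev, prev, TRUE)
      layers[[sprintf("dec%d_conv", d)]] <- new_conv_layer(prev, ch[d], 3, TRUE)
      prev <- ch[d]
    }
    layers[["out_conv"]] <- new_conv_layer(prev, 1L, 1, FALSE)
  })
  structure(list(kind = "dae", spec = spec, layers = layers),
            class = "anatseg_network")
}

#' Encoder/decoder parameter groups of a network
#'
#' @param net An `anatseg_network`.
#' @return List with character vectors `encoder` and `decoder` of layer
#'   names. For the segmentation network the encoder group is
#'   `theta_fSEG` (encoder blocks + bottleneck, i.e. everything producing
#'   `h`), the decoder group `theta_gSEG`; analogously `theta_fDAE` /
#'   `theta_gDAE` for the DAE.
#' @export
param_groups <- function(net) {
  nm <- names(net$layers)
  enc <- nm[grepl("^enc|^bott|^z_conv", nm)]
  dec <- nm[grepl("^dec|^out_conv", nm)]
  list(encoder = enc, decoder = dec)
}

#' Snapshot of all network parameters
#'
#' @param net An `anatseg_network`.
#' @return Named list of `list(W, b)` per layer, suitable for `identical()`
#'   comparison between training trajectories.
#' @export
parameter_snapshot <- function(net) {
  lapply(net$layers, function(l) list(W = l$W, b = l$b))
}

as_input_cube <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L)) else x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass through a network
#'
#' @param net An `anatseg_network` (segmentation net or DAE).
#' @param x Input image or mask as an H x W matrix (values in `[0,1]`).
#' @param keep_cache Keep intermediate activations for a subsequent backward
#'   pass.
#' @param record_shapes Also record every layer's output feature-map shape.
#' @return List with `prob` (H x W probability matrix), `latent` (the
#'   bottleneck feature map, `h` for the segmentation net, `z` for the DAE),
#'   `cache` (when requested) and `shapes` (tibble, when requested).
#' @export
net_forward <- function(net, x, keep_cache = FALSE, record_shapes = FALSE) {
  if (net$kind == "seg") seg_forward(net, x, keep_cache, record_shapes)
  else dae_forward(net, x, keep_cache, record_shapes)
}

rec_shape <- function(shapes, name, a) {
  shapes[[length(shapes) + 1L]] <- tibble::tibble(
    layer = name, height = dim(a)[1], width = dim(a)[2], channels = dim(a)[3])
  shapes
}

seg_forward <- function(net, x, keep_cache = FALSE, record_shapes = FALSE) {
  L <- net$layers
  depth <- net$spec$depth
  a <- as_input_cube(x)
  if (any(dim(a)[1:2] != net$spec$input_size))
    stop_invalid("input size does not match network spec")
  cache <- list(input = a)
  shapes <- list()
  for (d in seq_len(depth)) {
    n1 <- sprintf("enc%d_conv1", d); n2 <- sprintf("enc%d_conv2", d)
    c1 <- .conv2d_fwd(a, L[[n1]]$W, L[[n1]]$b, 3L, TRUE)
    c2 <- .conv2d_fwd(c1, L[[n2]]$W, L[[n2]]$b, 3L, TRUE)
    pl <- .maxpool2_fwd(c2)
    cache[[n1]] <- list(x = a, out = c1)
    cache[[n2]] <- list(x = c1, out = c2)
    cache[[sprintf("pool%d", d)]] <- list(idx = pl$idx, H = dim(c2)[1], W = dim(c2)[2])
    cache[[sprintf("skip%d", d)]] <- c2
    if (record_shapes) {
      shapes <- rec_shape(shapes, n1, c1)
      shapes <- rec_shape(shapes, n2, c2)
      shapes <- rec_shape(shapes, sprintf("enc%d_pool", d), pl$out)
    }
    a <- pl$out
  }
  b1 <- .conv2d_fwd(a, L$bott_conv1$W, L$bott_conv1$b, 3L, TRUE)
  h <- .conv2d_fwd(b1, L$bott_conv2$W, L$bott_conv2$b, 3L, TRUE)
  cache$bott_conv1 <- list(x = a, out = b1)
  cache$bott_conv2 <- list(x = b1, out = h)
  if (record_shapes) {
    shapes <- rec_shape(shapes, "bott_conv1", b1)
    shapes <- rec_shape(shapes, "bott_conv2", h)
  }
  a <- h
  for (d in rev(seq_len(depth))) {
    nd <- sprintf("dec%d_deconv", d)
    n1 <- sprintf("dec%d_conv1", d); n2 <- sprintf("dec%d_conv2", d)
    u <- .deconv2_fwd(a, L[[nd]]$W, L[[nd]]$b, TRUE)
    sk <- cache[[sprintf("skip%d", d)]]
    cs <- dim(sk)[3]; cu <- dim(u)[3]
    cat_ <- array(0, c(dim(u)[1], dim(u)[2], cs + cu))
    cat_[, , seq_len(cs)] <- sk
    cat_[, , cs + seq_len(cu)] <- u
    c1 <- .conv2d_fwd(cat_, L[[n1]]$W, L[[n1]]$b, 3L, TRUE)
    c2 <- .conv2d_fwd(c1, L[[n2]]$W, L[[n2]]$b, 3L, TRUE)
    cache[[nd]] <- list(x = a, out = u)
    cache[[n1]] <- list(x = cat_, out = c1)
    cache[[n2]] <- list(x = c1, out = c2)
    if (record_shapes) {
      shapes <- rec_shape(shapes, nd, u)
      shapes <- rec_shape(shapes, n1, c1)
      shapes <- rec_shape(shapes, n2, c2)
    }
    a <- c2
  }
  logits <- .conv2d_fwd(a, L$out_conv$W, L$out_conv$b, 1L, FALSE)
  cache$out_conv <- list(x = a, out = logits)
  prob <- sigmoid(logits[, , 1])
  if (record_shapes) shapes <- rec_shape(shapes, "out_conv", logits)
  res <- list(prob = prob, latent = h)
  if (keep_cache) res$cache <- cache
  if (record_shapes) res$shapes <- dplyr::bind_rows(shapes)
  res
}

# Backward through the segmentation network.
# dlogits: gradient w.r.t. the pre-sigmoid output (H x W matrix or cube).
# dlatent: optional extra gradient injected at h (the embedding-loss term);
# it reaches only encoder parameters because h is produced by the encoder.
seg_backward <- function(net, cache, dlogits, dlatent = NULL) {
  L <- net$layers
  depth <- net$spec$depth
  grads <- list()
  dl <- if (is.matrix(dlogits)) array(dlogits, c(dim(dlogits), 1L)) else dlogits
  bw <- .conv2d_bwd(cache$out_conv$x, L$out_conv$W, cache$out_conv$out, dl, 1L, FALSE)
  grads$out_conv <- list(W = bw$dW, b = bw$db)
  da <- bw$dx
  dskips <- list()
  for (d in seq_len(depth)) {
    n2 <- sprintf("dec%d_conv2", d); n1 <- sprintf("dec%d_conv1", d)
    nd <- sprintf("dec%d_deconv", d)
    bw <- .conv2d_bwd(cache[[n2]]$x, L[[n2]]$W, cache[[n2]]$out, da, 3L, TRUE)
    grads[[n2]] <- list(W = bw$dW, b = bw$db)
    bw <- .conv2d_bwd(cache[[n1]]$x, L[[n1]]$W, cache[[n1]]$out, bw$dx, 3L, TRUE)
    grads[[n1]] <- list(W = bw$dW, b = bw$db)
    cs <- dim(cache[[sprintf("skip%d", d)]])[3]
    dcat <- bw$dx
    dskips[[d]] <- dcat[, , seq_len(cs), drop = FALSE]
    du <- dcat[, , cs + seq_len(dim(dcat)[3] - cs), drop = FALSE]
    bw <- .deconv2_bwd(cache[[nd]]$x, L[[nd]]$W, cache[[nd]]$out, du, TRUE)
    grads[[nd]] <- list(W = bw$dW, b = bw$db)
    da <- bw$dx
  }
  if (!is.null(dlatent)) da <- da + dlatent
  bw <- .conv2d_bwd(cache$bott_conv2$x, L$bott_conv2$W, cache$bott_conv2$out, da, 3L, TRUE)
  grads$bott_conv2 <- list(W = bw$dW, b = bw$db)
  bw <- .conv2d_bwd(cache$bott_conv1$x, L$bott_conv1$W, cache$bott_conv1$out, bw$dx, 3L, TRUE)
  grads$bott_conv1 <- list(W = bw$dW, b = bw$db)
  da <- bw$dx
  for (d in rev(seq_len(depth))) {
    n2 <- sprintf("enc%d_conv2", d); n1 <- sprintf("enc%d_conv1", d)
    pl <- cache[[sprintf("pool%d", d)]]
    dc2 <- .maxpool2_bwd(pl$idx, da, pl$H, pl$W)
    dc2 <- dc2 + dskips[[d]]
    bw <- .conv2d_bwd(cache[[n2]]$x, L[[n2]]$W, cache[[n2]]$out, dc2, 3L, TRUE)
    grads[[n2]] <- list(W = bw$dW, b = bw$db)
    bw <- .conv2d_bwd(cache[[n1]]$x, L[[n1]]$W, cache[[n1]]$out, bw$dx, 3L, TRUE)
    grads[[n1]] <- list(W = bw$dW, b = bw$db)
    da <- bw$dx
  }
  list(grads = grads, dx = da)
}

dae_forward <- function(net, x, keep_cache = FALSE, record_shapes = FALSE) {
  L <- net$layers
  depth <- net$spec$depth
  a <- as_input_cube(x)
  if (any(dim(a)[1:2] != net$spec$input_size))
    stop_invalid("input size does not match network spec")
  cache <- list(input = a)
  shapes <- list()
  for (d in seq_len(depth)) {
    n1 <- sprintf("enc%d_conv", d)
    c1 <- .conv2d_fwd(a, L[[n1]]$W, L[[n1]]$b, 3L, TRUE)
    pl <- .maxpool2_fwd(c1)
    cache[[n1]] <- list(x = a, out = c1)
    cache[[sprintf("pool%d", d)]] <- list(idx = pl$idx, H = dim(c1)[1], W = dim(c1)[2])
    if (record_shapes) {
      shapes <- rec_shape(shapes, n1, c1)
      shapes <- rec_shape(shapes, sprintf("enc%d_pool", d), pl$out)
    }
    a <- pl$out
  }
  z <- .conv2d_fwd(a, L$z_conv$W, L$z_conv$b, 3L, TRUE)
  cache$z_conv <- list(x = a, out = z)
  if (record_shapes) shapes <- rec_shape(shapes, "z_conv", z)
  a <- z
  for (d in rev(seq_len(depth))) {
    nd <- sprintf("dec%d_deconv", d); n1 <- sprintf("dec%d_conv", d)
    u <- .deconv2_fwd(a, L[[nd]]$W, L[[nd]]$b, TRUE)
    c1 <- .conv2d_fwd(u, L[[n1]]$W, L[[n1]]$b, 3L, TRUE)
    cache[[nd]] <- list(x = a, out = u)
    cache[[n1]] <- list(x = u, out = c1)
    if (record_shapes) {
      shapes <- rec_shape(shapes, nd, u)
      shapes <- rec_shape(shapes, n1, c1)
    }
    a <- c1
  }
  logits <- .conv2d_fwd(a, L$out_conv$W, L$out_conv$b, 1L, FALSE)
  cache$out_conv <- list(x = a, out = logits)
  if (record_shapes) shapes <- rec_shape(shapes, "out_conv", logits)
  res <- list(prob = sigmoid(logits[, , 1]), latent = z)
  if (keep_cache) res$cache <- cache
  if (record_shapes) res$shapes <- dplyr::bind_rows(shapes)
  res
}

# Backward through the DAE. dlogits may be NULL (no reconstruction-loss
# gradient), dlatent injects the embedding-loss gradient at z (mode BI).
# stop_at_latent = TRUE limits the pass to the decoder (gradients w.r.t.
# encoder parameters are then structurally zero).
dae_backward <- function(net, cache, dlogits, dlatent = NULL,
                         stop_at_latent = FALSE) {
  L <- net$layers
  depth <- net$spec$depth
  grads <- list()
  if (!is.null(dlogits)) {
    dl <- if (is.matrix(dlogits)) array(dlogits, c(dim(dlogits), 1L)) else dlogits
    bw <- .conv2d_bwd(cache$out_conv$x, L$out_conv$W, cache$out_conv$out, dl, 1L, FALSE)
    grads$out_conv <- list(W = bw$dW, b = bw$db)
    da <- bw$dx
    for (d in seq_len(depth)) {
      n1 <- sprintf("dec%d_conv", d); nd <- sprintf("dec%d_deconv", d)
      bw <- .conv2d_bwd(cache[[n1]]$x, L[[n1]]$W, cache[[n1]]$out, da, 3L, TRUE)
      grads[[n1]] <- list(W = bw$dW, b = bw$db)
      bw <- .deconv2_bwd(cache[[nd]]$x, L[[nd]]$W, cache[[nd]]$out, bw$dx, TRUE)
      grads[[nd]] <- list(W = bw$dW, b = bw$db)
      da <- bw$dx
    }
  } else {
    da <- NULL
  }
  dz <- da
  if (!is.null(dlatent)) dz <- if (is.null(dz)) dlatent else dz + dlatent
  if (stop_at_latent || is.null(dz)) return(list(grads = grads, dlatent_in = dz))
  bw <- .conv2d_bwd(cache$z_conv$x, L$z_conv$W, cache$z_conv$out, dz, 3L, TRUE)
  grads$z_conv <- list(W = bw$dW, b = bw$db)
  da <- bw$dx
  for (d in rev(seq_len(depth))) {
    n1 <- sprintf("enc%d_conv", d)
    pl <- cache[[sprintf("pool%d", d)]]
    dc <- .maxpool2_bwd(pl$idx, da, pl$H, pl$W)
    bw <- .conv2d_bwd(cache[[n1]]$x, L[[n1]]$W, cache[[n1]]$out, dc, 3L, TRUE)
    grads[[n1]] <- list(W = bw$dW, b = bw$db)
    da <- bw$dx
  }
  list(grads = grads, dx = da)
}

# Encoder-only passes of the DAE (used by the two-stage baselines, where the
# pre-trained encoder projects predictions and labels into the shape space).
dae_encode <- function(net, x, keep_cache = FALSE) {
  L <- net$layers
  depth <- net$spec$depth
  a <- as_input_cube(x)
  cache <- list()
  for (d in seq_len(depth)) {
    n1 <- sprintf("enc%d_conv", d)
    c1 <- .conv2d_fwd(a, L[[n1]]$W, L[[n1]]$b, 3L, TRUE)
    pl <- .maxpool2_fwd(c1)
    cache[[n1]] <- list(x = a, out = c1)
    cache[[sprintf("pool%d", d)]] <- list(idx = pl$idx, H = dim(c1)[1], W = dim(c1)[2])
    a <- pl$out
  }
  z <- .conv2d_fwd(a, L$z_conv$W, L$z_conv$b, 3L, TRUE)
  cache$z_conv <- list(x = a, out = z)
  res <- list(latent = z)
  if (keep_cache) res$cache <- cache
  res
}

# Gradient of the encoder output w.r.t. the encoder *input* (parameters are
# not of interest here: the baselines keep the DAE frozen, but the loss
# gradient must flow through it into the segmentation prediction).
dae_encode_backward_input <- function(net, cache, dlatent) {
  L <- net$layers
  depth <- net$spec$depth
  bw <- .conv2d_bwd(cache$z_conv$x, L$z_conv$W, cache$z_conv$out, dlatent, 3L, TRUE)
  da <- bw$dx
  for (d in rev(seq_len(depth))) {
    n1 <- sprintf("enc%d_conv", d)
    pl <- cache[[sprintf("pool%d", d)]]
    dc <- .maxpool2_bwd(pl$idx, da, pl$H, pl$W)
    bw <- .conv2d_bwd(cache[[n1]]$x, L[[n1]]$W, cache[[n1]]$out, dc, 3L, TRUE)
    da <- bw$dx
  }
  da
}

# Decoder-only forward of the DAE from a given latent feature map.
dae_decode <- function(net, z) {
  L <- net$layers
  depth <- net$spec$depth
  a <- z
  for (d in rev(seq_len(depth))) {
    nd <- sprintf("dec%d_deconv", d); n1 <- sprintf("dec%d_conv", d)
    a <- .deconv2_fwd(a, L[[nd]]$W, L[[nd]]$b, TRUE)
    a <- .conv2d_fwd(a, L[[n1]]$W, L[[n1]]$b, 3L, TRUE)
  }
  logits <- .conv2d_fwd(a, L$out_conv$W, L$out_conv$b, 1L, FALSE)
  sigmoid(logits[, , 1])
}

#' Composite diagnostic head: segmentation encoder + DAE decoder
#'
#' Decodes the segmentation encoder's latent features with the DAE decoder
#' (`f_SEG -> g_DAE`). After successful joint training this pathway produces
#' segmentations comparable to the main head, evidencing that the
#' segmentation encoder embeds images into the anatomical feature space
#' learned by the DAE. Inspection only; it is never trained directly.
#'
#' @param x Input image (H x W matrix).
#' @param seg Trained segmentation network.
#' @param dae Trained DAE with a latent shape matching the segmentation
#'   network's.
#' @return H x W probability matrix.
#' @export
composite_forward <- function(x, seg, dae) {
  stopifnot(inherits(seg, "anatseg_network"), inherits(dae, "anatseg_network"))
  if (!identical(latent_shape(seg), latent_shape(dae)))
    stop_invalid("latent shapes of segmentation network and DAE differ")
  h <- seg_forward(seg, x)$latent
  dae_decode(dae, h)
}

#' Latent feature-map shape of a network
#'
#' @param net An `anatseg_network`.
#' @return Integer vector `c(H, W, C)` of the bottleneck feature map.
#' @export
latent_shape <- function(net) {
  c(net$spec$input_size %/% 2L^net$spec$depth, net$spec$bottleneck_kernels)
}

#' @export
print.anatseg_network <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0))
  cat(sprintf("<anatseg_network:%s> %d layers, %s parameters, latent %s\n",
              x$kind, length(x$layers), format(np, big.mark = ","),
              paste(latent_shape(x), collapse = "x")))
  invisible(x)
}
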