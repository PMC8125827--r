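#' Training configuration
#'
#' @param optimizer `"adam"` or `"adamp"`. Adam (beta 0.9/0.999) is the
#'   implemented optimizer; `"adamp"` is accepted in configurations and mapped
#'   to Adam with the configured weight decay — a documented limitation.
#' @param learning_rate Positive step size (reference protocol: 1e-4).
#' @param weight_decay Non-negative L2 penalty added to gradients.
#' @param epochs Number of passes over the training split (reference: 120).
#' @param batch_size Mini-batch size (default 8).
#' @param lambda Weight of the embedding loss in the total objective.
#' @param routing_mode `"UN"`: the embedding-loss gradient updates only the
#'   segmentation encoder (the DAE side is treated as a constant). `"BI"`:
#'   it also updates the DAE encoder. Decoders never receive it.
#' @param seed Integer seed driving initialisation, shuffling, augmentation
#'   and mask corruption through separate derived streams.
#' @param flip_prob Salt-and-pepper corruption level for the DAE input.
#' @param augment An [augment_config()] or `NULL` to disable augmentation.
#' @param hist_eq Apply histogram equalization to images before training.
#' @return A `train_config` object.
#' @export
train_config <- function(optimizer = c("adam", "adamp"), learning_rate = 1e-4,
                         weight_decay = 0, epochs = 120L, batch_size = 8L,
                         lambda = 1, routing_mode = c("UN", "BI"), seed = 1L,
                         flip_prob = 0.1, augment = augment_config(),
                         hist_eq = TRUE) {
  optimizer <- match.arg(optimizer)
  routing_mode <- match.arg(routing_mode)
  if (learning_rate <= 0) stop_invalid("`learning_rate` must be positive")
  if (epochs < 1L) stop_invalid("`epochs` must be at least 1")
  if (lambda < 0) stop_invalid("`lambda` must be non-negative")
  if (weight_decay < 0) stop_invalid("`weight_decay` must be non-negative")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lambda = lambda,
                 routing_mode = routing_mode, seed = as.integer(seed),
                 flip_prob = flip_prob, augment = augment,
                 hist_eq = isTRUE(hist_eq)),
            class = "train_config")
}

#' Baseline / method configuration
#'
#' @param method `"proposed"` (single-stage joint training), `"unet"` (plain
#'   segmentation network), `"acnn"` (two-stage: pre-trained autoencoder,
#'   frozen, MSE shape regularisation on latent projections) or `"srm"`
#'   (two-stage with Dice segmentation/reconstruction losses and a BCE shape
#'   regulariser on squashed latents).
#' @param shape_reg_weight Weight of the shape-regularisation term
#'   (reference value 0.01).
#' @param recon_weight Weight of the reconstruction term for `"srm"`
#'   (reference value 0.001).
#' @param pretrain_epochs DAE pre-training epochs for the two-stage methods.
#' @return A `baseline_config` object.
#' @export
baseline_config <- function(method = c("proposed", "unet", "acnn", "srm"),
                            shape_reg_weight = 0.01, recon_weight = 0.001,
                            pretrain_epochs = 60L) {
  method <- match.arg(method)
  if (shape_reg_weight < 0 || recon_weight < 0)
    stop_invalid("loss weights must be non-negative")
  structure(list(method = method, shape_reg_weight = shape_reg_weight,
                 recon_weight = recon_weight,
                 pretrain_epochs = as.integer(pretrain_epochs)),
            class = "baseline_config")
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(net) {
  st <- lapply(net$layers, function(l) {
    list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
         mb = rep(0, length(l$b)), vb = rep(0, length(l$b)))
  })
  list(t = 0L, layers = st)
}

adam_update <- function(net, grads, state, lr, wd = 0,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    l <- net$layers[[nm]]
    s <- state$layers[[nm]]
    gW <- g$W + wd * l$W
    gb <- g$b + wd * l$b
    s$mW <- beta1 * s$mW + (1 - beta1) * gW
    s$vW <- beta2 * s$vW + (1 - beta2) * gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * gb
    s$vb <- beta2 * s$vb + (1 - beta2) * gb^2
    net$layers[[nm]]$W <- l$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net$layers[[nm]]$b <- l$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state$layers[[nm]] <- s
  }
  list(net = net, state = state)
}

acc_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) {
    if (is.null(total[[nm]])) total[[nm]] <- g[[nm]]
    else {
      total[[nm]]$W <- total[[nm]]$W + g[[nm]]$W
      total[[nm]]$b <- total[[nm]]$b + g[[nm]]$b
    }
  }
  total
}

zero_grads_like <- function(net, names_ = names(net$layers)) {
  setNames(lapply(names_, function(nm) {
    l <- net$layers[[nm]]
    list(W = array(0, dim(l$W)), b = rep(0, length(l$b)))
  }), names_)
}

# --- joint training step ---------------------------------------------------

#' One optimizer step of single-stage joint training
#'
#' For every pair `(x, y)` in the batch the step computes the segmentation
#' prediction `x' = g_SEG(f_SEG(x))`, a freshly corrupted mask `y~`, the DAE
#' reconstruction `y' = g_DAE(f_DAE(y~))`, and the three losses
#' `L_SEG = BCE(x', y)`, `L_DAE = BCE(y', y)`, `L_E = MSE(h, z)`; it then
#' takes one Adam step on `L_Total = L_SEG + L_DAE + lambda * L_E`.
#'
#' Gradient routing: `L_SEG` reaches only the segmentation network, `L_DAE`
#' only the DAE, and the embedding term reaches the segmentation encoder
#' always, the DAE encoder only in mode `"BI"`, and no decoder ever.
#' Mask corruption draws from the current RNG stream (fresh noise per call).
#'
#' @param batch List of samples, each a list with `x` (image matrix) and `y`
#'   (binary mask matrix).
#' @param models List with `seg` and (unless training a plain U-Net) `dae`
#'   networks with matching latent shapes.
#' @param cfg A [train_config()].
#' @param opt_state Optimizer state list with elements `seg`, `dae` (created
#'   with defaults when `NULL`).
#' @return List with updated `models`, `opt_state`, and `losses` (a
#'   [total_loss()] bundle averaged over the batch).
#' @export
joint_train_step <- function(batch, models, cfg, opt_state = NULL) {
  if (length(batch) == 0L) stop_invalid("batch must be non-empty")
  seg <- models$seg
  dae <- models$dae
  if (!is.null(dae) && !identical(latent_shape(seg), latent_shape(dae)))
    stop_invalid("latent shapes of segmentation network and DAE differ")
  if (is.null(opt_state))
    opt_state <- list(seg = adam_init(seg),
                      dae = if (!is.null(dae)) adam_init(dae))
  nb <- length(batch)
  gseg <- NULL; gdae <- NULL
  L_SEG <- 0; L_DAE <- 0; L_E <- 0
  for (s in batch) {
    sf <- seg_forward(seg, s$x, keep_cache = TRUE)
    L_SEG <- L_SEG + bce_loss(sf$prob, s$y) / nb
    dlog_seg <- bce_dlogits(sf$prob, s$y) / nb
    dlat_seg <- NULL
    if (!is.null(dae)) {
      yt <- corrupt_mask(s$y, corruption_config(cfg$flip_prob))
      df <- dae_forward(dae, yt, keep_cache = TRUE)
      L_DAE <- L_DAE + bce_loss(df$prob, s$y) / nb
      L_E <- L_E + embedding_loss(sf$latent, df$latent) / nb
      dlat_seg <- cfg$lambda * mse_dh(sf$latent, df$latent) / nb
      dlog_dae <- bce_dlogits(df$prob, s$y) / nb
      dlat_dae <- if (cfg$routing_mode == "BI")
        cfg$lambda * mse_dh(df$latent, sf$latent) / nb else NULL
      gdae <- acc_grads(gdae, dae_backward(dae, df$cache, dlog_dae, dlat_dae)$grads)
    }
    gseg <- acc_grads(gseg, seg_backward(seg, sf$cache, dlog_seg, dlat_seg)$grads)
  }
  losses <- total_loss(L_SEG, L_DAE, L_E, cfg$lambda)
  if (!is.finite(losses$L_Total))
    rlang::abort(sprintf("non-finite loss (L_SEG=%g L_DAE=%g L_E=%g)",
                         L_SEG, L_DAE, L_E), class = "anatseg_numeric_error")
  up <- adam_update(seg, gseg, opt_state$seg, cfg$learning_rate, cfg$weight_decay)
  seg <- up$net; opt_state$seg <- up$state
  if (!is.null(dae)) {
    up <- adam_update(dae, gdae, opt_state$dae, cfg$learning_rate, cfg$weight_decay)
    dae <- up$net; opt_state$dae <- up$state
  }
  list(models = list(seg = seg, dae = dae), opt_state = opt_state,
       losses = losses)
}

#' Per-parameter gradients of the embedding-loss term alone
#'
#' Computes the gradients of `lambda * L_E` with respect to every parameter
#' of both networks, under the requested routing mode, with the other loss
#' terms switched off. Gradients that the routing contract forbids (both
#' decoders always; the DAE encoder in mode `"UN"`) are exactly zero.
#'
#' @param batch List of `(x, y)` samples (masks are corrupted with
#'   `cfg$flip_prob` for the DAE input).
#' @param models List with `seg` and `dae` networks.
#' @param cfg A [train_config()].
#' @return List with `seg` and `dae`, each a named list of `list(W, b)`
#'   gradient arrays covering every layer.
#' @export
embedding_gradients <- function(batch, models, cfg) {
  seg <- models$seg; dae <- models$dae
  nb <- length(batch)
  gseg <- zero_grads_like(seg)
  gdae <- zero_grads_like(dae)
  for (s in batch) {
    sf <- seg_forward(seg, s$x, keep_cache = TRUE)
    yt <- corrupt_mask(s$y, corruption_config(cfg$flip_prob))
    df <- dae_forward(dae, yt, keep_cache = TRUE)
    dlat_seg <- cfg$lambda * mse_dh(sf$latent, df$latent) / nb
    zero_dlog <- matrix(0, nrow(sf$prob), ncol(sf$prob))
    gseg <- acc_grads(gseg, seg_backward(seg, sf$cache, zero_dlog, dlat_seg)$grads)
    if (cfg$routing_mode == "BI") {
      dlat_dae <- cfg$lambda * mse_dh(df$latent, sf$latent) / nb
      gdae <- acc_grads(gdae,
        dae_backward(dae, df$cache, NULL, dlat_dae)$grads)
    }
  }
  list(seg = gseg, dae = gdae)
}

# --- dataset plumbing ------------------------------------------------------

# Normalise the accepted dataset forms to list(train=, val=) of samples with
# preprocessed images.
resolve_splits <- function(dataset, cfg, domains = NULL) {
  if (inherits(dataset, "phantom_dataset")) {
    man <- dataset$manifest
    if (!is.null(domains)) man <- dplyr::filter(man, .data$domain %in% domains)
    tr <- dataset$samples[man$sample_id[man$split == "train"]]
    va <- dataset$samples[man$sample_id[man$split == "val"]]
    dataset <- list(train = tr, val = va)
  }
  if (length(dataset$train) == 0L || length(dataset$val) == 0L)
    stop_invalid("training and validation splits must be non-empty")
  prep <- function(s) {
    x <- if (cfg$hist_eq) hist_equalize(s$image) else s$image
    list(x = x, y = s$mask)
  }
  list(train = lapply(dataset$train, prep), val = lapply(dataset$val, prep))
}

val_seg_loss <- function(seg, val, loss = c("bce", "dice")) {
  loss <- match.arg(loss)
  mean(vapply(val, function(s) {
    p <- seg_forward(seg, s$x)$prob
    if (loss == "bce") bce_loss(p, s$y) else dice_loss(p, s$y)
  }, 0))
}

#' Train a segmentation model
#'
#' Runs the configured number of epochs of the method selected in `baseline`:
#' the single-stage joint scheme (`"proposed"`), a plain U-Net (`"unet"`), or
#' the two-stage pre-trained-autoencoder baselines (`"acnn"`, `"srm"`). Each
#' epoch shuffles the training split, applies brightness/contrast
#' augmentation to images (never masks), corrupts DAE inputs afresh, takes
#' one optimizer step per mini-batch, and evaluates the validation
#' segmentation loss. The returned model is the checkpoint with the best
#' validation segmentation loss; the DAE is returned for inspection only and
#' plays no role at inference.
#'
#' All randomness is driven by `cfg$seed` through separate derived streams
#' (initialisation, per-epoch order, augmentation, corruption), so runs are
#' exactly reproducible and methods sharing a seed see identical data order
#' and augmentation.
#'
#' @param dataset A `phantom_dataset` (its manifest's train/val splits are
#'   used) or a list with `train` and `val` lists of samples.
#' @param spec A [network_spec()] for the segmentation network; the DAE uses
#'   the same geometry without skip connections.
#' @param cfg A [train_config()].
#' @param baseline A [baseline_config()].
#' @param keep_history Store a parameter snapshot of both networks after
#'   every epoch (for trajectory analyses).
#' @param domains Optional character vector restricting training to samples
#'   from these domains (for cross-domain experiments).
#' @return An `anatseg_fit` with elements `seg`, `dae`, `log` (per-epoch
#'   tibble: `epoch, L_SEG, L_DAE, L_E, L_Total, val_L_SEG`), `best_epoch`,
#'   `cfg`, `baseline`, and optionally `history`.
#' @export
train <- function(dataset, spec, cfg = train_config(),
                  baseline = baseline_config("proposed"),
                  keep_history = FALSE, domains = NULL) {
  stopifnot(inherits(spec, "network_spec"), inherits(cfg, "train_config"),
            inherits(baseline, "baseline_config"))
  if (baseline$method %in% c("acnn", "srm"))
    return(train_two_stage(dataset, spec, cfg, baseline, keep_history, domains))

  splits <- resolve_splits(dataset, cfg, domains)
  seg <- build_segmentation_network(spec, seed = derive_seed(cfg$seed, "init_seg"))
  use_dae <- baseline$method == "proposed"
  dae <- if (use_dae) {
    dspec <- network_spec(spec$input_size, spec$base_kernels, spec$depth,
                          spec$bottleneck_kernels, skip_connections = FALSE)
    build_dae(dspec, seed = derive_seed(cfg$seed, "init_dae"))
  }
  opt <- list(seg = adam_init(seg), dae = if (use_dae) adam_init(dae))
  n <- length(splits$train)
  log_rows <- vector("list", cfg$epochs)
  history <- if (keep_history) vector("list", cfg$epochs)
  best <- list(val = Inf, seg = NULL, dae = NULL, epoch = NA_integer_)

  for (e in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, "epoch", e, "order"), sample.int(n))
    aug <- if (!is.null(cfg$augment))
      with_seed(derive_seed(cfg$seed, "epoch", e, "augment"), {
        list(b = runif(n, cfg$augment$brightness_range[1], cfg$augment$brightness_range[2]),
             c = runif(n, cfg$augment$contrast_range[1], cfg$augment$contrast_range[2]))
      })
    set.seed(derive_seed(cfg$seed, "epoch", e, "corrupt"))
    ep <- c(L_SEG = 0, L_DAE = 0, L_E = 0)
    nb <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      batch <- lapply(seq_along(idx), function(k) {
        s <- splits$train[[idx[k]]]
        x <- s$x
        if (!is.null(cfg$augment)) {
          i <- idx[k]
          xb <- aug$b[i] * x
          m <- mean(xb)
          x <- clip01(aug$c[i] * (xb - m) + m)
        }
        list(x = x, y = s$y)
      })
      st <- joint_train_step(batch, list(seg = seg, dae = dae), cfg, opt)
      seg <- st$models$seg; dae <- st$models$dae; opt <- st$opt_state
      ep <- ep + c(st$losses$L_SEG, st$losses$L_DAE, st$losses$L_E)
      nb <- nb + 1L
    }
    ep <- ep / nb
    vl <- val_seg_loss(seg, splits$val, "bce")
    log_rows[[e]] <- tibble::tibble(
      epoch = e, L_SEG = ep[["L_SEG"]], L_DAE = ep[["L_DAE"]], L_E = ep[["L_E"]],
      L_Total = ep[["L_SEG"]] + ep[["L_DAE"]] + cfg$lambda * ep[["L_E"]],
      val_L_SEG = vl)
    if (keep_history)
      history[[e]] <- list(seg = parameter_snapshot(seg),
                           dae = if (use_dae) parameter_snapshot(dae))
    if (vl < best$val)
      best <- list(val = vl, seg = seg, dae = dae, epoch = e)
  }
  structure(list(seg = best$seg, dae = best$dae, best_epoch = best$epoch,
                 final_seg = seg, final_dae = dae,
                 log = dplyr::bind_rows(log_rows), cfg = cfg,
                 baseline = baseline, history = history),
            class = "anatseg_fit")
}

#' Train the DAE alone on masks
#'
#' Denoising pre-training / competence check: every epoch corrupts each mask
#' with salt-and-pepper noise at `cfg$flip_prob` and minimises the BCE
#' between the reconstruction and the clean mask.
#'
#' @param masks List of binary mask matrices.
#' @param spec A [network_spec()]; `skip_connections` is forced off.
#' @param cfg A [train_config()] (`epochs`, `batch_size`, `learning_rate`,
#'   `flip_prob`, `seed` are used).
#' @return List with `dae` (trained network) and `log` (per-epoch tibble of
#'   the reconstruction loss).
#' @export
train_dae <- function(masks, spec, cfg = train_config()) {
  dspec <- network_spec(spec$input_size, spec$base_kernels, spec$depth,
                        spec$bottleneck_kernels, skip_connections = FALSE)
  dae <- build_dae(dspec, seed = derive_seed(cfg$seed, "init_dae"))
  opt <- adam_init(dae)
  n <- length(masks)
  log_rows <- vector("list", cfg$epochs)
  for (e in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, "dae_epoch", e, "order"), sample.int(n))
    set.seed(derive_seed(cfg$seed, "dae_epoch", e, "corrupt"))
    tot <- 0; nb <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      g <- NULL; lb <- 0
      for (i in idx) {
        y <- masks[[i]]
        yt <- corrupt_mask(y, corruption_config(cfg$flip_prob))
        df <- dae_forward(dae, yt, keep_cache = TRUE)
        lb <- lb + bce_loss(df$prob, y) / length(idx)
        g <- acc_grads(g, dae_backward(dae, df$cache,
                                       bce_dlogits(df$prob, y) / length(idx))$grads)
      }
      up <- adam_update(dae, g, opt, cfg$learning_rate, cfg$weight_decay)
      dae <- up$net; opt <- up$state
      tot <- tot + lb; nb <- nb + 1L
    }
    log_rows[[e]] <- tibble::tibble(epoch = e, L_DAE = tot / nb)
  }
  list(dae = dae, log = dplyr::bind_rows(log_rows))
}

# --- two-stage baselines (pre-trained frozen DAE) --------------------------

train_two_stage <- function(dataset, spec, cfg, baseline,
                            keep_history = FALSE, domains = NULL) {
  splits <- resolve_splits(dataset, cfg, domains)
  pre_cfg <- cfg
  pre_cfg$epochs <- baseline$pretrain_epochs
  dae <- train_dae(lapply(splits$train, `[[`, "y"), spec, pre_cfg)$dae

  seg <- build_segmentation_network(spec, seed = derive_seed(cfg$seed, "init_seg"))
  opt <- adam_init(seg)
  n <- length(splits$train)
  seg_loss_kind <- if (baseline$method == "srm") "dice" else "bce"
  log_rows <- vector("list", cfg$epochs)
  history <- if (keep_history) vector("list", cfg$epochs)
  best <- list(val = Inf, seg = NULL, epoch = NA_integer_)

  for (e in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, "epoch", e, "order"), sample.int(n))
    aug <- if (!is.null(cfg$augment))
      with_seed(derive_seed(cfg$seed, "epoch", e, "augment"), {
        list(b = runif(n, cfg$augment$brightness_range[1], cfg$augment$brightness_range[2]),
             c = runif(n, cfg$augment$contrast_range[1], cfg$augment$contrast_range[2]))
      })
    tot <- 0; nb <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      g <- NULL; lb <- 0
      for (k in seq_along(idx)) {
        s <- splits$train[[idx[k]]]
        x <- s$x
        if (!is.null(cfg$augment)) {
          i <- idx[k]
          xb <- aug$b[i] * x; m <- mean(xb)
          x <- clip01(aug$c[i] * (xb - m) + m)
        }
        res <- two_stage_sample_grad(seg, dae, x, s$y, baseline)
        lb <- lb + res$loss / length(idx)
        res$dlogits <- res$dlogits / length(idx)
        g <- acc_grads(g, seg_backward(seg, res$cache, res$dlogits)$grads)
      }
      up <- adam_update(seg, g, opt, cfg$learning_rate, cfg$weight_decay)
      seg <- up$net; opt <- up$state
      tot <- tot + lb; nb <- nb + 1L
    }
    vl <- val_seg_loss(seg, splits$val, seg_loss_kind)
    log_rows[[e]] <- tibble::tibble(epoch = e, L_SEG = tot / nb, L_DAE = NA_real_,
                                    L_E = NA_real_, L_Total = tot / nb,
                                    val_L_SEG = vl)
    if (keep_history) history[[e]] <- list(seg = parameter_snapshot(seg),
                                           dae = parameter_snapshot(dae))
    if (vl < best$val) best <- list(val = vl, seg = seg, epoch = e)
  }
  structure(list(seg = best$seg, dae = dae, best_epoch = best$epoch,
                 final_seg = seg, final_dae = dae,
                 log = dplyr::bind_rows(log_rows), cfg = cfg,
                 baseline = baseline, history = history),
            class = "anatseg_fit")
}

# Per-sample objective and seg-logit gradient for the frozen-DAE baselines.
# The DAE's parameters receive no update; its layers only route gradients
# from the auxiliary losses back into the segmentation prediction.
two_stage_sample_grad <- function(seg, dae, x, y, baseline) {
  sf <- seg_forward(seg, x, keep_cache = TRUE)
  p <- sf$prob
  dsig <- p * (1 - p)
  if (baseline$method == "acnn") {
    loss <- bce_loss(p, y)
    dlog <- bce_dlogits(p, y)
    if (baseline$shape_reg_weight > 0) {
      ep <- dae_encode(dae, p, keep_cache = TRUE)
      et <- dae_encode(dae, y)
      loss <- loss + baseline$shape_reg_weight * embedding_loss(ep$latent, et$latent)
      dz <- baseline$shape_reg_weight * mse_dh(ep$latent, et$latent)
      dxp <- dae_encode_backward_input(dae, ep$cache, dz)
      dlog <- dlog + dxp[, , 1] * dsig
    }
  } else {                                   # srm
    loss <- dice_loss(p, y)
    dlog <- dice_dprob(p, y) * dsig
    if (baseline$shape_reg_weight > 0 || baseline$recon_weight > 0) {
      df <- dae_forward(dae, p, keep_cache = TRUE)
      et <- dae_encode(dae, y)
      sp <- sigmoid(df$latent); st <- sigmoid(et$latent)
      loss <- loss + baseline$shape_reg_weight * bce_loss(sp, st) +
        baseline$recon_weight * dice_loss(df$prob, y)
      dlat <- baseline$shape_reg_weight * (sp - st) / length(sp)
      dlog_dae <- baseline$recon_weight * dice_dprob(df$prob, y) *
        df$prob * (1 - df$prob)
      bw <- dae_backward(dae, df$cache, dlog_dae, dlat)
      dlog <- dlog + bw$dx[, , 1] * dsig
    }
  }
  list(loss = loss, dlogits = dlog, cache = sf$cache)
}

#' Predict a segmentation probability map
#'
#' Applies the fitted model's preprocessing (histogram equalization if it was
#' trained with it) and the segmentation network. The DAE is not involved:
#' it is discarded at inference.
#'
#' @param object An `anatseg_fit`.
#' @param image H x W grayscale matrix in `[0, 1]`.
#' @param ... Unused.
#' @return H x W probability matrix.
#' @export
predict.anatseg_fit <- function(object, image, ...) {
  x <- if (object$cfg$hist_eq) hist_equalize(image) else image
  seg_forward(object$seg, x)$prob
}

#' @export
print.anatseg_fit <- function(x, ...) {
  cat(sprintf("<anatseg_fit> method '%s', %d epochs (best %d, val L_SEG %.4f)\n",
              x$baseline$method, nrow(x$log), x$best_epoch,
              min(x$log$val_L_SEG)))
  invisible(x)
}
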