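# Brute-force oracles and small fixture builders, independent of the package
# implementation paths they validate.

# Random non-empty binary mask (speckle plus a guaranteed blob).
rand_mask <- function(h, w, p = 0.3) {
  m <- matrix(rbinom(h * w, 1, p), h, w)
  if (sum(m) == 0) m[sample(h, 1), sample(w, 1)] <- 1
  m
}

# Per-pixel ellipse-inequality rasterizer (double loop; pixel centres).
bf_ellipse_mask <- function(geom, H, W) {
  m <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      x <- (cc - 0.5) / W
      y <- (r - 0.5) / H
      for (i in seq_len(nrow(geom))) {
        g <- geom[i, ]
        u <- x - g$cx; v <- y - g$cy
        up <- u * cos(g$theta) + v * sin(g$theta)
        vp <- -u * sin(g$theta) + v * cos(g$theta)
        if ((up / g$ax)^2 + (vp / g$ay)^2 <= 1) m[r, cc] <- 1
      }
    }
  }
  m
}

# Boundary pixels by explicit neighbour enumeration (4-connectivity,
# off-image = background).
bf_boundary <- function(M) {
  H <- nrow(M); W <- ncol(M)
  out <- NULL
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      if (M[r, cc] != 1) next
      nb <- c(if (r > 1) M[r - 1, cc] else 0,
              if (r < H) M[r + 1, cc] else 0,
              if (cc > 1) M[r, cc - 1] else 0,
              if (cc < W) M[r, cc + 1] else 0)
      if (any(nb == 0)) out <- rbind(out, c(r, cc))
    }
  }
  out
}

# Exhaustive all-pairs surface distances from the boundary sets.
bf_surface_dists <- function(S, G) {
  bs <- bf_boundary(S); bg <- bf_boundary(G)
  d_sg <- vapply(seq_len(nrow(bs)), function(i) {
    min(sqrt((bs[i, 1] - bg[, 1])^2 + (bs[i, 2] - bg[, 2])^2))
  }, 0)
  d_gs <- vapply(seq_len(nrow(bg)), function(j) {
    min(sqrt((bg[j, 1] - bs[, 1])^2 + (bg[j, 2] - bs[, 2])^2))
  }, 0)
  list(d_sg = d_sg, d_gs = d_gs)
}

bf_acd <- function(S, G) {
  d <- bf_surface_dists(S, G)
  (mean(d$d_sg) + mean(d$d_gs)) / 2
}

bf_asd <- function(S, G) {
  d <- bf_surface_dists(S, G)
  (sum(d$d_sg) + sum(d$d_gs)) / (length(d$d_sg) + length(d$d_gs))
}

# Tiny network specs shared by the training-contract tests.
tiny_seg_spec <- function() network_spec(c(32L, 32L), base_kernels = 2L, depth = 2L)

tiny_batch <- function(n = 2, h = 32, w = 32, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    list(x = matrix(runif(h * w), h, w),
         y = {
           m <- matrix(0, h, w)
           r0 <- sample(5:(h - 12), 1); c0 <- sample(5:(w - 12), 1)
           m[r0:(r0 + 7), c0:(c0 + 7)] <- 1
           m
         })
  }))
}

# Desk-scale configuration used by the joint-training acceptance checks.
desk_spec <- function() network_spec(c(64L, 64L), base_kernels = 4L, depth = 3L)

desk_train_cfg <- function(seed, epochs = 30L) {
  train_config(epochs = epochs, batch_size = 2L, learning_rate = 2e-3,
               lambda = 1, seed = seed, flip_prob = 0.1)
}

max_abs_grad <- function(grads) {
  max(vapply(grads, function(g) max(abs(g$W), abs(g$b)), 0))
}
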