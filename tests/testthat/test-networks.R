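test_that("network shapes follow the spec arithmetic", {
  sp <- network_spec(c(64, 64), base_kernels = 4, depth = 4)
  seg <- build_segmentation_network(sp, seed = 1)
  expect_equal(latent_shape(seg), c(4, 4, 64))
  f <- net_forward(seg, matrix(0, 64, 64))
  expect_equal(dim(f$prob), c(64, 64))
  expect_equal(dim(f$latent), c(4, 4, 64))
  expect_true(all(f$prob > 0 & f$prob < 1))  # sigmoid range on zero input
  dsp <- network_spec(c(64, 64), 4, 4, skip_connections = FALSE)
  dae <- build_dae(dsp, seed = 2)
  expect_equal(latent_shape(dae), latent_shape(seg))
  expect_error(network_spec(c(60, 64), 4, 4), class = "anatseg_invalid_argument")
  expect_error(build_dae(sp), class = "anatseg_invalid_argument")
  expect_error(build_segmentation_network(dsp), class = "anatseg_invalid_argument")
})

test_that("parameter groups are disjoint and cover every layer", {
  seg <- build_segmentation_network(network_spec(c(32, 32), 2, 2), seed = 1)
  dae <- build_dae(network_spec(c(32, 32), 2, 2, skip_connections = FALSE), seed = 1)
  for (net in list(seg, dae)) {
    pg <- param_groups(net)
    expect_length(intersect(pg$encoder, pg$decoder), 0)
    expect_setequal(c(pg$encoder, pg$decoder), names(net$layers))
  }
  # different seeds / networks have independent parameters
  seg2 <- build_segmentation_network(network_spec(c(32, 32), 2, 2), seed = 2)
  expect_false(identical(parameter_snapshot(seg), parameter_snapshot(seg2)))
})

test_that("analytic gradients match finite differences on both networks", {
  set.seed(11)
  sp <- network_spec(c(16, 16), 2, 2)
  seg <- build_segmentation_network(sp, seed = 3)
  dae <- build_dae(network_spec(c(16, 16), 2, 2, skip_connections = FALSE), seed = 4)
  x <- matrix(runif(256), 16, 16)
  y <- matrix(rbinom(256, 1, 0.3), 16, 16)
  zt <- array(rnorm(prod(latent_shape(seg))), latent_shape(seg))
  lam <- 0.7
  eps <- 1e-5

  seg_loss <- function(net) {
    f <- anatseg:::seg_forward(net, x)
    bce_loss(f$prob, y) + lam * embedding_loss(f$latent, zt)
  }
  f <- anatseg:::seg_forward(seg, x, keep_cache = TRUE)
  gr <- anatseg:::seg_backward(seg, f$cache, anatseg:::bce_dlogits(f$prob, y),
                               lam * anatseg:::mse_dh(f$latent, zt))$grads
  for (nm in names(seg$layers)) {
    W <- seg$layers[[nm]]$W
    for (k in sample(length(W), min(3, length(W)))) {
      net2 <- seg
      net2$layers[[nm]]$W[k] <- W[k] + eps; lp <- seg_loss(net2)
      net2$layers[[nm]]$W[k] <- W[k] - eps; lm <- seg_loss(net2)
      expect_equal(gr[[nm]]$W[k], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }

  dae_loss <- function(net) {
    f <- anatseg:::dae_forward(net, x)
    bce_loss(f$prob, y) + lam * embedding_loss(f$latent, zt)
  }
  f <- anatseg:::dae_forward(dae, x, keep_cache = TRUE)
  gr <- anatseg:::dae_backward(dae, f$cache, anatseg:::bce_dlogits(f$prob, y),
                               lam * anatseg:::mse_dh(f$latent, zt))$grads
  for (nm in names(dae$layers)) {
    W <- dae$layers[[nm]]$W
    for (k in sample(length(W), min(3, length(W)))) {
      net2 <- dae
      net2$layers[[nm]]$W[k] <- W[k] + eps; lp <- dae_loss(net2)
      net2$layers[[nm]]$W[k] <- W[k] - eps; lm <- dae_loss(net2)
      expect_equal(gr[[nm]]$W[k], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("spinal preset multiplies kernels by four and removes one block", {
  lung <- network_spec(c(256, 256), 16, 4)
  sp1 <- spinal_preset(lung)
  expect_equal(sp1$base_kernels, 64)
  expect_equal(sp1$depth, 3)
  expect_equal(sp1$input_size, c(128, 128))
  expect_equal(sp1$input_size %/% 2^sp1$depth, c(16, 16))
  sp2 <- spinal_preset(sp1)
  expect_equal(sp2$base_kernels, 256)
  expect_equal(sp2$depth, 2)
  expect_error(spinal_preset(network_spec(c(64, 64), 4, 1)),
               class = "anatseg_invalid_argument")
})

test_that("composite head produces a valid map and rejects shape mismatches", {
  seg <- build_segmentation_network(network_spec(c(32, 32), 2, 2), seed = 5)
  dae <- build_dae(network_spec(c(32, 32), 2, 2, skip_connections = FALSE), seed = 6)
  p <- composite_forward(matrix(runif(1024), 32, 32), seg, dae)
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p > 0 & p < 1))
  dae_big <- build_dae(network_spec(c(32, 32), 4, 2, skip_connections = FALSE), seed = 6)
  expect_error(composite_forward(matrix(0, 32, 32), seg, dae_big),
               class = "anatseg_invalid_argument")
})
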