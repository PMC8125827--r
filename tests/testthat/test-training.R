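make_tiny_models <- function(seed = 1) {
  sp <- tiny_seg_spec()
  list(seg = build_segmentation_network(sp, seed = seed),
       dae = build_dae(network_spec(sp$input_size, sp$base_kernels, sp$depth,
                                    skip_connections = FALSE), seed = seed + 1))
}

test_that("embedding-loss gradients respect the routing contract", {
  models <- make_tiny_models()
  batch <- tiny_batch(2)
  for (mode in c("UN", "BI")) {
    cfg <- train_config(routing_mode = mode, lambda = 1, seed = 3, epochs = 1)
    set.seed(42)
    g <- embedding_gradients(batch, models, cfg)
    pg_seg <- param_groups(models$seg)
    pg_dae <- param_groups(models$dae)
    # decoders never receive the embedding gradient, in either mode
    for (nm in pg_seg$decoder) expect_identical(max(abs(g$seg[[nm]]$W)), 0)
    for (nm in pg_dae$decoder) expect_identical(max(abs(g$dae[[nm]]$W)), 0)
    # the segmentation encoder always does
    expect_gt(max_abs_grad(g$seg[pg_seg$encoder]), 0)
    # the DAE encoder only in BI mode
    dae_enc <- max_abs_grad(g$dae[pg_dae$encoder])
    if (mode == "UN") expect_identical(dae_enc, 0) else expect_gt(dae_enc, 0)
  }
})

test_that("joint step bookkeeping: additive bundle, lambda = 0 decoupling", {
  models <- make_tiny_models()
  batch <- tiny_batch(2)
  cfg <- train_config(lambda = 0.5, seed = 1, epochs = 1, learning_rate = 1e-3)
  set.seed(7)
  st <- joint_train_step(batch, models, cfg)
  expect_s3_class(st$losses, "loss_bundle")
  expect_identical(st$losses$L_Total,
                   st$losses$L_SEG + st$losses$L_DAE + 0.5 * st$losses$L_E)
  expect_false(identical(parameter_snapshot(st$models$seg),
                         parameter_snapshot(models$seg)))
  expect_error(joint_train_step(list(), models, cfg),
               class = "anatseg_invalid_argument")
})

test_that("mode UN leaves the whole DAE trajectory independent of lambda", {
  ds <- phantom_benchmark(n_per_domain = 12, size = c(32, 32), seed = 50)
  sp <- tiny_seg_spec()
  run <- function(lambda) {
    cfg <- train_config(epochs = 2, batch_size = 4, learning_rate = 1e-3,
                        lambda = lambda, routing_mode = "UN", seed = 9)
    train(ds, sp, cfg, baseline_config("proposed"), keep_history = TRUE,
          domains = "siteA")
  }
  f1 <- run(1); f0 <- run(0)
  for (e in seq_along(f1$history)) {
    expect_identical(f1$history[[e]]$dae, f0$history[[e]]$dae)
  }
  # ... while the segmentation encoder trajectory does depend on lambda
  expect_false(identical(f1$history[[2]]$seg, f0$history[[2]]$seg))
})

test_that("mode BI couples the DAE encoder to lambda within one step", {
  models <- make_tiny_models()
  batch <- tiny_batch(3)
  step_dae <- function(lambda) {
    cfg <- train_config(lambda = lambda, routing_mode = "BI", seed = 1,
                        epochs = 1, learning_rate = 1e-3)
    set.seed(123)  # identical corruption draws for both lambdas
    parameter_snapshot(joint_train_step(batch, models, cfg)$models$dae)
  }
  s1 <- step_dae(1); s0 <- step_dae(0)
  enc <- param_groups(models$dae)$encoder
  expect_false(identical(s1[enc], s0[enc]))
})

test_that("proposed with lambda = 0 matches the plain U-Net trajectory", {
  ds <- phantom_benchmark(n_per_domain = 12, size = c(32, 32), seed = 51)
  sp <- tiny_seg_spec()
  cfg <- train_config(epochs = 2, batch_size = 4, learning_rate = 1e-3,
                      lambda = 0, seed = 4)
  fp <- train(ds, sp, cfg, baseline_config("proposed"), keep_history = TRUE,
              domains = "siteA")
  fu <- train(ds, sp, cfg, baseline_config("unet"), keep_history = TRUE,
              domains = "siteA")
  for (e in seq_along(fp$history))
    expect_identical(fp$history[[e]]$seg, fu$history[[e]]$seg)
  expect_equal(nrow(fp$log), 2)           # loss log length equals epochs
  expect_true(all(is.finite(fp$log$val_L_SEG)))
})

test_that("training descends on an easy phantom task", {
  ds <- phantom_benchmark(n_per_domain = 12, size = c(32, 32), seed = 52)
  sp <- tiny_seg_spec()
  drops <- vapply(1:3, function(seed) {
    cfg <- train_config(epochs = 4, batch_size = 4, learning_rate = 2e-3,
                        seed = seed)
    fit <- train(ds, sp, cfg, baseline_config("proposed"), domains = "siteA")
    fit$log$L_Total[1] - tail(fit$log$L_Total, 1)
  }, 0)
  expect_gt(mean(drops), 0)
})

test_that("two-stage baselines freeze the DAE and reduce to U-Net at zero weights", {
  ds <- phantom_benchmark(n_per_domain = 12, size = c(32, 32), seed = 53)
  sp <- tiny_seg_spec()
  cfg <- train_config(epochs = 2, batch_size = 4, learning_rate = 1e-3, seed = 6)
  fa <- train(ds, sp, cfg, baseline_config("acnn", pretrain_epochs = 2),
              keep_history = TRUE, domains = "siteA")
  # frozen contract: the DAE snapshot never moves during stage 2
  expect_identical(fa$history[[1]]$dae, fa$history[[2]]$dae)
  expect_identical(parameter_snapshot(fa$dae), fa$history[[1]]$dae)
  # zero shape weight reduces the ACNN stage-2 trajectory to the plain U-Net
  fa0 <- train(ds, sp, cfg, baseline_config("acnn", shape_reg_weight = 0,
                                            pretrain_epochs = 2),
               keep_history = TRUE, domains = "siteA")
  fu <- train(ds, sp, cfg, baseline_config("unet"), keep_history = TRUE,
              domains = "siteA")
  for (e in 1:2) expect_identical(fa0$history[[e]]$seg, fu$history[[e]]$seg)
})

test_that("SRM objective equals the hand-summed three terms on a fixed batch", {
  models <- make_tiny_models(seed = 8)
  s <- tiny_batch(1)[[1]]
  bl <- baseline_config("srm", shape_reg_weight = 0.01, recon_weight = 0.001)
  res <- anatseg:::two_stage_sample_grad(models$seg, models$dae, s$x, s$y, bl)
  p <- anatseg:::seg_forward(models$seg, s$x)$prob
  df <- anatseg:::dae_forward(models$dae, p)
  zt <- anatseg:::dae_encode(models$dae, s$y)$latent
  manual <- dice_loss(p, s$y) +
    0.01 * bce_loss(anatseg:::sigmoid(df$latent), anatseg:::sigmoid(zt)) +
    0.001 * dice_loss(df$prob, s$y)
  expect_equal(res$loss, manual, tolerance = 1e-12)
  # with both auxiliary weights zero the objective is the pure dice loss
  bl0 <- baseline_config("srm", shape_reg_weight = 0, recon_weight = 0)
  res0 <- anatseg:::two_stage_sample_grad(models$seg, models$dae, s$x, s$y, bl0)
  expect_equal(res0$loss, dice_loss(p, s$y), tolerance = 1e-12)
})

test_that("fit accessors: tidy, glance, predict, autoplot", {
  ds <- phantom_benchmark(n_per_domain = 12, size = c(32, 32), seed = 54)
  cfg <- train_config(epochs = 2, batch_size = 4, learning_rate = 1e-3, seed = 2)
  fit <- train(ds, tiny_seg_spec(), cfg, baseline_config("proposed"),
               domains = "siteA")
  td <- tidy(fit)
  expect_true(all(c("epoch", "term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$method, "proposed")
  expect_equal(gl$epochs, 2)
  p <- predict(fit, ds$samples[[1]]$image)
  expect_equal(dim(p), c(32, 32))
  expect_s3_class(autoplot(fit), "ggplot")
})
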