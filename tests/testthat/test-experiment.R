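small_bench <- function(seed = 60) phantom_benchmark(n_per_domain = 12,
                                                     size = c(32, 32),
                                                     seed = seed)

small_cfg <- function() train_config(epochs = 2, batch_size = 4,
                                     learning_rate = 1e-3, seed = 1)

test_that("run_experiment aggregates per-run metrics into a result table", {
  ds <- small_bench()
  tab <- run_experiment(ds, tiny_seg_spec(), "siteA",
                        target_domains = "siteB", cfg = small_cfg(),
                        baseline = baseline_config("unet"), n_runs = 2,
                        base_seed = 10)
  expect_s3_class(tab, "result_table")
  expect_equal(nrow(tab), 2 * 4)                  # two domains x four metrics
  expect_setequal(unique(tab$eval_domain), c("siteA", "siteB"))
  expect_true(all(tab$n_runs == 2))
  expect_true(all(tab$std >= 0))
  # std recomputable from the persisted per-run values
  runs <- attr(tab, "runs")
  one <- dplyr::filter(runs, eval_domain == "siteA", metric == "iou")
  expect_equal(tab$std[tab$eval_domain == "siteA" & tab$metric == "iou"],
               sd(one$value))
  expect_equal(tab$mean[tab$eval_domain == "siteA" & tab$metric == "iou"],
               mean(one$value))
})

test_that("experiments are deterministic and validate their domains", {
  ds <- small_bench(61)
  t1 <- run_experiment(ds, tiny_seg_spec(), "siteA", cfg = small_cfg(),
                       baseline = baseline_config("unet"), n_runs = 1,
                       base_seed = 3)
  t2 <- run_experiment(ds, tiny_seg_spec(), "siteA", cfg = small_cfg(),
                       baseline = baseline_config("unet"), n_runs = 1,
                       base_seed = 3)
  expect_equal(nrow(t1), 4)                       # one source row-group
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
  expect_error(run_experiment(ds, tiny_seg_spec(), "nope", cfg = small_cfg()),
               class = "anatseg_config_error")
})

test_that("cross-domain report appends the unweighted average row-group", {
  mk <- function(src, vals) {
    t <- tibble::tibble(method = "unet", source_domain = src,
                        eval_domain = "x", metric = c("iou", "dsc", "acd", "asd"),
                        mean = vals, std = 0.01, n_runs = 3L)
    class(t) <- c("result_table", class(t)); t
  }
  rep2 <- cross_domain_report(list(mk("a", c(.9, .94, 1, .8)),
                                   mk("b", c(.7, .8, 3, 2))))
  avg <- dplyr::filter(rep2, source_domain == "Average")
  expect_equal(avg$mean[avg$metric == "iou"], (0.9 + 0.7) / 2)
  expect_equal(avg$mean[avg$metric == "acd"], 2)
  # degenerate single setting: average equals the setting itself
  rep1 <- cross_domain_report(list(mk("a", c(.9, .94, 1, .8))))
  avg1 <- dplyr::arrange(dplyr::filter(rep1, source_domain == "Average"), metric)
  expect_equal(avg1$mean, c(1, .8, .94, .9))     # acd, asd, dsc, iou
  bad <- mk("c", c(.5, .6, 2, 1)); bad$method <- "other"
  expect_error(cross_domain_report(list(mk("a", c(.9, .94, 1, .8)), bad)),
               class = "anatseg_invalid_argument")
})

test_that("overlay rendering writes a correctly sized RGB file", {
  img <- matrix(runif(32 * 32), 32, 32)
  truth <- matrix(0, 32, 32); truth[10:20, 10:20] <- 1
  pred <- truth
  path <- file.path(withr::local_tempdir(), "ov.png")
  render_overlay(img, pred, truth, path)
  expect_true(file.exists(path))
  arr <- png::readPNG(path)
  expect_equal(dim(arr)[1:2], c(32, 32))
  expect_equal(dim(arr)[3], 3)
  # ground-truth contour drawn in pure red
  b <- extract_boundary(truth)[1, ]
  expect_equal(arr[b[1], b[2], ], c(1, 0, 0))
  # empty prediction still renders
  path2 <- file.path(withr::local_tempdir(), "ov2.png")
  render_overlay(img, matrix(0, 32, 32), truth, path2, pred_color = "blue")
  expect_true(file.exists(path2))
})

test_that("JSON experiment configurations round-trip into package objects", {
  cfgfile <- file.path(withr::local_tempdir(), "cfg.json")
  jsonlite::write_json(list(
    data = list(shape = "lung_pair", n_per_domain = 8, size = c(32, 32),
                domains = list(
                  list(name = "a", background_level = 0.3, foreground_contrast = 0.4),
                  list(name = "b", background_level = 0.6, foreground_contrast = 0.15,
                       noise_sigma = 0.07, texture_amplitude = 0.2, lesion_rate = 2))),
    model = list(seg = list(input_size = c(32, 32), base_kernels = 2, depth = 2)),
    train = list(epochs = 3, batch_size = 4, learning_rate = 0.001, lambda = 0.5,
                 routing_mode = "BI", corruption = list(flip_prob = 0.2),
                 augment = list(brightness = c(0.9, 1.1), contrast = c(0.8, 1.2))),
    baseline = list(method = "acnn", shape_reg_weight = 0.05),
    experiment = list(source_domains = list("a"), target_domains = list("b"),
                      n_runs = 2)), cfgfile, auto_unbox = TRUE)
  cfg <- read_experiment_config(cfgfile, seed = 7)
  expect_equal(cfg$spec$base_kernels, 2)
  expect_equal(cfg$train$lambda, 0.5)
  expect_equal(cfg$train$routing_mode, "BI")
  expect_equal(cfg$train$flip_prob, 0.2)
  expect_equal(cfg$train$seed, 7L)
  expect_equal(cfg$baseline$method, "acnn")
  expect_equal(cfg$baseline$shape_reg_weight, 0.05)
  expect_equal(cfg$experiment$n_runs, 2L)
  expect_equal(names(cfg$data$domains), c("a", "b"))
  expect_equal(cfg$data$domains$b$lesion_rate, 2)
})
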