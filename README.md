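# anatseg

Anatomically constrained 2D biomedical image segmentation with a **jointly
trained denoising autoencoder (DAE)** shape prior, implemented entirely in R
(RcppArmadillo compute core, tidyverse-style interfaces).

## The problem

U-Net-style networks segment organs well in-distribution but optimise a
purely pixel-wise loss, so nothing stops them from predicting anatomically
implausible regions — and they degrade sharply when applied to images from a
different site or scanner. Medical images, however, share strong global
structure (two lung fields on a chest film, one cord cross-section on
cervical MRI). `anatseg` trains that structure into the network.

## The method

Two networks are optimised **jointly in a single stage**:

- a **DAE** learns the space of plausible anatomy by reconstructing clean
  binary masks `y` from salt-and-pepper-corrupted inputs `ỹ`:
  `L_DAE = BCE(g_DAE(f_DAE(ỹ)), y)`;
- a **U-Net** segments the image: `L_SEG = BCE(g_SEG(f_SEG(x)), y)`;
- an **embedding loss** couples their equal-shaped latent feature maps,
  `L_E = MSE(h, z)` with `h = f_SEG(x)`, `z = f_DAE(ỹ)`:

```
L_Total = L_SEG + L_DAE + λ·L_E
```

The gradient of `λ·L_E` is routed **one-directionally**: it updates only the
segmentation encoder (`routing_mode = "UN"`), so the DAE's anatomical feature
space is never perturbed by the segmentation task (the bidirectional ablation
`"BI"` is available). At inference the DAE is discarded. The classic
two-stage baselines (pre-trained frozen autoencoder with MSE shape
regularisation; its Dice/reconstruction variant) are included behind the same
`train()` interface, as are the four evaluation metrics — IOU, DSC
(`DSC = 2·IOU/(1+IOU)`), and the boundary metrics ACD and ASD (directed mean
and pooled mean of nearest-boundary Euclidean distances, in pixels).

Because no clinical data ships with the package, a seeded **phantom
generator** synthesises multi-domain datasets whose samples share identical
anatomy (masks) while appearance — brightness, contrast, noise, texture,
lesions — varies per domain, which is exactly the regime needed to study
domain robustness.

## Worked example

Train the joint model on the clean domain of the built-in appearance-shift
benchmark and evaluate in- and cross-domain (about a minute on CPU):

```r
library(anatseg)

bench <- phantom_benchmark()          # siteA: clean; siteB: strong shift
bench
#> <phantom_dataset> 100 samples, 2 domain(s)
#> # A tibble: 6 × 3
#>   domain split     n
#>   <chr>  <chr> <int>
#> 1 siteA  test     11
#> 2 siteA  train    32
#> 3 siteA  val       7
#> ...

spec <- network_spec(c(64, 64), base_kernels = 4, depth = 3)
cfg  <- train_config(epochs = 30, batch_size = 2, learning_rate = 2e-3,
                     lambda = 1, seed = 6)

fit <- train(bench, spec, cfg, baseline_config("proposed"), domains = "siteA")
fit
#> <anatseg_fit> method 'proposed', 30 epochs (best 30, val L_SEG 0.0248)

tab <- run_experiment(bench, spec, "siteA", target_domains = "siteB",
                      cfg = cfg, baseline = baseline_config("proposed"),
                      n_runs = 1, base_seed = 5)
tibble::as_tibble(tab)
#> # A tibble: 8 × 7
#>   method   source_domain eval_domain metric  mean   std n_runs
#>   <chr>    <chr>         <chr>       <chr>  <dbl> <dbl>  <int>
#> 1 proposed siteA         siteA       acd    0.289     0      1
#> 2 proposed siteA         siteA       asd    0.289     0      1
#> 3 proposed siteA         siteA       dsc    0.977     0      1
#> 4 proposed siteA         siteA       iou    0.956     0      1
#> 5 proposed siteA         siteB       acd    1.04      0      1
#> 6 proposed siteA         siteB       asd    1.05      0      1
#> 7 proposed siteA         siteB       dsc    0.906     0      1
#> 8 proposed siteA         siteB       iou    0.831     0      1
```

In-domain the model reaches IOU 0.956 with sub-pixel mean boundary error
(ACD 0.29 px); on the strongly shifted domain it keeps IOU 0.83 with ACD
about 1 px. Per-image scoring works the same way:

```r
s <- bench$samples[[ bench$manifest$sample_id[bench$manifest$split == "test"][1] ]]
evaluate_batch(predict(fit, s$image), s$mask)
#> # A tibble: 1 × 7
#>   sample_id domain   iou   dsc   acd   asd flagged
#>       <int> <chr>  <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1         1 <NA>   0.943 0.971 0.372 0.372 FALSE
```

`autoplot(fit)` plots the loss curves, `tidy(fit)`/`glance(fit)` return the
training log and a one-row summary, `composite_forward()` exposes the
diagnostic `f_SEG → g_DAE` head, and `render_overlay()` writes
prediction/ground-truth overlay PNGs. A thin command-line interface
(`inst/scripts/anatseg`) wraps data generation, training, evaluation,
cross-domain reports, metric scoring and overlay rendering around JSON
experiment configurations.

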