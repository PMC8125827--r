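#' Repeated-seed training and (cross-)domain evaluation
#'
#' Trains `n_runs` models on the training split of `source_domain` (run `r`
#' uses seed `base_seed + r` for every stochastic component) and evaluates
#' each on the test split of the source domain and of every target domain.
#' Per-image metrics are averaged within each run and domain; the table
#' reports their mean and standard deviation across runs.
#'
#' @param dataset A `phantom_dataset` containing all involved domains.
#' @param spec A [network_spec()].
#' @param source_domain Domain trained on.
#' @param target_domains Character vector of unseen domains evaluated on
#'   (may be empty).
#' @param cfg A [train_config()]; its `seed` is overridden per run.
#' @param baseline A [baseline_config()] naming the method.
#' @param n_runs Number of repeated runs (>= 1).
#' @param base_seed Base of the per-run seeds (default `cfg$seed`).
#' @param threshold Binarization threshold for evaluation.
#' @return A `result_table` tibble with columns `method, source_domain,
#'   eval_domain, metric, mean, std, n_runs`; per-run values are attached as
#'   the `"runs"` attribute, and the fitted models of the last run as
#'   `"last_fit"`.
#' @export
run_experiment <- function(dataset, spec, source_domain,
                           target_domains = character(),
                           cfg = train_config(),
                           baseline = baseline_config("proposed"),
                           n_runs = 1L, base_seed = cfg$seed,
                           threshold = 0.5) {
  man <- dataset$manifest
  for (d in c(source_domain, target_domains))
    if (!d %in% man$domain)
      rlang::abort(sprintf("domain '%s' not present in the manifest", d),
                   class = "anatseg_config_error")
  eval_domains <- c(source_domain, target_domains)
  run_rows <- list()
  fit <- NULL
  for (r in seq_len(n_runs)) {
    cfg_r <- cfg
    cfg_r$seed <- as.integer(base_seed + r)
    fit <- train(dataset, spec, cfg_r, baseline, domains = source_domain)
    for (ed in eval_domains) {
      ids <- man$sample_id[man$domain == ed & man$split == "test"]
      preds <- lapply(dataset$samples[ids], function(s) predict(fit, s$image))
      recs <- evaluate_batch(preds, lapply(dataset$samples[ids], `[[`, "mask"),
                             threshold = threshold, sample_id = ids,
                             domain = rep(ed, length(ids)))
      agg <- suppressMessages(aggregate_metrics(recs))
      # keep all four metrics per row-group; a distance metric left undefined
      # by universally empty predictions stays NA rather than disappearing
      full <- tibble::tibble(metric = c("iou", "dsc", "acd", "asd"))
      agg <- dplyr::left_join(full, agg, by = "metric")
      run_rows[[length(run_rows) + 1L]] <- tibble::tibble(
        method = baseline$method, run = r, eval_domain = ed,
        metric = agg$metric, value = agg$mean)
    }
  }
  runs <- dplyr::bind_rows(run_rows)
  tab <- dplyr::summarise(
    dplyr::group_by(runs, .data$method, .data$eval_domain, .data$metric),
    mean = mean(.data$value),
    std = if (dplyr::n() > 1) sd(.data$value) else 0,
    n_runs = dplyr::n(), .groups = "drop")
  tab <- dplyr::mutate(tab, source_domain = source_domain,
                       .after = "method")
  tab <- tab[, c("method", "source_domain", "eval_domain", "metric",
                 "mean", "std", "n_runs")]
  attr(tab, "runs") <- runs
  attr(tab, "last_fit") <- fit
  class(tab) <- c("result_table", class(tab))
  tab
}

#' Combine experiment settings and append their average
#'
#' Binds the result tables of several source-domain settings and appends an
#' `"Average"` row group holding, per method and metric, the unweighted mean
#' over settings.
#'
#' @param tables List of `result_table` tibbles from [run_experiment()]
#'   (consistent method sets).
#' @return A `result_table` tibble including the average rows
#'   (`source_domain = "Average"`).
#' @export
cross_domain_report <- function(tables) {
  if (length(tables) < 1L) stop_invalid("need at least one result table")
  methods <- lapply(tables, function(t) sort(unique(t$method)))
  if (!all(vapply(methods, identical, TRUE, methods[[1]])))
    stop_invalid("result tables carry inconsistent method sets")
  all_rows <- dplyr::bind_rows(lapply(tables, function(t) {
    attr(t, "runs") <- NULL; attr(t, "last_fit") <- NULL
    tibble::as_tibble(t)
  }))
  per_setting <- dplyr::summarise(
    dplyr::group_by(all_rows, .data$method, .data$source_domain, .data$metric),
    value = mean(.data$mean), .groups = "drop")
  avg <- dplyr::summarise(
    dplyr::group_by(per_setting, .data$method, .data$metric),
    mean = mean(.data$value), .groups = "drop")
  avg <- dplyr::mutate(avg, source_domain = "Average", eval_domain = "Average",
                       std = NA_real_, n_runs = NA_integer_)
  out <- dplyr::bind_rows(all_rows, avg[, names(all_rows)])
  class(out) <- c("result_table", class(out))
  out
}

#' Write a color overlay of prediction and ground truth
#'
#' Renders the grayscale image with the predicted region filled in
#' `pred_color` (alpha-blended) and the ground-truth boundary drawn as a red
#' contour, and writes it as an RGB PNG of the same dimensions.
#'
#' @param image Grayscale H x W matrix in `[0, 1]`.
#' @param prediction Binary prediction mask (or probability map, binarized at
#'   0.5).
#' @param truth Binary ground-truth mask.
#' @param path Output PNG path.
#' @param pred_color `"green"` (in-domain convention) or `"blue"`
#'   (cross-domain convention).
#' @param alpha Fill opacity of the predicted region.
#' @return The path, invisibly.
#' @export
render_overlay <- function(image, prediction, truth, path,
                           pred_color = c("green", "blue"), alpha = 0.4) {
  pred_color <- match.arg(pred_color)
  check_same_shape(image, truth)
  check_same_shape(image, prediction)
  S <- (prediction >= 0.5) * 1
  rgb_ <- array(rep(clip01(image), 3), c(dim(image), 3))
  fill <- c(0, 1, 0)
  if (pred_color == "blue") fill <- c(0, 0.3, 1)
  for (ch in 1:3) {
    plane <- rgb_[, , ch]
    plane[S == 1] <- (1 - alpha) * plane[S == 1] + alpha * fill[ch]
    rgb_[, , ch] <- plane
  }
  if (sum(truth) > 0) {
    b <- extract_boundary(truth)
    for (k in seq_len(nrow(b))) {
      rgb_[b[k, 1], b[k, 2], ] <- c(1, 0, 0)
    }
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(rgb_, path)
  invisible(path)
}
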