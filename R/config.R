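#' Read a JSON experiment configuration
#'
#' Parses the declarative JSON configuration used by the command-line
#' interface into package objects. Recognised sections (all optional, with
#' package defaults):
#'
#' * `data`: `shape` (`"lung_pair"`/`"cord_disc"`), `domains` (array of
#'   domain objects with `name`, `background_level`, `foreground_contrast`,
#'   `noise_sigma`, `texture_amplitude`, `lesion_rate`), `n_per_domain`,
#'   `size`.
#' * `model.seg`: `input_size`, `base_kernels`, `depth`,
#'   `bottleneck_kernels`, plus `spinal_preset: true` to apply the
#'   reduced-depth/4x-kernel transform.
#' * `train`: `optimizer`, `learning_rate`, `weight_decay`, `epochs`,
#'   `batch_size`, `lambda`, `routing_mode`, `hist_eq`,
#'   `corruption.flip_prob`, `augment.brightness`, `augment.contrast`.
#' * `baseline`: `method`, `shape_reg_weight`, `recon_weight`,
#'   `pretrain_epochs`.
#' * `experiment`: `source_domains`, `target_domains`, `n_runs`, `threshold`.
#'
#' @param path Path to the JSON file.
#' @param seed Seed installed into the training configuration.
#' @return List with `data`, `spec`, `train`, `baseline`, `experiment`.
#' @export
read_experiment_config <- function(path, seed = 1L) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)

  dat <- js$data %||% list()
  shape <- shape_family(dat$shape %||% "lung_pair")
  domains <- NULL
  if (!is.null(dat$domains)) {
    dd <- dat$domains
    if (is.data.frame(dd)) dd <- split(dd, seq_len(nrow(dd)))
    val_or <- function(v, default)
      if (is.null(v) || (length(v) == 1L && is.na(v))) default else v
    domains <- lapply(dd, function(d)
      domain_config(d$name, d$background_level, d$foreground_contrast,
                    val_or(d$noise_sigma, 0.02), val_or(d$texture_amplitude, 0),
                    val_or(d$lesion_rate, 0)))
    names(domains) <- vapply(domains, `[[`, "", "name")
  }
  size <- as.integer(dat$size %||% c(64L, 64L))
  if (length(size) == 1L) size <- rep(size, 2L)

  ms <- js$model$seg %||% list()
  spec <- network_spec(
    input_size = as.integer(ms$input_size %||% size),
    base_kernels = as.integer(ms$base_kernels %||% 16L),
    depth = as.integer(ms$depth %||% 4L),
    bottleneck_kernels = ms$bottleneck_kernels)
  if (isTRUE(ms$spinal_preset)) spec <- spinal_preset(spec)

  tr <- js$train %||% list()
  aug <- NULL
  br <- tr$augment$brightness %||% c(0.8, 1.2)
  cr <- tr$augment$contrast %||% c(0.8, 1.2)
  if (!isFALSE(tr$augment)) aug <- augment_config(as.numeric(br), as.numeric(cr))
  cfg <- train_config(
    optimizer = tr$optimizer %||% "adam",
    learning_rate = tr$learning_rate %||% 1e-4,
    weight_decay = tr$weight_decay %||% 0,
    epochs = tr$epochs %||% 120L,
    batch_size = tr$batch_size %||% 8L,
    lambda = tr$lambda %||% 1,
    routing_mode = tr$routing_mode %||% "UN",
    seed = seed,
    flip_prob = tr$corruption$flip_prob %||% 0.1,
    augment = aug,
    hist_eq = tr$hist_eq %||% TRUE)

  bl <- js$baseline %||% list()
  baseline <- baseline_config(
    method = bl$method %||% "proposed",
    shape_reg_weight = bl$shape_reg_weight %||% 0.01,
    recon_weight = bl$recon_weight %||% 0.001,
    pretrain_epochs = bl$pretrain_epochs %||% 60L)

  ex <- js$experiment %||% list()
  experiment <- list(
    source_domains = ex$source_domains,
    target_domains = ex$target_domains %||% character(),
    n_runs = as.integer(ex$n_runs %||% 1L),
    threshold = ex$threshold %||% 0.5)

  list(data = list(shape = shape, domains = domains,
                   n_per_domain = as.integer(dat$n_per_domain %||% 20L),
                   size = size),
       spec = spec, train = cfg, baseline = baseline, experiment = experiment)
}
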