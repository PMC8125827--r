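#' Domain appearance configuration for phantom generation
#'
#' A domain describes the *appearance* of images from one acquisition source:
#' background intensity, signed foreground contrast, additive Gaussian noise,
#' a low-frequency texture field, and a rate of bright lesion-like blobs.
#' Domains sharing a [shape_family()] produce images of the same anatomy with
#' different appearance, emulating the distributional shift between imaging
#' sites or scanners.
#'
#' @param name Domain identifier (single string).
#' @param background_level Background intensity in `[0, 1]`.
#' @param foreground_contrast Signed intensity offset of the foreground
#'   structure, in `[-1, 1]`.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise.
#' @param texture_amplitude Amplitude of a smooth low-frequency intensity
#'   field (sum of 2-4 seeded sinusoids), in `[0, 1]`.
#' @param lesion_rate Expected number of lesion blobs per image (Poisson).
#' @return An object of class `domain_config`.
#' @export
#' @examples
#' domain_config("siteA", background_level = 0.3, foreground_contrast = 0.4)
domain_config <- function(name, background_level, foreground_contrast,
                          noise_sigma = 0.02, texture_amplitude = 0,
                          lesion_rate = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_invalid("`name` must be a non-empty string")
  if (background_level < 0 || background_level > 1)
    stop_invalid("`background_level` must lie in [0, 1]")
  if (abs(foreground_contrast) > 1)
    stop_invalid("`foreground_contrast` must lie in [-1, 1]")
  if (noise_sigma < 0) stop_invalid("`noise_sigma` must be non-negative")
  if (texture_amplitude < 0 || texture_amplitude > 1)
    stop_invalid("`texture_amplitude` must lie in [0, 1]")
  if (lesion_rate < 0) stop_invalid("`lesion_rate` must be non-negative")
  structure(list(name = name, background_level = background_level,
                 foreground_contrast = foreground_contrast,
                 noise_sigma = noise_sigma,
                 texture_amplitude = texture_amplitude,
                 lesion_rate = lesion_rate),
            class = "domain_config")
}

#' Foreground shape family for phantom generation
#'
#' The shape family fixes the *anatomy* of the phantom: a union of ellipses in
#' fractional image coordinates plus per-sample jitter ranges. `lung_pair`
#' (two tilted ellipses, mimicking lung fields on a chest radiograph) and
#' `cord_disc` (one near-circular ellipse, mimicking a spinal-cord
#' cross-section) are provided with sensible default geometry.
#'
#' @param kind `"lung_pair"` or `"cord_disc"`.
#' @param base_geometry Optional data frame with columns `cx, cy, ax, ay,
#'   theta` (ellipse centres, semi-axes and rotation, in unit-square
#'   coordinates). Defaults depend on `kind`.
#' @param jitter Named list with elements `center`, `scale`, `angle`: uniform
#'   half-ranges for per-sample centre translation (unit coords),
#'   multiplicative axis scaling, and rotation (radians). Use zeros for fully
#'   deterministic geometry.
#' @return An object of class `shape_family`.
#' @details All ellipses must lie fully inside the unit square after maximal
#'   jitter, which guarantees that every generated mask is non-empty and never
#'   touches the image border.
#' @export
shape_family <- function(kind = c("lung_pair", "cord_disc"),
                         base_geometry = NULL,
                         jitter = list(center = 0.03, scale = 0.08, angle = 0.08)) {
  kind <- match.arg(kind)
  if (is.null(base_geometry)) {
    base_geometry <- switch(kind,
      lung_pair = data.frame(
        cx = c(0.33, 0.67), cy = c(0.52, 0.52),
        ax = c(0.15, 0.15), ay = c(0.28, 0.28),
        theta = c(0.10, -0.10)),
      cord_disc = data.frame(cx = 0.5, cy = 0.5, ax = 0.18, ay = 0.14, theta = 0))
  }
  need <- c("cx", "cy", "ax", "ay", "theta")
  if (!all(need %in% names(base_geometry)))
    stop_invalid("`base_geometry` needs columns cx, cy, ax, ay, theta")
  ncomp <- nrow(base_geometry)
  if (kind == "lung_pair" && ncomp != 2L)
    stop_invalid("lung_pair must have exactly two ellipse components")
  if (kind == "cord_disc" && ncomp != 1L)
    stop_invalid("cord_disc must have exactly one ellipse component")
  if (any(base_geometry$ax <= 0) || any(base_geometry$ay <= 0))
    stop_invalid("ellipse semi-axes must be positive")
  jd <- list(center = 0, scale = 0, angle = 0)
  jd[names(jitter)] <- jitter
  # worst-case rotated-ellipse bounding box must stay inside the unit square
  for (i in seq_len(ncomp)) {
    g <- base_geometry[i, ]
    for (th in c(g$theta - jd$angle, g$theta + jd$angle)) {
      rx <- sqrt((g$ax * cos(th))^2 + (g$ay * sin(th))^2) * (1 + jd$scale) + jd$center
      ry <- sqrt((g$ax * sin(th))^2 + (g$ay * cos(th))^2) * (1 + jd$scale) + jd$center
      if (g$cx - rx < 0 || g$cx + rx > 1 || g$cy - ry < 0 || g$cy + ry > 1)
        stop_invalid("ellipse may leave the unit square under maximal jitter")
    }
  }
  structure(list(kind = kind, base_geometry = base_geometry, jitter = jd),
            class = "shape_family")
}

rasterize_ellipses <- function(geom, size) {
  H <- size[1]; W <- size[2]
  x <- (matrix(rep(seq_len(W), each = H), H, W) - 0.5) / W   # horizontal coord
  y <- (matrix(rep(seq_len(H), times = W), H, W) - 0.5) / H  # vertical coord
  mask <- matrix(0, H, W)
  for (i in seq_len(nrow(geom))) {
    g <- geom[i, ]
    u <- x - g$cx; v <- y - g$cy
    up <- u * cos(g$theta) + v * sin(g$theta)
    vp <- -u * sin(g$theta) + v * cos(g$theta)
    mask[(up / g$ax)^2 + (vp / g$ay)^2 <= 1] <- 1
  }
  mask
}

#' Generate one phantom image/mask pair
#'
#' Draws a jittered instance of the shape family, rasterizes it to a binary
#' mask, and renders a grayscale image under the domain's appearance model:
#' `background + contrast * mask + texture + lesions + noise`, clipped to
#' `[0, 1]`. Geometry randomness is driven by a sub-seed that does not depend
#' on the domain, so two domains with the same seed share an identical mask
#' while their images differ — the defining property of a multi-site dataset
#' with common anatomy.
#'
#' @param shape A [shape_family()].
#' @param domain A [domain_config()].
#' @param size Integer pair `c(H, W)`, both at least 32.
#' @param seed Integer seed; calls with identical arguments are bit-identical.
#' @return An object of class `phantom_sample`: list with `image` (H x W
#'   matrix in `[0,1]`), `mask` (H x W 0/1 matrix), `domain`, `sample_id`.
#' @export
#' @examples
#' s <- generate_phantom(shape_family("lung_pair"),
#'                       domain_config("a", 0.3, 0.4), c(64, 64), seed = 1)
#' mean(s$mask)
generate_phantom <- function(shape, domain, size = c(64L, 64L), seed = 1L) {
  stopifnot(inherits(shape, "shape_family"), inherits(domain, "domain_config"))
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 32L))
    stop_invalid("`size` must be two integers, each at least 32")
  H <- size[1]; W <- size[2]

  geo_seed <- derive_seed(seed, "geometry")
  app_seed <- derive_seed(seed, "appearance", domain$name)

  geom <- with_seed(geo_seed, {
    g <- shape$base_geometry
    j <- shape$jitter
    for (i in seq_len(nrow(g))) {
      g$cx[i] <- g$cx[i] + runif(1, -j$center, j$center)
      g$cy[i] <- g$cy[i] + runif(1, -j$center, j$center)
      s <- 1 + runif(1, -j$scale, j$scale)
      g$ax[i] <- g$ax[i] * s
      g$ay[i] <- g$ay[i] * s
      g$theta[i] <- g$theta[i] + runif(1, -j$angle, j$angle)
    }
    g
  })
  mask <- rasterize_ellipses(geom, size)

  img <- with_seed(app_seed, {
    out <- domain$background_level + domain$foreground_contrast * mask
    if (domain$texture_amplitude > 0) {
      xg <- (matrix(rep(seq_len(W), each = H), H, W) - 0.5) / W
      yg <- (matrix(rep(seq_len(H), times = W), H, W) - 0.5) / H
      ntex <- sample(2:4, 1)
      tex <- matrix(0, H, W)
      for (k in seq_len(ntex)) {
        fx <- runif(1, 0.5, 3); fy <- runif(1, 0.5, 3); ph <- runif(1, 0, 2 * pi)
        tex <- tex + sin(2 * pi * (fx * xg + fy * yg) + ph)
      }
      out <- out + domain$texture_amplitude * tex / ntex
    }
    if (domain$lesion_rate > 0) {
      nles <- rpois(1, domain$lesion_rate)
      if (nles > 0) {
        xg <- (matrix(rep(seq_len(W), each = H), H, W) - 0.5) / W
        yg <- (matrix(rep(seq_len(H), times = W), H, W) - 0.5) / H
        for (k in seq_len(nles)) {
          if (shape$kind == "lung_pair") {
            fg <- which(mask == 1)
            p <- fg[sample.int(length(fg), 1)]
          } else {
            p <- sample.int(H * W, 1)
          }
          cy <- yg[p]; cx <- xg[p]
          sg <- runif(1, 0.02, 0.05)
          amp <- runif(1, 0.15, 0.30)
          out <- out + amp * exp(-(((xg - cx)^2 + (yg - cy)^2) / (2 * sg^2)))
        }
      }
    }
    if (domain$noise_sigma > 0)
      out <- out + matrix(rnorm(H * W, 0, domain$noise_sigma), H, W)
    clip01(out)
  })

  structure(list(image = img, mask = mask, domain = domain$name,
                 sample_id = NA_integer_, seed = as.integer(seed)),
            class = "phantom_sample")
}

split_labels <- function(n, seed) {
  # floor/floor/remainder rule on the 65/15/20 ratio, order shuffled by seed
  n_train <- floor(n * 0.65)
  n_val <- floor(n * 0.15)
  lab <- c(rep("train", n_train), rep("val", n_val),
           rep("test", n - n_train - n_val))
  ord <- with_seed(seed, sample.int(n))
  lab[order(ord)]
}

#' Generate a multi-domain phantom dataset
#'
#' Generates `n_per_domain` samples for every domain, assigns each sample to a
#' train/validation/test split at the 65/15/20 ratio (floored counts, the
#' remainder going to test, shuffled by a seeded permutation), and optionally
#' writes 8-bit PNG images/masks plus a CSV manifest to `out_dir`. For a fixed
#' seed the i-th sample of every domain shares one mask; only image appearance
#' differs across domains.
#'
#' @inheritParams generate_phantom
#' @param domains List of [domain_config()] objects (at least one).
#' @param n_per_domain Samples per domain (>= 1).
#' @param out_dir Optional output directory; when given, `images/` and
#'   `masks/` PNG trees and `manifest.csv` are written under it.
#' @return A list of class `phantom_dataset` with `samples` (list of
#'   `phantom_sample`) and `manifest` (tibble with columns `path_image,
#'   path_mask, domain, split, sample_id, seed`).
#' @export
generate_dataset <- function(shape, domains, n_per_domain, size = c(64L, 64L),
                             seed = 1L, out_dir = NULL) {
  if (length(domains) == 0L) stop_invalid("`domains` must be non-empty")
  if (!all(vapply(domains, inherits, TRUE, "domain_config")))
    stop_invalid("`domains` must be a list of domain_config objects")
  if (n_per_domain < 1L) stop_invalid("`n_per_domain` must be at least 1")

  samples <- list()
  rows <- list()
  sid <- 0L
  for (di in seq_along(domains)) {
    dom <- domains[[di]]
    split <- split_labels(n_per_domain, derive_seed(seed, "split", dom$name))
    for (i in seq_len(n_per_domain)) {
      sample_seed <- derive_seed(seed, "sample", i)
      s <- generate_phantom(shape, dom, size, seed = sample_seed)
      sid <- sid + 1L
      s$sample_id <- sid
      samples[[sid]] <- s
      rows[[sid]] <- tibble::tibble(
        path_image = file.path("images", sprintf("%s_%04d.png", dom$name, i)),
        path_mask = file.path("masks", sprintf("%s_%04d.png", dom$name, i)),
        domain = dom$name, split = split[i], sample_id = sid,
        seed = sample_seed)
    }
  }
  manifest <- dplyr::bind_rows(rows)

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(samples)) {
      s <- samples[[k]]
      png::writePNG(round(255 * s$image) / 255,
                    file.path(out_dir, manifest$path_image[k]))
      png::writePNG(s$mask, file.path(out_dir, manifest$path_mask[k]))
    }
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  }
  structure(list(samples = samples, manifest = manifest),
            class = "phantom_dataset")
}

#' Load a phantom dataset written by [generate_dataset()]
#'
#' @param dir Directory containing `manifest.csv`, `images/` and `masks/`.
#' @return A `phantom_dataset` list (samples + manifest).
#' @export
load_dataset <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  samples <- vector("list", nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    img <- png::readPNG(file.path(dir, manifest$path_image[k]))
    msk <- png::readPNG(file.path(dir, manifest$path_mask[k]))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    samples[[k]] <- structure(
      list(image = img, mask = round(msk), domain = manifest$domain[k],
           sample_id = manifest$sample_id[k], seed = manifest$seed[k]),
      class = "phantom_sample")
  }
  structure(list(samples = samples, manifest = tibble::as_tibble(manifest)),
            class = "phantom_dataset")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %dx%d, domain '%s', foreground %.1f%%\n",
              nrow(x$image), ncol(x$image), x$domain, 100 * mean(x$mask)))
  invisible(x)
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d samples, %d domain(s)\n",
              length(x$samples), dplyr::n_distinct(x$manifest$domain)))
  print(dplyr::count(x$manifest, .data$domain, .data$split))
  invisible(x)
}
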