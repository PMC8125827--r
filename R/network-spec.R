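#' Declarative network specification
#'
#' Describes the encoder-decoder family used by both the segmentation network
#' and the DAE: `depth` encoder blocks whose kernel counts start at
#' `base_kernels` and double per block, a bottleneck with
#' `base_kernels * 2^depth` kernels, and a mirrored decoder. The reference
#' lung configuration is 256 x 256 input, base 16, depth 4, bottleneck 256,
#' which puts the latent feature map at 16 x 16 x 256.
#'
#' @param input_size Integer pair `c(H, W)`; both must be divisible by
#'   `2^depth`.
#' @param base_kernels Kernels in the first encoder block.
#' @param depth Number of encoder blocks.
#' @param bottleneck_kernels Kernels at the bottleneck; defaults to
#'   `base_kernels * 2^depth`, keeping the doubling rule.
#' @param skip_connections `TRUE` for the U-Net segmentation network, `FALSE`
#'   for the DAE.
#' @return A `network_spec` object.
#' @export
#' @examples
#' network_spec(c(256, 256), base_kernels = 16, depth = 4)
network_spec <- function(input_size = c(256L, 256L), base_kernels = 16L,
                         depth = 4L, bottleneck_kernels = NULL,
                         skip_connections = TRUE) {
  input_size <- as.integer(input_size)
  base_kernels <- as.integer(base_kernels)
  depth <- as.integer(depth)
  if (length(input_size) != 2L || any(input_size < 2L))
    stop_invalid("`input_size` must be a pair of positive integers")
  if (base_kernels < 1L) stop_invalid("`base_kernels` must be positive")
  if (depth < 1L) stop_invalid("`depth` must be at least 1")
  if (any(input_size %% (2^depth) != 0L))
    stop_invalid("input size must be divisible by 2^depth")
  if (is.null(bottleneck_kernels))
    bottleneck_kernels <- base_kernels * 2L^depth
  bottleneck_kernels <- as.integer(bottleneck_kernels)
  if (bottleneck_kernels < 1L) stop_invalid("`bottleneck_kernels` must be positive")
  structure(list(input_size = input_size, base_kernels = base_kernels,
                 depth = depth, bottleneck_kernels = bottleneck_kernels,
                 skip_connections = isTRUE(skip_connections)),
            class = "network_spec")
}

#' Spinal-cord configuration preset
#'
#' Transforms a lung-style specification into the spinal-cord variant:
#' four times more kernels, one encoder/decoder block removed, and a
#' 128 x 128 working resolution. The bottleneck keeps the doubling rule
#' (`base_kernels * 2^depth`).
#'
#' @param spec A [network_spec()] with `depth >= 2`.
#' @return The transformed `network_spec`.
#' @export
#' @examples
#' spinal_preset(network_spec(c(256, 256), 16, 4))  # base 64, depth 3
spinal_preset <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$depth < 2L) stop_invalid("preset requires depth >= 2")
  network_spec(input_size = c(128L, 128L),
               base_kernels = spec$base_kernels * 4L,
               depth = spec$depth - 1L,
               skip_connections = spec$skip_connections)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec> %dx%d input, base %d, depth %d, bottleneck %d, skips %s\n",
    x$input_size[1], x$input_size[2], x$base_kernels, x$depth,
    x$bottleneck_kernels, x$skip_connections))
  invisible(x)
}
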