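clip01 <- function(x) pmin(pmax(x, 0), 1)

is_binary <- function(m) is.numeric(m) && all(m == 0 | m == 1)

stop_invalid <- function(msg) rlang::abort(msg, class = "anatseg_invalid_argument")

stop_empty_region <- function(msg) rlang::abort(msg, class = "anatseg_empty_region")

# Deterministic 32-bit sub-seed derivation. Keeps every stochastic component
# on its own stream so that, e.g., the data-order draws of a run do not depend
# on whether a DAE is being initialised alongside the segmentation network.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    h <- (h * 69069 + v + 12345) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
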