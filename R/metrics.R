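#' Pixel confusion counts between two binary masks
#'
#' @param S Predicted binary mask.
#' @param G Ground-truth binary mask of the same shape.
#' @return List of class `confusion_counts` with integer `TP, FP, FN, TN`.
#' @export
confusion <- function(S, G) {
  check_same_shape(S, G)
  if (!is_binary(S) || !is_binary(G)) stop_invalid("masks must be binary 0/1")
  TP <- sum(S == 1 & G == 1)
  FP <- sum(S == 1 & G == 0)
  FN <- sum(S == 0 & G == 1)
  TN <- sum(S == 0 & G == 0)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN),
            class = "confusion_counts")
}

#' Intersection over union
#'
#' `TP / (TP + FP + FN)`: the ratio of the intersection and the union of the
#' predicted and ground-truth regions.
#'
#' @inheritParams confusion
#' @return Real in `[0, 1]`. Raises an error when both masks are empty
#'   (the ratio is undefined).
#' @export
iou <- function(S, G) {
  cc <- confusion(S, G)
  denom <- cc$TP + cc$FP + cc$FN
  if (denom == 0) stop_empty_region("IOU undefined: both masks are empty")
  cc$TP / denom
}

#' Dice similarity coefficient
#'
#' `2 TP / (2 TP + FP + FN)`; algebraically equal to `2*IOU / (1 + IOU)` and
#' therefore always at least as large as the IOU.
#'
#' @inheritParams confusion
#' @return Real in `[0, 1]`; errors when both masks are empty.
#' @export
dsc <- function(S, G) {
  cc <- confusion(S, G)
  denom <- 2 * cc$TP + cc$FP + cc$FN
  if (denom == 0) stop_empty_region("DSC undefined: both masks are empty")
  2 * cc$TP / denom
}

#' Boundary pixels of a binary mask
#'
#' A boundary pixel is a foreground pixel with at least one background
#' neighbour under the chosen connectivity (4 by default), where off-image
#' neighbours count as background — so a mask touching the image border has
#' boundary pixels along that border, and an isolated pixel is its own
#' boundary.
#'
#' @param M Non-empty binary mask.
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal).
#' @return Integer matrix with one `(row, col)` pixel coordinate per row.
#' @export
extract_boundary <- function(M, connectivity = 4) {
  if (!is_binary(M)) stop_invalid("mask must be binary 0/1")
  if (sum(M) == 0) stop_empty_region("cannot extract the boundary of an empty mask")
  if (!connectivity %in% c(4, 8)) stop_invalid("connectivity must be 4 or 8")
  H <- nrow(M); W <- ncol(M)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- M
  ctr <- pad[2:(H + 1), 2:(W + 1)]
  nb_min <- pmin(pad[1:H, 2:(W + 1)], pad[3:(H + 2), 2:(W + 1)],
                 pad[2:(H + 1), 1:W], pad[2:(H + 1), 3:(W + 2)])
  if (connectivity == 8) {
    nb_min <- pmin(nb_min, pad[1:H, 1:W], pad[1:H, 3:(W + 2)],
                   pad[3:(H + 2), 1:W], pad[3:(H + 2), 3:(W + 2)])
  }
  idx <- which(ctr == 1 & nb_min == 0, arr.ind = TRUE)
  unname(idx)
}

boundary_dists <- function(S, G, connectivity = 4) {
  bs <- extract_boundary(S, connectivity)
  bg <- extract_boundary(G, connectivity)
  list(d_sg = .min_dists(bs * 1.0, bg * 1.0),
       d_gs = .min_dists(bg * 1.0, bs * 1.0))
}

#' Average contour distance
#'
#' Mean of the two directed average boundary distances: for each boundary
#' pixel of one mask, the Euclidean distance to the nearest boundary pixel of
#' the other, averaged within each direction, then averaged across the two
#' directions. Symmetric in its arguments; zero iff the boundary sets
#' coincide. Units are pixels.
#'
#' @inheritParams extract_boundary
#' @param S,G Non-empty binary masks of equal shape.
#' @return Non-negative real.
#' @export
acd <- function(S, G, connectivity = 4) {
  check_same_shape(S, G)
  d <- boundary_dists(S, G, connectivity)
  (mean(d$d_sg) + mean(d$d_gs)) / 2
}

#' Average surface distance
#'
#' Pools all `n_S + n_G` nearest-boundary distances into a single mean
#' (rather than averaging the two directed means as [acd()] does); the two
#' coincide when the boundary sets have equal cardinality.
#'
#' @inheritParams acd
#' @return Non-negative real.
#' @export
asd <- function(S, G, connectivity = 4) {
  check_same_shape(S, G)
  d <- boundary_dists(S, G, connectivity)
  (sum(d$d_sg) + sum(d$d_gs)) / (length(d$d_sg) + length(d$d_gs))
}

#' Evaluate a batch of predictions
#'
#' Binarizes probability maps at `threshold` and computes IOU, DSC, ACD and
#' ASD per image. Images whose binarized prediction is empty have undefined
#' distance metrics; they are returned with `acd`/`asd` set to `NA` and
#' `flagged = TRUE` so that aggregation can exclude them with a logged count.
#'
#' @param predictions List of probability matrices (or a single matrix).
#' @param masks List of binary ground-truth masks (same length/shapes).
#' @param threshold Binarization threshold in `(0, 1)`.
#' @param sample_id,domain Optional vectors recycled into the output.
#' @return Tibble with one row per image: `sample_id, domain, iou, dsc, acd,
#'   asd, flagged`.
#' @export
evaluate_batch <- function(predictions, masks, threshold = 0.5,
                           sample_id = NULL, domain = NULL) {
  if (is.matrix(predictions)) predictions <- list(predictions)
  if (is.matrix(masks)) masks <- list(masks)
  if (length(predictions) != length(masks))
    stop_invalid("`predictions` and `masks` must have the same length")
  if (threshold <= 0 || threshold >= 1)
    stop_invalid("`threshold` must lie in (0, 1)")
  n <- length(predictions)
  sample_id <- sample_id %||% seq_len(n)
  domain <- domain %||% rep(NA_character_, n)
  rows <- lapply(seq_len(n), function(i) {
    S <- (predictions[[i]] >= threshold) * 1
    G <- masks[[i]]
    flagged <- sum(S) == 0 || sum(G) == 0
    cc <- confusion(S, G)
    denom <- cc$TP + cc$FP + cc$FN
    tibble::tibble(
      sample_id = sample_id[i], domain = domain[i],
      iou = if (denom == 0) NA_real_ else cc$TP / denom,
      dsc = if (denom == 0) NA_real_ else 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN),
      acd = if (flagged) NA_real_ else acd(S, G),
      asd = if (flagged) NA_real_ else asd(S, G),
      flagged = flagged)
  })
  dplyr::bind_rows(rows)
}

#' Aggregate per-image metric records
#'
#' @param records Tibble from [evaluate_batch()].
#' @return Tibble with one row per metric: `metric, mean, sd, n`. Flagged
#'   records are excluded from the distance metrics (their count is reported
#'   in the `n` column and as a message when any were dropped).
#' @export
aggregate_metrics <- function(records) {
  n_flag <- sum(records$flagged)
  if (n_flag > 0)
    message(sprintf("%d record(s) with empty predictions excluded from ACD/ASD", n_flag))
  long <- tidyr::pivot_longer(records, c("iou", "dsc", "acd", "asd"),
                              names_to = "metric", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  dplyr::summarise(dplyr::group_by(long, .data$metric),
                   mean = mean(.data$value), sd = sd(.data$value),
                   n = dplyr::n(), .groups = "drop")
}
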