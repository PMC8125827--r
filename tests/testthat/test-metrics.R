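test_that("confusion counts and overlap metrics match pixel enumeration", {
  G <- matrix(0, 6, 6); G[2:3, 2:3] <- 1
  S <- matrix(0, 6, 6); S[3:4, 2:3] <- 1     # overlap of two pixels
  cc <- confusion(S, G)
  expect_equal(cc$TP, 2); expect_equal(cc$FP, 2); expect_equal(cc$FN, 2)
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 36)
  expect_equal(iou(S, G), 2 / 6)
  expect_equal(dsc(S, G), 4 / 8)
  expect_equal(iou(G, G), 1)
  expect_equal(dsc(G, G), 1)
  expect_equal(iou(S * 0 + (1 - G), G), 0)   # complement: no intersection...
  expect_error(iou(matrix(0, 4, 4), matrix(0, 4, 4)),
               class = "anatseg_empty_region")
  expect_error(confusion(G, matrix(0, 4, 4)), class = "anatseg_invalid_argument")
})

test_that("dsc and iou obey their algebraic identity on random masks", {
  set.seed(1)
  for (i in 1:200) {
    S <- rand_mask(12, 12); G <- rand_mask(12, 12)
    a <- iou(S, G); d <- dsc(S, G)
    expect_equal(d, 2 * a / (1 + a), tolerance = 1e-12)
    expect_gte(d, a)
  }
})

test_that("boundary extraction matches enumeration and its conventions", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  expect_equal(extract_boundary(m), matrix(c(3, 3), 1, 2))  # isolated pixel
  sq <- matrix(0, 5, 5); sq[2:4, 2:4] <- 1
  b <- extract_boundary(sq)
  expect_equal(nrow(b), 8)                                  # 3x3 square rim
  expect_equal(bf_boundary(sq)[order(bf_boundary(sq)[, 1], bf_boundary(sq)[, 2]), ],
               b[order(b[, 1], b[, 2]), ])
  full <- matrix(1, 4, 6)                                   # off-image = background
  expect_equal(nrow(extract_boundary(full)), 2 * 4 + 2 * 6 - 4)
  expect_error(extract_boundary(matrix(0, 3, 3)), class = "anatseg_empty_region")
  # 8-connectivity can only add boundary pixels, never remove them
  expect_gte(nrow(extract_boundary(sq, connectivity = 8)), nrow(b))
})

test_that("surface distances match the exhaustive oracle on random pairs", {
  set.seed(2)
  S1 <- matrix(0, 5, 5); S1[1, 1] <- 1
  G1 <- matrix(0, 5, 5); G1[1, 3] <- 1
  expect_equal(acd(S1, G1), 2.0)            # single-pixel boundary sets
  expect_equal(asd(S1, G1), 2.0)            # equal cardinality: ASD == ACD
  for (i in 1:40) {
    S <- rand_mask(24, 24); G <- rand_mask(24, 24)
    expect_equal(acd(S, G), bf_acd(S, G), tolerance = 1e-9)
    expect_equal(asd(S, G), bf_asd(S, G), tolerance = 1e-9)
    expect_equal(acd(S, G), acd(G, S), tolerance = 1e-12)   # symmetry
    expect_equal(asd(S, G), asd(G, S), tolerance = 1e-12)
  }
  G <- rand_mask(10, 10)
  expect_equal(acd(G, G), 0)
  expect_equal(asd(G, G), 0)
})

test_that("all four metrics are translation invariant", {
  set.seed(3)
  S <- matrix(0, 20, 20); S[4:9, 5:11] <- 1
  G <- matrix(0, 20, 20); G[5:11, 4:9] <- 1
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  S2 <- shift(S, 4, 3); G2 <- shift(G, 4, 3)
  expect_equal(iou(S2, G2), iou(S, G))
  expect_equal(dsc(S2, G2), dsc(S, G))
  expect_equal(acd(S2, G2), acd(S, G), tolerance = 1e-12)
  expect_equal(asd(S2, G2), asd(S, G), tolerance = 1e-12)
})

test_that("batch evaluation records, flags and aggregates correctly", {
  set.seed(4)
  masks <- lapply(1:3, function(i) rand_mask(16, 16, 0.2))
  preds <- lapply(masks, function(m) m * 0.9 + 0.05)  # perfect at threshold .5
  rec <- evaluate_batch(preds, masks, domain = rep("d1", 3))
  expect_equal(nrow(rec), 3)
  expect_equal(rec$iou, rep(1, 3))
  expect_equal(rec$dsc, rep(1, 3))
  expect_equal(rec$acd, rep(0, 3))
  expect_equal(rec$asd, rep(0, 3))
  # empty prediction is flagged and excluded from distance aggregation
  preds[[2]] <- matrix(0.1, 16, 16)
  rec <- evaluate_batch(preds, masks)
  expect_true(rec$flagged[2])
  expect_true(is.na(rec$acd[2]))
  expect_equal(rec$iou[2], 0)
  expect_message(agg <- aggregate_metrics(rec), "excluded")
  expect_equal(agg$n[agg$metric == "acd"], 2)
  expect_equal(agg$mean[agg$metric == "iou"], mean(rec$iou))
  expect_equal(agg$sd[agg$metric == "dsc"], sd(rec$dsc))
  expect_error(evaluate_batch(preds, masks, threshold = 1.5),
               class = "anatseg_invalid_argument")
})
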