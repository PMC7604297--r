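test_that("confusion counts match a brute-force per-pixel tally", {
  set.seed(31)
  m <- matrix(sample(0:1, 64, TRUE), 8, 8)
  expect_equal(confusion(m, m)$FP, 0)
  expect_equal(confusion(m, m)$FN, 0)
  allr <- matrix(1L, 10, 10); allb <- matrix(0L, 10, 10)
  cc <- confusion(allr, allb)
  expect_equal(cc$FP, 100); expect_equal(cc$TP, 0)
  for (i in 1:5) {
    pred <- matrix(sample(0:1, 64, TRUE), 8, 8)
    truth <- matrix(sample(0:1, 64, TRUE), 8, 8)
    tp <- fp <- fn <- tn <- 0
    for (r in 1:8) for (c in 1:8) {
      if (pred[r, c] == 1 && truth[r, c] == 1) tp <- tp + 1
      else if (pred[r, c] == 1) fp <- fp + 1
      else if (truth[r, c] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
    cc <- confusion(pred, truth)
    expect_equal(unlist(cc[c("TP", "FP", "FN", "TN")]),
                 c(TP = tp, FP = fp, FN = fn, TN = tn))
  }
  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3)), "dims")
  expect_error(confusion(matrix(2L, 2, 2), matrix(0L, 2, 2)), "binary")
})

test_that("metric identities hold on randomized counts", {
  set.seed(17)
  for (i in 1:50) {
    cc <- random_counts()
    mr <- metrics_from_counts(cc)
    vals <- c(mr$accuracy, mr$precision, mr$recall, mr$f1, mr$dice)
    expect_true(all(vals >= 0 & vals <= 1))
    # rational-arithmetic oracle
    if (cc$TP + cc$FP > 0) expect_equal(mr$precision, cc$TP / (cc$TP + cc$FP))
    if (cc$TP + cc$FN > 0) expect_equal(mr$recall, cc$TP / (cc$TP + cc$FN))
    # dice == F1 from the same counts
    if (2 * cc$TP + cc$FP + cc$FN > 0)
      expect_equal(mr$dice, mr$f1, tolerance = 1e-12)
    # F1 is the harmonic mean, bounded by min/max of P and R
    if (mr$precision + mr$recall > 0) {
      expect_equal(mr$f1, 2 * mr$precision * mr$recall / (mr$precision + mr$recall))
      expect_gte(mr$f1 + 1e-12, min(mr$precision, mr$recall))
      expect_lte(mr$f1 - 1e-12, max(mr$precision, mr$recall))
    }
    # swapping pred/truth swaps FP/FN and precision/recall, keeps TP and dice
    sw <- metrics_from_counts(as_confusion(c(TP = cc$TP, FP = cc$FN,
                                             FN = cc$FP, TN = cc$TN)))
    expect_equal(sw$precision, mr$recall)
    expect_equal(sw$recall, mr$precision)
    expect_equal(sw$dice, mr$dice)
  }
  # P = R = p -> F1 = p
  for (p in c(0.1, 0.5, 0.9702)) expect_equal(f1_score(p, p), p)
  # degenerate counts are flagged, not NaN
  z <- metrics_from_counts(as_confusion(c(TP = 0, FP = 0, FN = 0, TN = 10)))
  expect_equal(z$precision, 0)
  expect_true("precision" %in% z$degenerate)
  expect_false(anyNA(unlist(z[c("accuracy", "precision", "recall", "f1", "dice")])))
})

test_that("evaluation pools counts per image and is order-invariant", {
  scenes <- thin_scenes(4L, 3000L)
  m <- build_model(tiny_spec(), seed = 2)
  r1 <- evaluate_model(m, scenes)
  r2 <- evaluate_model(m, scenes)
  expect_equal(r1$counts, r2$counts)             # deterministic
  per <- attr(r1, "per_image")
  expect_equal(nrow(per), 4L)
  expect_equal(sum(per$TP), r1$counts$TP)        # micro = summed counts
  expect_equal(sum(per$FP), r1$counts$FP)
  r3 <- evaluate_model(m, rev(scenes))
  expect_equal(r3$counts, r1$counts)             # order-invariant
  # macro averages the per-image metrics
  rm <- evaluate_model(m, scenes, aggregation = "macro")
  expect_equal(rm$dice, mean(per$dice))
  # self-comparison: evaluating the truth as prediction is perfect
  self <- confusion(scenes[[1]]$mask, scenes[[1]]$mask)
  mr <- metrics_from_counts(self)
  expect_equal(mr$f1, 1)
  expect_equal(mr$dice, 1)
})

test_that("compare_heads reports per-model rows and zero delta for identical models", {
  scenes <- thin_scenes(3L, 4000L)
  m <- build_model(tiny_spec(), seed = 2)
  res <- compare_heads(scenes, list(a = m, b = m))
  expect_equal(nrow(res$summary), 2L)
  expect_equal(res$summary$dice[1], res$summary$dice[2])
  expect_true(all(res$per_image$dice_delta[res$per_image$model == "b"] == 0))
})

test_that("root length follows the link-weighted skeleton convention", {
  expect_equal(estimate_root_length(matrix(0L, 10, 10)), 0)
  line <- matrix(0L, 20, 60); line[10, 6:55] <- 1L
  expect_equal(estimate_root_length(line), 49)
  diag <- matrix(0L, 40, 40); for (i in 5:30) diag[i, i] <- 1L
  expect_equal(estimate_root_length(diag), 25 * sqrt(2))
  expect_error(estimate_root_length(matrix(3L, 4, 4)), "binary")
})

test_that("skeleton length tracks the generator's analytic centreline", {
  # frozen seeds; thin unbranched strokes (widths <= 5 px); the +-10%
  # tolerance absorbs the sqrt(2) chain-code digitisation bias
  for (s in 1:5) {
    sc <- generate_scene(scene_params(canvas_height = 256L, canvas_width = 256L,
                                      n_roots = 2L, main_width_range = c(2, 4),
                                      branch_probability = 0, n_distractors = 0L,
                                      seed = s))
    est <- estimate_root_length(sc$mask)
    expect_lt(abs(est - sc$extras$centerline_length) / sc$extras$centerline_length,
              0.10)
  }
})
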