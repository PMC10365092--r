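test_that("confusion counts partition the grid", {
  pred <- array(0L, c(10, 1, 1)); pred[1:4, 1, 1] <- 1L
  truth <- pred
  cc <- confusion(pred, truth)
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 4L, fp = 0L, tn = 6L, fn = 0L))
  empty <- array(0L, c(10, 1, 1))
  t3 <- array(0L, c(10, 1, 1)); t3[1:3, 1, 1] <- 1L
  cc2 <- confusion(empty, t3)
  expect_equal(cc2$fn, 3L)
  expect_equal(cc2$tp + cc2$fp + cc2$tn + cc2$fn, 10L)
  expect_error(confusion(pred, array(0L, c(9, 1, 1))), "shape mismatch")
})

test_that("overlap metrics and both naming conventions are correct", {
  a <- array(1L, c(3, 1, 1))
  expect_equal(dice(confusion(a, a)), 1)
  expect_equal(sensitivity(confusion(a, a)), 1)
  b <- array(0L, c(3, 1, 1))
  expect_equal(dice(confusion(a, rev(b))), 0)
  # truth = [1,1,1,0], pred = [1,0,0,0]: the two conventions disagree
  truth <- array(c(1L, 1L, 1L, 0L), c(4, 1, 1))
  pred <- array(c(1L, 0L, 0L, 0L), c(4, 1, 1))
  cc <- confusion(pred, truth)
  expect_equal(sensitivity(cc, "standard"), 1 / 3)
  expect_equal(sensitivity(cc, "as_printed"), 1)
  expect_equal(specificity(cc, "standard"), 1)
  expect_equal(specificity(cc, "as_printed"), 1 / 3)
  # both masks empty: Dice 1 by convention, flagged
  d0 <- dice(confusion(b, b))
  expect_equal(as.numeric(d0), 1)
  expect_true(attr(d0, "degenerate"))
})

test_that("overlap metrics agree with brute force on random 3x3x3 masks", {
  set.seed(99)
  for (rep in 1:200) {
    pred <- array(rbinom(27, 1, 0.4), c(3, 3, 3))
    truth <- array(rbinom(27, 1, 0.4), c(3, 3, 3))
    tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
    tn <- sum(pred == 0 & truth == 0); fn <- sum(pred == 0 & truth == 1)
    cc <- confusion(pred, truth)
    expect_equal(cc$tp, tp); expect_equal(cc$fp, fp)
    expect_equal(cc$tn, tn); expect_equal(cc$fn, fn)
    if (2 * tp + fp + fn > 0) {
      expect_equal(dice(cc), 2 * tp / (2 * tp + fp + fn))
    }
  }
})

test_that("surface distances respect geometry and spacing", {
  a <- array(0L, c(7, 3, 3)); a[2, 2, 2] <- 1L
  b <- array(0L, c(7, 3, 3)); b[5, 2, 2] <- 1L
  sd_ <- surface_distances(a, b, spacing = 1)
  expect_equal(as.vector(sd_$pred_to_truth), 3)
  expect_equal(as.vector(sd_$truth_to_pred), 3)
  # identical masks: all zero
  sd0 <- surface_distances(a, a)
  expect_true(all(c(sd0$pred_to_truth, sd0$truth_to_pred) == 0))
  # anisotropic spacing: one-voxel offset along the third axis, 2 mm slices
  c1 <- array(0L, c(3, 3, 3)); c1[2, 2, 1] <- 1L
  c2 <- array(0L, c(3, 3, 3)); c2[2, 2, 2] <- 1L
  sd2 <- surface_distances(c1, c2, spacing = c(1, 1, 2))
  expect_equal(as.vector(sd2$pred_to_truth), 2)
  expect_error(surface_distances(a, array(0L, c(7, 3, 3))), "empty mask")
})

test_that("hausdorff and ASSD summarize the union of directed sets", {
  sd_ <- structure(list(pred_to_truth = c(1, 3), truth_to_pred = 2),
                   class = "surface_distance_set")
  expect_equal(hausdorff(sd_), 3)
  expect_equal(assd(sd_), 2)
  z <- structure(list(pred_to_truth = 0, truth_to_pred = 0),
                 class = "surface_distance_set")
  expect_equal(hausdorff(z), 0)
  expect_equal(assd(z), 0)
})

test_that("distance metrics match brute force on exhaustive single-voxel pairs", {
  dims <- c(3, 3, 3)
  coords <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  for (i in seq_len(27)) for (j in seq_len(27)) {
    a <- array(0L, dims); a[coords[i, 1], coords[i, 2], coords[i, 3]] <- 1L
    b <- array(0L, dims); b[coords[j, 1], coords[j, 2], coords[j, 3]] <- 1L
    d_true <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    sd_ <- surface_distances(a, b)
    expect_equal(hausdorff(sd_), d_true)
    expect_equal(assd(sd_), d_true)
    expect_gte(hausdorff(sd_), assd(sd_))
  }
})

test_that("hausdorff is symmetric and HD >= ASSD on random masks", {
  set.seed(13)
  for (rep in 1:20) {
    a <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
    b <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
    if (!any(a == 1) || !any(b == 1)) next
    sab <- surface_distances(a, b)
    sba <- surface_distances(b, a)
    expect_equal(hausdorff(sab), hausdorff(sba))
    expect_gte(hausdorff(sab), assd(sab))
  }
})

test_that("VVC is the population coefficient of variation of pass volumes", {
  # identical passes -> 0
  probs <- array(rep(c(1, 1, 0, 0), each = 2), c(2, 2, 2, 1, 2))
  v0 <- vvc(as_stack(probs), tract = 1)
  expect_equal(v0$vvc, 0)
  # volumes 2 and 4: mu 3, sigma 1, VVC 1/3
  p2 <- array(0, c(2, 4, 1, 1, 1))
  p2[1, 1:2, 1, 1, 1] <- 1
  p2[2, 1:4, 1, 1, 1] <- 1
  v2 <- vvc(as_stack(p2), tract = 1)
  expect_equal(v2$volumes, c(2, 4))
  expect_equal(v2$mu, 3)
  expect_equal(v2$sigma, 1)
  expect_equal(v2$vvc, 1 / 3)
  # scale invariance: doubling the grid (voxel counts) preserves VVC
  p4 <- array(0, c(2, 8, 1, 1, 1))
  p4[1, 1:4, 1, 1, 1] <- 1
  p4[2, 1:8, 1, 1, 1] <- 1
  expect_equal(vvc(as_stack(p4), 1)$vvc, v2$vvc)
})

test_that("mean pass Dice averages per-pass agreement with the truth", {
  truth <- array(c(1L, 1L, 0L, 0L), c(4, 1, 1))
  # passes alternate between the truth and a disjoint mask
  probs <- array(0, c(2, 4, 1, 1, 1))
  probs[1, 1:2, 1, 1, 1] <- 1
  probs[2, 3:4, 1, 1, 1] <- 1
  expect_equal(mean_pass_dice(as_stack(probs), truth), 0.5)
  # all passes equal to truth -> 1
  probs2 <- array(rep(c(1, 1, 0, 0), each = 2), c(2, 4, 1, 1, 1))
  expect_equal(mean_pass_dice(as_stack(probs2), truth), 1)
})

test_that("spearman follows the average-rank convention", {
  x <- c(1, 5, 9, 12)
  expect_equal(spearman(x, exp(x)), 1)
  expect_equal(spearman(x, -x^3), -1)
  # hand-computed tie case
  expect_equal(spearman(c(1, 2, 3), c(2, 2, 3)), 0.866025, tolerance = 1e-6)
  # independent oracle: pearson on average ranks
  set.seed(21)
  a <- rnorm(30); b <- rnorm(30) + a
  expect_equal(spearman(a, b), cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_true(is.na(spearman(c(1, 1, 1), c(1, 2, 3))))
})

test_that("residual maps are signed and obey the complement symmetry", {
  truth <- array(c(1L, 0L), c(2, 1, 1))
  prob <- array(c(0.3, 0.3), c(2, 1, 1))
  r <- residual_map(truth, prob)
  expect_equal(as.vector(r), c(0.7, -0.3))
  expect_equal(residual_map(truth, array(c(1, 0), c(2, 1, 1))),
               array(0, c(2, 1, 1)))
  # y -> 1 - y flips the residual around (1 - 2p)
  r2 <- residual_map(1L - truth, prob)
  expect_equal(as.vector(r + r2), as.vector(1 - 2 * prob))
})

test_that("metric report tabulates all metrics per tract", {
  pred <- array(0L, c(5, 5, 5, 2))
  truth <- array(0L, c(5, 5, 5, 2))
  pred[2:4, 2:4, 2:4, 1] <- 1L
  truth[2:4, 2:4, 2:4, 1] <- 1L
  truth[1:2, 1, 1, 2] <- 1L
  rep_ <- metric_report(pred, truth, subject = "s1")
  expect_equal(nrow(rep_), 2)
  expect_equal(rep_$dice[1], 1)
  expect_equal(rep_$hausdorff_mm[1], 0)
  expect_true(is.na(rep_$hausdorff_mm[2]))  # empty prediction -> missing
  agg <- aggregate_metrics(rep_)
  expect_true("dice" %in% agg$metric)
})
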