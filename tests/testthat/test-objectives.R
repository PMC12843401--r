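test_that("cross-entropy identities hold", {
  y <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(ce_loss(y, y), 0, tolerance = 1e-9)
  p_unif <- matrix(0.5, 2, 2)
  expect_equal(ce_loss(p_unif, y), log(2), tolerance = 1e-12)
  p <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, byrow = TRUE)
  expect_equal(ce_loss(p, y), -(log(0.8) + log(0.6)) / 2, tolerance = 1e-12)
  expect_equal(round(ce_loss(p, y), 4), 0.3670)
  # exact zero at a true class stays finite
  p0 <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  expect_true(is.finite(ce_loss(p0, y)))
})

test_that("Dice loss identities hold over the foreground classes", {
  cfg <- loss_config()
  y <- to_onehot(matrix(c(0L, 1L, 1L, 0L), 2), 2)
  expect_lt(dice_loss(y, y, cfg), 2 * cfg$smooth)
  # disjoint hard masks on the foreground class
  p_disj <- to_onehot(matrix(c(1L, 0L, 0L, 1L), 2), 2)
  expect_gt(dice_loss(p_disj, y, cfg), 1 - 1e-3)
  # |P| = |G| = 2, overlap 1: 1 - 2/4
  yy <- to_onehot(matrix(c(1L, 1L, 0L, 0L), 4, 1), 2)
  pp <- to_onehot(matrix(c(1L, 0L, 1L, 0L), 4, 1), 2)
  expect_equal(dice_loss(pp, yy, cfg), 0.5, tolerance = 1e-4)
  expect_error(dice_loss(matrix(1, 4, 1), matrix(0L, 2, 2)), "foreground")
})

test_that("the compound loss is the stated weighted sum", {
  withr::with_seed(6, {
    for (k in 1:5) {
      logit <- matrix(stats::rnorm(20 * 3), 20, 3)
      p <- t(apply(logit, 1, function(r) { e <- exp(r); e / sum(e) }))
      y <- matrix(sample(0:2, 20, TRUE), 4, 5)
      tl <- total_loss(p, y, loss_config())
      expect_equal(as.numeric(tl),
                   0.5 * ce_loss(p, y) + 0.5 * dice_loss(p, y),
                   tolerance = 1e-15)
      expect_equal(attr(tl, "ce") * 0.5 + attr(tl, "dice") * 0.5,
                   as.numeric(tl), tolerance = 1e-15)
    }
  })
  # perfect prediction
  y <- matrix(c(0L, 1L, 1L, 0L), 2)
  tl <- total_loss(to_onehot(y, 2), y)
  expect_lt(as.numeric(tl), 1e-4)
})

test_that("Dice loss decreases as probability mass moves onto the target", {
  y <- to_onehot(matrix(c(0L, 1L, 1L, 1L), 2), 2)
  losses <- vapply(seq(0.05, 0.95, by = 0.1), function(a) {
    p <- matrix(c(1 - a, a), 4, 2, byrow = TRUE)
    dice_loss(p, y)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("DSC and IOU identities and conventions hold", {
  A <- matrix(c(1, 1, 0, 0), 2); B <- matrix(c(1, 0, 1, 0), 2)
  expect_equal(dsc(A, A), 100)
  expect_equal(iou(A, A), 1)
  expect_equal(dsc(A, B), 50)
  expect_equal(iou(A, B), 1 / 3)
  disj <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(dsc(A, disj), 0)
  z <- matrix(0, 2, 2)
  expect_equal(dsc(z, z), 100)
  expect_equal(iou(z, z), 1)
  expect_equal(dsc(A, B), dsc(B, A))
  expect_equal(iou(A, B), iou(B, A))
  expect_error(dsc(A, matrix(0, 3, 3)), "identical shape")
})

test_that("DSC = 2 IOU / (1 + IOU) on random mask pairs", {
  withr::with_seed(12, {
    for (k in 1:200) {
      P <- matrix(stats::runif(64) > 0.5, 8, 8)
      G <- matrix(stats::runif(64) > 0.5, 8, 8)
      i <- iou(P, G)
      expect_equal(dsc(P, G), 100 * 2 * i / (1 + i), tolerance = 1e-12)
    }
  })
})

test_that("HD95 matches the exhaustive pairwise oracle", {
  expect_equal(hd95(matrix(c(0, 1, 0, 0), 2), matrix(c(0, 1, 0, 0), 2)), 0)
  # single pixels offset by one along each axis, anisotropic spacing
  P <- matrix(0, 5, 5); P[2, 2] <- 1
  G1 <- matrix(0, 5, 5); G1[3, 2] <- 1   # offset along axis 1
  G2 <- matrix(0, 5, 5); G2[2, 3] <- 1   # offset along axis 2
  expect_equal(hd95(P, G1, spacing = c(1, 2)), 1.0)
  expect_equal(hd95(P, G2, spacing = c(1, 2)), 2.0)
  expect_equal(hd95(P, G1, spacing = c(1, 1)), 1.0)
  # random blobs vs the brute-force oracle
  withr::with_seed(30, {
    for (k in 1:10) {
      A <- matrix(stats::runif(100) > 0.6, 10, 10)
      B <- matrix(stats::runif(100) > 0.6, 10, 10)
      if (!any(A) || !any(B)) next
      sp <- sample(1:3, 2, TRUE)
      expect_equal(hd95(A, B, spacing = sp), ref_hd95(A, B, spacing = sp),
                   tolerance = 1e-12)
      expect_equal(hd95(A, B, spacing = sp), hd95(B, A, spacing = sp))
    }
  })
})

test_that("empty masks give a flagged undefined HD95, excluded from summaries", {
  P <- matrix(0, 4, 4); G <- matrix(0, 4, 4); G[2, 2] <- 1
  h <- hd95(P, G)
  expect_true(is.na(h))
  expect_true(attr(h, "undefined"))
  rep <- evaluate_masks(matrix(0L, 4, 4), G + 0L, num_classes = 2)
  expect_equal(rep$dsc, 0)
  expect_false(rep$hd95_defined)
  s <- summarize_metrics(rep)
  expect_equal(s$n_hd95_undefined, 1L)
  expect_true(is.na(s$mean_hd95))
})

test_that("volumetric evaluation equals stacked slice evaluation shapes", {
  withr::with_seed(9, {
    sl <- matrix(sample(0:2, 64, TRUE, prob = c(0.7, 0.2, 0.1)), 8, 8)
  })
  v <- array(sl, c(8, 8, 3))  # identical slices stacked
  rep3 <- evaluate_masks(v, v, num_classes = 3, spacing = c(1, 1, 2))
  expect_equal(rep3$dsc, c(100, 100))
  expect_equal(rep3$hd95[rep3$hd95_defined], rep(0, sum(rep3$hd95_defined)))
  rep2 <- evaluate_masks(sl, sl, num_classes = 3)
  expect_equal(rep2$iou, rep3$iou)
})
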