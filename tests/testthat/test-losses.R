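# Box-regression and classification losses.

test_that("giou_loss matches hand geometry", {
  # identical boxes: GIoU = 1, loss 0
  expect_equal(giou_loss(c(0, 0, 1, 1), c(0, 0, 1, 1)), 0, tolerance = 1e-12)
  # corner-touching unit squares: IoU 0, C area 4, union 2 -> GIoU -0.5
  expect_equal(giou_loss(c(0, 0, 1, 1), c(1, 1, 2, 2)), 1.5, tolerance = 1e-9)
  # far-separated equal boxes approach loss 2
  expect_gt(giou_loss(c(0, 0, 1, 1), c(1e5, 0, 1e5 + 1, 1)), 1.99)
  # hand case: half-overlapping horizontal pair
  # pred (0,0,2,2), target (1,0,3,2): inter 2, union 6, IoU 1/3;
  # C = (0,0,3,2) area 6 -> GIoU = 1/3 - 0 = 1/3, loss 2/3
  expect_equal(giou_loss(c(0, 0, 2, 2), c(1, 0, 3, 2)), 2 / 3, tolerance = 1e-9)
  expect_error(giou_loss(c(0, 0, 0, 1), c(0, 0, 1, 1)), "positive area")
})

test_that("diou_loss matches hand geometry and stays within bounds", {
  expect_identical(diou_loss(c(3, 4, 7, 9), c(3, 4, 7, 9)), 0)
  # IoU 0, centers (0.5,0.5) vs (1.5,1.5): rho2 = 2; diag of (0,0,2,2): c2 = 8
  expect_equal(diou_loss(c(0, 0, 1, 1), c(1, 1, 2, 2)), 1 + 2 / 8, tolerance = 1e-9)
  # IoU 1/3, rho2 = 1, c2 = 9 + 4 = 13
  expect_equal(diou_loss(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 - 1 / 3 + 1 / 13,
               tolerance = 1e-9)
  # vectorized over pairs
  p <- rbind(c(0, 0, 1, 1), c(0, 0, 2, 2))
  t <- rbind(c(1, 1, 2, 2), c(1, 0, 3, 2))
  expect_equal(diou_loss(p, t), c(1.25, 1 - 1 / 3 + 1 / 13), tolerance = 1e-9)
  expect_error(diou_loss(c(1, 1, 1, 2), c(0, 0, 1, 1)), "positive area")
})

test_that("diou_loss >= 1 - IoU with equality iff centroids coincide", {
  set.seed(11)
  for (i in 1:2000) {
    p <- random_corner_boxes(1)
    t <- random_corner_boxes(1)
    d <- diou_loss(p, t)
    iou <- box_iou(p, t)[1, 1]
    expect_gte(d, 1 - iou - 1e-12)
  }
  # concentric boxes of different size: centroids coincide -> equality
  p <- c(10, 10, 30, 30); t <- c(15, 15, 25, 25)
  expect_equal(diou_loss(p, t), 1 - box_iou(matrix(p, 1), matrix(t, 1))[1, 1],
               tolerance = 1e-12)
})

test_that("diou gradient on disjoint boxes is nonzero and center-seeking", {
  pred <- c(0, 0, 1, 1)
  target <- c(5, 3, 6, 4) # far away, zero overlap
  eps <- 1e-6
  shift <- function(b, dx, dy) b + c(dx, dy, dx, dy)
  gx <- (diou_loss(shift(pred, eps, 0), target) -
           diou_loss(shift(pred, -eps, 0), target)) / (2 * eps)
  gy <- (diou_loss(shift(pred, 0, eps), target) -
           diou_loss(shift(pred, 0, -eps), target)) / (2 * eps)
  # gradient is nonzero and descending it moves the center toward the target
  expect_gt(sqrt(gx^2 + gy^2), 1e-6)
  expect_lt(gx, 0) # target lies at larger x: loss decreases as x grows
  expect_lt(gy, 0)
  # the IoU term alone is flat for disjoint boxes
  iou_g <- (box_iou(matrix(shift(pred, eps, 0), 1), matrix(target, 1))[1, 1] -
              box_iou(matrix(shift(pred, -eps, 0), 1), matrix(target, 1))[1, 1])
  expect_identical(iou_g, 0)
})

test_that("bce_loss has its closed-form values and monotonicity", {
  # uniform 0.5 over C classes -> C * ln 2
  for (C in c(2, 3, 7)) {
    expect_equal(bce_loss(rep(0.5, C), 0), C * log(2), tolerance = 1e-9)
  }
  # near-perfect prediction -> near zero
  expect_lt(bce_loss(c(1 - 1e-9, 1e-9, 1e-9), 0), 1e-6)
  # decreasing the true-class confidence increases the loss
  l1 <- bce_loss(c(0.9, 0.1, 0.1), 0)
  l2 <- bce_loss(c(0.6, 0.1, 0.1), 0)
  expect_gt(l2, l1)
})

test_that("acsl_weights reproduces the suppression rule exhaustively", {
  alpha <- 0.5
  grid <- expand.grid(conf = c(0.1, alpha, 0.9), k = 0:2)
  for (r in seq_len(nrow(grid))) {
    conf <- rep(grid$conf[r], 3)
    w <- acsl_weights(conf, grid$k[r], alpha)
    # true class always weighted 1 regardless of its confidence
    expect_identical(w[grid$k[r] + 1], 1)
    for (i in 0:2) {
      if (i == grid$k[r]) next
      expect_identical(w[i + 1], as.numeric(conf[i + 1] >= alpha))
    }
  }
  # boundary: confidence exactly alpha is kept (>=)
  expect_identical(acsl_weights(c(0.5, 0.5), 0, 0.5)[2], 1)
})

test_that("l_bce matches a term-by-term hand sum and is bounded by bce_loss", {
  # C = 3, k = 0, conf (0.6, 0.7, 0.1), alpha 0.5: class 2 suppressed
  conf <- c(0.6, 0.7, 0.1)
  hand <- -(log(0.6) + log(1 - 0.7)) # class 0 (true) + class 1 (kept)
  expect_equal(l_bce(conf, 0, 0.5), hand, tolerance = 1e-9)
  # alpha = 0 keeps every class: equals plain BCE
  set.seed(5)
  for (i in 1:200) {
    conf <- runif(sample(2:6, 1))
    k <- sample(seq_along(conf), 1) - 1
    expect_equal(l_bce(conf, k, 0), bce_loss(conf, k), tolerance = 1e-12)
    a <- runif(1, 0.05, 0.95)
    expect_lte(l_bce(conf, k, a), bce_loss(conf, k) + 1e-12)
  }
})

test_that("acsl_weights is equivariant under joint class permutation", {
  set.seed(9)
  for (i in 1:50) {
    conf <- runif(5)
    k <- sample(0:4, 1)
    a <- runif(1, 0.1, 0.9)
    p <- sample(5)
    w <- acsl_weights(conf, k, a)
    wp <- acsl_weights(conf[p], which(p == k + 1) - 1, a)
    expect_identical(wp, w[p])
  }
})

test_that("assign_targets puts a centered object on every matching stride", {
  cfg <- model_config(3, input_side = 160, width_mult = 0.125, window = 5)
  b <- list(rbind(c(cx = 0.5, cy = 0.5, w = 0.2, h = 0.2, class_id = 1)))
  tg <- assign_targets(b, cfg)
  expect_gte(sum(vapply(tg, nrow, numeric(1))), 1)
  # all assignments reference image 1 and the true class
  for (s in 1:3) {
    if (nrow(tg[[s]])) {
      expect_true(all(tg[[s]]$n == 1))
      expect_true(all(tg[[s]]$class == 1))
    }
  }
  # empty ground truth -> all-negative targets
  tg0 <- assign_targets(list(matrix(numeric(0), 0, 5)), cfg)
  expect_identical(sum(vapply(tg0, nrow, numeric(1))), 0)
  # determinism
  expect_identical(assign_targets(b, cfg), tg)
  # out-of-image ground truth is an error
  expect_error(assign_targets(list(rbind(c(1.5, 0.5, 0.1, 0.1, 0))), cfg),
               "outside")
})

test_that("composite_loss recomposes from its parts and handles no positives", {
  set.seed(21)
  cfg <- model_config(2, input_side = 96, width_mult = 0.125, window = 3)
  m <- build_model(cfg)
  imgs <- fixture_scenes(4, classes = 2, side = 96)
  b <- wildetect:::prepare_batch(imgs, 96)
  h <- forward_detector(m, b$x, train = TRUE)
  tg <- assign_targets(b$boxes, cfg)
  L <- composite_loss(h, tg, cfg)
  lw <- cfg$loss_weights
  expect_equal(as.numeric(L$total$value),
               (lw[["box"]] * L$breakdown[["box"]] +
                  lw[["obj"]] * L$breakdown[["obj"]] +
                  lw[["cls"]] * L$breakdown[["cls"]]) * dim(b$x)[4],
               tolerance = 1e-9)
  expect_true(all(is.finite(L$breakdown)))
  expect_true(all(L$breakdown >= 0))
  # zero-ground-truth batch: only the objectness term remains
  empty <- lapply(1:4, function(i) matrix(numeric(0), 0, 5))
  L0 <- composite_loss(h, assign_targets(empty, cfg), cfg)
  expect_identical(L0$breakdown[["box"]], 0)
  expect_identical(L0$breakdown[["cls"]], 0)
  expect_gt(L0$breakdown[["obj"]], 0)
})

test_that("composite_loss gradient reaches the model input", {
  set.seed(22)
  cfg <- model_config(2, input_side = 96, width_mult = 0.125, window = 3)
  m <- build_model(cfg)
  imgs <- fixture_scenes(2, classes = 2, side = 96)
  b <- wildetect:::prepare_batch(imgs, 96)
  xt <- ag_tensor(b$x / 255, requires_grad = TRUE)
  h <- forward_detector(m, xt, train = TRUE)
  L <- composite_loss(h, assign_targets(b$boxes, cfg), cfg)
  ag_backward(L$total)
  expect_false(is.null(xt$grad))
  expect_true(all(is.finite(xt$grad)))
  expect_gt(sum(abs(xt$grad)), 0)
})
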