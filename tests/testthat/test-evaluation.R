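# PR-curve evaluation, matching and the background-aware confusion matrix.

make_dets <- function(...) {
  rows <- list(...)
  if (!length(rows)) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), conf = numeric(0), class_id = integer(0)))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(x1 = r[1], y1 = r[2], x2 = r[3], y2 = r[4], conf = r[5],
               class_id = as.integer(r[6]))
  }))
}

test_that("match_detections implements greedy one-to-one matching", {
  gts <- cbind(x1 = c(0, 10), y1 = c(0, 0), x2 = c(5, 15), y2 = c(5, 5),
               class_id = c(0, 0))
  # perfect predictions
  d <- make_dets(c(0, 0, 5, 5, 0.9, 0), c(10, 0, 15, 5, 0.8, 0))
  m <- match_detections(d, gts)
  expect_identical(m$n_tp, 2L)
  expect_identical(m$n_fn, 0L)
  expect_equal(unname(precision_recall(m)), c(1, 1))
  # no detections
  m0 <- match_detections(make_dets()[0, ], gts)
  expect_identical(m0$n_fn, 2L)
  expect_equal(unname(precision_recall(m0)), c(0, 0))
  # each ground truth consumed at most once
  d2 <- make_dets(c(0, 0, 5, 5, 0.9, 0), c(0, 0, 5, 5, 0.8, 0))
  m2 <- match_detections(d2, gts)
  expect_identical(m2$n_tp, 1L)
  expect_identical(m2$n_fp, 1L)
  # wrong class never matches
  d3 <- make_dets(c(0, 0, 5, 5, 0.9, 1))
  expect_identical(match_detections(d3, gts)$n_tp, 0L)
})

test_that("matcher agrees with a brute-force loop oracle on random instances", {
  set.seed(31)
  for (rep in 1:60) {
    ng <- sample(0:8, 1)
    nd <- sample(0:8, 1)
    gts <- cbind(random_corner_boxes(ng), class_id = sample(0:1, ng, TRUE))
    dets <- data.frame(random_corner_boxes(nd), conf = runif(nd),
                       class_id = sample(0:1, nd, TRUE))
    names(dets)[1:4] <- c("x1", "y1", "x2", "y2")
    if (ng == 0) gts <- matrix(numeric(0), 0, 5)
    m <- match_detections(dets, gts)
    expect_identical(m$n_tp, as.integer(brute_force_match_tp(dets, gts)))
  }
})

test_that("precision_recall substitutes counts directly", {
  expect_equal(unname(precision_recall(list(n_tp = 8, n_fp = 2, n_fn = 2))),
               c(0.8, 0.8))
})

test_that("average_precision reproduces the hand-integrated curve", {
  # single correct detection of a single ground truth
  expect_equal(average_precision(TRUE, 1), 1)
  # 2 GT, ranked (TP, FP, TP): area = 0.5*1 + 0.5*(2/3) = 5/6
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2), 5 / 6,
               tolerance = 1e-12)
  # injecting a high-confidence FP at the top never increases AP
  set.seed(32)
  for (i in 1:50) {
    tps <- runif(10) > 0.4
    ng <- sum(tps) + sample(0:3, 1)
    if (ng == 0) next
    expect_lte(average_precision(c(FALSE, tps), ng),
               average_precision(tps, ng) + 1e-12)
  }
})

test_that("mean_ap averages and is permutation-invariant", {
  expect_equal(mean_ap(c(1, 0.5)), 0.75)
  expect_equal(mean_ap(0.4), 0.4)
  expect_equal(mean_ap(c(0.2, 0.9, 0.5)), mean_ap(c(0.9, 0.5, 0.2)))
})

test_that("evaluation is invariant to detection input order", {
  set.seed(33)
  gts <- list(cbind(random_corner_boxes(4), class_id = c(0, 0, 1, 1)))
  dets <- data.frame(random_corner_boxes(6), conf = runif(6),
                     class_id = sample(0:1, 6, TRUE))
  names(dets)[1:4] <- c("x1", "y1", "x2", "y2")
  r1 <- evaluate_detections(list(dets), gts, 2)
  r2 <- evaluate_detections(list(dets[sample(6), ]), gts, 2)
  expect_equal(r1$map, r2$map)
  expect_equal(r1$confusion, r2$confusion)
})

test_that("perfect oracle detections give P = R = mAP = 1 and identity confusion", {
  imgs <- fixture_scenes(20, classes = 3, side = 96)
  dets <- perfect_oracle_detections(imgs)
  gts <- lapply(imgs, gt_corners)
  rep <- evaluate_detections(dets, gts, 3)
  expect_equal(rep$map, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  cmn <- rep$confusion_normalized
  present <- which(rowSums(rep$confusion) > 0)
  for (i in present) expect_equal(cmn[i, i], 1)
  # dropping one ground-truth box per non-empty image lowers recall below 1
  dets2 <- lapply(dets, function(d) if (nrow(d)) d[-1, , drop = FALSE] else d)
  rep2 <- evaluate_detections(dets2, gts, 3)
  expect_lt(rep2$recall, 1)
})

test_that("jittering boxes below IoU 0.5 converts TP to FP", {
  imgs <- fixture_scenes(10, classes = 3, side = 96)
  dets <- perfect_oracle_detections(imgs)
  gts <- lapply(imgs, gt_corners)
  jit <- lapply(dets, function(d) {
    if (!nrow(d)) return(d)
    w <- d$x2 - d$x1
    d$x1 <- d$x1 + 0.8 * w # overlap drops to 0.2/1.8 < 0.5
    d$x2 <- d$x2 + 0.8 * w
    d
  })
  rep <- evaluate_detections(jit, gts, 3)
  expect_equal(rep$map, 0, tolerance = 1e-12)
})

test_that("confusion matrix places cross-class, missed and spurious mass per the background semantics", {
  # one image, 3 classes: gt0 detected as class 1 (cross-class confusion),
  # gt1 missed (background column), plus a spurious detection (background row)
  gts <- list(cbind(x1 = c(0, 50), y1 = c(0, 50), x2 = c(10, 60),
                    y2 = c(10, 60), class_id = c(0, 1)))
  dets <- list(make_dets(c(0, 0, 10, 10, 0.9, 1), c(80, 80, 90, 90, 0.8, 2)))
  cm <- confusion_matrix(dets, gts, 3)
  expect_equal(cm["class0", "class1"], 1) # matched but mislabelled
  expect_equal(cm["class1", "background"], 1) # missed detection
  expect_equal(cm["background", "class2"], 1) # false detection of background
  expect_equal(sum(cm), 3)
  # below-threshold detections are ignored entirely
  dets_low <- list(make_dets(c(0, 0, 10, 10, 0.4, 1)))
  cm2 <- confusion_matrix(dets_low, gts, 3, conf_thresh = 0.5)
  expect_equal(sum(cm2[, "background"]), 2)
  expect_equal(sum(cm2["background", ]), 0)
  # no detections at all: all mass in the background column
  cm3 <- confusion_matrix(list(make_dets()[0, ]), gts, 3)
  expect_equal(sum(cm3[, "background"]), 2)
  # row-normalized rows sum to one where they have mass
  cmn <- confusion_matrix(dets, gts, 3, normalize = TRUE)
  rs <- rowSums(cmn)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
})
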