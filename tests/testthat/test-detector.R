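# Architecture assembly, decode, NMS, checkpoints.

test_that("model_config validates its invariants up front", {
  expect_error(model_config(0), "num_classes")
  expect_error(model_config(2, input_side = 100), "divisible by 32")
  bad_anchors <- default_anchors()
  bad_anchors$p3[1, 1] <- -1
  expect_error(model_config(2, anchors = bad_anchors), "positive")
})

test_that("head maps have stride-8/16/32 geometry and 3*(5+N) channels", {
  set.seed(81)
  cfg <- model_config(2, input_side = 640, width_mult = 0.125, window = 5)
  m <- build_model(cfg)
  x <- array(runif(640 * 640 * 3, 0, 255), c(640, 640, 3, 1))
  h <- forward_detector(m, x, train = FALSE)
  expect_equal(dim(h$p3$value), c(80, 80, 21, 1)) # 3*(5+2) = 21
  expect_equal(dim(h$p4$value), c(40, 40, 21, 1))
  expect_equal(dim(h$p5$value), c(20, 20, 21, 1))
})

test_that("doubling the input side exactly doubles head extents", {
  set.seed(82)
  cfg1 <- model_config(3, input_side = 96, width_mult = 0.125, window = 3)
  cfg2 <- model_config(3, input_side = 192, width_mult = 0.125, window = 3)
  m1 <- build_model(cfg1)
  m2 <- build_model(cfg2)
  h1 <- forward_detector(m1, array(100, c(96, 96, 3, 1)))
  h2 <- forward_detector(m2, array(100, c(192, 192, 3, 1)))
  for (s in c("p3", "p4", "p5")) {
    expect_equal(dim(h2[[s]]$value)[1:2], 2 * dim(h1[[s]]$value)[1:2])
  }
})

test_that("the graph has exactly 4 swin insertion points and SE-gated merges at all 4 neck nodes", {
  cfg <- model_config(3, input_side = 96, width_mult = 0.125, window = 3)
  m <- build_model(cfg)
  swins <- names(m$.children)[vapply(m$.children, inherits, logical(1), "nn_swin")]
  expect_length(swins, 4)
  expect_setequal(swins, m$swin_points)
  expect_identical(sum(grepl("^swin_", swins)), 4L)
  merges <- names(m$.children)[vapply(m$.children, inherits, logical(1), "nn_concat_e")]
  expect_length(merges, 4)
  expect_setequal(merges, m$merge_nodes)
  # one backbone insertion, three in the neck
  expect_identical(sum(swins == "swin_backbone"), 1L)
})

test_that("eval-mode forward is deterministic for fixed weights and input", {
  set.seed(83)
  cfg <- model_config(2, input_side = 96, width_mult = 0.125, window = 3)
  m <- build_model(cfg)
  x <- array(runif(96 * 96 * 3 * 2, 0, 255), c(96, 96, 3, 2))
  h1 <- forward_detector(m, x)
  h2 <- forward_detector(m, x)
  for (s in c("p3", "p4", "p5")) expect_identical(h1[[s]]$value, h2[[s]]$value)
})

test_that("decode maps a hand-set activation to its analytic pixel box", {
  cfg <- model_config(2, input_side = 160, width_mult = 0.125, window = 5)
  nf <- 5 + 2
  heads <- list(p3 = array(-20, c(20, 20, 3 * nf, 1)),
                p4 = array(-20, c(10, 10, 3 * nf, 1)),
                p5 = array(-20, c(5, 5, 3 * nf, 1)))
  # all-(-inf) objectness decodes to nothing
  expect_identical(nrow(decode_heads(heads, cfg)[[1]]), 0L)
  # one cell on p4 (stride 16), anchor 2, row 4, col 7 (1-based)
  a <- 2; off <- (a - 1) * nf
  heads$p4[4, 7, off + 1, 1] <- 0 # sigmoid 0.5 -> x offset 2*0.5-0.5 = 0.5
  heads$p4[4, 7, off + 2, 1] <- 0
  heads$p4[4, 7, off + 3, 1] <- 0 # wh = (2*0.5)^2 * anchor = anchor
  heads$p4[4, 7, off + 4, 1] <- 0
  heads$p4[4, 7, off + 5, 1] <- 5 # objectness ~ 0.9933
  heads$p4[4, 7, off + 6, 1] <- 5 # class 0
  d <- decode_heads(heads, cfg)[[1]]
  expect_identical(nrow(d), 1L)
  anchor <- default_anchors()$p4[2, ] * 160 / 640
  cx <- (0.5 + 6) * 16 # col 7 -> grid x 6
  cy <- (0.5 + 3) * 16
  expect_equal(d$x1, cx - anchor[1] / 2, tolerance = 1e-9)
  expect_equal(d$y2, cy + anchor[2] / 2, tolerance = 1e-9)
  expect_equal(d$conf, (1 / (1 + exp(-5)))^2, tolerance = 1e-9)
  expect_identical(d$class_id, 0L)
  # shape mismatch errors
  bad <- heads
  bad$p3 <- array(0, c(20, 20, 7, 1))
  expect_error(decode_heads(bad, cfg))
})

test_that("nms keeps the highest-confidence box among duplicates and all disjoint boxes", {
  d <- data.frame(x1 = c(0, 0, 50), y1 = c(0, 0, 50), x2 = c(10, 10, 60),
                  y2 = c(10, 10, 60), conf = c(0.9, 0.8, 0.7),
                  class_id = c(0L, 0L, 0L))
  out <- nms(d, 0.45)
  expect_identical(nrow(out), 2L)
  expect_equal(out$conf, c(0.9, 0.7))
  # same geometry, different classes: no cross-class suppression
  d2 <- d; d2$class_id <- c(0L, 1L, 0L)
  expect_identical(nrow(nms(d2, 0.45)), 3L)
})

test_that("nms matches a brute-force quadratic reference on random boxes", {
  set.seed(84)
  for (rep in 1:20) {
    n <- 50
    d <- data.frame(random_corner_boxes(n, 60), conf = round(runif(n), 3),
                    class_id = sample(0:2, n, TRUE))
    names(d)[1:4] <- c("x1", "y1", "x2", "y2")
    ours <- nms(d, 0.45)
    ref <- brute_force_nms(d, 0.45)
    expect_setequal(as.integer(rownames(ours)), ref)
  }
})

test_that("checkpoints round-trip exactly and the half-precision form is 2 bytes per weight", {
  set.seed(85)
  cfg <- model_config(2, input_side = 96, width_mult = 0.125, window = 3)
  m <- build_model(cfg)
  x <- array(runif(96 * 96 * 3, 0, 255), c(96, 96, 3, 1))
  h0 <- forward_detector(m, x)
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, tmp)
  m2 <- load_checkpoint(tmp)
  h1 <- forward_detector(m2, x)
  expect_identical(h0$p5$value, h1$p5$value)
  raw <- checkpoint_half_raw(m)
  expect_identical(length(raw), 2L * as.integer(n_parameters(m)))
  # half precision reconstructs weights to ~1e-3 relative accuracy
  back <- wildetect:::half_to_double_cpp(raw)
  flat <- unlist(lapply(nn_parameters(m), function(p) as.numeric(p$value)))
  expect_lt(max(abs(back - flat) / pmax(abs(flat), 1e-2)), 2e-3)
})

test_that("the full-scale 10-class model serializes near the published 15 MB half-precision size", {
  set.seed(86)
  cfg <- model_config(10) # defaults: 640 input, width 0.5, depth 0.33
  m <- build_model(cfg)
  bytes <- 2 * n_parameters(m)
  expect_gt(bytes, 15.2e6 * 0.85)
  expect_lt(bytes, 15.2e6 * 1.15)
})

test_that("detect_images on an untrained model at high confidence returns nothing", {
  set.seed(87)
  cfg <- model_config(3, input_side = 96, width_mult = 0.125, window = 3)
  m <- build_model(cfg)
  img <- tiny_image(96, 96)
  dets <- detect_images(m, list(img), conf_thresh = 0.99)
  expect_identical(nrow(dets[[1]]), 0L)
})
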