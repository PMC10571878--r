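# Box-aware augmentation geometry and determinism.

test_that("rotation by 0 and 360 degrees is the identity on boxes", {
  img <- fixture_scenes(1, side = 96)[[1]]
  r0 <- rotate_with_boxes(img, 0)
  expect_equal(r0$pixels, img$pixels)
  expect_equal(wildetect:::boxes_as_matrix(r0$boxes),
               wildetect:::boxes_as_matrix(img$boxes))
  r360 <- rotate_with_boxes(img, 360)
  m0 <- wildetect:::boxes_as_matrix(img$boxes)
  m1 <- wildetect:::boxes_as_matrix(r360$boxes)
  expect_equal(unname(m1), unname(m0), tolerance = 1e-6)
})

test_that("rotation by 90 degrees maps centers to (y, 1-x) and swaps extents", {
  img <- tiny_image(100, 100, list(bounding_box(0, 0.3, 0.2, 0.2, 0.1)))
  r <- rotate_with_boxes(img, 90)
  b <- r$boxes[[1]]
  expect_equal(b$cx, 0.2, tolerance = 1e-9)
  expect_equal(b$cy, 0.7, tolerance = 1e-9)
  expect_equal(b$w, 0.1, tolerance = 1e-9)
  expect_equal(b$h, 0.2, tolerance = 1e-9)
  # raster content rotates consistently with the box: paint the box region
  px <- array(0, c(100, 100, 3))
  px[16:25, 21:40, ] <- 255 # rows 15..25 = y in [0.15,0.25], cols = x in [0.2,0.4]
  img2 <- annotated_image(px, list(), "paint")
  r2 <- rotate_with_boxes(img2, 90, fill = 0)
  # bright mass should now be centered at (0.2, 0.7)
  bright <- which(r2$pixels[, , 1] > 128, arr.ind = TRUE)
  expect_equal(mean(bright[, 2]) / 100, 0.2, tolerance = 0.03)
  expect_equal(mean(bright[, 1]) / 100, 0.7, tolerance = 0.03)
})

test_that("rotated boxes are the axis-aligned hull of the rotated corners", {
  img <- tiny_image(200, 200, list(bounding_box(0, 0.5, 0.5, 0.2, 0.1)))
  r <- rotate_with_boxes(img, 45)
  b <- r$boxes[[1]]
  # hull of a w x h rectangle rotated 45 degrees has side (w+h)/sqrt(2)
  expect_equal(b$w, (0.2 + 0.1) / sqrt(2), tolerance = 1e-6)
  expect_equal(b$h, (0.2 + 0.1) / sqrt(2), tolerance = 1e-6)
  expect_equal(b$cx, 0.5, tolerance = 1e-9)
})

test_that("gaussian_corrupt is deterministic, clips, and leaves boxes alone", {
  img <- fixture_scenes(1, side = 96)[[1]]
  # both sigmas zero: identity
  same <- gaussian_corrupt(img, 0, 0, 7)
  expect_equal(same$pixels, img$pixels)
  # fixed seed: bit-identical outputs
  a <- gaussian_corrupt(img, 1.2, 10, rng_seed = 99)
  b <- gaussian_corrupt(img, 1.2, 10, rng_seed = 99)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, gaussian_corrupt(img, 1.2, 10, 100)$pixels))
  expect_identical(a$boxes, img$boxes)
  expect_true(all(a$pixels >= 0 & a$pixels <= 255))
  # blur of a constant image stays constant
  cst <- annotated_image(array(77, c(64, 64, 3)), list(), "c")
  bl <- gaussian_corrupt(cst, blur_sigma = 2, noise_sigma = 0)
  expect_equal(bl$pixels, cst$pixels, tolerance = 1e-6)
})

test_that("fuse_images respects patch counts and the IoU ceiling", {
  set.seed(71)
  scenes <- fixture_scenes(8, side = 96)
  host <- scenes[[1]]
  donors <- scenes[2:5]
  cfg <- fusion_config(max_iou_with_main = 0.1)
  out <- fuse_images(host, donors, cfg, rng_seed = 5)
  n_new <- length(out$boxes) - length(host$boxes)
  expect_gte(n_new + attr(out, "fusion_shortfall"), 2)
  expect_lte(n_new + attr(out, "fusion_shortfall"), 4)
  # pasted boxes keep IoU <= ceiling against host boxes and each other
  d <- dim(host$pixels)
  all_c <- boxes_to_corners(out$boxes, d[2], d[1])
  nh <- length(host$boxes)
  if (n_new > 0) {
    pasted <- all_c[(nh + 1):nrow(all_c), 1:4, drop = FALSE]
    if (nh > 0) {
      expect_true(all(box_iou(pasted, all_c[1:nh, 1:4, drop = FALSE]) <= 0.1 + 1e-9))
    }
    if (n_new > 1) {
      ious <- box_iou(pasted, pasted)
      diag(ious) <- 0
      expect_true(all(ious <= 0.1 + 1e-9))
    }
  }
  # determinism
  out2 <- fuse_images(host, donors, cfg, rng_seed = 5)
  expect_identical(out$pixels, out2$pixels)
  # error/warning contract
  expect_error(fuse_images(host, list(), cfg), "non-empty")
  boxless <- tiny_image(96, 96)
  expect_warning(fuse_images(host, list(boxless, donors[[1]]), cfg, 1),
                 "without boxes")
})

test_that("fusion draws patch counts in 2..4 across many seeds", {
  scenes <- fixture_scenes(5, side = 96)
  ks <- integer(0)
  for (s in 1:200) {
    out <- fuse_images(scenes[[1]], scenes[2:5], fusion_config(), rng_seed = s)
    ks <- c(ks, length(out$boxes) - length(scenes[[1]]$boxes) +
              attr(out, "fusion_shortfall"))
  }
  expect_true(all(ks >= 2 & ks <= 4))
  expect_length(unique(ks), 3) # all of 2, 3, 4 occur
})

test_that("mosaic4 stitches quadrants with in-bounds remapped boxes", {
  scenes <- fixture_scenes(4, side = 96)
  mo <- mosaic4(scenes, 128, rng_seed = 3)
  expect_equal(dim(mo$pixels), c(128, 128, 3))
  m <- wildetect:::boxes_as_matrix(mo$boxes)
  if (nrow(m)) {
    corners <- boxes_to_corners(mo$boxes, 128, 128)
    expect_true(all(corners[, 1:4] >= -1e-9 & corners[, 1:4] <= 128 + 1e-9))
  }
  # box-free inputs produce a box-free mosaic
  empties <- replicate(4, tiny_image(64, 64), simplify = FALSE)
  expect_length(mosaic4(empties, 96, 1)$boxes, 0)
  expect_error(mosaic4(scenes[1:3], 128, 1), "exactly 4")
  expect_identical(mosaic4(scenes, 128, 3)$pixels, mo$pixels)
})

test_that("expand_dataset multiplies, tags provenance, and is seed-stable", {
  imgs <- fixture_scenes(6, side = 96)
  out <- expand_dataset(imgs, c(rotation = 1, gaussian = 1, fusion = 0),
                        rng_seed = 4)
  expect_length(out, 18) # originals + one rotation + one blur each
  ids <- vapply(out, function(i) i$source_id, character(1))
  expect_identical(sum(grepl("_rot", ids)), 6L)
  expect_identical(sum(grepl("_gauss", ids)), 6L)
  out2 <- expand_dataset(imgs, c(rotation = 1, gaussian = 1, fusion = 0),
                         rng_seed = 4)
  expect_identical(sort(ids), sort(vapply(out2, function(i) i$source_id,
                                          character(1))))
  # a schedule with one copy per method approaches 4x expansion
  out3 <- expand_dataset(imgs, c(rotation = 1, gaussian = 1, fusion = 1),
                         rng_seed = 4)
  expect_gte(length(out3), 22) # 4x minus any fusion shortfalls
  expect_lte(length(out3), 24)
})

test_that("augmented outputs satisfy the annotated-image invariants", {
  set.seed(72)
  imgs <- fixture_scenes(6, side = 96)
  for (rep in 1:40) {
    img <- imgs[[sample(6, 1)]]
    op <- sample(3, 1)
    out <- switch(op,
                  rotate_with_boxes(img, runif(1, -180, 180)),
                  gaussian_corrupt(img, runif(1, 0, 2), runif(1, 0, 20), rep),
                  fuse_images(img, imgs[sample(6, 3)], fusion_config(), rep))
    d <- dim(out$pixels)
    expect_identical(d, dim(img$pixels))
    expect_true(all(out$pixels >= 0 & out$pixels <= 255))
    m <- wildetect:::boxes_as_matrix(out$boxes)
    if (nrow(m)) {
      expect_true(all(m[, "w"] > 0 & m[, "h"] > 0))
      expect_true(all(m[, "cx"] - m[, "w"] / 2 >= -1e-9 &
                        m[, "cx"] + m[, "w"] / 2 <= 1 + 1e-9))
      expect_true(all(m[, "cy"] - m[, "h"] / 2 >= -1e-9 &
                        m[, "cy"] + m[, "h"] / 2 <= 1 + 1e-9))
    }
  }
})
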