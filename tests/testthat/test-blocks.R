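# Neural building blocks: focus slicing, CBL/CSP/SPP contracts, the Swin
# block against a dense-attention oracle, and the SE-gated concatenation.

ag_sum <- wildetect:::ag_sum
ag_square <- wildetect:::ag_square

test_that("focus_slice is a lossless space-to-depth rearrangement", {
  set.seed(51)
  x <- array(rnorm(8 * 6 * 3 * 2), c(8, 6, 3, 2))
  y <- focus_slice(x)
  expect_equal(dim(y), c(4, 3, 12, 2))
  expect_equal(sum(y), sum(x)) # every value appears exactly once
  expect_equal(sort(as.numeric(y)), sort(as.numeric(x)))
  # checkerboard input -> each slice is constant
  cb <- array(0, c(4, 4, 1, 1))
  cb[, , 1, 1] <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  ycb <- focus_slice(array(rep(cb, 3), c(4, 4, 3, 1)))
  for (s in 1:12) expect_length(unique(as.numeric(ycb[, , s, 1])), 1)
  expect_error(focus_slice(array(0, c(5, 4, 3, 1))), "even")
})

test_that("cbl preserves or halves spatial extent by stride", {
  set.seed(52)
  x <- ag_tensor(array(rnorm(12 * 10 * 3 * 2), c(12, 10, 3, 2)))
  c1 <- wildetect:::nn_cbl(3, 8, 3, 1)
  expect_equal(dim(c1$forward(x)$value), c(12, 10, 8, 2))
  c2 <- wildetect:::nn_cbl(3, 8, 3, 2)
  expect_equal(dim(c2$forward(x)$value), c(6, 5, 8, 2))
  expect_true(all(is.finite(c2$forward(x, TRUE)$value)))
})

test_that("csp blocks keep shape, pass gradient, and zeroed residual branches reduce to the pass-through", {
  set.seed(53)
  x <- ag_tensor(array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2)), TRUE)
  for (ctor in list(wildetect:::nn_csp1, wildetect:::nn_csp2)) {
    blk <- ctor(6, 8, 2)
    y <- blk$forward(x, TRUE)
    expect_equal(dim(y$value), c(8, 8, 8, 2))
    ag_zero_grad(list(x))
    ag_backward(ag_sum(ag_square(y)))
    expect_gt(sum(abs(x$grad)), 0)
  }
  # zero every weight inside the residual units of csp1: each unit must act
  # as the identity on its branch input (y = x + 0)
  blk <- wildetect:::nn_csp1(6, 8, 2)
  for (nm in grep("^res", names(blk$.children), value = TRUE)) {
    for (sub in blk$.children[[nm]]$.children) {
      sub$.params$weight$value[] <- 0
      sub$.params$gamma$value[] <- 0 # batch-norm gain off too
    }
  }
  cv1out <- blk$.children$cv1$forward(x, FALSE)
  through <- cv1out
  for (nm in grep("^res", names(blk$.children), value = TRUE)) {
    through <- blk$.children[[nm]]$forward(through, FALSE)
  }
  expect_equal(through$value, cv1out$value, tolerance = 1e-12)
})

test_that("spp preserves shape and constant inputs pass through its pool branches", {
  set.seed(54)
  spp <- wildetect:::nn_spp(8, 16)
  x <- ag_tensor(array(rnorm(10 * 10 * 8 * 2), c(10, 10, 8, 2)))
  expect_equal(dim(spp$forward(x)$value), c(10, 10, 16, 2))
  # max pooling of a constant map is that constant, for every kernel
  const <- ag_tensor(array(3.5, c(9, 9, 4, 1)))
  for (k in c(5, 9, 13)) {
    expect_true(all(wildetect:::ag_maxpool(const, k)$value == 3.5))
  }
  # max pool commutes with monotone rescaling of a positive input
  xp <- ag_tensor(array(runif(81 * 4, 0.1, 2), c(9, 9, 4, 1)))
  p1 <- wildetect:::ag_maxpool(xp, 5)$value
  xp2 <- ag_tensor(xp$value * 7)
  expect_equal(wildetect:::ag_maxpool(xp2, 5)$value, p1 * 7, tolerance = 1e-12)
})


test_that("swin block with a map-spanning window equals dense self-attention", {
  set.seed(55)
  cfg <- swin_config(64, window = 8, heads = 2, shifted = FALSE)
  blk <- wildetect:::nn_swin_block(cfg)
  x <- array(rnorm(8 * 8 * 64), c(8, 8, 64, 1))
  y <- blk$forward(ag_tensor(x), FALSE)$value
  yo <- dense_attention_oracle(x, nn_parameters(blk), 8)
  expect_lt(max(abs(y - yo)), 1e-5)
})

test_that("swin block preserves shape, pads odd extents, and treats identical tokens identically", {
  set.seed(56)
  cfg <- swin_config(16, window = 4, heads = 2, shifted = TRUE)
  blk <- wildetect:::nn_swin_block(cfg)
  x <- array(rnorm(10 * 14 * 16 * 2), c(10, 14, 16, 2))
  y <- blk$forward(ag_tensor(x), FALSE)$value
  expect_equal(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  # two identical token rows inside one (unshifted) window receive identical
  # attention outputs once the (position-dependent) relative bias is zeroed
  cfg2 <- swin_config(8, window = 2, heads = 1, shifted = FALSE)
  blk2 <- wildetect:::nn_swin_block(cfg2)
  p2 <- nn_parameters(blk2)
  p2[["relpos"]]$value[] <- 0
  x2 <- array(rnorm(2 * 2 * 8), c(2, 2, 8, 1))
  x2[2, 1, , 1] <- x2[1, 1, , 1] # duplicate a token within the window
  y2 <- blk2$forward(ag_tensor(x2), FALSE)$value
  expect_equal(y2[2, 1, , 1], y2[1, 1, , 1], tolerance = 1e-12)
})

test_that("window partition and reverse form an exact identity permutation", {
  set.seed(57)
  cfg <- swin_config(8, window = 3, heads = 1, shifted = TRUE)
  blk <- wildetect:::nn_swin_block(cfg)
  x <- array(rnorm(7 * 9 * 8), c(7, 9, 8, 1))
  invisible(blk$forward(ag_tensor(x), FALSE)) # populate the index cache
  cc <- blk$cache[[ls(blk$cache)[1]]]
  expect_identical(sort(cc$part_idx), seq_along(cc$part_idx))
  expect_identical(cc$part_idx[cc$part_inv], seq_along(cc$part_idx))
})

test_that("the shifted-window mask blocks exactly the cross-region pairs", {
  msk <- wildetect:::swin_shift_mask(8, 8, 4, 2)
  expect_equal(dim(msk), c(16, 16, 4))
  # the first window (interior) has no masked pairs; the last (corner,
  # wrapping in both axes) mixes four regions
  expect_true(all(msk[, , 1] == 0))
  expect_gt(sum(msk[, , 4] < 0), 0)
  # masking is symmetric and zero on the diagonal
  for (w in 1:4) {
    expect_equal(msk[, , w], t(msk[, , w]))
    expect_true(all(diag(msk[, , w]) == 0))
  }
  # every masked pair spans two different pre-shift regions: region ids for
  # the wrapped corner window alternate with period 2 in each axis
  ids <- matrix(0, 4, 4)
  ids[3:4, ] <- 2; ids[, 3:4] <- ids[, 3:4] + 1
  flat <- as.vector(ids)
  expect_equal(msk[, , 4] < 0, outer(flat, flat, "!="))
})

test_that("swin with window 1 is shift-invariant (each token its own window)", {
  set.seed(58)
  a <- wildetect:::nn_swin_block(swin_config(8, window = 1, heads = 1, shifted = FALSE))
  b <- wildetect:::nn_swin_block(swin_config(8, window = 1, heads = 1, shifted = TRUE))
  pa <- nn_parameters(a); pb <- nn_parameters(b)
  for (nm in names(pa)) pb[[nm]]$value <- pa[[nm]]$value
  x <- array(rnorm(6 * 6 * 8), c(6, 6, 8, 1))
  expect_equal(a$forward(ag_tensor(x))$value, b$forward(ag_tensor(x))$value,
               tolerance = 1e-12)
})

test_that("concat_e concatenates channels and gates them with SE weights in (0,1)", {
  set.seed(59)
  a1 <- array(rnorm(5 * 5 * 128 * 2), c(5, 5, 128, 2))
  a2 <- array(rnorm(5 * 5 * 128 * 2), c(5, 5, 128, 2))
  y <- concat_e(list(a1, a2))
  expect_equal(dim(y), c(5, 5, 256, 2))
  # gates lie strictly inside (0,1): |y| < |concat| elementwise
  plain <- array(0, c(5, 5, 256, 2))
  plain[, , 1:128, ] <- a1; plain[, , 129:256, ] <- a2
  expect_true(all(abs(y) < abs(plain) + 1e-12))
  expect_true(all(abs(y) > 0 | plain == 0))
  # forcing the excitation to saturate reproduces plain concatenation
  m <- wildetect:::nn_concat_e(256, r = 16)
  p <- nn_parameters(m)
  p[["fc2.weight"]]$value[] <- 0
  p[["fc2.bias"]]$value[] <- 1e3
  y2 <- m$forward(list(ag_tensor(a1), ag_tensor(a2)))$value
  expect_equal(y2, plain, tolerance = 1e-12)
  # squeeze of a constant channel is that constant
  cst <- array(0, c(4, 4, 2, 1)); cst[, , 1, ] <- 2.5; cst[, , 2, ] <- -1
  sq <- wildetect:::ag_mean_hw(ag_tensor(cst))$value
  expect_equal(as.numeric(sq), c(2.5, -1))
  # mismatched spatial extents error
  expect_error(m$forward(list(ag_tensor(a1), ag_tensor(a2[1:4, , , , drop = FALSE]))),
               "spatial extents differ")
})

test_that("blocks are differentiable end-to-end with finite gradients", {
  set.seed(60)
  x <- ag_tensor(array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2)), TRUE)
  blocks <- list(
    wildetect:::nn_cbl(6, 8, 3, 1),
    wildetect:::nn_csp1(6, 8, 1),
    wildetect:::nn_csp2(6, 8, 1),
    wildetect:::nn_spp(6, 8)
  )
  for (blk in blocks) {
    ag_zero_grad(c(list(x), nn_parameters(blk)))
    y <- blk$forward(x, TRUE)
    ag_backward(ag_sum(ag_square(y)))
    expect_true(all(is.finite(x$grad)))
    for (p in nn_parameters(blk)) {
      if (!is.null(p$grad)) expect_true(all(is.finite(p$grad)))
    }
  }
})
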