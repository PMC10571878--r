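# Shared fixtures: all built in code, deterministically.

tiny_image <- function(h = 64, w = 64, boxes = list(), id = "t") {
  set.seed(h * 1000 + w)
  annotated_image(array(runif(h * w * 3, 0, 255), dim = c(h, w, 3)), boxes, id)
}

# A small deterministic synthetic set reused across tests.
fixture_scenes <- function(n = 10, classes = 3, side = 96, seed = 7, ...) {
  generate_scenes(scene_spec(n, classes = classes, image_side = side,
                             seed = seed, ...))
}

random_corner_boxes <- function(n, side = 100) {
  x1 <- runif(n, 0, side - 10)
  y1 <- runif(n, 0, side - 10)
  w <- runif(n, 2, side / 3)
  h <- runif(n, 2, side / 3)
  cbind(x1 = x1, y1 = y1, x2 = pmin(x1 + w, side), y2 = pmin(y1 + h, side))
}

# Reference NMS: independent O(n^2) implementation with explicit loops.
brute_force_nms <- function(dets, iou_thresh) {
  keep <- integer(0)
  for (cl in unique(dets$class_id)) {
    idx <- which(dets$class_id == cl)
    idx <- idx[order(-dets$conf[idx], idx)]
    taken <- integer(0)
    for (i in idx) {
      ok <- TRUE
      for (j in taken) {
        bi <- as.numeric(dets[i, c("x1", "y1", "x2", "y2")])
        bj <- as.numeric(dets[j, c("x1", "y1", "x2", "y2")])
        ix <- max(0, min(bi[3], bj[3]) - max(bi[1], bj[1]))
        iy <- max(0, min(bi[4], bj[4]) - max(bi[2], bj[2]))
        inter <- ix * iy
        un <- (bi[3] - bi[1]) * (bi[4] - bi[2]) +
          (bj[3] - bj[1]) * (bj[4] - bj[2]) - inter
        if (inter / un > iou_thresh) { ok <- FALSE; break }
      }
      if (ok) taken <- c(taken, i)
    }
    keep <- c(keep, taken)
  }
  sort(keep)
}

# Reference matcher: plain-loop greedy assignment in confidence order.
brute_force_match_tp <- function(dets, gts, iou_thresh = 0.5) {
  gts <- as.matrix(gts)
  used <- rep(FALSE, nrow(gts))
  tp <- 0
  for (i in order(-dets$conf, seq_len(nrow(dets)))) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j] || gts[j, 5] != dets$class_id[i]) next
      bi <- as.numeric(dets[i, c("x1", "y1", "x2", "y2")])
      bj_ <- gts[j, 1:4]
      ix <- max(0, min(bi[3], bj_[3]) - max(bi[1], bj_[1]))
      iy <- max(0, min(bi[4], bj_[4]) - max(bi[2], bj_[2]))
      inter <- ix * iy
      un <- (bi[3] - bi[1]) * (bi[4] - bi[2]) +
        (bj_[3] - bj_[1]) * (bj_[4] - bj_[2]) - inter
      iou <- inter / un
      if (iou >= iou_thresh && iou > best) { best <- iou; bj <- j }
    }
    if (bj > 0) { used[bj] <- TRUE; tp <- tp + 1 }
  }
  tp
}

dense_attention_oracle <- function(x, params, win) {
  # straight-line reference: global self-attention over all tokens of a map
  # whose window spans it, with relative position bias; then the MLP.
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  tok <- matrix(x[, , , 1], H * W, C)
  ln <- function(m, g, b) {
    mu <- rowMeans(m); xc <- m - mu; v <- rowMeans(xc^2)
    sweep(sweep(xc / sqrt(v + 1e-5), 2, g, "*"), 2, b, "+")
  }
  p <- params
  heads <- ncol(p[["relpos"]]$value)
  hd <- C / heads
  Tn <- H * W
  ri <- wildetect:::relpos_index(win)
  tl <- ln(tok, p[["ln1.gamma"]]$value, p[["ln1.beta"]]$value)
  qkvm <- sweep(tl %*% p[["qkv.weight"]]$value, 2, p[["qkv.bias"]]$value, "+")
  outm <- matrix(0, Tn, C)
  for (h in seq_len(heads)) {
    cols <- (h - 1) * hd + seq_len(hd)
    q <- qkvm[, cols]; k <- qkvm[, C + cols]; v <- qkvm[, 2 * C + cols]
    sc <- q %*% t(k) / sqrt(hd) +
      t(matrix(p[["relpos"]]$value[cbind(as.vector(ri), h)], Tn, Tn))
    a <- exp(sweep(sc, 1, apply(sc, 1, max)))
    a <- a / rowSums(a)
    outm[, cols] <- a %*% v
  }
  outm <- sweep(outm %*% p[["proj.weight"]]$value, 2, p[["proj.bias"]]$value, "+")
  tok2 <- tok + outm
  tl2 <- ln(tok2, p[["ln2.gamma"]]$value, p[["ln2.beta"]]$value)
  mlp <- sweep(tl2 %*% p[["fc1.weight"]]$value, 2, p[["fc1.bias"]]$value, "+")
  mlp <- mlp / (1 + exp(-1.702 * mlp))
  mlp <- sweep(mlp %*% p[["fc2.weight"]]$value, 2, p[["fc2.bias"]]$value, "+")
  tok3 <- tok2 + mlp
  y <- array(0, c(H, W, C, 1))
  for (cc in seq_len(C)) y[, , cc, 1] <- matrix(tok3[, cc], H, W)
  y
}
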