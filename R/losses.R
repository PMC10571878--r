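# ---------------------------------------------------------------------------
# Detection losses.
#
# Box regression: distance-IoU (DIoU) loss, 1 - IoU + rho^2/c^2, where rho
# is the distance between box centroids and c the diagonal of the smallest
# enclosing box. Unlike plain IoU (and faster-converging than generalized
# IoU), it provides a center-seeking gradient even for disjoint boxes.
#
# Classification: adaptive class-suppression binary cross-entropy. For a
# positive cell with true class k, class i contributes with weight
#   w_i = 1           if i == k
#   w_i = 1           if i != k and conf_i >= alpha   (confusing class:
#                                                      keep discriminating)
#   w_i = 0           if i != k and conf_i <  alpha   (suppress the negative
#                                                      gradient on tails)
# The confidences driving the decision are detached from the gradient.
# ---------------------------------------------------------------------------

as_corner_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  stopifnot(ncol(b) >= 4)
  b[, 1:4, drop = FALSE]
}

check_positive_area <- function(m, what) {
  if (any(m[, 3] <= m[, 1] | m[, 4] <= m[, 2])) {
    stop(what, ": boxes must have positive area (x1 < x2, y1 < y2)")
  }
}

#' Generalized-IoU box regression loss
#'
#' `1 - GIoU` where `GIoU = IoU - (area(C) - area(A union B)) / area(C)` and
#' C is the smallest axis-aligned box enclosing both. Ranges over `[0, 2)`.
#'
#' @param pred,target corner boxes: length-4 vectors `(x1, y1, x2, y2)` or
#'   n x 4 matrices (paired rows).
#' @return numeric vector of per-pair losses.
#' @export
giou_loss <- function(pred, target) {
  p <- as_corner_matrix(pred); t <- as_corner_matrix(target)
  check_positive_area(p, "giou_loss(pred)")
  check_positive_area(t, "giou_loss(target)")
  iw <- pmax(pmin(p[, 3], t[, 3]) - pmax(p[, 1], t[, 1]), 0)
  ih <- pmax(pmin(p[, 4], t[, 4]) - pmax(p[, 2], t[, 2]), 0)
  inter <- iw * ih
  union <- (p[, 3] - p[, 1]) * (p[, 4] - p[, 2]) +
    (t[, 3] - t[, 1]) * (t[, 4] - t[, 2]) - inter
  cw <- pmax(p[, 3], t[, 3]) - pmin(p[, 1], t[, 1])
  ch <- pmax(p[, 4], t[, 4]) - pmin(p[, 2], t[, 2])
  carea <- cw * ch
  giou <- inter / union - (carea - union) / carea
  1 - giou
}

#' Distance-IoU box regression loss
#'
#' `1 - IoU + rho^2 / c^2`: IoU plus the squared centroid distance
#' normalized by the squared diagonal of the smallest enclosing box. Always
#' at least `1 - IoU`, with equality exactly when the centroids coincide,
#' and strictly center-seeking for non-overlapping pairs.
#'
#' @inheritParams giou_loss
#' @return numeric vector of per-pair losses in `[0, 2)`.
#' @export
diou_loss <- function(pred, target) {
  p <- as_corner_matrix(pred); t <- as_corner_matrix(target)
  check_positive_area(p, "diou_loss(pred)")
  check_positive_area(t, "diou_loss(target)")
  iw <- pmax(pmin(p[, 3], t[, 3]) - pmax(p[, 1], t[, 1]), 0)
  ih <- pmax(pmin(p[, 4], t[, 4]) - pmax(p[, 2], t[, 2]), 0)
  inter <- iw * ih
  union <- (p[, 3] - p[, 1]) * (p[, 4] - p[, 2]) +
    (t[, 3] - t[, 1]) * (t[, 4] - t[, 2]) - inter
  iou <- inter / union
  rho2 <- ((p[, 1] + p[, 3]) / 2 - (t[, 1] + t[, 3]) / 2)^2 +
    ((p[, 2] + p[, 4]) / 2 - (t[, 2] + t[, 4]) / 2)^2
  cw <- pmax(p[, 3], t[, 3]) - pmin(p[, 1], t[, 1])
  ch <- pmax(p[, 4], t[, 4]) - pmin(p[, 2], t[, 2])
  c2 <- cw^2 + ch^2
  1 - iou + rho2 / c2
}

#' Per-class binary cross-entropy for a one-hot target
#'
#' Sums `-[t_i log c_i + (1 - t_i) log(1 - c_i)]` over all classes, with the
#' one-hot target at `true_class`.
#'
#' @param conf numeric vector of per-class confidences in `[0, 1]`.
#' @param true_class zero-based true class index.
#' @param eps probability clamp for log stability.
#' @return scalar loss (>= 0).
#' @export
bce_loss <- function(conf, true_class, eps = 1e-7) {
  stopifnot(length(conf) >= 2, all(conf >= 0), all(conf <= 1),
            true_class >= 0, true_class < length(conf))
  c_ <- pmin(pmax(conf, eps), 1 - eps)
  t <- rep(0, length(conf))
  t[true_class + 1] <- 1
  -sum(t * log(c_) + (1 - t) * log(1 - c_))
}

#' Adaptive class-suppression weights
#'
#' Weight 1 for the true class; for other classes, weight 1 only when the
#' predicted confidence reaches the suppression threshold `alpha` (the
#' network is confusing that class with the true one and should keep
#' discriminating), otherwise 0 (suppressing the negative gradient).
#'
#' @param conf per-class confidences in `[0, 1]`.
#' @param true_class zero-based true class index.
#' @param alpha suppression threshold in (0, 1).
#' @return 0/1 numeric vector over classes.
#' @export
acsl_weights <- function(conf, true_class, alpha) {
  stopifnot(length(conf) >= 2, true_class >= 0, true_class < length(conf))
  w <- as.numeric(conf >= alpha)
  w[true_class + 1] <- 1
  w
}

#' Class-suppression weighted binary cross-entropy
#'
#' Multiplies each class's cross-entropy term by its [acsl_weights()] weight
#' and sums. Reduces to [bce_loss()] at `alpha = 0`; never exceeds it.
#'
#' @inheritParams acsl_weights
#' @param eps probability clamp for log stability.
#' @return scalar loss (>= 0).
#' @export
l_bce <- function(conf, true_class, alpha, eps = 1e-7) {
  w <- acsl_weights(conf, true_class, alpha)
  c_ <- pmin(pmax(conf, eps), 1 - eps)
  t <- rep(0, length(conf))
  t[true_class + 1] <- 1
  terms <- -(t * log(c_) + (1 - t) * log(1 - c_))
  sum(w * terms)
}

# --- target assignment ------------------------------------------------------

#' Assign ground-truth boxes to head cells and anchors
#'
#' A ground-truth box matches an anchor when the width/height ratio between
#' box and anchor stays below `ratio_max` in both directions; the positive
#' cells are the containing cell plus the two nearest neighbours of the box
#' center. Deterministic; duplicate (cell, anchor) assignments keep the
#' first box.
#'
#' @param boxes_per_image list (length = batch) of n x 5 matrices
#'   `cx, cy, w, h, class_id` in normalized coordinates, or lists of
#'   [bounding_box()]s.
#' @param cfg a [model_config()].
#' @param ratio_max anchor-match ratio bound.
#' @return list of three data frames (one per scale) with the positive-cell
#'   assignments: image `n`, cell column `gi`, cell row `gj` (0-based),
#'   anchor `a`, target box in grid units `gx, gy, gw, gh`, and `class`.
#' @export
assign_targets <- function(boxes_per_image, cfg, ratio_max = 4) {
  strides <- cfg_strides()
  anchors <- cfg_anchors_px(cfg)
  gs <- cfg$input_side / strides
  out <- vector("list", 3)
  for (s in 1:3) {
    rows <- list()
    aw <- anchors[[s]][, 1] / strides[s]
    ah <- anchors[[s]][, 2] / strides[s]
    G <- gs[s]
    for (n in seq_along(boxes_per_image)) {
      m <- boxes_as_matrix(boxes_per_image[[n]])
      if (nrow(m) == 0) next
      if (any(m[, "cx"] < 0 | m[, "cx"] > 1 | m[, "cy"] < 0 | m[, "cy"] > 1)) {
        stop("ground-truth box outside the image in batch element ", n)
      }
      for (b in seq_len(nrow(m))) {
        gx <- m[b, "cx"] * G; gy <- m[b, "cy"] * G
        gw <- m[b, "w"] * G; gh <- m[b, "h"] * G
        if (gw <= 0 || gh <= 0) next
        for (a in 1:3) {
          r <- max(gw / aw[a], aw[a] / gw, gh / ah[a], ah[a] / gh)
          if (r >= ratio_max) next
          ci <- floor(gx); cj <- floor(gy)
          cells <- list(c(ci, cj))
          fx <- gx - ci; fy <- gy - cj
          if (fx < 0.5 && gx > 1) cells <- c(cells, list(c(ci - 1, cj)))
          if (fx >= 0.5 && gx < G - 1) cells <- c(cells, list(c(ci + 1, cj)))
          if (fy < 0.5 && gy > 1) cells <- c(cells, list(c(ci, cj - 1)))
          if (fy >= 0.5 && gy < G - 1) cells <- c(cells, list(c(ci, cj + 1)))
          for (cl in cells) {
            gi <- min(max(cl[1], 0), G - 1)
            gj <- min(max(cl[2], 0), G - 1)
            rows[[length(rows) + 1]] <- c(n = n, gi = gi, gj = gj, a = a,
                                          gx = gx, gy = gy, gw = gw, gh = gh,
                                          class = m[b, "class_id"])
          }
        }
      }
    }
    df <- if (length(rows)) as.data.frame(do.call(rbind, rows))
    else data.frame(n = numeric(0), gi = numeric(0), gj = numeric(0),
                    a = numeric(0), gx = numeric(0), gy = numeric(0),
                    gw = numeric(0), gh = numeric(0), class = numeric(0))
    if (nrow(df)) {
      df <- df[!duplicated(df[, c("n", "gi", "gj", "a")]), , drop = FALSE]
    }
    out[[s]] <- df
  }
  names(out) <- c("p3", "p4", "p5")
  out
}

# Differentiable DIoU on center-format predictions vs constant targets
# (all arguments in the same units, e.g. grid cells).
ag_diou_center <- function(px, py, pw, ph, gx, gy, gw, gh, eps = 1e-9) {
  px1 <- ag_sub(px, ag_scale(pw, 0.5)); px2 <- ag_add(px, ag_scale(pw, 0.5))
  py1 <- ag_sub(py, ag_scale(ph, 0.5)); py2 <- ag_add(py, ag_scale(ph, 0.5))
  tx1 <- gx - gw / 2; tx2 <- gx + gw / 2
  ty1 <- gy - gh / 2; ty2 <- gy + gh / 2
  iw <- ag_clamp_min(ag_sub(ag_pmin2(px2, tx2), ag_pmax2(px1, tx1)), 0)
  ih <- ag_clamp_min(ag_sub(ag_pmin2(py2, ty2), ag_pmax2(py1, ty1)), 0)
  inter <- ag_mul(iw, ih)
  union <- ag_sub(ag_add(ag_mul(pw, ph), gw * gh), inter)
  iou <- ag_div(inter, ag_add(union, eps))
  rho2 <- ag_add(ag_square(ag_sub(px, gx)), ag_square(ag_sub(py, gy)))
  cw <- ag_sub(ag_pmax2(px2, tx2), ag_pmin2(px1, tx1))
  chh <- ag_sub(ag_pmax2(py2, ty2), ag_pmin2(py1, ty1))
  c2 <- ag_add(ag_add(ag_square(cw), ag_square(chh)), eps)
  ag_add(ag_sub(1, iou), ag_div(rho2, c2))
}

# Plain-numeric IoU between center-format boxes (paired vectors).
iou_center_numeric <- function(px, py, pw, ph, gx, gy, gw, gh) {
  ix <- pmax(pmin(px + pw / 2, gx + gw / 2) - pmax(px - pw / 2, gx - gw / 2), 0)
  iy <- pmax(pmin(py + ph / 2, gy + gh / 2) - pmax(py - ph / 2, gy - gh / 2), 0)
  inter <- ix * iy
  inter / (pw * ph + gw * gh - inter + 1e-9)
}

# Flat index helper for a (H, W, C, N) array (1-based inputs).
flat4 <- function(i, j, c, n, H, W, C) {
  i + H * ((j - 1) + W * ((c - 1) + C * (n - 1)))
}

#' Composite detection loss
#'
#' Box term: mean DIoU loss over positive cells. Objectness: binary
#' cross-entropy over all cells (per-scale balance 4 / 1 / 0.4). Class term:
#' class-suppression weighted binary cross-entropy over positives (plain BCE
#' when `cfg$use_acsl` is `FALSE` or `num_classes == 1`). The total is the
#' weighted sum with `cfg$loss_weights`, scaled by the batch size.
#'
#' @param heads list of raw head `ag_tensor`s from [forward_detector()].
#' @param targets output of [assign_targets()] for the same batch.
#' @param cfg the [model_config()].
#' @return list with `total` (`ag_tensor`) and a numeric `breakdown`
#'   (box, obj, cls, total).
#' @export
composite_loss <- function(heads, targets, cfg) {
  strides <- cfg_strides()
  anchors <- cfg_anchors_px(cfg)
  nC <- cfg$num_classes
  nf <- 5 + nC
  lw <- cfg$loss_weights
  obj_balance <- c(4.0, 1.0, 0.4)
  nb <- dim(heads[[1]]$value)[4]

  box_terms <- list(); cls_terms <- list(); obj_terms <- list()
  npos_tot <- 0L
  for (s in 1:3) {
    hm <- heads[[s]]
    d <- dim(hm$value)
    Hs <- d[1]; Ws <- d[2]; Ch <- d[3]
    tg <- targets[[s]]

    # objectness targets over every cell; positives get the detached IoU of
    # the current prediction with their ground truth (calibrates confidence
    # toward localization quality, the one-stage convention)
    tobj <- array(0, dim = d)
    wobj <- array(0, dim = d)
    for (a in 1:3) wobj[, , (a - 1) * nf + 5, ] <- 1

    if (nrow(tg)) {
      npos <- nrow(tg)
      npos_tot <- npos_tot + npos
      base_c <- (tg$a - 1) * nf
      gidx <- function(f) flat4(tg$gj + 1, tg$gi + 1, base_c + f, tg$n, Hs, Ws, Ch)
      sx <- ag_sigmoid(ag_gather(hm, gidx(1), npos))
      sy <- ag_sigmoid(ag_gather(hm, gidx(2), npos))
      sw <- ag_sigmoid(ag_gather(hm, gidx(3), npos))
      sh <- ag_sigmoid(ag_gather(hm, gidx(4), npos))
      px <- ag_add(ag_sub(ag_scale(sx, 2), 0.5), tg$gi)
      py <- ag_add(ag_sub(ag_scale(sy, 2), 0.5), tg$gj)
      aw <- anchors[[s]][tg$a, 1] / strides[s]
      ah <- anchors[[s]][tg$a, 2] / strides[s]
      pw <- ag_mul(ag_square(ag_scale(sw, 2)), aw)
      ph <- ag_mul(ag_square(ag_scale(sh, 2)), ah)
      dl <- ag_diou_center(px, py, pw, ph, tg$gx, tg$gy, tg$gw, tg$gh)
      box_terms[[length(box_terms) + 1]] <- ag_sum(dl)

      oi <- flat4(tg$gj + 1, tg$gi + 1, (tg$a - 1) * nf + 5, tg$n, Hs, Ws, Ch)
      if (isTRUE(cfg$obj_iou_target)) {
        iou_det <- iou_center_numeric(px$value, py$value, pw$value, ph$value,
                                      tg$gx, tg$gy, tg$gw, tg$gh)
        tobj[oi] <- pmax(iou_det, 0)
      } else {
        tobj[oi] <- 1
      }

      if (nC >= 2) {
        cls_idx <- matrix(0, npos, nC)
        for (k in seq_len(nC)) cls_idx[, k] <- gidx(5 + k)
        zc <- ag_gather(hm, as.integer(cls_idx), c(npos, nC))
        tcls <- matrix(0, npos, nC)
        tcls[cbind(seq_len(npos), tg$class + 1)] <- 1
        wcls <- matrix(1, npos, nC)
        if (cfg$use_acsl) {
          probs <- 1 / (1 + exp(-zc$value)) # detached suppression signal
          wcls <- (probs >= cfg$alpha) * 1
          wcls[cbind(seq_len(npos), tg$class + 1)] <- 1
        }
        cls_terms[[length(cls_terms) + 1]] <-
          ag_bce_logits(zc, tcls, wcls, reduction = "sum")
      }
    }

    n_obj_cells <- Hs * Ws * 3 * nb
    obj_terms[[s]] <- ag_scale(
      ag_bce_logits(hm, tobj, wobj, reduction = "sum"),
      obj_balance[s] / n_obj_cells)
  }

  zero <- ag_tensor(0)
  box <- if (length(box_terms)) {
    ag_scale(Reduce(ag_add, box_terms), 1 / max(npos_tot, 1))
  } else zero
  cls <- if (length(cls_terms)) {
    ag_scale(Reduce(ag_add, cls_terms), 1 / max(npos_tot, 1))
  } else zero
  obj <- Reduce(ag_add, obj_terms)
  total <- ag_scale(
    ag_add(ag_add(ag_scale(box, lw[["box"]]), ag_scale(obj, lw[["obj"]])),
           ag_scale(cls, lw[["cls"]])),
    nb)
  list(total = total,
       breakdown = c(box = as.numeric(box$value),
                     obj = as.numeric(obj$value),
                     cls = as.numeric(cls$value),
                     total = as.numeric(total$value)))
}
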