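# ---------------------------------------------------------------------------
# Detector assembly: a YOLOv5s-scale backbone/neck in which the first
# backbone CSP1 block and three of the four neck fusion blocks are Swin
# transformer blocks, and every neck feature merge is an SE-gated
# concatenation (ConcatE). Three 1x1 heads emit dense predictions at
# strides 8 / 16 / 32.
# ---------------------------------------------------------------------------

#' Default anchor set (pixels, for a 640-px input)
#'
#' Three anchors per output scale, ordered P3 (stride 8), P4 (16), P5 (32).
#' @export
default_anchors <- function() {
  list(p3 = matrix(c(10, 13, 16, 30, 33, 23), 3, 2, byrow = TRUE),
       p4 = matrix(c(30, 61, 62, 45, 59, 119), 3, 2, byrow = TRUE),
       p5 = matrix(c(116, 90, 156, 198, 373, 326), 3, 2, byrow = TRUE))
}

make_divisible <- function(x, d = 8) max(d, round(x / d) * d)

#' Cluster anchors from training-set box dimensions
#'
#' Standard data-driven anchor selection: k-means over the ground-truth box
#' widths/heights (in 640-px reference units, the anchor convention used by
#' [model_config()]), centers sorted by area and split across the three
#' output scales.
#'
#' @param images list of [annotated_image()]s with ground truth.
#' @param n number of anchors (9 = 3 per scale).
#' @param seed k-means seed.
#' @return anchor list shaped like [default_anchors()].
#' @export
cluster_anchors <- function(images, n = 9L, seed = 0L) {
  wh <- do.call(rbind, lapply(images, function(img) {
    m <- boxes_as_matrix(img$boxes)
    m[, c("w", "h"), drop = FALSE]
  }))
  wh <- wh[wh[, 1] > 0 & wh[, 2] > 0, , drop = FALSE] * 640
  if (nrow(unique(wh)) < n) {
    warning("fewer than ", n, " distinct box sizes; keeping default anchors")
    return(default_anchors())
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- stats::kmeans(wh, centers = n, nstart = 10, iter.max = 100)
  cen <- km$centers[order(km$centers[, 1] * km$centers[, 2]), , drop = FALSE]
  dimnames(cen) <- NULL
  list(p3 = cen[1:3, , drop = FALSE],
       p4 = cen[4:6, , drop = FALSE],
       p5 = cen[7:9, , drop = FALSE])
}

#' Detector configuration
#'
#' @param num_classes number of object categories (N >= 1).
#' @param input_side square network input in pixels, divisible by 32.
#' @param depth_mult,width_mult block-repeat and channel-width scale factors
#'   (0.33 / 0.50 reproduce the "s"-scale model).
#' @param anchors list of three 3x2 matrices of anchor (w, h) in pixels for a
#'   640-px input; scaled internally by `input_side / 640`.
#' @param window Swin attention window side (cells).
#' @param se_reduction squeeze-and-excitation bottleneck ratio.
#' @param conf_floor decode-time confidence floor.
#' @param nms_iou IoU threshold for non-maximum suppression.
#' @param conf_thresh evaluation-time confidence threshold (detections above
#'   this confidence count as targets).
#' @param alpha class-suppression threshold of the classification loss.
#' @param loss_weights named numeric (box, obj, cls) balance weights.
#' @param use_acsl use the adaptive class-suppression classification loss;
#'   `FALSE` falls back to plain binary cross-entropy.
#' @param obj_iou_target objectness targets at positive cells are the
#'   detached IoU of the current prediction with its ground truth (the
#'   one-stage calibration convention); `FALSE` uses plain 0/1 targets.
#' @return a `model_config` list (validated).
#' @export
model_config <- function(num_classes,
                         input_side = 640L,
                         depth_mult = 0.33,
                         width_mult = 0.50,
                         anchors = default_anchors(),
                         window = 7L,
                         se_reduction = 16L,
                         conf_floor = 0.001,
                         nms_iou = 0.45,
                         conf_thresh = 0.5,
                         alpha = 0.25,
                         loss_weights = c(box = 0.05, obj = 1.0, cls = 0.5),
                         use_acsl = TRUE,
                         obj_iou_target = TRUE) {
  if (num_classes < 1) stop("num_classes must be >= 1")
  if (input_side %% 32 != 0) stop("input_side must be divisible by 32")
  if (any(unlist(anchors) <= 0)) stop("anchors must be positive")
  stopifnot(length(anchors) == 3)
  cfg <- list(num_classes = as.integer(num_classes),
              input_side = as.integer(input_side),
              depth_mult = depth_mult, width_mult = width_mult,
              anchors = anchors, window = as.integer(window),
              se_reduction = as.integer(se_reduction),
              conf_floor = conf_floor, nms_iou = nms_iou,
              conf_thresh = conf_thresh, alpha = alpha,
              loss_weights = loss_weights, use_acsl = isTRUE(use_acsl),
              obj_iou_target = isTRUE(obj_iou_target))
  class(cfg) <- "model_config"
  cfg
}

cfg_channels <- function(cfg) {
  base <- c(64, 128, 256, 512, 1024)
  vapply(base, function(b) make_divisible(b * cfg$width_mult, 8), numeric(1))
}

cfg_depth <- function(cfg, n_base) max(1L, round(n_base * cfg$depth_mult))

cfg_strides <- function() c(8L, 16L, 32L)

# Anchors in pixels at the configured input side, one 3x2 matrix per scale.
cfg_anchors_px <- function(cfg) {
  s <- cfg$input_side / 640
  lapply(cfg$anchors, function(a) a * s)
}

#' Build the detector network
#'
#' Backbone: Focus, CBL, Swin block (in place of the first CSP1), CBL, CSP1,
#' CBL, CSP1, CBL, SPP. Neck: feature-pyramid top-down plus path-aggregation
#' bottom-up; all four merges use ConcatE and three of the four fusion
#' blocks (top-down P4 and P3, bottom-up P4) are Swin blocks, the deepest
#' (bottom-up P5) remaining a CSP2. Heads are 1x1 convolutions emitting
#' `3 * (5 + num_classes)` channels at strides 8 / 16 / 32.
#'
#' @param cfg a [model_config()].
#' @return a model module; run it with [forward_detector()].
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  ch <- cfg_channels(cfg) # c1..c5 at /2 /4 /8 /16 /32
  nC <- cfg$num_classes
  no <- 3L * (5L + nC)
  m <- nn_module("wd_model")
  m$cfg <- cfg

  swin_cfg <- function(dim, shifted = FALSE) {
    swin_config(dim, window = cfg$window, heads = max(1L, dim %/% 32L),
                mlp_ratio = 4, shifted = shifted)
  }

  # --- backbone ---
  focus <- nn_child(m, "focus", nn_focus(3, ch[1]))
  cb1 <- nn_child(m, "cb1", nn_cbl(ch[1], ch[2], 3, 2))
  sw_b <- nn_child(m, "swin_backbone", nn_swin_block(swin_cfg(ch[2], shifted = FALSE)))
  cb2 <- nn_child(m, "cb2", nn_cbl(ch[2], ch[3], 3, 2))
  csp3 <- nn_child(m, "csp_p3", nn_csp1(ch[3], ch[3], cfg_depth(cfg, 9)))
  cb3 <- nn_child(m, "cb3", nn_cbl(ch[3], ch[4], 3, 2))
  csp4 <- nn_child(m, "csp_p4", nn_csp1(ch[4], ch[4], cfg_depth(cfg, 9)))
  cb4 <- nn_child(m, "cb4", nn_cbl(ch[4], ch[5], 3, 2))
  spp <- nn_child(m, "spp", nn_spp(ch[5], ch[5]))

  # --- neck ---
  cv5 <- nn_child(m, "cv5", nn_cbl(ch[5], ch[4], 1))
  ce_fpn4 <- nn_child(m, "ce_fpn4", nn_concat_e(2 * ch[4], cfg$se_reduction))
  red_fpn4 <- nn_child(m, "red_fpn4", nn_cbl(2 * ch[4], ch[4], 1))
  sw_fpn4 <- nn_child(m, "swin_fpn4", nn_swin_block(swin_cfg(ch[4], shifted = TRUE)))
  cv4 <- nn_child(m, "cv4", nn_cbl(ch[4], ch[3], 1))
  ce_fpn3 <- nn_child(m, "ce_fpn3", nn_concat_e(2 * ch[3], cfg$se_reduction))
  red_fpn3 <- nn_child(m, "red_fpn3", nn_cbl(2 * ch[3], ch[3], 1))
  sw_fpn3 <- nn_child(m, "swin_fpn3", nn_swin_block(swin_cfg(ch[3], shifted = FALSE)))
  down3 <- nn_child(m, "down3", nn_cbl(ch[3], ch[3], 3, 2))
  ce_pan4 <- nn_child(m, "ce_pan4", nn_concat_e(2 * ch[3], cfg$se_reduction))
  red_pan4 <- nn_child(m, "red_pan4", nn_cbl(2 * ch[3], ch[4], 1))
  sw_pan4 <- nn_child(m, "swin_pan4", nn_swin_block(swin_cfg(ch[4], shifted = TRUE)))
  down4 <- nn_child(m, "down4", nn_cbl(ch[4], ch[4], 3, 2))
  ce_pan5 <- nn_child(m, "ce_pan5", nn_concat_e(2 * ch[4], cfg$se_reduction))
  csp_pan5 <- nn_child(m, "csp_pan5", nn_csp2(2 * ch[4], ch[5], cfg_depth(cfg, 3)))

  # --- heads (conv bias primed so early objectness is rare) ---
  head_bias <- function(stride) {
    b <- numeric(no)
    for (a in 0:2) {
      off <- a * (5 + nC)
      b[off + 5] <- log(8 / (cfg$input_side / stride)^2)
      b[off + 5 + seq_len(nC)] <- log(0.6 / (nC - 0.99 + 1e-9))
    }
    b
  }
  h3 <- nn_child(m, "head_p3", nn_cbl(ch[3], no, 1, 1, act = "none", bn = FALSE,
                                      bias_init = head_bias(8)))
  h4 <- nn_child(m, "head_p4", nn_cbl(ch[4], no, 1, 1, act = "none", bn = FALSE,
                                      bias_init = head_bias(16)))
  h5 <- nn_child(m, "head_p5", nn_cbl(ch[5], no, 1, 1, act = "none", bn = FALSE,
                                      bias_init = head_bias(32)))

  # structural audit metadata
  m$swin_points <- c("swin_backbone", "swin_fpn4", "swin_fpn3", "swin_pan4")
  m$merge_nodes <- c("ce_fpn4", "ce_fpn3", "ce_pan4", "ce_pan5")
  m$training <- FALSE

  m$forward <- function(x, train = FALSE) {
    if (!inherits(x, "ag_tensor")) x <- ag_tensor(x)
    y <- focus$forward(x, train)
    y <- cb1$forward(y, train)
    y <- sw_b$forward(y, train)
    y <- cb2$forward(y, train)
    p3 <- csp3$forward(y, train)
    y <- cb3$forward(p3, train)
    p4 <- csp4$forward(y, train)
    y <- cb4$forward(p4, train)
    p5 <- spp$forward(y, train)

    t5 <- cv5$forward(p5, train)
    f4 <- sw_fpn4$forward(
      red_fpn4$forward(ce_fpn4$forward(list(ag_upsample2(t5), p4), train), train),
      train)
    t4 <- cv4$forward(f4, train)
    f3 <- sw_fpn3$forward(
      red_fpn3$forward(ce_fpn3$forward(list(ag_upsample2(t4), p3), train), train),
      train)
    o4 <- sw_pan4$forward(
      red_pan4$forward(ce_pan4$forward(list(down3$forward(f3, train), t4), train), train),
      train)
    o5 <- csp_pan5$forward(ce_pan5$forward(list(down4$forward(o4, train), t5), train),
                           train)
    list(p3 = h3$forward(f3, train),
         p4 = h4$forward(o4, train),
         p5 = h5$forward(o5, train))
  }
  m
}

#' Run the detector forward pass
#'
#' @param model from [build_model()].
#' @param x input raster batch: (H, W, 3, N) array with values in `[0, 255]`
#'   (rescaled internally) or an `ag_tensor` already on the 0-1 scale.
#' @param train training mode (batch-norm batch statistics, gradient tape).
#' @return named list of raw head tensors `p3`, `p4`, `p5`, each of dim
#'   (H/stride, W/stride, 3*(5+N), batch).
#' @export
forward_detector <- function(model, x, train = FALSE) {
  if (!inherits(x, "ag_tensor")) {
    if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
    x <- ag_tensor(x / 255)
  }
  model$forward(x, train)
}

# --- decode -----------------------------------------------------------------

#' Decode raw head maps into detections
#'
#' Applies the sigmoid parameterisation (center offsets in (-0.5, 1.5) around
#' the cell, sizes up to 4x the anchor), multiplies objectness by the best
#' class probability, and drops candidates below the confidence floor.
#'
#' @param heads list of raw head arrays (values, not tensors) as returned by
#'   [forward_detector()] (use `lapply(h, function(t) t$value)` or pass the
#'   tensors themselves).
#' @param cfg the [model_config()] used to build the model.
#' @param conf_floor override of the decode confidence floor.
#' @return list (one per batch element) of data frames with columns
#'   x1, y1, x2, y2, conf, class_id (pixels in the network input frame).
#' @export
decode_heads <- function(heads, cfg, conf_floor = NULL) {
  if (is.null(conf_floor)) conf_floor <- cfg$conf_floor
  heads <- lapply(heads, ag_value)
  strides <- cfg_strides()
  anchors <- cfg_anchors_px(cfg)
  nC <- cfg$num_classes
  nf <- 5 + nC
  nb <- dim(heads[[1]])[4]
  out <- replicate(nb, list(), simplify = FALSE)
  for (s in 1:3) {
    hm <- heads[[s]]
    d <- dim(hm)
    Hs <- d[1]; Ws <- d[2]
    stopifnot(d[3] == 3 * nf)
    stride <- strides[s]
    for (n in seq_len(nb)) {
      for (a in 1:3) {
        v <- hm[, , (a - 1) * nf + seq_len(nf), n, drop = FALSE]
        dim(v) <- c(Hs, Ws, nf)
        sg <- 1 / (1 + exp(-v))
        obj <- sg[, , 5]
        clsm <- sg[, , 5 + seq_len(nC), drop = FALSE]
        dim(clsm) <- c(Hs * Ws, nC)
        best <- max.col(clsm, ties.method = "first")
        bestp <- clsm[cbind(seq_len(Hs * Ws), best)]
        conf <- as.vector(obj) * bestp
        keep <- which(conf >= conf_floor)
        if (!length(keep)) next
        rows <- ((keep - 1) %% Hs) + 1
        cols <- ((keep - 1) %/% Hs) + 1
        bx <- (2 * as.vector(sg[, , 1])[keep] - 0.5 + (cols - 1)) * stride
        by <- (2 * as.vector(sg[, , 2])[keep] - 0.5 + (rows - 1)) * stride
        bw <- (2 * as.vector(sg[, , 3])[keep])^2 * anchors[[s]][a, 1]
        bh <- (2 * as.vector(sg[, , 4])[keep])^2 * anchors[[s]][a, 2]
        out[[n]][[length(out[[n]]) + 1]] <- data.frame(
          x1 = bx - bw / 2, y1 = by - bh / 2,
          x2 = bx + bw / 2, y2 = by + bh / 2,
          conf = conf[keep], class_id = best[keep] - 1L)
      }
    }
  }
  lapply(out, function(l) {
    if (!length(l)) {
      return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                        y2 = numeric(0), conf = numeric(0), class_id = integer(0)))
    }
    do.call(rbind, l)
  })
}

#' Greedy per-class non-maximum suppression
#'
#' @param dets data frame with columns x1, y1, x2, y2, conf, class_id.
#' @param iou_thresh suppression IoU threshold in (0, 1).
#' @return the surviving subset, ordered by decreasing confidence.
#' @export
nms <- function(dets, iou_thresh = 0.45) {
  stopifnot(iou_thresh > 0, iou_thresh < 1)
  if (nrow(dets) == 0) return(dets)
  keep_all <- integer(0)
  for (cl in unique(dets$class_id)) {
    idx <- which(dets$class_id == cl)
    idx <- idx[order(dets$conf[idx], -idx, decreasing = TRUE)]
    boxes <- as.matrix(dets[idx, c("x1", "y1", "x2", "y2")])
    alive <- rep(TRUE, length(idx))
    for (i in seq_along(idx)) {
      if (!alive[i]) next
      keep_all <- c(keep_all, idx[i])
      if (i < length(idx)) {
        rest <- which(alive & seq_along(idx) > i)
        if (length(rest)) {
          ious <- box_iou(boxes[i, , drop = FALSE], boxes[rest, , drop = FALSE])
          alive[rest[ious[1, ] > iou_thresh]] <- FALSE
        }
      }
    }
  }
  out <- dets[keep_all, , drop = FALSE]
  out[order(out$conf, decreasing = TRUE), , drop = FALSE]
}

#' Detect objects in annotated images
#'
#' Letterboxes each image to the configured input side, runs the network,
#' decodes, applies NMS and maps boxes back to source-image pixels.
#'
#' @param model from [build_model()] (trained).
#' @param images list of [annotated_image()]s (boxes, if any, are ignored).
#' @param conf_thresh report only detections at or above this confidence.
#' @return list of data frames (x1, y1, x2, y2, conf, class_id) in source
#'   pixel coordinates.
#' @export
detect_images <- function(model, images, conf_thresh = NULL) {
  cfg <- model$cfg
  if (is.null(conf_thresh)) conf_thresh <- cfg$conf_thresh
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    lb <- letterbox(images[[i]], cfg$input_side)
    x <- lb$image$pixels
    dim(x) <- c(dim(x), 1)
    heads <- forward_detector(model, x, train = FALSE)
    dets <- decode_heads(heads, cfg)[[1]]
    dets <- nms(dets, cfg$nms_iou)
    dets <- dets[dets$conf >= conf_thresh, , drop = FALSE]
    out[[i]] <- letterbox_invert_dets(dets, lb$transform, images[[i]])
  }
  out
}

# --- checkpoints ------------------------------------------------------------

#' Save / load model checkpoints
#'
#' `save_checkpoint()` writes config plus parameter and buffer arrays;
#' `load_checkpoint()` rebuilds the model and restores them.
#' `checkpoint_half_raw()` serializes all parameters in IEEE half precision
#' and is what determines the on-disk weight size reported for the model.
#'
#' @param model a built model.
#' @param path file path.
#' @return `load_checkpoint()` returns the model; `checkpoint_half_raw()`
#'   a raw vector (2 bytes per parameter).
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(cfg = model$cfg, state = model_state(model))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$cfg)
  load_model_state(model, obj$state)
  model
}

#' @rdname save_checkpoint
#' @export
checkpoint_half_raw <- function(model) {
  ps <- nn_parameters(model)
  double_to_half_cpp(unlist(lapply(ps, function(p) as.numeric(p$value)),
                            use.names = FALSE))
}

#' @rdname save_checkpoint
#' @export
save_checkpoint_half <- function(model, path) {
  writeBin(checkpoint_half_raw(model), path)
  invisible(path)
}
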