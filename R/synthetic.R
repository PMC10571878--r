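# ---------------------------------------------------------------------------
# Deterministic synthetic camera-trap scenes.
#
# The generator emulates the structural difficulties of trap-camera imagery:
# textured, cluttered backgrounds with large illumination variation; a
# low-contrast mode in which object colour is drawn close to the local
# background; densely arranged, overlapping instances; a long-tailed class
# distribution; and pairs of near-identical shape archetypes standing in for
# confusable sister species. All randomness flows from one root seed through
# a per-image counter so any single image is regenerable in isolation.
# ---------------------------------------------------------------------------

shape_archetypes <- function() {
  list(
    list(name = "ellipse", color = c(150, 105, 70), tex_freq = 0.25, tex_dir = 0),
    list(name = "triangle", color = c(225, 222, 210), tex_freq = 0.15, tex_dir = 90),
    # the crescent is deliberately close to the ellipse archetype (same
    # family, small appearance difference) and sits early in the list so
    # that class-imbalanced subsets place a confusable shape in the tail
    list(name = "crescent", color = c(160, 112, 78), tex_freq = 0.25, tex_dir = 30),
    list(name = "star", color = c(205, 170, 60), tex_freq = 0.45, tex_dir = 45),
    list(name = "roundrect", color = c(120, 125, 135), tex_freq = 0.30, tex_dir = 0)
  )
}

#' Specification of a synthetic scene collection
#'
#' @param n_images number of images.
#' @param classes list of shape archetypes (see `shape_archetypes()`), or an
#'   integer: the first so-many default archetypes.
#' @param class_frequencies sampling proportions per class (sum 1); the
#'   default is long-tailed.
#' @param contrast_mode `"normal"` or `"low"` (object colours pulled toward
#'   the background).
#' @param overlap_rate fraction of multi-object images forced to contain an
#'   overlapping pair.
#' @param image_side square image side in pixels (>= 64).
#' @param seed root seed; all images derive from (seed, index).
#' @param max_objects most instances per image (counts 0..max are sampled,
#'   favouring 1-3).
#' @return a `scene_spec`.
#' @export
scene_spec <- function(n_images,
                       classes = 5,
                       class_frequencies = NULL,
                       contrast_mode = c("normal", "low"),
                       overlap_rate = 0.3,
                       image_side = 160L,
                       seed = 0L,
                       max_objects = 6L) {
  contrast_mode <- match.arg(contrast_mode)
  if (is.numeric(classes) && length(classes) == 1) {
    classes <- shape_archetypes()[seq_len(classes)]
  }
  nc <- length(classes)
  stopifnot(nc >= 2, image_side >= 64, overlap_rate >= 0, overlap_rate <= 1)
  if (is.null(class_frequencies)) {
    class_frequencies <- switch(as.character(nc),
                                "2" = c(0.75, 0.25),
                                "3" = c(0.60, 0.30, 0.10),
                                "4" = c(0.55, 0.25, 0.14, 0.06),
                                c(0.55, 0.25, 0.12, 0.05, 0.03)[seq_len(nc)])
    class_frequencies <- class_frequencies / sum(class_frequencies)
  }
  stopifnot(length(class_frequencies) == nc,
            abs(sum(class_frequencies) - 1) < 1e-6)
  structure(list(n_images = as.integer(n_images), classes = classes,
                 class_frequencies = class_frequencies,
                 contrast_mode = contrast_mode, overlap_rate = overlap_rate,
                 image_side = as.integer(image_side), seed = as.integer(seed),
                 max_objects = as.integer(max_objects)),
            class = "scene_spec")
}

scene_seed <- function(spec, index) {
  (abs(spec$seed) * 100003 + index * 97 + 11) %% 2147483647
}

forest_palette <- function() {
  rbind(c(58, 74, 48), c(84, 96, 60), c(70, 62, 44),
        c(96, 84, 58), c(52, 64, 52), c(104, 98, 70))
}

# Smooth value noise: low-resolution white noise upsampled bilinearly.
smooth_noise <- function(side, cells = 8) {
  base <- matrix(stats::rnorm(cells * cells), cells, cells)
  img <- EBImage::resize(EBImage::Image(base), w = side, h = side)
  t(as.array(img))
}

shape_mask <- function(name, X, Y, cx, cy, rx, ry, rot = 0) {
  dx <- X - cx; dy <- Y - cy
  if (rot != 0) {
    cr <- cos(rot); sr <- sin(rot)
    dx2 <- cr * dx + sr * dy
    dy <- -sr * dx + cr * dy
    dx <- dx2
  }
  switch(name,
         ellipse = (dx / rx)^2 + (dy / ry)^2 <= 1,
         triangle = abs(dx) / rx <= (dy + ry) / (2 * ry) & dy <= ry & dy >= -ry,
         star = {
           th <- atan2(dy, dx)
           r <- sqrt(dx^2 + dy^2)
           rad <- (0.55 + 0.45 * cos(5 * th)) * (rx + ry) / 2
           r <= rad
         },
         roundrect = {
           rr <- 0.35 * min(rx, ry)
           qx <- pmax(abs(dx) - (rx - rr), 0)
           qy <- pmax(abs(dy) - (ry - rr), 0)
           qx^2 + qy^2 <= rr^2
         },
         crescent = {
           outer_m <- (dx / rx)^2 + (dy / ry)^2 <= 1
           inner <- ((dx - 0.45 * rx) / (0.8 * rx))^2 + (dy / (0.8 * ry))^2 <= 1
           outer_m & !inner
         },
         stop("unknown shape archetype: ", name))
}

#' Generate one deterministic synthetic scene
#'
#' @param spec a [scene_spec()].
#' @param index 1-based image index; (seed, index) fully determine the
#'   output.
#' @return an [annotated_image()] with tight ground-truth boxes.
#' @export
generate_scene <- function(spec, index) {
  side <- spec$image_side
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(scene_seed(spec, index))

  pal <- forest_palette()
  base <- pal[sample(nrow(pal), 1), ]
  Y <- matrix(seq_len(side), side, side)
  X <- matrix(seq_len(side), side, side, byrow = TRUE)
  grad <- (Y / side - 0.5) * stats::runif(1, -40, 40)
  coarse <- smooth_noise(side, cells = sample(5:10, 1)) * stats::runif(1, 8, 22)
  px <- array(0, dim = c(side, side, 3))
  for (ch in 1:3) {
    px[, , ch] <- base[ch] + grad + coarse * stats::runif(1, 0.7, 1.3) +
      matrix(stats::rnorm(side * side, 0, 6), side, side)
  }

  n_classes <- length(spec$classes)
  count_probs <- c(0.05, 0.25, 0.30, 0.20, 0.12, 0.05, 0.03)[seq_len(spec$max_objects + 1)]
  count_probs <- count_probs / sum(count_probs)
  n_obj <- sample(0:spec$max_objects, 1, prob = count_probs)
  boxes <- list()
  centers <- list()
  tight_box <- function(mask) {
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    c(x1 = cols[1] - 1, y1 = rows[1] - 1, x2 = cols[2], y2 = rows[2])
  }
  for (k in seq_len(n_obj)) {
    cl <- sample(seq_len(n_classes), 1, prob = spec$class_frequencies)
    arch <- spec$classes[[cl]]
    rx <- stats::runif(1, 0.09, 0.20) * side
    ry <- rx * stats::runif(1, 0.75, 1.3)
    margin <- max(rx, ry) + 2
    rot <- stats::runif(1, -0.4, 0.4)
    overlap_forced <- k > 1 && stats::runif(1) < spec$overlap_rate
    if (overlap_forced) {
      refi <- sample(length(centers), 1)
      prev <- centers[[refi]]
      refbox <- matrix(boxes_to_corners(boxes[refi], side, side)[1, 1:4], 1)
      mask <- NULL
      sc <- 0.6
      for (try in 1:25) {
        cx <- min(max(prev[1] + stats::runif(1, -sc, sc) * rx, margin), side - margin)
        cy <- min(max(prev[2] + stats::runif(1, -sc, sc) * ry, margin), side - margin)
        cand <- shape_mask(arch$name, X, Y, cx, cy, rx, ry, rot)
        if (!any(cand)) next
        tb <- tight_box(cand)
        if (box_iou(matrix(tb, 1), refbox)[1, 1] > 0.3) { mask <- cand; break }
        sc <- sc * 0.8
        mask <- cand # fall back to the closest attempt
      }
      if (is.null(mask)) next
    } else {
      cx <- stats::runif(1, margin, side - margin)
      cy <- stats::runif(1, margin, side - margin)
      mask <- shape_mask(arch$name, X, Y, cx, cy, rx, ry, rot)
      if (!any(mask)) next
    }
    col <- arch$color + stats::rnorm(3, 0, 12)
    if (spec$contrast_mode == "low") {
      local_bg <- vapply(1:3, function(ch) mean(px[, , ch][mask]), numeric(1))
      col <- 0.75 * local_bg + 0.25 * col + stats::rnorm(3, 0, 4)
    }
    tex <- 1 + 0.18 * sin(2 * pi * arch$tex_freq *
                            (X * cospi(arch$tex_dir / 180) +
                               Y * sinpi(arch$tex_dir / 180)) / 8)
    shade <- matrix(stats::rnorm(side * side, 0, 5), side, side)
    for (ch in 1:3) {
      layer <- px[, , ch]
      layer[mask] <- (col[ch] * tex + shade)[mask]
      px[, , ch] <- layer
    }
    tb <- tight_box(mask)
    boxes[[length(boxes) + 1]] <- bounding_box(
      cl - 1L,
      cx = (tb["x1"] + tb["x2"]) / 2 / side, cy = (tb["y1"] + tb["y2"]) / 2 / side,
      w = (tb["x2"] - tb["x1"]) / side, h = (tb["y2"] - tb["y1"]) / side)
    centers[[length(centers) + 1]] <- c(cx, cy)
  }
  px <- pmin(pmax(px, 0), 255)
  annotated_image(px, boxes, source_id = sprintf("synth_%06d", index))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate all scenes of a specification in memory
#' @param spec a [scene_spec()].
#' @return list of [annotated_image()]s.
#' @export
generate_scenes <- function(spec) {
  lapply(seq_len(spec$n_images), function(i) generate_scene(spec, i))
}

#' Generate a train/validation dataset on disk
#'
#' Writes YOLO-txt datasets under `root/train` and `root/val` (80/20 split
#' by a deterministic function of the image index) plus a `data.yaml`
#' config naming the classes.
#'
#' @param spec a [scene_spec()].
#' @param root destination directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `root`, invisibly.
#' @export
generate_dataset <- function(spec, root, overwrite = FALSE) {
  if (dir.exists(root) && length(list.files(root)) && !overwrite) {
    stop("target directory ", root, " is non-empty; use overwrite = TRUE")
  }
  idx <- seq_len(spec$n_images)
  val <- idx %% 5L == 0L
  imgs <- generate_scenes(spec)
  write_dataset(imgs[!val], file.path(root, "train"), "yolo_txt")
  write_dataset(imgs[val], file.path(root, "val"), "yolo_txt")
  write_dataset_config(
    list(names = vapply(spec$classes, function(c) c$name, character(1)),
         train = file.path(root, "train"),
         val = file.path(root, "val")),
    file.path(root, "data.yaml"))
  invisible(root)
}

#' Ground-truth pass-through detections
#'
#' Turns each image's ground-truth boxes into detections with confidence
#' 1.0 — the perfect-oracle detector used to self-test the evaluation stack.
#'
#' @param images list of [annotated_image()]s.
#' @return list of detection data frames (pixel corners, conf, class_id).
#' @export
perfect_oracle_detections <- function(images) {
  lapply(images, function(img) {
    d <- dim(img$pixels)
    cm <- boxes_to_corners(img$boxes, d[2], d[1])
    data.frame(x1 = cm[, "x1"], y1 = cm[, "y1"], x2 = cm[, "x2"], y2 = cm[, "y2"],
               conf = rep(1, nrow(cm)), class_id = as.integer(cm[, "class_id"]))
  })
}

#' Ground truth of an annotated image as a corner matrix
#' @param img an [annotated_image()].
#' @return matrix with columns x1, y1, x2, y2, class_id (pixels).
#' @export
gt_corners <- function(img) {
  d <- dim(img$pixels)
  boxes_to_corners(img$boxes, d[2], d[1])
}
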