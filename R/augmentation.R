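# ---------------------------------------------------------------------------
# Box-aware dataset enrichment: rotation (raster and annotation geometry
# transformed together), Gaussian blur/noise corruption, object-level image
# fusion (annotated object crops pasted into host images away from the
# host's own objects, IoU-constrained), and four-image mosaic stitching.
# All operations are pure functions of (inputs, seed).
# ---------------------------------------------------------------------------

#' Rotate an image and its boxes about the image center
#'
#' The raster is rotated by `angle` degrees (bilinear resampling, constant
#' fill outside the source); each box is replaced by the axis-aligned hull
#' of its four rotated corners, clipped to the canvas. Hulls over-cover
#' rotated content — the conservative choice for an axis-aligned detector.
#'
#' @param img an [annotated_image()].
#' @param angle rotation in degrees (90 maps a point (x, y), in normalized
#'   coordinates, to (y, 1 - x)).
#' @param fill fill intensity for out-of-source pixels.
#' @return the rotated [annotated_image()].
#' @export
rotate_with_boxes <- function(img, angle, fill = 114) {
  th <- angle * pi / 180
  d <- dim(img$pixels)
  H <- d[1]; W <- d[2]
  if (abs(angle %% 360) < 1e-12) {
    out <- img
    out$source_id <- img$source_id
    return(out)
  }
  cx0 <- (W + 1) / 2; cy0 <- (H + 1) / 2
  X <- matrix(seq_len(W), H, W, byrow = TRUE) - cx0
  Y <- matrix(seq_len(H), H, W) - cy0
  # inverse map: source position of each output pixel
  xs <- cos(th) * X - sin(th) * Y + cx0
  ys <- sin(th) * X + cos(th) * Y + cy0
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  px <- array(fill, dim = d)
  inb <- function(x, y) x >= 1 & x <= W & y >= 1 & y <= H
  cl <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  valid <- inb(xs, ys)
  for (ch in 1:3) {
    src <- img$pixels[, , ch]
    at <- function(y, x) src[cbind(as.vector(cl(y, 1, H)), as.vector(cl(x, 1, W)))]
    v <- (1 - fx) * (1 - fy) * matrix(at(y0, x0), H, W) +
      fx * (1 - fy) * matrix(at(y0, x0 + 1), H, W) +
      (1 - fx) * fy * matrix(at(y0 + 1, x0), H, W) +
      fx * fy * matrix(at(y0 + 1, x0 + 1), H, W)
    layer <- matrix(fill, H, W)
    layer[valid] <- v[valid]
    px[, , ch] <- layer
  }
  px <- pmin(pmax(px, 0), 255) # guard against bilinear rounding overshoot
  m <- boxes_as_matrix(img$boxes)
  if (nrow(m) > 0) {
    ref_area <- m[, "w"] * m[, "h"]
    for (i in seq_len(nrow(m))) {
      # continuous (half-open) pixel coordinates, rotation about (W/2, H/2)
      xs_ <- (c(m[i, "cx"] - m[i, "w"] / 2, m[i, "cx"] + m[i, "w"] / 2,
                m[i, "cx"] - m[i, "w"] / 2, m[i, "cx"] + m[i, "w"] / 2)) * W - W / 2
      ys_ <- (c(m[i, "cy"] - m[i, "h"] / 2, m[i, "cy"] - m[i, "h"] / 2,
                m[i, "cy"] + m[i, "h"] / 2, m[i, "cy"] + m[i, "h"] / 2)) * H - H / 2
      # forward map of the corners
      xr <- cos(th) * xs_ + sin(th) * ys_ + W / 2
      yr <- -sin(th) * xs_ + cos(th) * ys_ + H / 2
      m[i, "cx"] <- (min(xr) + max(xr)) / 2 / W
      m[i, "cy"] <- (min(yr) + max(yr)) / 2 / H
      m[i, "w"] <- (max(xr) - min(xr)) / W
      m[i, "h"] <- (max(yr) - min(yr)) / H
    }
    m <- clip_boxes_norm(m, ref_area = ref_area)
  }
  annotated_image(px, matrix_as_boxes(m), img$source_id)
}

gaussian_kernel_brush <- function(sigma, max_side) {
  size <- min(2 * ceiling(3 * sigma) + 1, max_side - (1 - max_side %% 2))
  size <- max(size, 3)
  if (size %% 2 == 0) size <- size - 1
  EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
}

#' Corrupt an image with Gaussian blur and additive Gaussian noise
#'
#' Boxes are untouched; pixel values are clipped back to `[0, 255]`.
#'
#' @param img an [annotated_image()].
#' @param blur_sigma blur standard deviation in pixels (0 = none).
#' @param noise_sigma additive noise standard deviation in intensity units
#'   (0 = none).
#' @param rng_seed integer seed; the output is a pure function of
#'   (inputs, seed).
#' @return the corrupted [annotated_image()].
#' @export
gaussian_corrupt <- function(img, blur_sigma = 0, noise_sigma = 0, rng_seed = 0L) {
  stopifnot(blur_sigma >= 0, noise_sigma >= 0)
  px <- img$pixels
  d <- dim(px)
  if (blur_sigma > 0) {
    k <- gaussian_kernel_brush(blur_sigma, min(d[1], d[2]))
    ei <- EBImage::Image(aperm(px / 255, c(2, 1, 3)), colormode = "Color")
    ei <- EBImage::filter2(ei, k, boundary = "replicate")
    px <- aperm(as.array(ei), c(2, 1, 3)) * 255
  }
  if (noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(rng_seed %% 2147483647)
    px <- px + array(stats::rnorm(length(px), 0, noise_sigma), dim = d)
  }
  annotated_image(pmin(pmax(px, 0), 255), img$boxes, img$source_id)
}

#' Configuration of object-level image fusion
#'
#' @param n_patches_range inclusive integer range of object crops pasted per
#'   host image (within 2..4).
#' @param max_iou_with_main largest admissible IoU between a pasted crop and
#'   any host ground-truth box (the host's "main information"), and between
#'   pasted crops.
#' @param patch_scale_range pasted crop size as a fraction of the host side
#'   (within (0, 0.5]).
#' @param max_attempts placement draws per patch before it is skipped.
#' @return a `fusion_config`.
#' @export
fusion_config <- function(n_patches_range = c(2L, 4L),
                          max_iou_with_main = 0.1,
                          patch_scale_range = c(0.1, 0.3),
                          max_attempts = 50L) {
  stopifnot(length(n_patches_range) == 2,
            n_patches_range[1] >= 2, n_patches_range[2] <= 4,
            n_patches_range[1] <= n_patches_range[2],
            max_iou_with_main >= 0, max_iou_with_main < 1,
            patch_scale_range[1] > 0, patch_scale_range[2] <= 0.5,
            patch_scale_range[1] <= patch_scale_range[2])
  structure(list(n_patches_range = as.integer(n_patches_range),
                 max_iou_with_main = max_iou_with_main,
                 patch_scale_range = patch_scale_range,
                 max_attempts = as.integer(max_attempts)),
            class = "fusion_config")
}

#' Paste annotated object crops from donor images into a host image
#'
#' Cuts 2-4 ground-truth object crops out of donor images, rescales each to
#' a fraction of the host side, and pastes it at a random location whose IoU
#' with every host box and every previously pasted crop stays at or below
#' the configured ceiling. Crops for which no admissible location is found
#' within the attempt budget are skipped; the shortfall is recorded in the
#' `"fusion_shortfall"` attribute.
#'
#' @param host an [annotated_image()] (raster at least 64 x 64).
#' @param donors list of [annotated_image()]s, each with at least one box.
#' @param cfg a [fusion_config()].
#' @param rng_seed integer seed.
#' @return the fused [annotated_image()]; its box list is the host boxes
#'   followed by the pasted boxes.
#' @export
fuse_images <- function(host, donors, cfg = fusion_config(), rng_seed = 0L) {
  if (!length(donors)) stop("fuse_images: donors must be a non-empty list")
  hasbox <- vapply(donors, function(d) length(d$boxes) > 0, logical(1))
  if (any(!hasbox)) {
    warning(sum(!hasbox), " donor image(s) without boxes skipped")
    donors <- donors[hasbox]
  }
  if (!length(donors)) stop("fuse_images: no donor has any annotated object")
  d <- dim(host$pixels)
  stopifnot(d[1] >= 64, d[2] >= 64)
  H <- d[1]; W <- d[2]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed %% 2147483647)

  k <- sample(seq(cfg$n_patches_range[1], cfg$n_patches_range[2]), 1)
  px <- host$pixels
  host_corners <- boxes_to_corners(host$boxes, W, H)
  placed <- host_corners[, 1:4, drop = FALSE]
  n_host <- nrow(placed)
  new_boxes <- list()
  shortfall <- 0L
  for (p in seq_len(k)) {
    don <- donors[[sample(length(donors), 1)]]
    dd <- dim(don$pixels)
    bc <- boxes_to_corners(don$boxes, dd[2], dd[1])
    bi <- sample(nrow(bc), 1)
    x1 <- max(floor(bc[bi, "x1"]) + 1, 1); x2 <- min(ceiling(bc[bi, "x2"]), dd[2])
    y1 <- max(floor(bc[bi, "y1"]) + 1, 1); y2 <- min(ceiling(bc[bi, "y2"]), dd[1])
    if (x2 - x1 < 2 || y2 - y1 < 2) { shortfall <- shortfall + 1L; next }
    crop <- don$pixels[y1:y2, x1:x2, , drop = FALSE]
    scale <- stats::runif(1, cfg$patch_scale_range[1], cfg$patch_scale_range[2])
    long <- max(dim(crop)[1:2])
    f <- scale * min(H, W) / long
    ph <- max(round(dim(crop)[1] * f), 4)
    pw <- max(round(dim(crop)[2] * f), 4)
    patch <- resize_raster(crop, ph, pw)
    ok <- FALSE
    for (a in seq_len(cfg$max_attempts)) {
      ox <- sample.int(W - pw + 1, 1) - 1
      oy <- sample.int(H - ph + 1, 1) - 1
      cand <- matrix(c(ox, oy, ox + pw, oy + ph), 1)
      if (nrow(placed) == 0 || all(box_iou(cand, placed) <= cfg$max_iou_with_main)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) { shortfall <- shortfall + 1L; next }
    px[oy + seq_len(ph), ox + seq_len(pw), ] <- patch
    placed <- rbind(placed, cand)
    new_boxes[[length(new_boxes) + 1]] <- bounding_box(
      bc[bi, "class_id"],
      cx = (ox + pw / 2) / W, cy = (oy + ph / 2) / H,
      w = pw / W, h = ph / H)
  }
  out <- annotated_image(px, c(host$boxes, new_boxes), host$source_id)
  attr(out, "fusion_shortfall") <- shortfall
  out
}

#' Stitch four images into one mosaic canvas
#'
#' A random interior split point divides the square canvas into four
#' quadrants; each source image is rescaled into its quadrant and the boxes
#' remapped, clipped and filtered by the visibility floor.
#'
#' @param imgs list of exactly four [annotated_image()]s.
#' @param out_side output side in pixels, divisible by 32.
#' @param rng_seed integer seed.
#' @return the mosaic [annotated_image()].
#' @export
mosaic4 <- function(imgs, out_side, rng_seed = 0L) {
  if (length(imgs) != 4) stop("mosaic4 requires exactly 4 images, got ", length(imgs))
  stopifnot(out_side %% 32 == 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed %% 2147483647)
  sx <- round(stats::runif(1, 0.25, 0.75) * out_side)
  sy <- round(stats::runif(1, 0.25, 0.75) * out_side)
  quads <- list(c(0, 0, sx, sy), c(sx, 0, out_side - sx, sy),
                c(0, sy, sx, out_side - sy), c(sx, sy, out_side - sx, out_side - sy))
  px <- array(114, dim = c(out_side, out_side, 3))
  boxes <- list()
  for (q in 1:4) {
    ox <- quads[[q]][1]; oy <- quads[[q]][2]
    qw <- quads[[q]][3]; qh <- quads[[q]][4]
    img <- imgs[[q]]
    px[oy + seq_len(qh), ox + seq_len(qw), ] <- resize_raster(img$pixels, qh, qw)
    m <- boxes_as_matrix(img$boxes)
    if (nrow(m)) {
      m[, "cx"] <- (ox + m[, "cx"] * qw) / out_side
      m[, "cy"] <- (oy + m[, "cy"] * qh) / out_side
      m[, "w"] <- m[, "w"] * qw / out_side
      m[, "h"] <- m[, "h"] * qh / out_side
      m <- clip_boxes_norm(m)
      boxes <- c(boxes, matrix_as_boxes(m))
    }
  }
  annotated_image(px, boxes,
                  paste0("mosaic_", paste(vapply(imgs, function(i) i$source_id,
                                                 character(1)), collapse = "+")))
}

#' Expand a dataset with per-method augmented copies
#'
#' Returns the originals plus derived copies per method, each tagged with
#' provenance in `source_id`. Multipliers may be fractional: each image
#' receives `floor(m)` copies plus one more with probability `m - floor(m)`.
#'
#' @param images list of [annotated_image()]s.
#' @param multipliers named list/vector with entries `rotation`, `gaussian`,
#'   `fusion` (copies per original; default 1 each).
#' @param rng_seed integer seed; the output (including the `source_id`
#'   multiset) is deterministic given the seed.
#' @param fusion_cfg a [fusion_config()] for the fusion copies.
#' @return list of [annotated_image()]s (originals first).
#' @export
expand_dataset <- function(images, multipliers = c(rotation = 1, gaussian = 1, fusion = 1),
                           rng_seed = 0L, fusion_cfg = fusion_config()) {
  stopifnot(length(images) >= 1)
  multipliers <- as.list(multipliers)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed %% 2147483647)
  n_copies <- function(m) if (is.null(m)) 0L else floor(m) + (stats::runif(1) < m - floor(m))
  out <- images
  withbox <- which(vapply(images, function(i) length(i$boxes) > 0, logical(1)))
  for (i in seq_along(images)) {
    img <- images[[i]]
    for (r in seq_len(n_copies(multipliers$rotation))) {
      ang <- stats::runif(1, -35, 35)
      cp <- rotate_with_boxes(img, ang)
      cp$source_id <- sprintf("%s_rot%d", img$source_id, r)
      out[[length(out) + 1]] <- cp
    }
    for (g in seq_len(n_copies(multipliers$gaussian))) {
      cp <- gaussian_corrupt(img, blur_sigma = stats::runif(1, 0.6, 1.6),
                             noise_sigma = stats::runif(1, 4, 12),
                             rng_seed = sample.int(2147483646, 1))
      cp$source_id <- sprintf("%s_gauss%d", img$source_id, g)
      out[[length(out) + 1]] <- cp
    }
    for (f in seq_len(n_copies(multipliers$fusion))) {
      dons <- setdiff(withbox, i)
      if (!length(dons)) next
      donors <- images[sample(dons, min(3, length(dons)))]
      cp <- fuse_images(img, donors, fusion_cfg, rng_seed = sample.int(2147483646, 1))
      cp$source_id <- sprintf("%s_fuse%d", img$source_id, f)
      out[[length(out) + 1]] <- cp
    }
  }
  out
}
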