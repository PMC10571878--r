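# ---------------------------------------------------------------------------
# Box geometry. Two conventions are used in the package and conversion is
# centralised here:
#   * annotations: normalized center format (cx, cy, w, h), fractions of the
#     image width/height — the YOLO label-file convention;
#   * internal geometry (IoU, losses, NMS, mAP): pixel corner format
#     (x1, y1, x2, y2), half-open intervals so width = x2 - x1 exactly.
# ---------------------------------------------------------------------------

#' Construct a bounding box in normalized center format
#'
#' @param class_id zero-based integer index into the label list.
#' @param cx,cy box center as fractions of image width / height.
#' @param w,h box extent as fractions of image width / height.
#' @return a `bounding_box` (named list).
#' @export
bounding_box <- function(class_id, cx, cy, w, h) {
  stopifnot(class_id >= 0, w > 0, h > 0)
  structure(list(class_id = as.integer(unname(class_id)),
                 cx = as.numeric(unname(cx)), cy = as.numeric(unname(cy)),
                 w = as.numeric(unname(w)), h = as.numeric(unname(h))),
            class = "bounding_box")
}

#' Convert normalized center boxes to pixel corners
#'
#' @param boxes list of [bounding_box()]s or a matrix with columns cx,cy,w,h.
#' @param width,height image size in pixels.
#' @return matrix with columns x1, y1, x2, y2 (and class_id when available).
#' @export
boxes_to_corners <- function(boxes, width, height) {
  m <- boxes_as_matrix(boxes)
  if (nrow(m) == 0) {
    return(matrix(numeric(0), 0, 5,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2", "class_id"))))
  }
  out <- cbind(x1 = (m[, "cx"] - m[, "w"] / 2) * width,
               y1 = (m[, "cy"] - m[, "h"] / 2) * height,
               x2 = (m[, "cx"] + m[, "w"] / 2) * width,
               y2 = (m[, "cy"] + m[, "h"] / 2) * height,
               class_id = m[, "class_id"])
  out
}

#' Convert pixel corner boxes to normalized center format
#' @param corners matrix with columns x1,y1,x2,y2 (class_id optional).
#' @param width,height image size in pixels.
#' @return list of [bounding_box()]s.
#' @export
corners_to_boxes <- function(corners, width, height) {
  if (is.null(dim(corners))) corners <- matrix(corners, nrow = 1)
  n <- nrow(corners)
  out <- vector("list", n)
  cls <- if ("class_id" %in% colnames(corners)) corners[, "class_id"] else rep(0, n)
  for (i in seq_len(n)) {
    out[[i]] <- bounding_box(
      class_id = cls[i],
      cx = (corners[i, 1] + corners[i, 3]) / 2 / width,
      cy = (corners[i, 2] + corners[i, 4]) / 2 / height,
      w = (corners[i, 3] - corners[i, 1]) / width,
      h = (corners[i, 4] - corners[i, 2]) / height)
  }
  out
}

# Normalize a list of bounding_box (or matrix) into an n x 5 matrix
# cx, cy, w, h, class_id.
boxes_as_matrix <- function(boxes) {
  if (is.matrix(boxes)) {
    if (is.null(colnames(boxes))) {
      colnames(boxes) <- c("cx", "cy", "w", "h", "class_id")[seq_len(ncol(boxes))]
    }
    if (!"class_id" %in% colnames(boxes)) boxes <- cbind(boxes, class_id = 0)
    return(boxes[, c("cx", "cy", "w", "h", "class_id"), drop = FALSE])
  }
  if (length(boxes) == 0) {
    return(matrix(numeric(0), 0, 5,
                  dimnames = list(NULL, c("cx", "cy", "w", "h", "class_id"))))
  }
  do.call(rbind, lapply(boxes, function(b) {
    c(cx = b$cx, cy = b$cy, w = b$w, h = b$h, class_id = b$class_id)
  }))
}

matrix_as_boxes <- function(m) {
  if (nrow(m) == 0) return(list())
  lapply(seq_len(nrow(m)), function(i) {
    bounding_box(m[i, "class_id"], m[i, "cx"], m[i, "cy"], m[i, "w"], m[i, "h"])
  })
}

# Clip normalized center boxes to the unit square; drop boxes whose clipped
# area falls below `min_frac` of the pre-clip area (degenerate slivers).
clip_boxes_norm <- function(m, min_frac = 0.2, ref_area = NULL) {
  if (nrow(m) == 0) return(m)
  x1 <- pmax(m[, "cx"] - m[, "w"] / 2, 0)
  y1 <- pmax(m[, "cy"] - m[, "h"] / 2, 0)
  x2 <- pmin(m[, "cx"] + m[, "w"] / 2, 1)
  y2 <- pmin(m[, "cy"] + m[, "h"] / 2, 1)
  w <- pmax(x2 - x1, 0)
  h <- pmax(y2 - y1, 0)
  area0 <- if (is.null(ref_area)) m[, "w"] * m[, "h"] else ref_area
  keep <- w * h >= min_frac * area0 & w > 1e-6 & h > 1e-6
  out <- cbind(cx = (x1 + x2) / 2, cy = (y1 + y2) / 2, w = w, h = h,
               class_id = m[, "class_id"])
  out[keep, , drop = FALSE]
}

#' Pairwise intersection-over-union of corner boxes
#'
#' @param a,b matrices with columns x1, y1, x2, y2.
#' @return `nrow(a)` x `nrow(b)` IoU matrix.
#' @export
box_iou <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(numeric(0), na, nb))
  ix1 <- pmax(matrix(a[, 1], na, nb), matrix(b[, 1], na, nb, byrow = TRUE))
  iy1 <- pmax(matrix(a[, 2], na, nb), matrix(b[, 2], na, nb, byrow = TRUE))
  ix2 <- pmin(matrix(a[, 3], na, nb), matrix(b[, 3], na, nb, byrow = TRUE))
  iy2 <- pmin(matrix(a[, 4], na, nb), matrix(b[, 4], na, nb, byrow = TRUE))
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  aa <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  un <- matrix(aa, na, nb) + matrix(ab, na, nb, byrow = TRUE) - inter
  iou <- inter / un
  iou[un <= 0] <- 0
  iou
}

#' Construct an annotated image
#'
#' @param pixels H x W x 3 numeric array with 8-bit channel values in
#'   `[0, 255]` (RGB order).
#' @param boxes list of [bounding_box()]s (possibly empty).
#' @param source_id identifier string carried through transforms.
#' @return an `annotated_image`.
#' @export
annotated_image <- function(pixels, boxes = list(), source_id = "") {
  d <- dim(pixels)
  stopifnot(length(d) == 3, d[3] == 3, d[1] >= 32, d[2] >= 32)
  structure(list(pixels = pixels, boxes = boxes, source_id = source_id),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<annotated_image %s: %dx%d px, %d box(es)>\n",
              x$source_id, d[2], d[1], length(x$boxes)))
  invisible(x)
}
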