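# ---------------------------------------------------------------------------
# Dataset input/output. Annotations are read and written in the two formats
# produced by common labelling tools: YOLO txt (one file per image, lines
# "class cx cy w h", normalized center format) and Pascal-VOC XML (1-based
# inclusive pixel corners). Rasters are stored as PNG. All coordinate
# conventions and the letterbox resize live here.
# ---------------------------------------------------------------------------

#' Read an RGB image file as an (H, W, 3) array in `[0, 255]`
#' @param path PNG or JPEG file path.
#' @return numeric array, RGB channel order.
#' @export
read_image <- function(path) {
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    aperm(as.array(EBImage::readImage(path)), c(2, 1, 3))
  }
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]
  px * 255
}

#' Write an (H, W, 3) array in `[0, 255]` as PNG
#' @param pixels raster array.
#' @param path destination path.
#' @export
write_image <- function(pixels, path) {
  png::writePNG(pmin(pmax(pixels / 255, 0), 1), path)
  invisible(path)
}

parse_yolo_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  boxes <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 5 || anyNA(vals[1:5])) {
      stop("malformed annotation line ", i, " in ", path, ": '", lines[i], "'")
    }
    boxes[[i]] <- bounding_box(vals[1], vals[2], vals[3], vals[4], vals[5])
  }
  boxes
}

format_yolo_txt <- function(boxes) {
  m <- boxes_as_matrix(boxes)
  if (nrow(m) == 0) return(character(0))
  sprintf("%d %.6f %.6f %.6f %.6f",
          as.integer(m[, "class_id"]), m[, "cx"], m[, "cy"], m[, "w"], m[, "h"])
}

parse_voc_xml <- function(path, class_names) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e)))
  W <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/width")))
  H <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/height")))
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- list()
  for (o in objs) {
    nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    cid <- match(nm, class_names) - 1L
    if (is.na(cid)) stop("class label '", nm, "' in ", path,
                         " absent from the configured label list")
    bb <- xml2::xml_find_first(o, "./bndbox")
    g <- function(tag) as.numeric(xml2::xml_text(xml2::xml_find_first(bb, paste0("./", tag))))
    xmin <- g("xmin"); ymin <- g("ymin"); xmax <- g("xmax"); ymax <- g("ymax")
    if (anyNA(c(xmin, ymin, xmax, ymax))) stop("malformed bndbox in ", path)
    # 1-based inclusive pixel corners -> half-open corners -> normalized center
    boxes[[length(boxes) + 1]] <- bounding_box(
      cid,
      cx = ((xmin - 1) + xmax) / 2 / W,
      cy = ((ymin - 1) + ymax) / 2 / H,
      w = (xmax - xmin + 1) / W,
      h = (ymax - ymin + 1) / H)
  }
  boxes
}

format_voc_xml <- function(img, class_names) {
  d <- dim(img$pixels)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", paste0(img$source_id, ".png"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(d[2]))
  xml2::xml_add_child(size, "height", as.character(d[1]))
  xml2::xml_add_child(size, "depth", "3")
  m <- boxes_as_matrix(img$boxes)
  corners <- boxes_to_corners(img$boxes, d[2], d[1])
  for (i in seq_len(nrow(m))) {
    o <- xml2::xml_add_child(doc, "object")
    cid <- as.integer(m[i, "class_id"])
    nm <- if (cid + 1 <= length(class_names)) class_names[cid + 1] else as.character(cid)
    xml2::xml_add_child(o, "name", nm)
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", sprintf("%.0f", corners[i, "x1"] + 1))
    xml2::xml_add_child(bb, "ymin", sprintf("%.0f", corners[i, "y1"] + 1))
    xml2::xml_add_child(bb, "xmax", sprintf("%.0f", corners[i, "x2"]))
    xml2::xml_add_child(bb, "ymax", sprintf("%.0f", corners[i, "y2"]))
  }
  doc
}

dataset_dirs <- function(root) {
  img_dir <- file.path(root, "images")
  lab_dir <- file.path(root, "labels")
  if (dir.exists(img_dir)) list(images = img_dir,
                                labels = if (dir.exists(lab_dir)) lab_dir else img_dir)
  else list(images = root, labels = root)
}

#' Read a detection dataset from disk
#'
#' Accepts either a flat directory of images with side-by-side annotation
#' files, or the conventional `images/` + `labels/` layout. Images without
#' an annotation file yield empty box lists (background-only images).
#'
#' @param root dataset directory.
#' @param format `"yolo_txt"` or `"voc_xml"`.
#' @param class_names character vector of class labels (required for VOC;
#'   used for bounds checking with YOLO).
#' @return list of [annotated_image()]s, sorted by file name.
#' @export
read_dataset <- function(root, format = c("yolo_txt", "voc_xml"), class_names = NULL) {
  format <- match.arg(format)
  dirs <- dataset_dirs(root)
  files <- sort(list.files(dirs$images, pattern = "\\.(png|jpe?g)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (!length(files)) stop("no PNG/JPEG images found under ", root)
  ext <- if (format == "yolo_txt") ".txt" else ".xml"
  out <- vector("list", length(files))
  for (i in seq_along(files)) {
    stem <- tools::file_path_sans_ext(basename(files[i]))
    px <- read_image(files[i])
    ann <- file.path(dirs$labels, paste0(stem, ext))
    boxes <- if (!file.exists(ann)) list()
    else if (format == "yolo_txt") parse_yolo_txt(ann)
    else parse_voc_xml(ann, class_names)
    if (!is.null(class_names)) {
      for (b in boxes) {
        if (b$class_id >= length(class_names)) {
          stop("class id ", b$class_id, " in ", ann,
               " exceeds the configured label list (", length(class_names), " classes)")
        }
      }
    }
    out[[i]] <- annotated_image(px, boxes, source_id = stem)
  }
  out
}

#' Write a detection dataset to disk
#'
#' Uses the `images/` + `labels/` layout; annotation files are written even
#' when empty so background-only images round-trip.
#'
#' @param images list of [annotated_image()]s.
#' @param root destination directory (created if needed).
#' @param format `"yolo_txt"` or `"voc_xml"`.
#' @param class_names labels used for VOC `<name>` entries.
#' @export
write_dataset <- function(images, root, format = c("yolo_txt", "voc_xml"),
                          class_names = NULL) {
  format <- match.arg(format)
  img_dir <- file.path(root, "images")
  lab_dir <- file.path(root, "labels")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(images)) {
    img <- images[[i]]
    stem <- if (nzchar(img$source_id)) img$source_id else sprintf("img_%05d", i)
    write_image(img$pixels, file.path(img_dir, paste0(stem, ".png")))
    if (format == "yolo_txt") {
      writeLines(format_yolo_txt(img$boxes), file.path(lab_dir, paste0(stem, ".txt")))
    } else {
      xml2::write_xml(format_voc_xml(img, class_names),
                      file.path(lab_dir, paste0(stem, ".xml")))
    }
  }
  invisible(root)
}

#' Read / write the dataset config file
#'
#' YAML with `names:` (class labels), `train:` and `val:` dataset paths.
#' @param path YAML file.
#' @return named list.
#' @export
read_dataset_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$names)) stop("dataset config ", path, " lacks a `names:` entry")
  cfg$names <- as.character(unlist(cfg$names))
  cfg
}

#' @rdname read_dataset_config
#' @param cfg named list with at least `names`.
#' @export
write_dataset_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# --- letterbox --------------------------------------------------------------

resize_raster <- function(pixels, out_h, out_w) {
  img <- EBImage::Image(aperm(pixels / 255, c(2, 1, 3)), colormode = "Color")
  r <- EBImage::resize(img, w = out_w, h = out_h)
  # the resampling filter can overshoot slightly at sharp edges
  pmin(pmax(aperm(as.array(r), c(2, 1, 3)) * 255, 0), 255)
}

#' Aspect-preserving resize with constant-colour padding
#'
#' Scales the image uniformly so the longer side matches `target`, then pads
#' the shorter side symmetrically with a constant colour to reach a square
#' `target` x `target` raster. Boxes are remapped through the transform,
#' which is returned so detections can be mapped back.
#'
#' @param img an [annotated_image()].
#' @param target output side in pixels, divisible by 32.
#' @param pad_value padding intensity (default the conventional mid-gray 114).
#' @return list with `image` (letterboxed [annotated_image()]) and
#'   `transform` (a `letterbox_transform`).
#' @export
letterbox <- function(img, target, pad_value = 114) {
  stopifnot(target >= 32, target %% 32 == 0)
  d <- dim(img$pixels)
  H <- d[1]; W <- d[2]
  scale <- min(target / W, target / H)
  new_w <- round(W * scale)
  new_h <- round(H * scale)
  pad_left <- (target - new_w) %/% 2
  pad_top <- (target - new_h) %/% 2
  content <- if (new_h == H && new_w == W) img$pixels
  else resize_raster(img$pixels, new_h, new_w)
  out <- array(pad_value, dim = c(target, target, 3))
  out[pad_top + seq_len(new_h), pad_left + seq_len(new_w), ] <- content
  tf <- structure(list(scale = scale, pad_left = pad_left, pad_top = pad_top,
                       out_h = target, out_w = target, src_h = H, src_w = W),
                  class = "letterbox_transform")
  m <- boxes_as_matrix(img$boxes)
  if (nrow(m) > 0) {
    m[, "cx"] <- (m[, "cx"] * W * scale + pad_left) / target
    m[, "cy"] <- (m[, "cy"] * H * scale + pad_top) / target
    m[, "w"] <- m[, "w"] * W * scale / target
    m[, "h"] <- m[, "h"] * H * scale / target
    m <- clip_boxes_norm(m)
  }
  list(image = annotated_image(out, matrix_as_boxes(m), img$source_id),
       transform = tf)
}

#' Invert a letterbox transform on normalized boxes
#'
#' @param boxes list of [bounding_box()]s in the letterboxed frame.
#' @param tf a `letterbox_transform` from [letterbox()].
#' @return boxes in the source-image normalized frame.
#' @export
letterbox_invert_boxes <- function(boxes, tf) {
  m <- boxes_as_matrix(boxes)
  if (nrow(m) == 0) return(list())
  m[, "cx"] <- (m[, "cx"] * tf$out_w - tf$pad_left) / tf$scale / tf$src_w
  m[, "cy"] <- (m[, "cy"] * tf$out_h - tf$pad_top) / tf$scale / tf$src_h
  m[, "w"] <- m[, "w"] * tf$out_w / tf$scale / tf$src_w
  m[, "h"] <- m[, "h"] * tf$out_h / tf$scale / tf$src_h
  matrix_as_boxes(m)
}

# Map pixel-corner detections from the letterboxed frame back to source
# pixels, clipping to the source raster.
letterbox_invert_dets <- function(dets, tf, src_img) {
  if (nrow(dets) == 0) return(dets)
  dets$x1 <- pmin(pmax((dets$x1 - tf$pad_left) / tf$scale, 0), tf$src_w)
  dets$x2 <- pmin(pmax((dets$x2 - tf$pad_left) / tf$scale, 0), tf$src_w)
  dets$y1 <- pmin(pmax((dets$y1 - tf$pad_top) / tf$scale, 0), tf$src_h)
  dets$y2 <- pmin(pmax((dets$y2 - tf$pad_top) / tf$scale, 0), tf$src_h)
  dets[dets$x2 > dets$x1 & dets$y2 > dets$y1, , drop = FALSE]
}
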