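# ---------------------------------------------------------------------------
# Training loop: mosaic-augmented batches, composite DIoU + objectness +
# class-suppression loss, Adam updates with a short linear warmup, per-epoch
# validation mAP@0.5 and best-checkpoint tracking.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the conventional one-stage-detector recipe: learning
#' rate 0.01, Adam, batch size 8, 200 epochs, 640-px inputs.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size images per gradient step.
#' @param epochs training epochs (>= 1).
#' @param input_side network input side in pixels, divisible by 32.
#' @param seed root seed controlling shuffling and augmentation.
#' @param mosaic_prob probability that a drawn image enters the batch as a
#'   four-image mosaic.
#' @param warmup_epochs epochs of linear learning-rate warmup.
#' @param lr_final final learning rate as a fraction of the initial one
#'   (cosine decay across the configured epochs; 1 = constant).
#' @param grad_clip global gradient-norm ceiling (0 disables).
#' @param use_ema keep an exponential moving average of the weights and use
#'   it for validation and checkpoints (stabilises the evaluated model).
#' @param repeat_thresh repeat-factor sampling threshold `t`: images
#'   containing a class present in fewer than a fraction `t` of images are
#'   repeated within each epoch by `sqrt(t / f_c)` (the standard long-tail
#'   oversampling rule); 0 disables.
#' @param val_every validate every so-many epochs (always on the last).
#' @param early_stop_map stop once validation mAP reaches this value
#'   (`NULL` / `Inf` disables).
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 0.01,
                         batch_size = 8L,
                         epochs = 200L,
                         input_side = 640L,
                         seed = 0L,
                         mosaic_prob = 0.5,
                         warmup_epochs = 1,
                         lr_final = 0.1,
                         grad_clip = 10,
                         use_ema = TRUE,
                         repeat_thresh = 0.5,
                         val_every = 1L,
                         early_stop_map = NULL) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            input_side %% 32 == 0, mosaic_prob >= 0, mosaic_prob <= 1,
            lr_final > 0, lr_final <= 1)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), input_side = as.integer(input_side),
                 seed = as.integer(seed), mosaic_prob = mosaic_prob,
                 warmup_epochs = warmup_epochs, lr_final = lr_final,
                 grad_clip = grad_clip, use_ema = isTRUE(use_ema),
                 repeat_thresh = repeat_thresh,
                 val_every = as.integer(val_every),
                 early_stop_map = early_stop_map),
            class = "train_config")
}

# Repeat factors for class-balanced sampling: image i is drawn
# ceil/floor(r_i) times per epoch with r_i = max over its classes of
# sqrt(t / f_c), f_c the fraction of images containing class c.
repeat_factors <- function(images, t) {
  cls_per_img <- lapply(images, function(img) {
    unique(vapply(img$boxes, function(b) b$class_id, integer(1)))
  })
  all_cls <- sort(unique(unlist(cls_per_img)))
  if (!length(all_cls) || t <= 0) return(rep(1, length(images)))
  f <- vapply(all_cls, function(cl) {
    mean(vapply(cls_per_img, function(s) cl %in% s, logical(1)))
  }, numeric(1))
  r_cls <- pmax(1, sqrt(t / f))
  vapply(cls_per_img, function(s) {
    if (!length(s)) 1 else max(r_cls[match(s, all_cls)])
  }, numeric(1))
}

clip_gradients <- function(params, max_norm) {
  if (max_norm <= 0) return(invisible())
  tot <- 0
  for (p in params) if (!is.null(p$grad)) tot <- tot + sum(p$grad^2)
  tot <- sqrt(tot)
  if (tot > max_norm) {
    sc <- max_norm / (tot + 1e-12)
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * sc
  }
  invisible(tot)
}

prepare_batch <- function(images, side) {
  nb <- length(images)
  x <- array(0, dim = c(side, side, 3, nb))
  boxes <- vector("list", nb)
  for (i in seq_len(nb)) {
    lb <- letterbox(images[[i]], side)
    x[, , , i] <- lb$image$pixels
    boxes[[i]] <- boxes_as_matrix(lb$image$boxes)
  }
  list(x = x, boxes = boxes)
}

#' Evaluate a model on annotated images
#'
#' Runs the full inference path (letterbox, forward, decode at the low
#' confidence floor, NMS, inverse letterbox) and scores detections against
#' the images' ground truth.
#'
#' @param model a built (trained) model.
#' @param images list of [annotated_image()]s with ground truth.
#' @param max_dets cap on detections per image (by confidence).
#' @return an `eval_report` (see [evaluate_detections()]).
#' @export
evaluate_model <- function(model, images, max_dets = 300L) {
  cfg <- model$cfg
  dets_list <- vector("list", length(images))
  gts_list <- vector("list", length(images))
  bs <- 8L
  i <- 1L
  while (i <= length(images)) {
    idx <- i:min(i + bs - 1L, length(images))
    lbs <- lapply(images[idx], letterbox, target = cfg$input_side)
    x <- array(0, dim = c(cfg$input_side, cfg$input_side, 3, length(idx)))
    for (j in seq_along(idx)) x[, , , j] <- lbs[[j]]$image$pixels
    heads <- forward_detector(model, x, train = FALSE)
    dec <- decode_heads(heads, cfg)
    for (j in seq_along(idx)) {
      d <- nms(dec[[j]], cfg$nms_iou)
      if (nrow(d) > max_dets) d <- d[seq_len(max_dets), , drop = FALSE]
      dets_list[[idx[j]]] <- letterbox_invert_dets(d, lbs[[j]]$transform,
                                                   images[[idx[j]]])
      gts_list[[idx[j]]] <- gt_corners(images[[idx[j]]])
    }
    i <- i + bs
  }
  evaluate_detections(dets_list, gts_list, cfg$num_classes)
}

#' Train the detector
#'
#' @param train_images,val_images lists of [annotated_image()]s.
#' @param model_cfg a [model_config()] (its `input_side` should match the
#'   training config).
#' @param cfg a [train_config()].
#' @param model optionally a prebuilt/warm-started model to continue.
#' @param verbose print per-epoch progress lines.
#' @return list: `model` (final weights), `best_state` (parameters at the
#'   best validation mAP), `best_map`, `history` (per-epoch data frame with
#'   loss breakdown and validation mAP).
#' @export
train_detector <- function(train_images, val_images, model_cfg, cfg,
                           model = NULL, verbose = TRUE) {
  stopifnot(inherits(cfg, "train_config"))
  set.seed(cfg$seed)
  if (is.null(model)) model <- build_model(model_cfg)
  params <- nn_parameters(model)
  opt <- optim_adam(params, lr = cfg$learning_rate)
  n <- length(train_images)
  steps_per_epoch <- max(1L, ceiling(n / cfg$batch_size))
  warmup_steps <- max(1, round(cfg$warmup_epochs * steps_per_epoch))
  side <- model_cfg$input_side
  history <- data.frame()
  best_map <- -Inf
  best_state <- NULL
  step <- 0L
  ema <- if (cfg$use_ema) lapply(params, function(p) p$value) else NULL
  with_ema <- function(f) {
    if (is.null(ema)) return(f())
    saved <- lapply(params, function(p) p$value)
    for (i in seq_along(params)) params[[i]]$value <- ema[[i]]
    on.exit(for (i in seq_along(params)) params[[i]]$value <- saved[[i]])
    f()
  }

  rfac <- repeat_factors(train_images, cfg$repeat_thresh)

  # with mosaic disabled every batch is assembled from static images, so
  # letterboxing and target assignment can be done once per image
  static <- cfg$mosaic_prob == 0
  if (static) {
    prep_px <- vector("list", n)
    prep_tg <- vector("list", n)
    for (i in seq_len(n)) {
      lb <- letterbox(train_images[[i]], side)
      prep_px[[i]] <- lb$image$pixels
      prep_tg[[i]] <- assign_targets(list(boxes_as_matrix(lb$image$boxes)),
                                     model_cfg)
    }
  }

  for (epoch in seq_len(cfg$epochs)) {
    reps <- floor(rfac) + (stats::runif(n) < rfac - floor(rfac))
    pool <- rep(seq_len(n), reps)
    ord <- sample(pool)
    steps_per_epoch <- max(1L, ceiling(length(ord) / cfg$batch_size))
    ep_loss <- c(box = 0, obj = 0, cls = 0, total = 0)
    nbatch <- 0L
    for (b in seq_len(steps_per_epoch)) {
      take <- ord[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size, length(ord))]
      if (static) {
        nb <- length(take)
        x <- array(0, dim = c(side, side, 3, nb))
        for (j in seq_len(nb)) x[, , , j] <- prep_px[[take[j]]]
        targets <- lapply(1:3, function(s) {
          do.call(rbind, lapply(seq_len(nb), function(j) {
            df <- prep_tg[[take[j]]][[s]]
            if (nrow(df)) df$n <- j
            df
          }))
        })
        names(targets) <- c("p3", "p4", "p5")
        heads <- forward_detector(model, x, train = TRUE)
      } else {
        imgs <- lapply(take, function(i) {
          if (stats::runif(1) < cfg$mosaic_prob) {
            mosaic4(train_images[sample(n, 4, replace = n < 4)], side,
                    rng_seed = sample.int(2147483646, 1))
          } else {
            train_images[[i]]
          }
        })
        batch <- prepare_batch(imgs, side)
        heads <- forward_detector(model, batch$x, train = TRUE)
        targets <- assign_targets(batch$boxes, model_cfg)
      }
      loss <- composite_loss(heads, targets, model_cfg)
      ag_zero_grad(params)
      ag_backward(loss$total)
      clip_gradients(params, cfg$grad_clip)
      step <- step + 1L
      progress <- (epoch - 1) / max(1, cfg$epochs - 1)
      cosine <- cfg$lr_final + (1 - cfg$lr_final) * 0.5 * (1 + cos(pi * progress))
      lr_t <- cfg$learning_rate * cosine * min(1, step / warmup_steps)
      optim_step(opt, lr = lr_t)
      if (!is.null(ema)) {
        de <- 0.99 * (1 - exp(-step / 100))
        for (i in seq_along(params)) {
          ema[[i]] <- de * ema[[i]] + (1 - de) * params[[i]]$value
        }
      }
      ep_loss <- ep_loss + loss$breakdown
      nbatch <- nbatch + 1L
    }
    ep_loss <- ep_loss / nbatch
    vmap <- NA_real_
    if (epoch %% cfg$val_every == 0 || epoch == cfg$epochs) {
      vmap <- if (length(val_images)) {
        with_ema(function() evaluate_model(model, val_images)$map)
      } else NA_real_
      if (!is.na(vmap) && vmap > best_map) {
        best_map <- vmap
        best_state <- with_ema(function() model_state(model))
      }
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, box = ep_loss["box"],
                                obj = ep_loss["obj"], cls = ep_loss["cls"],
                                total = ep_loss["total"], val_map = vmap,
                                row.names = NULL))
    if (verbose) {
      message(sprintf("epoch %3d | loss %.4f (box %.4f obj %.4f cls %.4f) | val mAP %s",
                      epoch, ep_loss["total"], ep_loss["box"], ep_loss["obj"],
                      ep_loss["cls"],
                      ifelse(is.na(vmap), "-", sprintf("%.4f", vmap))))
    }
    if (!is.null(cfg$early_stop_map) && !is.na(vmap) &&
        vmap >= cfg$early_stop_map) break
  }
  list(model = model, best_state = best_state,
       best_map = if (is.finite(best_map)) best_map else NA_real_,
       history = history)
}

#' Restore the best-validation weights into a trained model
#' @param fit result of [train_detector()].
#' @return the model with the best checkpoint loaded (falls back to final
#'   weights when no validation was run).
#' @export
best_model <- function(fit) {
  if (!is.null(fit$best_state)) load_model_state(fit$model, fit$best_state)
  fit$model
}
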