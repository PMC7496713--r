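# The user-facing modelling interface: one fitting function returning a
# classed object with print / summary / predict / plot methods.

#' Fit a sticky-trap fly detector
#'
#' Trains the fully convolutional grid classifier on a set of annotated
#' trap scenes and returns the fitted detector. This is the high-level
#' entry point; [build_model()] and [train()] expose the pieces.
#'
#' @param train_set,val_set Lists of `trap_scene` objects (image +
#'   annotation), e.g. from [render_scene()] or [load_scene_dir()]. If
#'   `val_set` is `NULL`, one fifth of `train_set` (at least one scene) is
#'   held out for validation.
#' @param detector A [detector_config()].
#' @param control A [train_config()].
#' @param match_cfg A [match_config()] used for validation-time model
#'   selection (pooled-class AUC).
#' @param seed Master seed for weight initialisation and training.
#' @param verbose Print per-epoch progress.
#' @return An object of class `swd_detector` with components `model`
#'   (best-on-validation weights), `history`, `class_weights`,
#'   `best_epoch`, `detector`, `control` and `call`.
#' @examples
#' \donttest{
#' cfg <- scene_config(image_size = c(160, 160), n_dsm = 3, n_dsf = 3,
#'                     n_bc = 2, fly_area_mean = 120, cluster_prob = 0)
#' scenes <- lapply(1:8, function(i) {
#'   cfg$seed <- i
#'   render_scene(cfg, sprintf("scene_%02d", i))
#' })
#' fit <- swd_detector(scenes[1:6], scenes[7:8],
#'                     detector = detector_config("tiny"),
#'                     control = train_config(patches_per_image = 2,
#'                                            patch_size = 128,
#'                                            lr_phase1 = 1e-3,
#'                                            epochs_phase1 = 2,
#'                                            epochs_phase2 = 0,
#'                                            val_every = 2))
#' print(fit)
#' }
#' @export
swd_detector <- function(train_set, val_set = NULL,
                         detector = detector_config("tiny"),
                         control = train_config(),
                         match_cfg = match_config(), seed = 1L,
                         verbose = FALSE) {
  cl <- match.call()
  train_set <- lapply(train_set, scene_pair)
  if (is.null(val_set)) {
    n_val <- max(1L, length(train_set) %/% 5L)
    idx <- with_seed(seed, sample(seq_along(train_set), n_val))
    val_set <- train_set[idx]
    train_set <- train_set[-idx]
  }
  seeds <- derive_seeds(seed, 2L)
  model <- build_model(detector, seed = seeds[1])
  control$seed <- seeds[2]
  fit <- train(model, train_set, val_set, control, match_cfg,
               verbose = verbose)
  structure(list(model = fit$model, final_model = fit$final_model,
                 history = fit$history, class_weights = fit$class_weights,
                 best_epoch = fit$best_epoch,
                 best_val_auc = fit$best_val_auc,
                 detector = detector, control = control, call = cl),
            class = "swd_detector")
}

#' @export
print.swd_detector <- function(x, ...) {
  cat("Fully convolutional sticky-trap fly detector\n\n")
  cat("Call:\n  ")
  print(x$call)
  cat(sprintf("\nBackbone: %s (stride %d px), head %d channels\n",
              x$detector$backbone_depth, x$detector$stride,
              x$detector$head_hidden))
  cat(sprintf("Epochs trained: %d; selected epoch %d (validation AUC %.3f)\n",
              nrow(x$history), x$best_epoch, x$best_val_auc))
  cat(sprintf("Class weights (background, DSF, DSM): %s\n",
              paste(sprintf("%.2f", x$class_weights), collapse = ", ")))
  invisible(x)
}

#' @export
summary.swd_detector <- function(object, ...) {
  h <- object$history
  out <- list(
    epochs = nrow(h),
    best_epoch = object$best_epoch,
    best_val_auc = object$best_val_auc,
    final_train_loss = h$train_loss[nrow(h)],
    final_val_loss = h$val_loss[nrow(h)],
    class_weights = object$class_weights,
    history = h
  )
  class(out) <- "summary.swd_detector"
  out
}

#' @export
print.summary.swd_detector <- function(x, ...) {
  cat(sprintf("Training: %d epochs; final train loss %.4f, val loss %.4f\n",
              x$epochs, x$final_train_loss, x$final_val_loss))
  cat(sprintf("Model selection: epoch %d, validation AUC (both sexes) %.3f\n",
              x$best_epoch, x$best_val_auc))
  cat("Last epochs:\n")
  print(utils::tail(x$history, 5), row.names = FALSE)
  invisible(x)
}

#' Predict detections (or the raw probability grid) for new images
#'
#' @param object A fitted `swd_detector`.
#' @param newdata A `trap_scene`, a list of them, a single
#'   `height x width x 3` image array, or a path to a PNG.
#' @param type `"detections"` for NMS-filtered point detections,
#'   `"grid"` for the stitched probability grid(s).
#' @param floor_threshold Post-NMS confidence floor.
#' @param ... Unused.
#' @return A detection table, or a `prob_grid` / list of them.
#' @export
predict.swd_detector <- function(object, newdata,
                                 type = c("detections", "grid"),
                                 floor_threshold = object$detector$nms_floor,
                                 ...) {
  type <- match.arg(type)
  items <- normalise_newdata(newdata)
  out <- lapply(seq_along(items), function(i) {
    it <- items[[i]]
    if (type == "grid") {
      predict_image(object$model, it$image)
    } else {
      detect_image(object$model, it$image, image_id = it$id,
                   floor_threshold = floor_threshold)
    }
  })
  if (type == "detections") {
    do.call(rbind, out)
  } else if (length(out) == 1) {
    out[[1]]
  } else {
    out
  }
}

normalise_newdata <- function(newdata) {
  as_item <- function(x, i) {
    if (inherits(x, "trap_scene")) {
      list(image = x$image, id = x$annotation$image_id)
    } else if (is.character(x)) {
      list(image = read_image(x), id = tools::file_path_sans_ext(basename(x)))
    } else if (is.array(x) && length(dim(x)) == 3) {
      list(image = x, id = sprintf("image_%03d", i))
    } else {
      stopf("cannot interpret newdata element %d as an image", i)
    }
  }
  if (inherits(newdata, "trap_scene") ||
        (is.array(newdata) && length(dim(newdata)) == 3)) {
    list(as_item(newdata, 1L))
  } else if (is.character(newdata)) {
    lapply(seq_along(newdata), function(i) as_item(newdata[i], i))
  } else if (is.list(newdata)) {
    lapply(seq_along(newdata), function(i) as_item(newdata[[i]], i))
  } else {
    stopf("unsupported newdata type")
  }
}

#' Plot training history
#'
#' Training and validation loss per epoch (left axis) and the
#' intermittently computed validation AUC (right axis).
#'
#' @param x A fitted `swd_detector`.
#' @param ... Passed to `plot()`.
#' @export
plot.swd_detector <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  ylim <- range(c(h$train_loss, h$val_loss), finite = TRUE)
  plot(h$epoch, h$train_loss, type = "l", col = "steelblue",
       xlab = "Epoch", ylab = "Loss", ylim = ylim, ...)
  graphics::lines(h$epoch, h$val_loss, col = "firebrick")
  has_auc <- !is.na(h$val_auc)
  if (any(has_auc)) {
    graphics::par(new = TRUE)
    plot(h$epoch[has_auc], h$val_auc[has_auc], type = "b", pch = 16,
         col = "darkgreen", axes = FALSE, xlab = "", ylab = "",
         ylim = c(0, 1), xlim = range(h$epoch))
    graphics::axis(4)
    graphics::mtext("Validation AUC", side = 4, line = 2.5)
  }
  graphics::legend("topright",
                   legend = c("train loss", "val loss", "val AUC"),
                   col = c("steelblue", "firebrick", "darkgreen"),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Draw detections onto an image
#'
#' Marks each detection with a circle (yellow for DSF, blue for DSM) in a
#' copy of the image — the usual overlay product for visual inspection.
#'
#' @param image `height x width x 3` array.
#' @param dets A detection table for this image.
#' @param radius Circle radius in px.
#' @return The annotated image array.
#' @export
overlay_detections <- function(image, dets, radius = NULL) {
  H <- dim(image)[1]; W <- dim(image)[2]
  radius <- radius %||% max(3, round(min(H, W) / 40))
  cols <- list(DSF = c(1, 0.85, 0.1), DSM = c(0.2, 0.4, 1))
  for (i in seq_len(nrow(dets))) {
    th <- seq(0, 2 * pi, length.out = max(16, 4 * radius))
    for (rr in c(radius - 1, radius)) {
      px <- round(dets$x[i] + rr * cos(th))
      py <- round(dets$y[i] + rr * sin(th))
      ok <- px >= 0 & px < W & py >= 0 & py < H
      col <- cols[[dets$class[i]]]
      for (c in 1:3) {
        image[cbind(py[ok] + 1L, px[ok] + 1L, c)] <- col[c]
      }
    }
  }
  image
}
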