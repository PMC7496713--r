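# Patch sampling, target-grid construction, dihedral augmentation, the
# class-weighted cross-entropy loss and the two-phase Adam schedule.

#' Training configuration
#'
#' Defaults follow the full-scale recipe: 16 random 512-px patches per
#' full-sized training image per epoch, batches of four, Adam at 1e-5 for
#' the first 50 epochs then 1e-6 for the remaining 250. The tiny profile
#' (see [run_profile()]) shrinks all of this to CPU scale.
#'
#' @param patches_per_image Random patches drawn from each training image
#'   per epoch.
#' @param patch_size Patch side length in px.
#' @param batch_size Patches per optimiser step.
#' @param lr_phase1,epochs_phase1 Learning rate and length of phase 1.
#' @param lr_phase2,epochs_phase2 Learning rate and length of phase 2
#'   (must not exceed `lr_phase1`).
#' @param class_weights `"auto"` (inverse cell-frequency, clamped to
#'   \[1, 100\]) or a numeric length-3 vector (background, DSF, DSM).
#' @param val_every Validate with the full point-matching metric every
#'   this many epochs (model selection is by validation AUC, both classes
#'   pooled).
#' @param seed Master seed for patch sampling, augmentation and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(patches_per_image = 16L, patch_size = 512L,
                         batch_size = 4L,
                         lr_phase1 = 1e-5, epochs_phase1 = 50L,
                         lr_phase2 = 1e-6, epochs_phase2 = 250L,
                         class_weights = "auto", val_every = 10L,
                         seed = 1L) {
  if (patches_per_image < 1 || patch_size < 1 || batch_size < 1) {
    stopf("counts must be positive")
  }
  if (lr_phase1 <= 0 || lr_phase2 <= 0) stopf("learning rates must be > 0")
  if (lr_phase2 > lr_phase1) stopf("phase-2 lr must not exceed phase-1 lr")
  if (!identical(class_weights, "auto")) {
    stopifnot(is.numeric(class_weights), length(class_weights) == 3)
  }
  structure(list(patches_per_image = as.integer(patches_per_image),
                 patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 lr_phase1 = lr_phase1,
                 epochs_phase1 = as.integer(epochs_phase1),
                 lr_phase2 = lr_phase2,
                 epochs_phase2 = as.integer(epochs_phase2),
                 class_weights = class_weights,
                 val_every = as.integer(val_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build the ground-truth grid for one patch
#'
#' A cell is labelled DSF or DSM iff the centroid of a box of that class
#' falls inside the cell's pixel footprint; boxes whose centroid lies
#' outside the patch are ignored, bycatch centroids count as background.
#' When centroids of different classes share a cell, the centroid nearest
#' the cell centre wins.
#'
#' @param boxes Box table in full-image coordinates.
#' @param patch_origin Pixel offset `(x, y)` of the patch.
#' @param patch_size Patch side length in px.
#' @param stride Grid stride in px.
#' @return An integer matrix `(patch_size / stride)` square with codes
#'   0 = background, 1 = DSF, 2 = DSM, of class `target_grid`.
#' @export
make_target_grid <- function(boxes, patch_origin, patch_size, stride) {
  n <- patch_size %/% stride
  g <- matrix(0L, n, n)
  fly <- boxes[boxes$label %in% FLY_CLASSES, , drop = FALSE]
  if (nrow(fly)) {
    cen <- box_centroid(fly)
    px <- cen$x - patch_origin[1]
    py <- cen$y - patch_origin[2]
    ok <- px >= 0 & px < patch_size & py >= 0 & py < patch_size
    if (any(ok)) {
      px <- px[ok]; py <- py[ok]
      lab <- ifelse(fly$label[ok] == "DSM", 2L, 1L)
      col <- pmin(floor(px / stride), n - 1) + 1L
      row <- pmin(floor(py / stride), n - 1) + 1L
      # nearest-to-cell-centre wins when several centroids share a cell
      d2 <- (px - (col - 0.5) * stride)^2 + (py - (row - 0.5) * stride)^2
      ord <- order(d2)
      cell <- (row - 1L) * n + col
      first <- ord[!duplicated(cell[ord])]
      g[cbind(row[first], col[first])] <- lab[first]
    }
  }
  structure(g, class = c("target_grid", "matrix", "array"))
}

#' Sample training patches from an annotated image
#'
#' Crops `k` square patches at uniformly random top-left corners and
#' builds the matching target grid for each. An image exactly the patch
#' size yields the full image (corner `(0, 0)`).
#'
#' @param ann The image's [annotated_image()].
#' @param image `height x width x 3` array.
#' @param k Number of patches.
#' @param patch_size Patch side length; the image must be at least this
#'   large in both dimensions.
#' @param stride Grid stride for the target grids.
#' @param seed Seed; the corner list is deterministic given it.
#' @return A list of `k` lists with elements `patch`, `target`, `origin`.
#' @export
sample_patches <- function(ann, image, k, patch_size, stride, seed = NULL) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < patch_size || W < patch_size) {
    stopf("image %d x %d is smaller than the %d px patch", W, H, patch_size)
  }
  corners <- with_seed(seed, {
    data.frame(x = sample.int(W - patch_size + 1L, k, replace = TRUE) - 1L,
               y = sample.int(H - patch_size + 1L, k, replace = TRUE) - 1L)
  })
  lapply(seq_len(k), function(i) {
    ox <- corners$x[i]; oy <- corners$y[i]
    list(patch = image[oy + seq_len(patch_size), ox + seq_len(patch_size), ,
                       drop = FALSE],
         target = make_target_grid(ann$boxes, c(ox, oy), patch_size, stride),
         origin = c(ox, oy))
  })
}

# The 8 elements of the dihedral group D4, encoded 0..7:
# t %% 4 = number of 90-degree anticlockwise rotations, t >= 4 = horizontal
# flip applied first.
rot90_mat <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

d4_apply_mat <- function(m, t) {
  if (t >= 4) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  for (i in seq_len(t %% 4)) m <- rot90_mat(m)
  m
}

d4_apply_array <- function(a, t) {
  if (t == 0) return(a)
  slices <- lapply(seq_len(dim(a)[3]), function(c) d4_apply_mat(a[, , c], t))
  array(unlist(slices), c(dim(slices[[1]]), dim(a)[3]))
}

# index of the inverse transform of t (flip-first encoding)
d4_inverse <- function(t) {
  if (t < 4) (4 - t) %% 4 else t
}

#' Dihedral augmentation of a patch and its target grid
#'
#' Draws one of the eight axis-aligned symmetries (identity, rotations by
#' multiples of 90 degrees, horizontal/vertical flips and their
#' compositions) uniformly at random and applies the same transform to
#' patch and target grid.
#'
#' @param patch Square `h x w x 3` array.
#' @param target The matching `target_grid`.
#' @param seed Optional seed for the draw.
#' @param transform Force a specific element `0..7` instead of sampling
#'   (`t %% 4` anticlockwise quarter-turns, `t >= 4` flips first).
#' @return A list `(patch, target, transform)`.
#' @export
augment <- function(patch, target, seed = NULL, transform = NULL) {
  t <- transform %||% with_seed(seed, sample(0:7, 1))
  if (dim(patch)[1] != dim(patch)[2] && (t %% 2) == 1) {
    stopf("90-degree rotation requires a square patch")
  }
  list(patch = d4_apply_array(patch, t),
       target = structure(d4_apply_mat(unclass(target), t),
                          class = class(target)),
       transform = t)
}

# Inverse-frequency class weights over the full-image target grids of the
# training scenes, clamped to [1, 100].
auto_class_weights <- function(scenes, stride) {
  counts <- c(0, 0, 0)
  for (s in scenes) {
    ann <- s$annotation
    ps <- floor(min(ann$width, ann$height) / stride) * stride
    g <- make_target_grid(ann$boxes, c(0, 0), ps, stride)
    tab <- tabulate(as.integer(g) + 1L, 3L)
    counts <- counts + tab
  }
  total <- sum(counts)
  w <- total / (3 * pmax(counts, 1))
  clamp(w, 1, 100)
}

scene_pair <- function(s) {
  if (inherits(s, "trap_scene")) return(s)
  stopifnot(is.list(s), !is.null(s$image), !is.null(s$annotation))
  s
}

#' Train a grid detector
#'
#' Optimises the per-cell class-weighted cross-entropy of the 3-class
#' softmax grid with Adam under the two-phase learning-rate schedule. Each
#' epoch draws fresh random patches from every training image and applies
#' dihedral augmentation. Validation loss is computed each epoch on the
#' full validation grids; every `val_every` epochs the full detection
#' metric (point matching, both classes pooled) is evaluated on the
#' validation scenes and the best-scoring weights are retained.
#'
#' @param model An `swd_model` (see [build_model()]).
#' @param train_set,val_set Lists of `trap_scene` objects (or lists with
#'   `image` and `annotation` elements).
#' @param cfg A [train_config()].
#' @param match_cfg A [match_config()] used for the validation metric.
#' @param verbose Print one line per epoch.
#' @return A list of class `swd_fit`: `model` (best-on-validation
#'   weights), `final_model`, `history` (data.frame epoch, lr, train_loss,
#'   val_loss, val_auc), `class_weights`, `best_epoch`.
#' @export
train <- function(model, train_set, val_set, cfg = train_config(),
                  match_cfg = match_config(), verbose = FALSE) {
  stopifnot(inherits(model, "swd_model"), inherits(cfg, "train_config"))
  if (length(train_set) == 0 || length(val_set) == 0) {
    stopf("train and validation sets must be non-empty")
  }
  train_set <- lapply(train_set, scene_pair)
  val_set <- lapply(val_set, scene_pair)
  stride <- model$cfg$stride
  ps <- min(cfg$patch_size, model$cfg$patch_size)
  weights <- if (identical(cfg$class_weights, "auto")) {
    auto_class_weights(train_set, stride)
  } else {
    as.numeric(cfg$class_weights)
  }

  # fixed full-image targets for the validation loss
  val_targets <- lapply(val_set, function(s) {
    H <- dim(s$image)[1]; W <- dim(s$image)[2]
    stopifnot(H %% stride == 0, W %% stride == 0)
    list(image = s$image,
         target = make_target_grid_rect(s$annotation$boxes, W, H, stride))
  })

  n_epochs <- cfg$epochs_phase1 + cfg$epochs_phase2
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric(),
                        val_auc = numeric())
  best <- list(auc = -Inf, epoch = 0L, layers = model$layers)
  epoch_seeds <- derive_seeds(cfg$seed, n_epochs)
  opt <- adam_init(model$layers)

  for (epoch in seq_len(n_epochs)) {
    lr <- if (epoch <= cfg$epochs_phase1) cfg$lr_phase1 else cfg$lr_phase2
    res <- with_seed(epoch_seeds[epoch], {
      order_imgs <- sample(seq_along(train_set))
      batch <- list(); losses <- numeric()
      layers <- model$layers
      flush_batch <- function() {
        gacc <- NULL; bl <- 0
        for (b in batch) {
          fw <- nn_forward(layers, b$patch, train = TRUE)
          ls <- cell_ce_loss(fw$out, b$target, weights)
          bl <- bl + ls$loss
          gacc <- grads_add(gacc, nn_backward(layers, fw$caches, ls$grad))
        }
        if (!is.finite(bl)) {
          stopf("training diverged at epoch %d (non-finite loss)", epoch)
        }
        gacc <- grads_scale(gacc, 1 / length(batch))
        st <- adam_step(layers, gacc, opt, lr)
        layers <<- st$layers; opt <<- st$opt
        losses <<- c(losses, bl / length(batch))
        batch <<- list()
      }
      for (ii in order_imgs) {
        s <- train_set[[ii]]
        patches <- sample_patches(s$annotation, s$image,
                                  cfg$patches_per_image, ps, stride,
                                  seed = NULL)
        for (p in patches) {
          batch[[length(batch) + 1]] <- augment(p$patch, p$target)
          if (length(batch) == cfg$batch_size) flush_batch()
        }
      }
      if (length(batch) > 0) flush_batch()  # trailing partial batch
      list(layers = layers, opt = opt, train_loss = mean(losses))
    })
    model$layers <- res$layers
    opt <- res$opt

    val_loss <- mean(vapply(val_targets, function(v) {
      fw <- nn_forward(model$layers, v$image, train = FALSE)
      cell_ce_loss(fw$out, v$target, weights)$loss
    }, numeric(1)))
    if (!is.finite(val_loss)) {
      stopf("training diverged at epoch %d (non-finite validation loss)",
            epoch)
    }

    val_auc <- NA_real_
    if (epoch %% cfg$val_every == 0 || epoch == n_epochs) {
      val_auc <- validation_auc(model, val_set, match_cfg)
      if (val_auc >= best$auc) {
        best <- list(auc = val_auc, epoch = epoch, layers = model$layers)
      }
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                train_loss = res$train_loss,
                                val_loss = val_loss, val_auc = val_auc))
    if (verbose) {
      cat(sprintf("epoch=%d lr=%g train_loss=%.4f val_loss=%.4f val_auc=%s\n",
                  epoch, lr, res$train_loss, val_loss,
                  ifelse(is.na(val_auc), "-", sprintf("%.3f", val_auc))))
    }
  }
  best_model <- model
  best_model$layers <- best$layers
  structure(list(model = best_model, final_model = model,
                 history = history, class_weights = weights,
                 best_epoch = best$epoch, best_val_auc = best$auc),
            class = "swd_fit")
}

# target grid for a full (rectangular) image
make_target_grid_rect <- function(boxes, width, height, stride) {
  nr <- height %/% stride; nc <- width %/% stride
  n <- max(nr, nc)
  g <- make_target_grid(boxes, c(0, 0), n * stride, stride)
  unclass(g)[seq_len(nr), seq_len(nc), drop = FALSE]
}

validation_auc <- function(model, val_set, match_cfg) {
  dets <- list(); anns <- list()
  for (i in seq_along(val_set)) {
    s <- val_set[[i]]
    id <- s$annotation$image_id %||% sprintf("val_%03d", i)
    dets[[i]] <- detect_image(model, s$image, image_id = id)
    anns[[i]] <- s$annotation
  }
  dets <- do.call(rbind, dets)
  gt_total <- sum(vapply(anns, function(a) {
    sum(a$boxes$label %in% FLY_CLASSES)
  }, numeric(1)))
  if (gt_total == 0) return(NA_real_)
  both_cfg <- match_config(match_cfg$dist_threshold, "both")
  pr_curve(dets, anns, both_cfg)$auc
}
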