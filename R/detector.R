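# The fully convolutional grid detector: backbone -> 1x1-conv head ->
# per-cell 3-class probability grid; tiled inference with stitching;
# class-agnostic 3x3 non-maximum suppression; grid cells -> point
# detections.

#' Detector configuration
#'
#' Two backbone variants share the same 1x1-convolution head
#' (`512 -> head_hidden -> 3` for the full model): `"resnet18"` is a
#' ResNet-18-style residual backbone truncated after its last residual
#' block (512 channels, natural output stride 32); `"tiny"` is a small
#' plain conv stack with stride 8 sized for CPU-scale experiments. The
#' head applies ReLU, dropout and a final per-cell softmax over the three
#' classes (background, DSF, DSM).
#'
#' @param backbone_depth `"resnet18"` or `"tiny"`.
#' @param head_hidden Hidden channels of the head (1024 for the full
#'   model; the tiny profile uses 64).
#' @param dropout_p Dropout probability in the head (training only).
#' @param patch_size Side length in px of training/inference tiles; must
#'   be divisible by the backbone stride.
#' @param nms_floor Confidence floor applied after non-maximum
#'   suppression; cells below it are dropped.
#' @return An object of class `detector_config` with derived field
#'   `stride` (32 for `"resnet18"`, 8 for `"tiny"`).
#' @export
detector_config <- function(backbone_depth = c("resnet18", "tiny"),
                            head_hidden = NULL, dropout_p = 0.5,
                            patch_size = NULL, nms_floor = 0.05) {
  backbone_depth <- match.arg(backbone_depth)
  stride <- if (backbone_depth == "resnet18") 32L else 8L
  head_hidden <- as.integer(head_hidden %||%
                              if (backbone_depth == "resnet18") 1024L else 64L)
  patch_size <- as.integer(patch_size %||%
                             if (backbone_depth == "resnet18") 512L else 128L)
  if (patch_size %% stride != 0) {
    stopf("patch_size (%d) must be divisible by the stride (%d)",
          patch_size, stride)
  }
  if (dropout_p < 0 || dropout_p >= 1) stopf("dropout_p must be in [0, 1)")
  structure(list(backbone_depth = backbone_depth, stride = stride,
                 head_hidden = head_hidden, n_classes = 3L,
                 dropout_p = dropout_p, patch_size = patch_size,
                 nms_floor = nms_floor),
            class = "detector_config")
}

#' Build an (untrained) grid-detector model
#'
#' The model is fully convolutional: it accepts any input whose height and
#' width are divisible by the stride and emits an
#' `(H / stride) x (W / stride) x 3` logit grid. Weights are He-normal
#' initialised.
#'
#' @param cfg A [detector_config()].
#' @param seed Seed for weight initialisation.
#' @return An object of class `swd_model`.
#' @export
build_model <- function(cfg = detector_config(), seed = 1L) {
  stopifnot(inherits(cfg, "detector_config"))
  layers <- with_seed(seed, {
    if (cfg$backbone_depth == "resnet18") {
      bb <- list(layer_conv(3L, 64L, 7L, 2L, 3L), layer_relu(),
                 layer_maxpool(2L, 2L),
                 layer_resblock(64L, 64L, 1L), layer_resblock(64L, 64L, 1L),
                 layer_resblock(64L, 128L, 2L), layer_resblock(128L, 128L, 1L),
                 layer_resblock(128L, 256L, 2L), layer_resblock(256L, 256L, 1L),
                 layer_resblock(256L, 512L, 2L), layer_resblock(512L, 512L, 1L))
      feat <- 512L
    } else {
      bb <- list(layer_conv(3L, 8L, 5L, 2L, 2L), layer_relu(),
                 layer_conv(8L, 16L, 3L, 2L, 1L), layer_relu(),
                 layer_conv(16L, 32L, 3L, 2L, 1L), layer_relu(),
                 layer_conv(32L, 64L, 3L, 1L, 1L), layer_relu())
      feat <- 64L
    }
    c(bb, list(layer_conv(feat, cfg$head_hidden, 1L, 1L, 0L), layer_relu(),
               layer_dropout(cfg$dropout_p),
               layer_conv(cfg$head_hidden, 3L, 1L, 1L, 0L)))
  })
  structure(list(cfg = cfg, layers = layers), class = "swd_model")
}

#' @export
print.swd_model <- function(x, ...) {
  np <- sum(vapply(param_paths(x$layers), function(p) {
    l <- get_path(x$layers, p)
    length(l$W) + length(l$b)
  }, numeric(1)))
  cat(sprintf("<swd_model> backbone=%s stride=%d head=%d params=%s\n",
              x$cfg$backbone_depth, x$cfg$stride, x$cfg$head_hidden,
              format(np, big.mark = ",")))
  invisible(x)
}

model_forward_logits <- function(model, x, train = FALSE) {
  d <- dim(x)
  if (d[1] %% model$cfg$stride != 0 || d[2] %% model$cfg$stride != 0) {
    stopf("input %d x %d is not divisible by the stride %d; pad first",
          d[2], d[1], model$cfg$stride)
  }
  nn_forward(model$layers, x, train = train)
}

new_prob_grid <- function(probs, stride, origin = c(0, 0)) {
  structure(list(probs = probs, stride = as.integer(stride),
                 origin = as.numeric(origin)),
            class = "prob_grid")
}

#' @export
print.prob_grid <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("<prob_grid> %d x %d cells, stride %d, origin (%g, %g)\n",
              d[1], d[2], x$stride, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Predict the class-probability grid of one patch
#'
#' Runs the model in inference mode (dropout disabled; deterministic) on a
#' single `patch_size x patch_size` tile and applies the per-cell softmax.
#'
#' @param model An `swd_model`.
#' @param patch `height x width x 3` array; both dimensions must equal
#'   `cfg$patch_size`.
#' @param origin Pixel offset `(x, y)` of the patch in the full image,
#'   recorded in the returned grid.
#' @return A `prob_grid`: probabilities `rows x cols x 3` (background,
#'   DSF, DSM), each cell summing to 1.
#' @export
predict_patch <- function(model, patch, origin = c(0, 0)) {
  stopifnot(inherits(model, "swd_model"))
  d <- dim(patch)
  ps <- model$cfg$patch_size
  if (is.null(d) || length(d) != 3 || d[1] != ps || d[2] != ps) {
    stopf("patch must be %d x %d x 3", ps, ps)
  }
  fw <- model_forward_logits(model, patch, train = FALSE)
  new_prob_grid(softmax_cells(fw$out), model$cfg$stride, origin)
}

reflect_pad_rb <- function(img, ph, pw) {
  if (ph == 0 && pw == 0) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  ridx <- c(seq_len(H), rev(seq_len(H)))[seq_len(H + ph)]
  cidx <- c(seq_len(W), rev(seq_len(W)))[seq_len(W + pw)]
  img[ridx, cidx, , drop = FALSE]
}

#' Predict the probability grid of a full image
#'
#' The image is reflection-padded at the right/bottom edges to a multiple
#' of the patch size, split into a regular grid of patches, each patch is
#' evaluated separately and the per-patch grids are stitched back to the
#' full image extent. Grid cells whose centres fall in the padded margin
#' are discarded, so no downstream detection can lie outside the original
#' image.
#'
#' @param model An `swd_model`.
#' @param image `height x width x 3` array of any size.
#' @return A `prob_grid` with origin `(0, 0)` holding every grid cell
#'   whose centre lies inside the image (about `height / stride` rows and
#'   `width / stride` columns).
#' @export
predict_image <- function(model, image) {
  stopifnot(inherits(model, "swd_model"))
  ps <- model$cfg$patch_size
  stride <- model$cfg$stride
  H <- dim(image)[1]; W <- dim(image)[2]
  Hp <- ceiling(H / ps) * ps
  Wp <- ceiling(W / ps) * ps
  padded <- reflect_pad_rb(image, Hp - H, Wp - W)
  gr <- Hp %/% stride; gc <- Wp %/% stride
  probs <- array(NA_real_, c(gr, gc, 3))
  pg <- ps %/% stride
  for (by in seq_len(Hp %/% ps)) {
    for (bx in seq_len(Wp %/% ps)) {
      rows <- (by - 1) * ps + seq_len(ps)
      cols <- (bx - 1) * ps + seq_len(ps)
      g <- predict_patch(model, padded[rows, cols, , drop = FALSE])
      probs[(by - 1) * pg + seq_len(pg), (bx - 1) * pg + seq_len(pg), ] <-
        g$probs
    }
  }
  # keep only cells whose centres lie inside the original image
  keep_r <- which((seq_len(gr) - 0.5) * stride < H)
  keep_c <- which((seq_len(gc) - 0.5) * stride < W)
  new_prob_grid(probs[keep_r, keep_c, , drop = FALSE], stride, c(0, 0))
}

#' Class-agnostic 3x3 non-maximum suppression on a probability grid
#'
#' A cell's confidence is the larger of its two fly-class probabilities
#' (DSF, DSM). A cell is retained iff its confidence beats all eight
#' neighbours (suppression ignores the predicted class); ties are broken
#' in row-major order, the earlier cell winning. Retained cells below the
#' confidence floor are dropped.
#'
#' @param grid A `prob_grid`.
#' @param floor_threshold Minimum confidence retained (default 0.05).
#' @return A `data.frame` of cell detections with columns `row`, `col`
#'   (0-based grid indices), `pred_class` and `confidence`.
#' @export
nms_grid <- function(grid, floor_threshold = 0.05) {
  stopifnot(inherits(grid, "prob_grid"))
  p <- grid$probs
  nr <- dim(p)[1]; nc <- dim(p)[2]
  conf <- pmax(p[, , 2, drop = TRUE], p[, , 3, drop = TRUE])
  conf <- matrix(conf, nr, nc)
  # row-major rank used for tie-breaking (earlier cell wins)
  rank <- matrix(seq_len(nr * nc), nr, nc, byrow = TRUE)
  padc <- matrix(-Inf, nr + 2, nc + 2)
  padc[2:(nr + 1), 2:(nc + 1)] <- conf
  padr <- matrix(Inf, nr + 2, nc + 2)
  padr[2:(nr + 1), 2:(nc + 1)] <- rank
  keep <- matrix(TRUE, nr, nc)
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      nconf <- padc[2:(nr + 1) + dy, 2:(nc + 1) + dx]
      nrank <- padr[2:(nr + 1) + dy, 2:(nc + 1) + dx]
      keep <- keep & (conf > nconf | (conf == nconf & rank < nrank))
    }
  }
  keep <- keep & conf >= floor_threshold
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(row = integer(), col = integer(),
                      pred_class = character(), confidence = numeric()))
  }
  cls <- ifelse(p[, , 3][idx] > p[, , 2][idx], "DSM", "DSF")
  out <- data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                    pred_class = cls, confidence = conf[idx])
  out[order(out$row, out$col), , drop = FALSE]
}

#' Convert retained grid cells to point detections
#'
#' Each cell becomes a point at its pixel-centre:
#' `(origin + (col + 0.5) * stride, origin + (row + 0.5) * stride)`.
#'
#' @param cells Output of [nms_grid()].
#' @param grid The `prob_grid` the cells came from.
#' @param image_id Identifier stored in the detection table.
#' @return A detection table (see [detections()]).
#' @export
cells_to_detections <- function(cells, grid, image_id = "image") {
  stopifnot(inherits(grid, "prob_grid"))
  if (nrow(cells) == 0) return(detections())
  detections(image_id = rep(image_id, nrow(cells)),
             x = grid$origin[1] + (cells$col + 0.5) * grid$stride,
             y = grid$origin[2] + (cells$row + 0.5) * grid$stride,
             class = cells$pred_class,
             confidence = cells$confidence)
}

#' Detect flies in one image
#'
#' Convenience wrapper: [predict_image()] then [nms_grid()] then
#' [cells_to_detections()].
#'
#' @param model An `swd_model`.
#' @param image `height x width x 3` array.
#' @param image_id Identifier for the detection table.
#' @param floor_threshold Post-NMS confidence floor.
#' @return A detection table.
#' @export
detect_image <- function(model, image, image_id = "image",
                         floor_threshold = model$cfg$nms_floor) {
  grid <- predict_image(model, image)
  cells_to_detections(nms_grid(grid, floor_threshold), grid, image_id)
}

#' Export per-class probability maps as greyscale PNGs
#'
#' Writes one image per fly class (`<prefix>_DSF.png`, `<prefix>_DSM.png`)
#' whose pixel intensity is the cell probability.
#'
#' @param grid A `prob_grid`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
export_prob_maps <- function(grid, prefix) {
  paths <- c(paste0(prefix, "_DSF.png"), paste0(prefix, "_DSM.png"))
  png::writePNG(grid$probs[, , 2], paths[1])
  png::writePNG(grid$probs[, , 3], paths[2])
  invisible(paths)
}

#' Save / load a model checkpoint
#'
#' Weights go to an RDS file; a JSON sidecar (`<path>.json`) records the
#' detector configuration for provenance.
#'
#' @param model An `swd_model`.
#' @param path Checkpoint path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "swd_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "swd_model"))
  m
}
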