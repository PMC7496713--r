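# Point-based detection evaluation: distance matching to ground-truth box
# centroids with one-to-one assignment, precision/recall over a confidence
# threshold sweep, area under the PR curve, and TP/FP/FN count curves.

#' Matching configuration
#'
#' @param dist_threshold Maximum pixel distance between a predicted point
#'   and the centroid of its nearest ground-truth box for a potential
#'   match (default 50 px at full acquisition scale).
#' @param class_mode `"per_class"`: a match also requires the predicted
#'   and ground-truth class to agree; `"both"`: any fly detection may
#'   match any fly ground truth (sex ignored).
#' @return An object of class `match_config`.
#' @export
match_config <- function(dist_threshold = 50,
                         class_mode = c("per_class", "both")) {
  if (dist_threshold <= 0) stopf("dist_threshold must be > 0")
  structure(list(dist_threshold = as.numeric(dist_threshold),
                 class_mode = match.arg(class_mode)),
            class = "match_config")
}

#' Match detections to ground-truth centroids at one confidence threshold
#'
#' Detections at or above the threshold are processed in descending
#' confidence order (ties: input order). Each is compared with the
#' centroid of its *nearest* ground-truth fly box: farther than
#' `dist_threshold` is a false positive; otherwise it is a true positive
#' iff that ground truth is still unmatched and the class rule of
#' `cfg$class_mode` holds, else a false positive (even if a compatible
#' ground truth lies slightly farther away). Unmatched fly ground truths
#' are false negatives. Bycatch boxes are excluded from matching entirely,
#' but false positives landing within the distance threshold of a bycatch
#' centroid are additionally tallied in `fp_on_bycatch`.
#'
#' @param dets A detection table (see [detections()]).
#' @param gts A box table (ground truth, may include BC rows).
#' @param cfg A [match_config()].
#' @param confidence_threshold Detections below it are discarded.
#' @return An object of class `match_report`: `tp`, `fp`, `fn`,
#'   `fp_on_bycatch`, `pairs` (data.frame `det` / `gt` row indices of the
#'   true-positive assignment) and `confidence_threshold`.
#' @export
match_detections <- function(dets, gts, cfg = match_config(),
                             confidence_threshold = 0) {
  stopifnot(inherits(cfg, "match_config"))
  fly_idx <- which(gts$label %in% FLY_CLASSES)
  fly <- gts[fly_idx, , drop = FALSE]
  cen <- box_centroid(fly)
  bc_cen <- box_centroid(gts[gts$label == "BC", , drop = FALSE])
  keep <- which(dets$confidence >= confidence_threshold)
  ord <- keep[order(-dets$confidence[keep])]
  matched <- rep(FALSE, nrow(fly))
  tp <- 0L; fp <- 0L; fp_bc <- 0L
  pairs <- data.frame(det = integer(), gt = integer())
  for (i in ord) {
    if (nrow(fly) == 0) {
      fp <- fp + 1L
      if (near_bycatch(dets$x[i], dets$y[i], bc_cen, cfg$dist_threshold)) {
        fp_bc <- fp_bc + 1L
      }
      next
    }
    d2 <- (cen$x - dets$x[i])^2 + (cen$y - dets$y[i])^2
    j <- which.min(d2)
    ok_dist <- sqrt(d2[j]) <= cfg$dist_threshold
    ok_class <- cfg$class_mode == "both" || dets$class[i] == fly$label[j]
    if (ok_dist && !matched[j] && ok_class) {
      tp <- tp + 1L
      matched[j] <- TRUE
      pairs <- rbind(pairs, data.frame(det = i, gt = fly_idx[j]))
    } else {
      fp <- fp + 1L
      if (near_bycatch(dets$x[i], dets$y[i], bc_cen, cfg$dist_threshold)) {
        fp_bc <- fp_bc + 1L
      }
    }
  }
  structure(list(tp = tp, fp = fp, fn = sum(!matched),
                 fp_on_bycatch = fp_bc, pairs = pairs,
                 confidence_threshold = confidence_threshold),
            class = "match_report")
}

near_bycatch <- function(x, y, bc_cen, thr) {
  nrow(bc_cen) > 0 && any((bc_cen$x - x)^2 + (bc_cen$y - y)^2 <= thr^2)
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> thr=%.3g tp=%d fp=%d fn=%d (fp on bycatch: %d)\n",
              x$confidence_threshold, x$tp, x$fp, x$fn, x$fp_on_bycatch))
  invisible(x)
}

# Normalise (dets, anns) into per-image lists keyed by image_id. `anns`
# may be one annotated_image or a list of them.
split_by_image <- function(dets, anns) {
  if (inherits(anns, "annotated_image")) anns <- list(anns)
  ids <- vapply(anns, function(a) a$image_id, character(1))
  gts <- lapply(anns, function(a) a$boxes)
  names(gts) <- ids
  dl <- split(dets, factor(dets$image_id, levels = ids))
  unknown <- setdiff(unique(dets$image_id), ids)
  if (length(unknown)) {
    stopf("detections reference unknown image id(s): %s", toString(unknown))
  }
  list(ids = ids, gts = gts, dets = dl)
}

pooled_counts <- function(by, cfg, thr) {
  tp <- fp <- fn <- fpbc <- 0L
  for (id in by$ids) {
    m <- match_detections(by$dets[[id]], by$gts[[id]], cfg, thr)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    fpbc <- fpbc + m$fp_on_bycatch
  }
  list(tp = tp, fp = fp, fn = fn, fp_on_bycatch = fpbc)
}

#' Precision-recall curve over the confidence-threshold sweep
#'
#' Thresholds are the sorted unique detection confidences (descending)
#' plus 0. At each, detections from all images are matched within their
#' own image and the counts pooled (micro-averaging); precision is
#' `Tp / (Tp + Fp)` (defined as 1 when no detections survive) and recall
#' `Tp / (Tp + Fn)`. The area under the curve is the trapezoidal integral
#' over the achieved (recall, precision) points sorted by recall, anchored
#' at recall 0 with the precision of the strictest threshold.
#'
#' @param dets A detection table (possibly covering several images).
#' @param anns An [annotated_image()] or a list of them; there must be at
#'   least one fly ground truth in scope.
#' @param cfg A [match_config()].
#' @return An object of class `pr_curve`: `thresholds`, `precision`,
#'   `recall` (aligned vectors) and `auc`.
#' @export
pr_curve <- function(dets, anns, cfg = match_config()) {
  by <- split_by_image(dets, anns)
  n_gt <- sum(vapply(by$gts, function(b) sum(b$label %in% FLY_CLASSES),
                     numeric(1)))
  if (n_gt == 0) {
    stopf("no fly ground truths in scope; recall is undefined")
  }
  thr <- c(sort(unique(dets$confidence), decreasing = TRUE), 0)
  precision <- recall <- numeric(length(thr))
  for (k in seq_along(thr)) {
    ct <- pooled_counts(by, cfg, thr[k])
    precision[k] <- if (ct$tp + ct$fp == 0) 1 else ct$tp / (ct$tp + ct$fp)
    recall[k] <- ct$tp / (ct$tp + ct$fn)
  }
  structure(list(thresholds = thr, precision = precision, recall = recall,
                 auc = pr_auc(recall, precision)),
            class = "pr_curve")
}

# Trapezoidal area under the (recall, precision) points, anchored at
# (0, precision of the strictest threshold). Points arrive in
# threshold-descending order, hence recall-ascending.
pr_auc <- function(recall, precision) {
  r <- c(0, recall)
  p <- c(precision[1], precision)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d thresholds, max recall %.3f, AUC %.3f\n",
              length(x$thresholds), max(x$recall), x$auc))
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, add = FALSE, col = "black", ...) {
  if (add) {
    graphics::lines(x$recall, x$precision, col = col, ...)
  } else {
    plot(x$recall, x$precision, type = "l", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "Recall", ylab = "Precision", col = col, ...)
  }
  invisible(x)
}

#' TP/FP/FN counts as a function of the detection threshold
#'
#' @param dets A detection table.
#' @param anns An [annotated_image()] or list of them.
#' @param cfg A [match_config()].
#' @param threshold_grid Numeric thresholds in \[0, 1\].
#' @return A `data.frame` with columns `threshold`, `tp`, `fp`, `fn`,
#'   `fp_on_bycatch`.
#' @export
count_curves <- function(dets, anns, cfg = match_config(),
                         threshold_grid = seq(0, 1, by = 0.05)) {
  if (any(threshold_grid < 0 | threshold_grid > 1)) {
    stopf("threshold_grid must lie in [0, 1]")
  }
  by <- split_by_image(dets, anns)
  rows <- lapply(threshold_grid, function(t) {
    ct <- pooled_counts(by, cfg, t)
    data.frame(threshold = t, tp = ct$tp, fp = ct$fp, fn = ct$fn,
               fp_on_bycatch = ct$fp_on_bycatch)
  })
  do.call(rbind, rows)
}

#' Plot count curves with the ground-truth total
#'
#' Line plot of TP, FP and FN versus detection threshold with a dashed
#' horizontal line at the total number of ground-truth labels.
#'
#' @param curves Output of [count_curves()].
#' @param main Plot title.
#' @return `curves`, invisibly.
#' @export
plot_count_curves <- function(curves, main = "") {
  total <- curves$tp[1] + curves$fn[1]
  ylim <- c(0, max(curves$tp, curves$fp, curves$fn, total))
  plot(curves$threshold, curves$tp, type = "l", col = "forestgreen",
       ylim = ylim, xlab = "Detection threshold", ylab = "Count",
       main = main)
  graphics::lines(curves$threshold, curves$fp, col = "firebrick")
  graphics::lines(curves$threshold, curves$fn, col = "steelblue")
  graphics::abline(h = total, lty = 2)
  graphics::legend("right", legend = c("Tp", "Fp", "Fn", "total GT"),
                   col = c("forestgreen", "firebrick", "steelblue", "black"),
                   lty = c(1, 1, 1, 2), bty = "n")
  invisible(curves)
}

#' Evaluate a detector (or a detection table) on an annotated test set
#'
#' Runs the detector over every scene (unless `object` is already a
#' detection table), pools detections across images and computes three PR
#' curves: per-class DSF and DSM (detections and ground truths of that
#' class only) and "Both" (all fly detections against all fly ground
#' truths, class ignored), plus the three-row AUC summary.
#'
#' @param object An `swd_model`, `swd_detector` fit, or detection table.
#' @param scenes List of `trap_scene` objects (or of
#'   [annotated_image()]s when `object` is a detection table).
#' @param cfg A [match_config()]; its `class_mode` is set internally per
#'   curve.
#' @return An object of class `swd_eval`: `curves` (named list of
#'   `pr_curve`s), `summary` (data.frame `sex`, `auc`), `detections`.
#' @export
evaluate_dataset <- function(object, scenes, cfg = match_config()) {
  if (is.data.frame(object)) {
    dets <- object
    anns <- lapply(scenes, function(s) {
      if (inherits(s, "annotated_image")) s else s$annotation
    })
  } else {
    model <- if (inherits(object, "swd_detector")) object$model else object
    stopifnot(inherits(model, "swd_model"))
    dets <- list(); anns <- list()
    for (i in seq_along(scenes)) {
      s <- scene_pair(scenes[[i]])
      dets[[i]] <- detect_image(model, s$image,
                                image_id = s$annotation$image_id)
      anns[[i]] <- s$annotation
    }
    dets <- do.call(rbind, dets)
  }
  curves <- list()
  for (cl in FLY_CLASSES) {
    sub_anns <- lapply(anns, function(a) {
      annotated_image(a$image_id, a$width, a$height,
                      a$boxes[a$boxes$label %in% c(cl, "BC"), , drop = FALSE])
    })
    sub_dets <- dets[dets$class == cl, , drop = FALSE]
    curves[[cl]] <- pr_curve(sub_dets, sub_anns,
                             match_config(cfg$dist_threshold, "per_class"))
  }
  curves[["Both"]] <- pr_curve(dets, anns,
                               match_config(cfg$dist_threshold, "both"))
  summary <- data.frame(sex = c("Female (DSF)", "Male (DSM)", "Both"),
                        auc = c(curves$DSF$auc, curves$DSM$auc,
                                curves$Both$auc))
  structure(list(curves = curves, summary = summary, detections = dets),
            class = "swd_eval")
}

#' @export
print.swd_eval <- function(x, ...) {
  cat("Area under the precision-recall curve\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s %.3f\n", s$sex[i], s$auc[i]))
  }
  invisible(x)
}

#' @export
plot.swd_eval <- function(x, ...) {
  cols <- c(DSF = "goldenrod", DSM = "steelblue", Both = "black")
  plot(x$curves$DSF, col = cols["DSF"], ...)
  plot(x$curves$DSM, add = TRUE, col = cols["DSM"])
  plot(x$curves$Both, add = TRUE, col = cols["Both"])
  graphics::legend("bottomleft",
                   legend = sprintf("%s (AUC %.3f)", names(cols),
                                    vapply(x$curves, `[[`, numeric(1),
                                           "auc")[names(cols)]),
                   col = cols, lty = 1, bty = "n")
  invisible(x)
}
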