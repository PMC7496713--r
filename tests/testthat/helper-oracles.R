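# Shared fixtures and independent brute-force oracles used across tests.

tiny_scene_cfg <- function(seed = 1L, n_dsm = 3, n_dsf = 3, n_bc = 2,
                           cluster_prob = 0) {
  scene_config(image_size = c(192, 192), n_dsm = n_dsm, n_dsf = n_dsf,
               n_bc = n_bc, fly_area_mean = 340, cluster_prob = cluster_prob,
               seed = seed)
}

random_boxes <- function(n, width, height, labels = c("DSM", "DSF", "BC")) {
  if (n == 0) return(swdgrid::bbox(numeric(), numeric(), numeric(),
                                   numeric(), character()))
  xmin <- floor(runif(n, 0, width - 12))
  ymin <- floor(runif(n, 0, height - 12))
  w <- floor(runif(n, 2, 11))
  h <- floor(runif(n, 2, 11))
  swdgrid::bbox(xmin, ymin, xmin + w, ymin + h,
                sample(labels, n, replace = TRUE))
}

random_detections <- function(n, width, height, id = "img") {
  if (n == 0) return(swdgrid::detections())
  swdgrid::detections(image_id = rep(id, n),
                      x = runif(n, 0, width), y = runif(n, 0, height),
                      class = sample(c("DSF", "DSM"), n, replace = TRUE),
                      confidence = round(runif(n), 3))
}

# Brute-force 3x3 local-maximum scan: for every cell, compare its fly
# confidence against each neighbour one at a time, with the row-major
# earlier cell winning ties. Written independently of nms_grid.
nms_bruteforce <- function(probs, floor_threshold = 0) {
  nr <- dim(probs)[1]; nc <- dim(probs)[2]
  res <- NULL
  for (r in 1:nr) {
    for (c in 1:nc) {
      conf <- max(probs[r, c, 2], probs[r, c, 3])
      if (conf < floor_threshold) next
      rank <- (r - 1) * nc + c
      is_max <- TRUE
      for (rr in max(1, r - 1):min(nr, r + 1)) {
        for (cc in max(1, c - 1):min(nc, c + 1)) {
          if (rr == r && cc == c) next
          nconf <- max(probs[rr, cc, 2], probs[rr, cc, 3])
          nrank <- (rr - 1) * nc + cc
          if (nconf > conf || (nconf == conf && nrank < rank)) {
            is_max <- FALSE
          }
        }
      }
      if (is_max) {
        res <- rbind(res, data.frame(
          row = r - 1L, col = c - 1L,
          pred_class = if (probs[r, c, 3] > probs[r, c, 2]) "DSM" else "DSF",
          confidence = conf))
      }
    }
  }
  if (is.null(res)) {
    res <- data.frame(row = integer(), col = integer(),
                      pred_class = character(), confidence = numeric())
  }
  res
}

# Independent re-statement of the matching protocol: detections at or
# above the threshold, in descending-confidence order; each is judged
# against its nearest ground-truth fly centroid only.
match_bruteforce <- function(dets, gts, dist_threshold, class_mode,
                             confidence_threshold) {
  fly <- gts[gts$label %in% c("DSF", "DSM"), , drop = FALSE]
  cx <- (fly$xmin + fly$xmax) / 2
  cy <- (fly$ymin + fly$ymax) / 2
  taken <- rep(FALSE, nrow(fly))
  dets <- dets[dets$confidence >= confidence_threshold, , drop = FALSE]
  dets <- dets[order(-dets$confidence), , drop = FALSE]
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(dets))) {
    if (nrow(fly) == 0) { fp <- fp + 1L; next }
    dist <- sqrt((cx - dets$x[i])^2 + (cy - dets$y[i])^2)
    j <- which.min(dist)
    class_ok <- if (class_mode == "both") TRUE else dets$class[i] == fly$label[j]
    if (dist[j] <= dist_threshold && !taken[j] && class_ok) {
      tp <- tp + 1L
      taken[j] <- TRUE
    } else {
      fp <- fp + 1L
    }
  }
  list(tp = tp, fp = fp, fn = sum(!taken))
}

# Brute-force target grid: every cell scans every fly centroid.
target_grid_bruteforce <- function(boxes, origin, patch_size, stride) {
  n <- patch_size %/% stride
  g <- matrix(0L, n, n)
  fly <- boxes[boxes$label %in% c("DSF", "DSM"), , drop = FALSE]
  for (r in 1:n) {
    for (c in 1:n) {
      x0 <- origin[1] + (c - 1) * stride; x1 <- x0 + stride
      y0 <- origin[2] + (r - 1) * stride; y1 <- y0 + stride
      best <- Inf; lab <- 0L
      for (k in seq_len(nrow(fly))) {
        cx <- (fly$xmin[k] + fly$xmax[k]) / 2
        cy <- (fly$ymin[k] + fly$ymax[k]) / 2
        # centroid must lie in this cell and inside the patch
        if (cx < x0 || cx >= x1 || cy < y0 || cy >= y1) next
        if (cx < origin[1] || cx >= origin[1] + patch_size ||
              cy < origin[2] || cy >= origin[2] + patch_size) next
        d <- (cx - (x0 + x1) / 2)^2 + (cy - (y0 + y1) / 2)^2
        if (d < best) {
          best <- d
          lab <- if (fly$label[k] == "DSM") 2L else 1L
        }
      }
      g[r, c] <- lab
    }
  }
  g
}

# A probability grid with given fly-confidence matrix (probabilities are
# normalised so each cell sums to 1; DSF carries the confidence).
grid_from_conf <- function(conf, stride = 8) {
  nr <- nrow(conf); nc <- ncol(conf)
  probs <- array(0, c(nr, nc, 3))
  probs[, , 2] <- conf
  probs[, , 1] <- 1 - conf
  structure(list(probs = probs, stride = as.integer(stride),
                 origin = c(0, 0)), class = "prob_grid")
}
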