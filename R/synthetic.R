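# Synthetic sticky-trap scene generator.
#
# Renders red sticky-trap photographs with dark fly silhouettes (body
# ellipse plus two pale wings; males additionally carry two dark wing
# spots, the only cue separating the sexes), non-target bycatch shapes and
# cluttered backgrounds, together with exact VOC-style annotations. The
# generator exists so the detector, trainer and evaluator can be exercised
# end-to-end; it makes no claim of photorealism.

#' Scene generator configuration
#'
#' Defaults emulate the field acquisition the package targets: 20 MP
#' (5472 x 3648) photographs of red Rebell-type sticky traps, fly bounding
#' boxes averaging 5700 px^2 with a ~1:1.3 width-to-length ratio, and
#' per-trap insect loads matching the mean label counts of the study
#' dataset (about 24 male and 23 female flies on fly-bearing traps, 66
#' bycatch). Scale `image_size` and `fly_area_mean` down together for fast
#' CPU-scale experiments.
#'
#' @param image_size Integer `(width, height)` in pixels.
#' @param n_dsm,n_dsf,n_bc Number of male flies, female flies and bycatch
#'   items per scene.
#' @param fly_area_mean Mean bounding-box area of a fly in px^2.
#' @param fly_aspect Mean width-to-length ratio of a fly box (length =
#'   `fly_aspect` x width); jittered by +/-15% per fly.
#' @param cluster_prob Probability that a fly is placed adjacent to or
#'   overlapping an already-placed insect (the occlusion regime).
#' @param illumination One of `"uniform"`, `"gradient"`, `"shadowed"`.
#' @param blur_sigma Gaussian blur in px applied to the final scene
#'   (emulates defocused aerial acquisitions); 0 disables.
#' @param contrast_margin Minimum darkening of mean intensity inside fly
#'   boxes relative to the bare trap surface that the renderer is designed
#'   to maintain.
#' @param seed Integer seed; rendering is deterministic given the config.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(5472, 3648),
                         n_dsm = 24, n_dsf = 23, n_bc = 66,
                         fly_area_mean = 5700, fly_aspect = 1.3,
                         cluster_prob = 0.2,
                         illumination = c("uniform", "gradient", "shadowed"),
                         blur_sigma = 0, contrast_margin = 0.03,
                         seed = 1L) {
  illumination <- match.arg(illumination)
  cfg <- list(image_size = as.integer(image_size),
              n_dsm = as.integer(n_dsm), n_dsf = as.integer(n_dsf),
              n_bc = as.integer(n_bc),
              fly_area_mean = as.numeric(fly_area_mean),
              fly_aspect = as.numeric(fly_aspect),
              cluster_prob = as.numeric(cluster_prob),
              illumination = illumination,
              blur_sigma = as.numeric(blur_sigma),
              contrast_margin = as.numeric(contrast_margin),
              seed = as.integer(seed))
  if (any(c(cfg$n_dsm, cfg$n_dsf, cfg$n_bc) < 0)) stopf("counts must be >= 0")
  if (cfg$blur_sigma < 0) stopf("blur_sigma must be >= 0")
  if (cfg$fly_area_mean <= 0) stopf("fly_area_mean must be > 0")
  if (cfg$cluster_prob < 0 || cfg$cluster_prob > 1) {
    stopf("cluster_prob must be in [0, 1]")
  }
  structure(cfg, class = "scene_config")
}

# log-normal area sampler: meanlog shifted by -sdlog^2/2 so the arithmetic
# mean equals fly_area_mean; sdlog 0.42 puts ~95% of areas within a factor
# ~2.3 of the centre (roughly 2300-12000 px^2 at the 5700 default).
FLY_AREA_SDLOG <- 0.42

sample_fly_geometry <- function(n, cfg) {
  area <- stats::rlnorm(n, log(cfg$fly_area_mean) - FLY_AREA_SDLOG^2 / 2,
                        FLY_AREA_SDLOG)
  aspect <- cfg$fly_aspect * stats::runif(n, 0.85, 1.15)
  data.frame(length = sqrt(area * aspect), width = sqrt(area / aspect))
}

ellipse_mask <- function(nr, nc, cy, cx, ry, rx) {
  dy <- ((seq_len(nr) - 0.5) - cy) / ry
  dx <- ((seq_len(nc) - 0.5) - cx) / rx
  outer(dy^2, dx^2, `+`) <= 1
}

blend_patch <- function(img, rows, cols, mask, colour, alpha = 1) {
  for (c in 1:3) {
    sub <- img[rows, cols, c]
    sub[mask] <- (1 - alpha) * sub[mask] + alpha * colour[c]
    img[rows, cols, c] <- sub
  }
  img
}

# Draw one insect into `img` inside the (0-based half-open) box, oriented
# with the body axis along the box's longer side.
draw_insect <- function(img, box, kind) {
  rows <- (floor(box$ymin) + 1):ceiling(box$ymax)
  cols <- (floor(box$xmin) + 1):ceiling(box$xmax)
  nr <- length(rows); nc <- length(cols)
  horiz <- nc >= nr
  L <- if (horiz) nc else nr
  Wd <- if (horiz) nr else nc
  flip <- stats::runif(1) < 0.5
  # (u, v): u in [0,1] along the body axis, v across it
  place <- function(u, v, ru, rv) {
    if (flip) u <- 1 - u
    if (horiz) {
      ellipse_mask(nr, nc, v * Wd, u * L, rv * Wd, ru * L)
    } else {
      ellipse_mask(nr, nc, u * L, v * Wd, ru * L, rv * Wd)
    }
  }
  if (kind == "BC") {
    pal <- list(c(0.22, 0.18, 0.12), c(0.30, 0.26, 0.10),
                c(0.15, 0.20, 0.12), c(0.35, 0.30, 0.28))
    col <- pal[[sample.int(length(pal), 1)]] * stats::runif(1, 0.7, 1.2)
    img <- blend_patch(img, rows, cols, place(0.5, 0.5, 0.46, 0.42),
                       clamp(col, 0, 1))
    return(img)
  }
  wing_col <- c(0.62, 0.60, 0.55) * stats::runif(1, 0.9, 1.05)
  body_col <- c(0.16, 0.10, 0.06) * stats::runif(1, 0.7, 1.2)
  if (kind == "BC_dros") {
    # another drosophilid: same build as a female but consistently
    # lighter/warmer, so the classes stay separable in principle
    body_col <- body_col * stats::runif(1, 1.25, 1.5) + c(0.06, 0.03, 0)
    wing_col <- wing_col * stats::runif(1, 0.92, 1.02)
  }
  spot_col <- c(0.05, 0.04, 0.04)
  img <- blend_patch(img, rows, cols, place(0.62, 0.30, 0.30, 0.18),
                     clamp(wing_col, 0, 1), alpha = 0.7)
  img <- blend_patch(img, rows, cols, place(0.62, 0.70, 0.30, 0.18),
                     clamp(wing_col, 0, 1), alpha = 0.7)
  img <- blend_patch(img, rows, cols, place(0.40, 0.50, 0.30, 0.27),
                     clamp(body_col, 0, 1))
  if (kind == "DSM") {
    # the sexing cue: one dark round spot near each wing tip
    rs <- 0.13
    img <- blend_patch(img, rows, cols,
                       place(0.82, 0.28, rs, rs * L / Wd), spot_col)
    img <- blend_patch(img, rows, cols,
                       place(0.82, 0.72, rs, rs * L / Wd), spot_col)
  }
  img
}

# Coarse value-noise field: random grid bilinearly upsampled to nr x nc.
noise_field <- function(nr, nc, cells = 8, amp = 1) {
  g <- matrix(stats::runif((cells + 1)^2), cells + 1, cells + 1)
  yi <- seq(1, cells + 1, length.out = nr)
  xi <- seq(1, cells + 1, length.out = nc)
  y0 <- pmin(floor(yi), cells); x0 <- pmin(floor(xi), cells)
  fy <- yi - y0; fx <- xi - x0
  m <- (1 - fy) %o% (1 - fx) * g[y0, x0] + (1 - fy) %o% fx * g[y0, x0 + 1] +
    fy %o% (1 - fx) * g[y0 + 1, x0] + fy %o% fx * g[y0 + 1, x0 + 1]
  amp * (m - 0.5)
}

#' Render one synthetic trap scene
#'
#' Produces the RGB image and its exact ground-truth annotation. Rendering
#' is fully deterministic given `cfg` (including `cfg$seed`).
#'
#' @param cfg A [scene_config()].
#' @param image_id Identifier stored in the annotation.
#' @return An object of class `trap_scene`: a list with `image`
#'   (`height x width x 3` array in \[0, 1\]), `annotation`
#'   (an [annotated_image()]) and `trap_rect` (the trap's pixel rectangle).
#' @export
render_scene <- function(cfg = scene_config(), image_id = "scene_001") {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, render_scene_impl(cfg, image_id))
}

render_scene_impl <- function(cfg, image_id) {
  W <- cfg$image_size[1]; H <- cfg$image_size[2]
  img <- array(0, c(H, W, 3))
  # cluttered background: grey-green base + coarse noise + a few rectangles
  base <- c(0.45, 0.44, 0.38)
  nf <- noise_field(H, W, cells = 8, amp = 0.25)
  for (c in 1:3) img[, , c] <- clamp(base[c] + nf, 0, 1)
  for (i in seq_len(sample(2:5, 1))) {
    rw <- sample.int(max(W %/% 4, 2), 1); rh <- sample.int(max(H %/% 4, 2), 1)
    rx <- sample.int(W - rw + 1, 1); ry <- sample.int(H - rh + 1, 1)
    col <- stats::runif(3, 0.1, 0.8)
    for (c in 1:3) img[ry:(ry + rh - 1), rx:(rx + rw - 1), c] <- col[c]
  }
  # red trap card with a faint printed grid, covering most of the frame
  mx <- round(W * stats::runif(1, 0.06, 0.10))
  my <- round(H * stats::runif(1, 0.06, 0.10))
  trap <- list(xmin = mx, ymin = my, xmax = W - mx, ymax = H - my)
  tr <- (trap$ymin + 1):trap$ymax; tc <- (trap$xmin + 1):trap$xmax
  trap_col <- c(0.78, 0.13, 0.12) * stats::runif(1, 0.92, 1.05)
  for (c in 1:3) img[tr, tc, c] <- clamp(trap_col[c], 0, 1)
  g <- max(8L, round(length(tc) / 12))
  gl_r <- tr[(tr - trap$ymin) %% g < max(1, g %/% 40)]
  gl_c <- tc[(tc - trap$xmin) %% g < max(1, g %/% 40)]
  for (c in 1:3) {
    img[gl_r, tc, c] <- img[gl_r, tc, c] * 0.88
    img[tr, gl_c, c] <- img[tr, gl_c, c] * 0.88
  }

  # place insects: flies (DSM/DSF) then bycatch
  kinds <- c(rep("DSM", cfg$n_dsm), rep("DSF", cfg$n_dsf),
             rep("BC", cfg$n_bc))
  boxes <- empty_boxes()
  centres <- matrix(numeric(), ncol = 2)
  # sample every insect's footprint up front and place the largest first,
  # which keeps rejection sampling reliable at high trap occupancy
  geom <- do.call(rbind, lapply(kinds, function(k) {
    shape <- k
    if (k == "BC" && stats::runif(1) < 0.5) {
      # half the bycatch are other drosophilids: fly-shaped, spotless,
      # near fly size -- the confuser class for females
      shape <- "BC_dros"
      geo <- sample_fly_geometry(1, cfg)
      sc <- stats::runif(1, 0.9, 1.3)
      L <- geo$length * sc; Wd <- geo$width * sc
    } else if (k == "BC") {
      area <- cfg$fly_area_mean * stats::runif(1, 0.5, 3)
      aspect <- stats::runif(1, 1, 4)
      L <- sqrt(area * aspect); Wd <- sqrt(area / aspect)
    } else {
      geo <- sample_fly_geometry(1, cfg)
      L <- geo$length; Wd <- geo$width
    }
    horiz <- stats::runif(1) < 0.5
    data.frame(kind = k, shape = shape, bw = if (horiz) L else Wd,
               bh = if (horiz) Wd else L)
  }))
  for (gi in order(-pmax(geom$bw, geom$bh))) {
    k <- geom$kind[gi]; shape <- geom$shape[gi]
    bw <- geom$bw[gi]; bh <- geom$bh[gi]
    placed <- FALSE
    for (try in 1:200) {
      cluster <- nrow(centres) > 0 && stats::runif(1) < cfg$cluster_prob
      if (cluster) {
        anchor <- centres[sample.int(nrow(centres), 1), ]
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0.3, 0.7) * bw
        cx <- anchor[1] + rad * cos(ang); cy <- anchor[2] + rad * sin(ang)
      } else {
        cx <- stats::runif(1, trap$xmin + bw / 2, trap$xmax - bw / 2)
        cy <- stats::runif(1, trap$ymin + bh / 2, trap$ymax - bh / 2)
      }
      b <- list(xmin = cx - bw / 2, ymin = cy - bh / 2,
                xmax = cx + bw / 2, ymax = cy + bh / 2)
      on_trap <- b$xmin >= trap$xmin && b$ymin >= trap$ymin &&
        b$xmax <= trap$xmax && b$ymax <= trap$ymax
      # non-clustered placements keep insects separated (2 px margin);
      # clustered ones deliberately allow contact and overlap
      clear <- cluster || nrow(boxes) == 0 ||
        !any(b$xmin - 2 < boxes$xmax & b$xmax + 2 > boxes$xmin &
               b$ymin - 2 < boxes$ymax & b$ymax + 2 > boxes$ymin)
      if (on_trap && clear) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stopf("could not place a %g x %g insect on the trap after 200 tries; %s",
            bw, bh, "increase image_size or reduce counts")
    }
    b <- lapply(b, round)
    if (b$xmax <= b$xmin) b$xmax <- b$xmin + 1
    if (b$ymax <= b$ymin) b$ymax <- b$ymin + 1
    img <- draw_insect(img, b, shape)
    boxes <- rbind(boxes, data.frame(xmin = b$xmin, ymin = b$ymin,
                                     xmax = b$xmax, ymax = b$ymax,
                                     label = k))
    centres <- rbind(centres, c((b$xmin + b$xmax) / 2,
                                (b$ymin + b$ymax) / 2))
  }

  # illumination applied to the whole frame, multiplicatively
  if (cfg$illumination == "gradient") {
    ramp <- seq(stats::runif(1, 0.70, 0.85), stats::runif(1, 1.05, 1.15),
                length.out = if (stats::runif(1) < 0.5) W else H)
    fac <- if (length(ramp) == W) matrix(ramp, H, W, byrow = TRUE)
    else matrix(ramp, H, W)
    for (c in 1:3) img[, , c] <- img[, , c] * fac
  } else if (cfg$illumination == "shadowed") {
    sm <- ellipse_mask(H, W, stats::runif(1, 0, H), stats::runif(1, 0, W),
                       H * stats::runif(1, 0.4, 0.8),
                       W * stats::runif(1, 0.4, 0.8))
    for (c in 1:3) {
      ch <- img[, , c]
      ch[sm] <- ch[sm] * 0.55
      img[, , c] <- ch
    }
  }
  if (cfg$blur_sigma > 0) img <- gaussian_blur(img, cfg$blur_sigma)
  img <- clamp(img, 0, 1)

  structure(list(image = img,
                 annotation = annotated_image(image_id, W, H, boxes),
                 trap_rect = trap),
            class = "trap_scene")
}

#' @export
print.trap_scene <- function(x, ...) {
  cat(sprintf("<trap_scene> %s\n", x$annotation$image_id))
  print(x$annotation)
  invisible(x)
}

#' Render a dataset of synthetic scenes to disk
#'
#' Writes `n_scenes` PNG + VOC XML pairs plus a `manifest.txt` listing the
#' scene ids (one per line). Per-scene seeds are derived deterministically
#' from `seed`, so the same master seed reproduces the dataset byte for
#' byte.
#'
#' @param n_scenes Number of scenes.
#' @param cfg_template A [scene_config()] whose `seed` field is replaced
#'   per scene.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @return A `data.frame` with columns `image_id`, `image`, `xml`.
#' @export
render_dataset <- function(n_scenes, cfg_template = scene_config(),
                           out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, n_scenes)
  out <- data.frame(image_id = character(), image = character(),
                    xml = character())
  for (i in seq_len(n_scenes)) {
    id <- sprintf("scene_%03d", i)
    cfg <- cfg_template
    cfg$seed <- seeds[i]
    sc <- render_scene(cfg, image_id = id)
    ipath <- file.path(out_dir, paste0(id, ".png"))
    xpath <- file.path(out_dir, paste0(id, ".xml"))
    write_image(sc$image, ipath)
    write_voc_annotation(sc$annotation, xpath)
    out <- rbind(out, data.frame(image_id = id, image = ipath, xml = xpath))
  }
  writeLines(out$image_id, file.path(out_dir, "manifest.txt"))
  out
}

#' Load a rendered scene directory
#'
#' Reads the manifest written by [render_dataset()] and returns the scenes
#' as in-memory image + annotation pairs.
#'
#' @param dir Directory containing `manifest.txt`, PNGs and XMLs.
#' @param ids Optional subset of ids to load.
#' @return A list of `trap_scene` objects (without `trap_rect`).
#' @export
load_scene_dir <- function(dir, ids = NULL) {
  mf <- file.path(dir, "manifest.txt")
  if (!file.exists(mf)) stopf("no manifest.txt in %s", dir)
  all_ids <- readLines(mf)
  ids <- ids %||% all_ids
  lapply(ids, function(id) {
    structure(list(image = read_image(file.path(dir, paste0(id, ".png"))),
                   annotation = read_voc_annotation(
                     file.path(dir, paste0(id, ".xml")))),
              class = "trap_scene")
  })
}

#' Degrade a scene to emulate aerial acquisition
#'
#' Applies Gaussian defocus blur, a rigid pixel translation (the trap no
#' longer centred in frame) and faint sensor noise. Annotations are shifted
#' identically; boxes are clipped to the frame and insects whose boxes
#' leave the frame entirely are dropped.
#'
#' @param scene A `trap_scene`.
#' @param blur_sigma Gaussian blur sigma in px (0 = none).
#' @param offset_px Integer `(dx, dy)` translation in px.
#' @param seed Seed for the sensor-noise draw; `NULL` disables the noise.
#' @return A new `trap_scene`.
#' @export
degrade_uav <- function(scene, blur_sigma = 3, offset_px = c(0, 0),
                        seed = NULL) {
  stopifnot(inherits(scene, "trap_scene"))
  if (blur_sigma < 0) stopf("blur_sigma must be >= 0")
  img <- scene$image
  H <- dim(img)[1]; W <- dim(img)[2]
  if (blur_sigma > 0) img <- gaussian_blur(img, blur_sigma)
  dx <- as.integer(offset_px[1]); dy <- as.integer(offset_px[2])
  if (dx != 0 || dy != 0) {
    shifted <- array(0.25, dim(img))  # out-of-trap fill: dark ground tone
    sr <- intersect(seq_len(H), seq_len(H) - dy)
    sc <- intersect(seq_len(W), seq_len(W) - dx)
    shifted[sr + dy, sc + dx, ] <- img[sr, sc, ]
    img <- shifted
  }
  if (!is.null(seed)) {
    img <- with_seed(seed, img + array(stats::rnorm(length(img), 0, 0.01),
                                       dim(img)))
  }
  img <- clamp(img, 0, 1)
  b <- scene$annotation$boxes
  if (nrow(b)) {
    b$xmin <- b$xmin + dx; b$xmax <- b$xmax + dx
    b$ymin <- b$ymin + dy; b$ymax <- b$ymax + dy
    b$xmin <- pmax(b$xmin, 0); b$ymin <- pmax(b$ymin, 0)
    b$xmax <- pmin(b$xmax, W); b$ymax <- pmin(b$ymax, H)
    b <- b[b$xmax > b$xmin & b$ymax > b$ymin, , drop = FALSE]
    rownames(b) <- NULL
  }
  structure(list(image = img,
                 annotation = annotated_image(scene$annotation$image_id,
                                              W, H, b),
                 trap_rect = scene$trap_rect),
            class = "trap_scene")
}
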