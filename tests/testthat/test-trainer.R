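test_that("target grids follow the centroid-in-cell rule", {
  # single DSM centroid at (100, 40), stride 32: row floor(40/32)=1,
  # col floor(100/32)=3
  b <- bbox(90, 30, 110, 50, "DSM")
  g <- make_target_grid(b, c(0, 0), 256, 32)
  expect_equal(sum(g != 0), 1)
  expect_equal(g[2, 4], 2L)

  # no boxes -> all background; BC centroids -> background
  expect_true(all(make_target_grid(bbox(10, 10, 30, 30, "BC"),
                                   c(0, 0), 128, 8) == 0))

  # oracle equivalence on random fixtures
  set.seed(33)
  for (rep in 1:100) {
    boxes <- random_boxes(sample(0:12, 1), 200, 200)
    origin <- c(sample(0:40, 1), sample(0:40, 1))
    got <- make_target_grid(boxes, origin, 96, 8)
    want <- target_grid_bruteforce(boxes, origin, 96, 8)
    expect_equal(unclass(got), want, ignore_attr = TRUE)
  }
})

test_that("target grids conserve fly counts", {
  set.seed(44)
  for (rep in 1:50) {
    boxes <- random_boxes(sample(1:10, 1), 100, 100)
    g <- make_target_grid(boxes, c(0, 0), 96, 8)
    cen <- box_centroid(boxes)
    in_patch <- boxes$label %in% c("DSF", "DSM") &
      cen$x >= 0 & cen$x < 96 & cen$y >= 0 & cen$y < 96
    expect_lte(sum(g != 0), sum(in_patch))
    cells <- paste(floor(cen$x[in_patch] / 8), floor(cen$y[in_patch] / 8))
    if (!anyDuplicated(cells)) expect_equal(sum(g != 0), sum(in_patch))
  }
})

test_that("patch sampling is deterministic, in-bounds and exhaustive at size", {
  cfg <- tiny_scene_cfg(seed = 12)
  sc <- render_scene(cfg, "p")
  p1 <- sample_patches(sc$annotation, sc$image, 16, 128, 8, seed = 4)
  p2 <- sample_patches(sc$annotation, sc$image, 16, 128, 8, seed = 4)
  expect_length(p1, 16)
  for (i in seq_along(p1)) {
    expect_identical(p1[[i]]$origin, p2[[i]]$origin)
    expect_equal(dim(p1[[i]]$patch), c(128, 128, 3))
    expect_true(all(p1[[i]]$origin >= 0 & p1[[i]]$origin <= 192 - 128))
  }

  # image exactly the patch size: the whole image at corner (0, 0)
  small <- render_scene(scene_config(image_size = c(128, 128), n_dsm = 1,
                                     n_dsf = 1, n_bc = 0,
                                     fly_area_mean = 300, seed = 2), "q")
  one <- sample_patches(small$annotation, small$image, 1, 128, 8, seed = 1)
  expect_equal(one[[1]]$origin, c(0, 0))
  expect_identical(one[[1]]$patch, small$image)

  expect_error(sample_patches(small$annotation, small$image, 1, 256, 8),
               "smaller than")
})

test_that("augmentation applies one dihedral element to patch and target", {
  set.seed(9)
  patch <- array(runif(32 * 32 * 3), c(32, 32, 3))
  target <- make_target_grid(bbox(2, 10, 8, 18, "DSF"), c(0, 0), 32, 8)

  # identity leaves the pair unchanged
  id <- augment(patch, target, transform = 0)
  expect_identical(id$patch, patch)
  expect_identical(unclass(id$target), unclass(target))

  # horizontal flip maps column j to cols - 1 - j
  fl <- augment(patch, target, transform = 4)
  expect_identical(fl$patch[, 32:1, ], patch)
  expect_identical(unclass(fl$target)[, 4:1], unclass(target))

  # every transform is undone by its inverse
  for (t in 0:7) {
    fwd <- augment(patch, target, transform = t)
    bwd <- augment(fwd$patch, fwd$target,
                   transform = swdgrid:::d4_inverse(t))
    expect_identical(bwd$patch, patch)
    expect_identical(unclass(bwd$target), unclass(target))
  }

  # label consistency: non-background cells move with the transform
  for (t in 0:7) {
    fwd <- augment(patch, target, transform = t)
    expect_equal(sum(fwd$target != 0), sum(target != 0))
    expect_setequal(as.integer(fwd$target), as.integer(target))
  }

  expect_error(augment(array(0, c(16, 32, 3)), matrix(0L, 2, 4),
                       transform = 1), "square")
})

test_that("a one-epoch run completes and records history", {
  cfg <- scene_config(image_size = c(96, 96), n_dsm = 2, n_dsf = 2,
                      n_bc = 1, fly_area_mean = 300, cluster_prob = 0)
  mk <- function(s) {
    cfg$seed <- s
    render_scene(cfg, sprintf("t%02d", s))
  }
  scenes <- lapply(1:3, mk)
  m <- build_model(detector_config("tiny", head_hidden = 16,
                                   patch_size = 96), seed = 1)
  tc <- train_config(patches_per_image = 2, patch_size = 96, batch_size = 2,
                     lr_phase1 = 1e-3, epochs_phase1 = 1, epochs_phase2 = 0,
                     val_every = 1, seed = 3)
  fit <- train(m, scenes[1:2], scenes[3], tc, match_config(12))
  expect_s3_class(fit, "swd_fit")
  expect_equal(nrow(fit$history), 1)
  expect_true(is.finite(fit$history$train_loss))
  expect_true(is.finite(fit$history$val_loss))
})

test_that("training is reproducible given the seed", {
  cfg <- scene_config(image_size = c(96, 96), n_dsm = 2, n_dsf = 2,
                      n_bc = 1, fly_area_mean = 300, cluster_prob = 0)
  mk <- function(s) {
    cfg$seed <- s
    render_scene(cfg, sprintf("r%02d", s))
  }
  scenes <- lapply(1:3, mk)
  run <- function() {
    m <- build_model(detector_config("tiny", head_hidden = 16,
                                     patch_size = 96), seed = 1)
    tc <- train_config(patches_per_image = 2, patch_size = 96,
                       batch_size = 2, lr_phase1 = 1e-3, epochs_phase1 = 2,
                       epochs_phase2 = 0, val_every = 2, seed = 3)
    train(m, scenes[1:2], scenes[3], tc, match_config(12))$history
  }
  expect_identical(run()$train_loss, run()$train_loss)
})

test_that("the model can overfit a single scene", {
  cfg <- scene_config(image_size = c(96, 96), n_dsm = 2, n_dsf = 2,
                      n_bc = 1, fly_area_mean = 300, cluster_prob = 0,
                      seed = 5)
  sc <- render_scene(cfg, "o")
  # capacity check: dropout off so the network can drive the loss down
  m <- build_model(detector_config("tiny", head_hidden = 32,
                                   patch_size = 96, dropout_p = 0), seed = 2)
  tc <- train_config(patches_per_image = 2, patch_size = 96, batch_size = 2,
                     lr_phase1 = 2e-3, epochs_phase1 = 200, epochs_phase2 = 0,
                     class_weights = c(1, 30, 30), val_every = 200, seed = 6)
  fit <- train(m, list(sc), list(sc), tc, match_config(12))
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], 0.05 * h$train_loss[1])
})

test_that("auto class weights are inverse-frequency, clamped to [1, 100]", {
  cfg <- scene_config(image_size = c(96, 96), n_dsm = 2, n_dsf = 2,
                      n_bc = 1, fly_area_mean = 300, cluster_prob = 0,
                      seed = 8)
  sc <- render_scene(cfg, "w")
  w <- swdgrid:::auto_class_weights(list(sc), 8)
  expect_length(w, 3)
  expect_true(all(w >= 1 & w <= 100))
  expect_equal(w[1], 1)        # background majority clamps to the floor
  expect_true(all(w[2:3] > 1)) # flies are rare, upweighted
})
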