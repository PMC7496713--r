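test_that("the model is fully convolutional with softmax-normalised cells", {
  m <- build_model(detector_config("tiny"), seed = 2)
  # 128 / 8 = 16 cells per side
  g <- predict_patch(m, array(runif(128 * 128 * 3), c(128, 128, 3)))
  expect_equal(dim(g$probs), c(16, 16, 3))
  expect_lt(max(abs(apply(g$probs, c(1, 2), sum) - 1)), 1e-6)
  expect_true(all(g$probs >= 0))

  # any stride-divisible size works; wrong patch size is a shape error
  fw <- swdgrid:::model_forward_logits(m, array(0.5, c(64, 96, 3)))
  expect_equal(dim(fw$out), c(8, 12, 3))
  expect_error(predict_patch(m, array(0, c(64, 64, 3))), "128 x 128")
  expect_error(swdgrid:::model_forward_logits(m, array(0, c(65, 64, 3))),
               "not divisible")
})

test_that("resnet18 backbone maps a 512-px patch to a 16x16 grid", {
  m <- build_model(detector_config("resnet18"), seed = 1)
  expect_equal(m$cfg$stride, 32L)
  fw <- swdgrid:::model_forward_logits(m, array(0.5, c(512, 512, 3)))
  expect_equal(dim(fw$out), c(16, 16, 3))
})

test_that("inference is deterministic (dropout disabled)", {
  m <- build_model(detector_config("tiny"), seed = 3)
  patch <- array(runif(128 * 128 * 3), c(128, 128, 3))
  g1 <- predict_patch(m, patch)
  g2 <- predict_patch(m, patch)
  expect_identical(g1$probs, g2$probs)
})

test_that("backward pass matches finite differences", {
  set.seed(14)
  layers <- list(swdgrid:::layer_conv(3L, 4L, 3L, 2L, 1L),
                 swdgrid:::layer_relu(),
                 swdgrid:::layer_maxpool(2L, 2L),
                 swdgrid:::layer_resblock(4L, 6L, 2L),
                 swdgrid:::layer_conv(6L, 3L, 1L, 1L, 0L))
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  tg <- matrix(sample(0:2, 4, TRUE), 2, 2)
  w <- c(1, 5, 5)
  lossfun <- function(ls) {
    fw <- swdgrid:::nn_forward(ls, x)
    swdgrid:::cell_ce_loss(fw$out, tg, w)$loss
  }
  fw <- swdgrid:::nn_forward(layers, x)
  gr <- swdgrid:::nn_backward(layers, fw$caches,
                              swdgrid:::cell_ce_loss(fw$out, tg, w)$grad)
  eps <- 1e-6
  check <- function(path) {
    l <- swdgrid:::get_path(layers, path)
    g <- swdgrid:::get_path(gr, path)
    for (k in 1:4) {
      i <- sample(length(l$W), 1)
      lp <- swdgrid:::set_path(layers, path,
                               within(l, W[i] <- W[i] + eps))
      lm <- swdgrid:::set_path(layers, path,
                               within(l, W[i] <- W[i] - eps))
      num <- (lossfun(lp) - lossfun(lm)) / (2 * eps)
      expect_lt(abs(num - g$W[i]), 1e-4 * max(1, abs(num)))
    }
  }
  check(list(1))
  check(list(4, "conv1"))
  check(list(4, "proj"))
  check(list(5))
})

test_that("NMS equals the exhaustive 3x3 scan on random grids", {
  set.seed(99)
  for (rep in 1:100) {
    conf <- matrix(runif(20 * 20), 20, 20)
    # inject plateaus so the tie-break rule is actually exercised
    conf[sample(400, 30)] <- round(conf[sample(400, 30)], 1)
    g <- grid_from_conf(conf)
    got <- nms_grid(g, floor_threshold = 0)
    want <- nms_bruteforce(g$probs, floor_threshold = 0)
    expect_equal(got$row, want$row)
    expect_equal(got$col, want$col)
    expect_equal(got$confidence, want$confidence)
    # sparsity: no two retained cells within Chebyshev distance 1
    if (nrow(got) > 1) {
      dr <- outer(got$row, got$row, function(a, b) abs(a - b))
      dc <- outer(got$col, got$col, function(a, b) abs(a - b))
      cheb <- pmax(dr, dc)
      diag(cheb) <- Inf
      expect_gt(min(cheb), 1)
    }
  }
})

test_that("NMS keeps isolated peaks and suppresses weaker neighbours", {
  conf <- matrix(0.1, 3, 3)
  conf[2, 2] <- 0.9
  got <- nms_grid(grid_from_conf(conf), floor_threshold = 0.05)
  expect_equal(nrow(got), 1)
  expect_equal(c(got$row, got$col), c(1, 1))

  conf2 <- matrix(0, 3, 4)
  conf2[2, 2] <- 0.8
  conf2[2, 3] <- 0.7
  got2 <- nms_grid(grid_from_conf(conf2), floor_threshold = 0.05)
  expect_equal(nrow(got2), 1)
  expect_equal(got2$confidence, 0.8)

  # class-agnostic: a strong DSM cell suppresses an adjacent weaker DSF cell
  probs <- array(0, c(3, 3, 3))
  probs[, , 1] <- 1
  probs[2, 2, ] <- c(0.1, 0.2, 0.7)   # DSM at 0.7
  probs[2, 3, ] <- c(0.4, 0.6, 0.0)   # DSF at 0.6
  g <- structure(list(probs = probs, stride = 8L, origin = c(0, 0)),
                 class = "prob_grid")
  got3 <- nms_grid(g, floor_threshold = 0.05)
  expect_equal(nrow(got3), 1)
  expect_equal(got3$pred_class, "DSM")
})

test_that("cells map to their pixel centres", {
  g <- grid_from_conf(matrix(0.5, 4, 4), stride = 32)
  cells <- data.frame(row = c(0L, 2L), col = c(0L, 3L),
                      pred_class = c("DSF", "DSM"),
                      confidence = c(0.5, 0.9))
  d <- cells_to_detections(cells, g, "img")
  expect_equal(d$x, c(16, 112))
  expect_equal(d$y, c(16, 80))
  expect_equal(d$class, c("DSF", "DSM"))
  # a detection's point lies inside its source cell's footprint
  expect_true(all(floor(d$x / 32) == cells$col))
  expect_true(all(floor(d$y / 32) == cells$row))
})

test_that("stitched full-image prediction equals tile-wise patch prediction", {
  m <- build_model(detector_config("tiny"), seed = 5)
  set.seed(5)
  img <- array(runif(128 * 256 * 3), c(128, 256, 3))
  whole <- predict_image(m, img)
  left <- predict_patch(m, img[, 1:128, , drop = FALSE])
  right <- predict_patch(m, img[, 129:256, , drop = FALSE])
  expect_equal(dim(whole$probs), c(16, 32, 3))
  expect_identical(whole$probs[, 1:16, ], left$probs)
  expect_identical(whole$probs[, 17:32, ], right$probs)

  # single-tile case collapses to predict_patch
  one <- predict_image(m, img[, 1:128, , drop = FALSE])
  expect_identical(one$probs, left$probs)
})

test_that("padded inference discards padding cells and stays in bounds", {
  m <- build_model(detector_config("tiny"), seed = 6)
  set.seed(6)
  img <- array(runif(150 * 170 * 3), c(150, 170, 3))
  g <- predict_image(m, img)
  # cells whose centres fall in the padded margin are dropped: the kept
  # counts are #{k : (k - 0.5) * stride < size}
  expect_equal(dim(g$probs), c(sum((1:32 - 0.5) * 8 < 150),
                               sum((1:32 - 0.5) * 8 < 170), 3))
  expect_equal(dim(g$probs)[1:2], c(19, 21))
  d <- cells_to_detections(nms_grid(g, 0), g, "img")
  expect_true(all(d$x < 170 & d$y < 150))
})

test_that("checkpoints round-trip through disk with a config sidecar", {
  m <- build_model(detector_config("tiny", head_hidden = 16), seed = 8)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$backbone_depth, "tiny")
  expect_equal(side$head_hidden, 16)
  m2 <- load_model(path)
  patch <- array(runif(128 * 128 * 3), c(128, 128, 3))
  expect_identical(predict_patch(m, patch)$probs,
                   predict_patch(m2, patch)$probs)
})
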