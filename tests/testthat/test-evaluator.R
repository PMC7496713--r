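ann_with <- function(boxes, id = "img", w = 1000, h = 1000) {
  annotated_image(id, w, h, boxes)
}

test_that("direct hits, class rules and double-detections match the protocol", {
  gts <- bbox(90, 90, 110, 110, "DSM")  # centroid (100, 100)

  # one DSM detection 10 px away
  d <- detections("img", 110, 100, "DSM", 0.9)
  m <- match_detections(d, gts, match_config(50, "per_class"))
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))

  # wrong sex: FP + FN under per_class, TP under both
  gts_f <- bbox(90, 90, 110, 110, "DSF")
  m2 <- match_detections(d, gts_f, match_config(50, "per_class"))
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 1))
  m3 <- match_detections(d, gts_f, match_config(50, "both"))
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(1, 0, 0))

  # two detections sharing one ground truth: second is an FP
  d2 <- detections(c("img", "img"), c(105, 95), c(100, 100),
                   c("DSM", "DSM"), c(0.9, 0.8))
  m4 <- match_detections(d2, gts, match_config(50, "per_class"))
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(1, 1, 0))
  expect_equal(m4$pairs$det, 1)

  # beyond the distance threshold
  d3 <- detections("img", 200, 200, "DSM", 0.9)
  m5 <- match_detections(d3, gts, match_config(50, "per_class"))
  expect_equal(c(m5$tp, m5$fp, m5$fn), c(0, 1, 1))
})

test_that("matching equals the brute-force protocol on random instances", {
  set.seed(77)
  for (rep in 1:200) {
    n_det <- sample(0:10, 1)
    n_gt <- sample(0:10, 1)
    dets <- random_detections(n_det, 300, 300)
    gts <- random_boxes(n_gt, 300, 300)
    if (sum(gts$label %in% c("DSF", "DSM")) == 0 && n_gt > 0) {
      gts$label[1] <- "DSF"
    }
    mode <- sample(c("per_class", "both"), 1)
    thr <- sample(c(0, 0.3, 0.6), 1)
    got <- match_detections(dets, gts, match_config(60, mode), thr)
    want <- match_bruteforce(dets, gts, 60, mode, thr)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$fn, want$fn)
  }
})

test_that("matching is one-to-one and conserves counts", {
  set.seed(78)
  for (rep in 1:50) {
    dets <- random_detections(sample(1:10, 1), 200, 200)
    gts <- random_boxes(sample(1:10, 1), 200, 200)
    m <- match_detections(dets, gts, match_config(60, "both"), 0.2)
    n_fly <- sum(gts$label %in% c("DSF", "DSM"))
    n_kept <- sum(dets$confidence >= 0.2)
    expect_equal(m$tp + m$fn, n_fly)
    expect_equal(m$tp + m$fp, n_kept)
    expect_equal(anyDuplicated(m$pairs$det), 0)
    expect_equal(anyDuplicated(m$pairs$gt), 0)
  }
})

test_that("precision and recall follow their defining ratios", {
  # Tp=3, Fp=1, Fn=2 -> precision 0.75, recall 0.60. Three flies detected
  # dead-on, one detection far away, two flies missed.
  gts <- bbox(c(100, 200, 300, 400, 500), c(100, 100, 100, 100, 100),
              c(120, 220, 320, 420, 520), c(120, 120, 120, 120, 120),
              rep("DSM", 5))
  dets <- detections(rep("img", 4), c(110, 210, 310, 800),
                     rep(110, 4), rep("DSM", 4), rep(0.9, 4))
  m <- match_detections(dets, gts, match_config(50, "per_class"))
  expect_equal(c(m$tp, m$fp, m$fn), c(3, 1, 2))
  pr <- pr_curve(dets, ann_with(gts), match_config(50, "per_class"))
  expect_equal(pr$precision[1], 0.75)
  expect_equal(pr$recall[1], 0.60)
})

test_that("the perfect detector achieves precision = recall = AUC = 1", {
  cfg <- tiny_scene_cfg(seed = 31)
  sc <- render_scene(cfg, "perfect")
  fly <- sc$annotation$boxes[sc$annotation$boxes$label != "BC", ]
  cen <- box_centroid(fly)
  dets <- detections(rep("perfect", nrow(fly)), cen$x, cen$y, fly$label,
                     rep(1, nrow(fly)))
  pr <- pr_curve(dets, sc$annotation, match_config(12, "per_class"))
  expect_true(all(pr$precision == 1))
  expect_true(all(pr$recall == 1))
  expect_equal(pr$auc, 1.0)
})

test_that("no detections gives zero recall and zero AUC", {
  gts <- bbox(10, 10, 30, 30, "DSF")
  pr <- pr_curve(detections(), ann_with(gts), match_config(50))
  expect_true(all(pr$recall == 0))
  expect_equal(pr$auc, 0)
  expect_error(pr_curve(detections(), ann_with(bbox(1, 1, 5, 5, "BC"))),
               "no fly ground truths")
})

test_that("AUC equals the hand-computed trapezoid on a small instance", {
  # 3 ground truths at x = 100, 200, 300 (y = 100); 4 detections sweeping
  # confidence 0.9, 0.7, 0.5, 0.3. Walking the thresholds by hand:
  #  thr 0.9: det at gt1          -> tp=1 fp=0 fn=2: P=1,    R=1/3
  #  thr 0.7: + det at gt2        -> tp=2 fp=0 fn=1: P=1,    R=2/3
  #  thr 0.5: + det far away      -> tp=2 fp=1 fn=1: P=2/3,  R=2/3
  #  thr 0.3 and 0: + det at gt3  -> tp=3 fp=1 fn=0: P=3/4,  R=1
  # Trapezoid over (0,1),(1/3,1),(2/3,1),(2/3,2/3),(1,3/4):
  #  1/3*1 + 1/3*1 + 0 + 1/3*(2/3+3/4)/2 = 2/3 + 17/72 = 65/72
  gts <- bbox(c(90, 190, 290), rep(90, 3), c(110, 210, 310), rep(110, 3),
              rep("DSM", 3))
  dets <- detections(rep("img", 4),
                     x = c(100, 200, 700, 300), y = c(100, 100, 700, 100),
                     class = rep("DSM", 4),
                     confidence = c(0.9, 0.7, 0.5, 0.3))
  pr <- pr_curve(dets, ann_with(gts), match_config(50, "per_class"))
  expect_equal(pr$auc, 65 / 72)
})

test_that("count curves hit their boundary cases and are monotone", {
  set.seed(55)
  dets <- random_detections(30, 400, 400)
  gts <- random_boxes(15, 400, 400)
  if (!any(gts$label %in% c("DSF", "DSM"))) gts$label[1] <- "DSF"
  ann <- ann_with(gts, w = 400, h = 400)
  cc <- count_curves(dets, ann, match_config(60, "both"),
                     seq(0, 1, by = 0.1))
  n_fly <- sum(gts$label %in% c("DSF", "DSM"))

  # conservation at every threshold
  for (i in seq_len(nrow(cc))) {
    expect_equal(cc$tp[i] + cc$fn[i], n_fly)
    expect_equal(cc$tp[i] + cc$fp[i],
                 sum(dets$confidence >= cc$threshold[i]))
  }
  # monotonicity in the threshold
  expect_true(all(diff(cc$tp) <= 0))
  expect_true(all(diff(cc$fn) >= 0))

  # above every confidence nothing survives
  high <- count_curves(dets, ann, match_config(60, "both"), 1)
  expect_equal(c(high$tp, high$fp), c(0, 0))
  expect_equal(high$fn, n_fly)
  # at zero every detection is counted
  zero <- count_curves(dets, ann, match_config(60, "both"), 0)
  expect_equal(zero$tp + zero$fp, nrow(dets))
})

test_that("recall never increases with the threshold", {
  set.seed(56)
  for (rep in 1:20) {
    dets <- random_detections(sample(5:25, 1), 300, 300)
    gts <- random_boxes(sample(3:12, 1), 300, 300)
    if (!any(gts$label %in% c("DSF", "DSM"))) gts$label[1] <- "DSM"
    pr <- pr_curve(dets, ann_with(gts, w = 300, h = 300),
                   match_config(60, "both"))
    # thresholds are descending, so recall must be non-increasing in the
    # threshold, i.e. non-decreasing along the vector
    expect_true(all(diff(pr$recall) >= -1e-12))
    expect_gte(pr$auc, 0)
    expect_lte(pr$auc, 1)
  }
})

test_that("dataset evaluation pools detections and is replication-invariant", {
  cfg <- tiny_scene_cfg(seed = 61)
  sc <- render_scene(cfg, "ev1")
  fly <- sc$annotation$boxes[sc$annotation$boxes$label != "BC", ]
  cen <- box_centroid(fly)
  # a detector that finds all flies but sexes one wrongly and adds one FP
  cls <- fly$label
  cls[1] <- ifelse(cls[1] == "DSM", "DSF", "DSM")
  dets <- rbind(
    detections(rep("ev1", nrow(fly)), cen$x, cen$y, cls,
               seq(0.95, 0.6, length.out = nrow(fly))),
    detections("ev1", 5, 5, "DSF", 0.4))
  ev1 <- evaluate_dataset(dets, list(sc$annotation), match_config(12))
  expect_equal(ev1$summary$sex, c("Female (DSF)", "Male (DSM)", "Both"))
  expect_equal(ev1$curves$Both$auc, ev1$summary$auc[3])

  # duplicating every image leaves precision/recall unchanged
  ann2 <- annotated_image("ev2", sc$annotation$width, sc$annotation$height,
                          sc$annotation$boxes)
  dets2 <- dets
  dets2$image_id <- "ev2"
  ev2 <- evaluate_dataset(rbind(dets, dets2),
                          list(sc$annotation, ann2), match_config(12))
  for (nm in names(ev1$curves)) {
    expect_equal(ev2$curves[[nm]]$precision, ev1$curves[[nm]]$precision)
    expect_equal(ev2$curves[[nm]]$recall, ev1$curves[[nm]]$recall)
    expect_equal(ev2$curves[[nm]]$auc, ev1$curves[[nm]]$auc)
  }

  # an oracle detector scores AUC 1 on all three rows
  oracle <- detections(rep("ev1", nrow(fly)), cen$x, cen$y, fly$label,
                       rep(1, nrow(fly)))
  ev3 <- evaluate_dataset(oracle, list(sc$annotation), match_config(12))
  expect_equal(ev3$summary$auc, c(1, 1, 1))
})

test_that("false positives near bycatch are tallied separately", {
  gts <- rbind(bbox(90, 90, 110, 110, "DSM"),
               bbox(300, 300, 340, 340, "BC"))
  dets <- detections(c("img", "img"), c(100, 320), c(100, 320),
                     c("DSM", "DSF"), c(0.9, 0.8))
  m <- match_detections(dets, gts, match_config(50, "per_class"))
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 1, 0))
  expect_equal(m$fp_on_bycatch, 1)
})
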