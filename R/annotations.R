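# Domain types and I/O for trap-image annotations and detections.
#
# Internal coordinate convention: 0-based, half-open boxes [xmin, xmax) x
# [ymin, ymax) in pixel units. Pascal VOC XML stores 1-based inclusive
# coordinates; the shift happens only at the I/O boundary.

#' Construct a bounding-box table
#'
#' Boxes are kept as a plain `data.frame` with one row per box and columns
#' `xmin`, `ymin`, `xmax`, `ymax` (0-based, half-open pixel coordinates) and
#' `label` (one of `"DSM"`, `"DSF"`, `"BC"`).
#'
#' @param xmin,ymin,xmax,ymax Numeric vectors of box coordinates.
#' @param label Character vector of class labels.
#' @return A `data.frame` of boxes.
#' @export
bbox <- function(xmin, ymin, xmax, ymax, label) {
  b <- data.frame(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                  xmax = as.numeric(xmax), ymax = as.numeric(ymax),
                  label = as.character(label))
  validate_boxes(b)
  b
}

empty_boxes <- function() {
  data.frame(xmin = numeric(), ymin = numeric(), xmax = numeric(),
             ymax = numeric(), label = character())
}

validate_boxes <- function(b) {
  stopifnot(is.data.frame(b))
  need <- c("xmin", "ymin", "xmax", "ymax", "label")
  if (!all(need %in% names(b))) stopf("boxes need columns %s", toString(need))
  bad <- b$label[!b$label %in% ANN_LABELS]
  if (length(bad)) {
    stopf("unknown class label(s): %s (vocabulary is %s)",
          toString(unique(bad)), toString(ANN_LABELS))
  }
  if (any(b$xmax <= b$xmin) || any(b$ymax <= b$ymin)) {
    stopf("degenerate box: xmax/ymax must exceed xmin/ymin")
  }
  invisible(b)
}

#' Construct an annotated image
#'
#' An annotated image is the ground-truth record for one trap photograph:
#' an identifier, pixel dimensions and a table of labelled bounding boxes.
#'
#' @param image_id Character scalar identifier.
#' @param width,height Image dimensions in pixels.
#' @param boxes A box table as produced by [bbox()]; may have zero rows.
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(image_id, width, height, boxes = empty_boxes()) {
  width <- as.numeric(width); height <- as.numeric(height)
  if (width <= 0 || height <= 0) stopf("width and height must be positive")
  validate_boxes(boxes)
  out <- which(boxes$xmin < 0 | boxes$ymin < 0 |
                 boxes$xmax > width | boxes$ymax > height)
  if (length(out)) {
    stopf("box %d lies outside the %g x %g image", out[1], width, height)
  }
  structure(list(image_id = as.character(image_id), width = width,
                 height = height, boxes = boxes),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image> %s (%g x %g px)\n", x$image_id,
              x$width, x$height))
  tab <- table(factor(x$boxes$label, levels = ANN_LABELS))
  cat(sprintf("  boxes: %d (%s)\n", nrow(x$boxes),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Box centroids
#'
#' The centre of each box, `((xmin + xmax) / 2, (ymin + ymax) / 2)`, in
#' continuous pixel coordinates. This is the reference point used by the
#' distance-based matching protocol.
#'
#' @param b A box table.
#' @return A `data.frame` with columns `x` and `y`, one row per box.
#' @export
box_centroid <- function(b) {
  data.frame(x = (b$xmin + b$xmax) / 2, y = (b$ymin + b$ymax) / 2)
}

xml_num <- function(node, xpath) {
  v <- xml2::xml_find_first(node, xpath)
  if (inherits(v, "xml_missing")) return(NA_real_)
  as.numeric(xml2::xml_text(v))
}

#' Read a Pascal VOC XML annotation
#'
#' Parses a LabelImg-dialect VOC file. The stored 1-based inclusive pixel
#' coordinates are converted to the internal 0-based half-open convention,
#' so a VOC box `(xmin=11, ymin=21, xmax=20, ymax=40)` becomes
#' `(10, 20, 20, 40)`.
#'
#' @param xml_path Path to the XML file.
#' @return An [annotated_image()].
#' @export
read_voc_annotation <- function(xml_path) {
  if (!file.exists(xml_path)) stopf("annotation file not found: %s", xml_path)
  doc <- xml2::read_xml(xml_path)
  size <- xml2::xml_find_first(doc, ".//size")
  if (inherits(size, "xml_missing")) {
    stopf("VOC format error in %s: missing <size> element", xml_path)
  }
  width <- xml_num(size, "./width")
  height <- xml_num(size, "./height")
  if (is.na(width) || is.na(height)) {
    stopf("VOC format error in %s: <size> lacks width/height", xml_path)
  }
  fname <- xml2::xml_find_first(doc, ".//filename")
  image_id <- if (inherits(fname, "xml_missing")) {
    tools::file_path_sans_ext(basename(xml_path))
  } else {
    tools::file_path_sans_ext(xml2::xml_text(fname))
  }
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- empty_boxes()
  for (i in seq_along(objs)) {
    nm <- xml2::xml_text(xml2::xml_find_first(objs[[i]], "./name"))
    if (!nm %in% ANN_LABELS) {
      stopf("object %d in %s has unknown class '%s' (vocabulary is %s)",
            i, xml_path, nm, toString(ANN_LABELS))
    }
    xmin <- xml_num(objs[[i]], "./bndbox/xmin") - 1
    ymin <- xml_num(objs[[i]], "./bndbox/ymin") - 1
    xmax <- xml_num(objs[[i]], "./bndbox/xmax")
    ymax <- xml_num(objs[[i]], "./bndbox/ymax")
    if (anyNA(c(xmin, ymin, xmax, ymax))) {
      stopf("object %d in %s has a malformed <bndbox>", i, xml_path)
    }
    if (xmin < 0 || ymin < 0 || xmax > width || ymax > height) {
      stopf("object %d in %s lies outside the %g x %g image",
            i, xml_path, width, height)
    }
    boxes <- rbind(boxes, data.frame(xmin = xmin, ymin = ymin, xmax = xmax,
                                     ymax = ymax, label = nm))
  }
  annotated_image(image_id, width, height, boxes)
}

#' Write a Pascal VOC XML annotation
#'
#' Inverse of [read_voc_annotation()]: internal 0-based half-open boxes are
#' stored as 1-based inclusive VOC coordinates. The round-trip is exact for
#' integer-valued boxes.
#'
#' @param ann An [annotated_image()].
#' @param xml_path Output path.
#' @return `xml_path`, invisibly.
#' @export
write_voc_annotation <- function(ann, xml_path) {
  stopifnot(inherits(ann, "annotated_image"))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", paste0(ann$image_id, ".png"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(ann$width, scientific = FALSE))
  xml2::xml_add_child(size, "height", format(ann$height, scientific = FALSE))
  xml2::xml_add_child(size, "depth", "3")
  b <- ann$boxes
  for (i in seq_len(nrow(b))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", b$label[i])
    xml2::xml_add_child(obj, "difficult", "0")
    bb <- xml2::xml_add_child(obj, "bndbox")
    fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
    xml2::xml_add_child(bb, "xmin", fmt(b$xmin[i] + 1))
    xml2::xml_add_child(bb, "ymin", fmt(b$ymin[i] + 1))
    xml2::xml_add_child(bb, "xmax", fmt(b$xmax[i]))
    xml2::xml_add_child(bb, "ymax", fmt(b$ymax[i]))
  }
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}

#' Split image ids into train/validation/test sets
#'
#' Random, seeded, disjoint split. Subset sizes are the requested fractions
#' of `length(ids)` rounded by the largest-remainder method, so the sizes
#' always sum to the total.
#'
#' @param ids Character vector of image ids.
#' @param fractions Length-3 numeric vector `(train, val, test)` summing to 1.
#' @param seed Integer seed; the split is deterministic given `ids` and
#'   `seed`.
#' @return An object of class `dataset_split` with elements `train`, `val`,
#'   `test`, `seed` and `fractions`.
#' @export
split_dataset <- function(ids, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  if (length(ids) == 0) stopf("ids must be non-empty")
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    stopf("fractions must be three numbers summing to 1")
  }
  n <- length(ids)
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- raw - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    # largest-remainder: hand leftover units to the largest fractional parts
    for (i in order(rem, decreasing = TRUE)[seq_len(short)]) {
      sizes[i] <- sizes[i] + 1
    }
  }
  perm <- with_seed(seed, sample(ids))
  structure(list(train = perm[seq_len(sizes[1])],
                 val = perm[sizes[1] + seq_len(sizes[2])],
                 test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])],
                 seed = as.integer(seed), fractions = fractions),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train=%d val=%d test=%d (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' Construct a detection table
#'
#' Detections are point predictions: full-image pixel coordinates, a
#' predicted fly class (`"DSF"` or `"DSM"`) and a confidence in \[0, 1\].
#'
#' @param image_id Character vector of source image ids.
#' @param x,y Numeric detection coordinates.
#' @param class Character vector of predicted classes.
#' @param confidence Numeric confidences in \[0, 1\].
#' @return A `data.frame` with the five columns above.
#' @export
detections <- function(image_id = character(), x = numeric(), y = numeric(),
                       class = character(), confidence = numeric()) {
  d <- data.frame(image_id = as.character(image_id), x = as.numeric(x),
                  y = as.numeric(y), class = as.character(class),
                  confidence = as.numeric(confidence))
  validate_detections(d)
  d
}

validate_detections <- function(d, line_offset = 0L) {
  need <- c("image_id", "x", "y", "class", "confidence")
  if (!all(need %in% names(d))) {
    stopf("detections need columns %s", toString(need))
  }
  bad <- which(!d$class %in% FLY_CLASSES)
  if (length(bad)) {
    stopf("line %d: invalid detection class '%s' (must be DSF or DSM)",
          bad[1] + line_offset, d$class[bad[1]])
  }
  bad <- which(!is.finite(d$confidence) | d$confidence < 0 | d$confidence > 1)
  if (length(bad)) {
    stopf("line %d: confidence %s outside [0, 1]",
          bad[1] + line_offset, format(d$confidence[bad[1]]))
  }
  bad <- which(!is.finite(d$x) | !is.finite(d$y))
  if (length(bad)) stopf("line %d: non-numeric coordinate", bad[1] + line_offset)
  invisible(d)
}

#' Write / read detection CSV files
#'
#' Fixed-header CSV (`image_id,x,y,class,confidence`) used to exchange
#' detections between the detect and evaluate steps.
#'
#' @param dets A detection table (see [detections()]).
#' @param path CSV file path.
#' @return `write_detections_csv()` returns `path` invisibly;
#'   `read_detections_csv()` returns a validated detection table.
#' @export
write_detections_csv <- function(dets, path) {
  validate_detections(dets)
  utils::write.csv(dets[, c("image_id", "x", "y", "class", "confidence")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  if (!file.exists(path)) stopf("detections file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(image_id = "character"))
  # +1 for the header row so reported line numbers match the file
  validate_detections(d, line_offset = 1L)
  d
}
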