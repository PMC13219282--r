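#' Expand a box by a margin and clip to the image
#'
#' Moves each side of every box outward by `pad` pixels, then clamps the
#' result to `[0, width] x [0, height]`. With `pad = 0` this is the
#' identity; output boxes always lie within the image.
#'
#' @param boxes Data frame of boxes in corner convention (extra columns pass
#'   through untouched).
#' @param pad Nonnegative margin in pixels (default 10, the usual context
#'   margin for crop classification).
#' @param width,height Image dimensions in pixels.
#' @return The boxes with expanded, clipped coordinates.
#' @export
pad_and_clip <- function(boxes, pad = 10, width, height) {
  stopifnot(pad >= 0)
  boxes <- tibble::as_tibble(boxes)
  dplyr::mutate(boxes,
                x_min = pmax(0, .data$x_min - pad),
                y_min = pmax(0, .data$y_min - pad),
                x_max = pmin(width, .data$x_max + pad),
                y_max = pmin(height, .data$y_max + pad))
}

#' Crop a box from an image and resize bilinearly
#'
#' Extracts the rectangular region under a (continuous-coordinate) box and
#' resamples it to `out_size x out_size` with bilinear interpolation.
#' Sampling uses the half-pixel-center convention: output pixel `(r, c)`
#' samples the source at `x = x_min + (c - 0.5) * w / out_size` (and
#' likewise in y), with interpolation between the four surrounding pixel
#' centers and clamping at image edges. When the box is axis-aligned on the
#' pixel grid and already `out_size` pixels wide and tall, the crop
#' reproduces the source region exactly.
#'
#' @param image Numeric raster (`H x W` or `H x W x C`) on `[0, 1]`.
#' @param box A one-row data frame (or named list) with `x_min`, `y_min`,
#'   `x_max`, `y_max`, lying within the image and of positive area.
#' @param out_size Output side length in pixels (>= 2), default 128.
#' @return A numeric `out_size x out_size` matrix (or
#'   `out_size x out_size x C` array), channel count preserved.
#' @export
crop_and_resize <- function(image, box, out_size = 128) {
  stopifnot(out_size >= 2)
  x_min <- box$x_min; x_max <- box$x_max
  y_min <- box$y_min; y_max <- box$y_max
  h <- image_height(image); w <- image_width(image)
  if (x_max <= x_min || y_max <= y_min) {
    rlang::abort("zero-area box cannot be cropped")
  }
  if (x_min < -1e-9 || y_min < -1e-9 || x_max > w + 1e-9 || y_max > h + 1e-9) {
    rlang::abort("box outside image bounds")
  }
  # continuous sample coordinates of output pixel centers
  xs <- x_min + (seq_len(out_size) - 0.5) * (x_max - x_min) / out_size
  ys <- y_min + (seq_len(out_size) - 0.5) * (y_max - y_min) / out_size
  # 0-based pixel-center coordinates, clamped to the grid of centers
  gx <- pmin(pmax(xs - 0.5, 0), w - 1)
  gy <- pmin(pmax(ys - 0.5, 0), h - 1)
  x0 <- pmin(floor(gx), w - 1); x1 <- pmin(x0 + 1, w - 1)
  y0 <- pmin(floor(gy), h - 1); y1 <- pmin(y0 + 1, h - 1)
  wx <- gx - x0; wy <- gy - y0
  # the grid is separable, so vector-indexed submatrices give the output
  i0 <- as.integer(y0) + 1L; i1 <- as.integer(y1) + 1L
  j0 <- as.integer(x0) + 1L; j1 <- as.integer(x1) + 1L
  sample_channel <- function(ch) {
    outer(1 - wy, 1 - wx) * ch[i0, j0, drop = FALSE] +
      outer(1 - wy, wx) * ch[i0, j1, drop = FALSE] +
      outer(wy, 1 - wx) * ch[i1, j0, drop = FALSE] +
      outer(wy, wx) * ch[i1, j1, drop = FALSE]
  }
  if (length(dim(image)) == 2) {
    sample_channel(image)
  } else {
    out <- array(0, dim = c(out_size, out_size, dim(image)[3]))
    for (k in seq_len(dim(image)[3])) {
      out[, , k] <- sample_channel(image[, , k])
    }
    out
  }
}

#' Construct a K-shot support set from labelled crops
#'
#' @param crops List of square numeric rasters sharing one side length.
#' @param labels Character vector of class labels, one per crop. Every class
#'   must occur the same number of times `k`.
#' @return An object of class `od_support`: a tibble with columns `class`
#'   and `crop` (list-column), with attributes `k` and `out_size`.
#' @export
support_set <- function(crops, labels) {
  labels <- as.character(labels)
  if (length(crops) != length(labels) || length(crops) == 0) {
    rlang::abort("`crops` and `labels` must be non-empty and equal-length")
  }
  sizes <- vapply(crops, function(x) dim(x)[1], numeric(1))
  widths <- vapply(crops, function(x) dim(x)[2], numeric(1))
  if (length(unique(c(sizes, widths))) != 1) {
    rlang::abort("all support crops must be square and share one size")
  }
  counts <- table(labels)
  if (length(unique(as.integer(counts))) != 1) {
    rlang::abort(paste0("unequal shots per class: ",
                        paste(sprintf("%s=%d", names(counts),
                                      as.integer(counts)), collapse = ", ")))
  }
  out <- tibble::tibble(class = labels, crop = crops)
  attr(out, "k") <- as.integer(counts[1])
  attr(out, "out_size") <- as.integer(sizes[1])
  class(out) <- c("od_support", class(out))
  out
}

#' @export
#' @rdname support_set
#' @param support An `od_support` object.
support_classes <- function(support) {
  stopifnot(inherits(support, "od_support"))
  sort(unique(support$class))
}

#' @export
print.od_support <- function(x, ...) {
  cat("<od_support> k = ", attr(x, "k"), " crops per class, ",
      length(support_classes(x)), " classes, ",
      attr(x, "out_size"), "px crops\n", sep = "")
  invisible(x)
}

#' Sample a K-shot support set from an example split
#'
#' Uniformly samples `k` ground-truth boxes per class (without replacement)
#' from the example images, then extracts each as a padded, clipped,
#' bilinearly resized crop. Deterministic per `seed`; classes are processed
#' in class-universe order so the draw is reproducible.
#'
#' @param pool An [od_pool()] restricted to the example (support) split.
#' @param images Named list of rasters keyed by `image_id`, covering every
#'   image of `pool`.
#' @param k Shots per class. Every class of the pool universe must have at
#'   least `k` boxes in the pool.
#' @param seed Integer seed for the draw (the study protocol samples shots
#'   with fixed seeds such as 42, 123, 456).
#' @param pad,out_size Crop extraction parameters, see [pad_and_clip()] and
#'   [crop_and_resize()].
#' @return An `od_support` set with exactly `k` crops per class.
#' @export
sample_support <- function(pool, images, k, seed, pad = 10, out_size = 128) {
  stopifnot(is_od_pool(pool), k >= 1)
  missing_imgs <- setdiff(unique(pool$boxes$image_id), names(images))
  if (length(missing_imgs) > 0) {
    rlang::abort(paste0("missing rasters for image(s): ",
                        paste(utils::head(missing_imgs, 5), collapse = ", ")))
  }
  counts <- class_box_counts(pool)
  short <- counts$class[counts$n_boxes < k]
  if (length(short) > 0) {
    rlang::abort(paste0("class(es) with fewer than k = ", k, " boxes: ",
                        paste(short, collapse = ", ")))
  }
  picks <- withr::with_seed(seed, {
    lapply(pool$classes, function(cl) {
      rows <- which(pool$boxes$class == cl)
      rows[sample.int(length(rows), k)]
    })
  })
  rows <- unlist(picks, use.names = FALSE)
  crops <- lapply(rows, function(r) {
    b <- pool$boxes[r, ]
    img <- images[[b$image_id]]
    padded <- pad_and_clip(b, pad = pad, width = image_width(img),
                           height = image_height(img))
    crop_and_resize(img, padded, out_size = out_size)
  })
  support_set(crops, pool$boxes$class[rows])
}

#' Run the crop-and-classify cascade on one image
#'
#' The cascaded few-shot detection pipeline: each class-agnostic proposal
#' box is expanded by `pad` pixels, clipped, cropped, bilinearly resized to
#' `out_size`, and handed to the classifier together with the support set.
#' The emitted detection reuses the proposal's original (unpadded) box —
#' padding is classifier context, not a localization refinement — with the
#' assigned label and confidence. Exactly one detection per proposal, in
#' proposal order.
#'
#' @param image Numeric raster on `[0, 1]`.
#' @param proposals Data frame of proposal boxes (corner convention), e.g.
#'   externally precomputed segmentation proposals read with
#'   [read_coco_detections()].
#' @param classifier A function `(crop, support) -> list(class_label,
#'   confidence)`; see [baseline_classifier()] for the contract.
#' @param support An `od_support` set.
#' @param image_id Id attached to the emitted detections.
#' @param pad,out_size Crop extraction parameters.
#' @return A detections tibble (one row per proposal).
#' @export
run_cascade <- function(image, proposals, classifier, support,
                        image_id = "image", pad = 10, out_size = 128) {
  stopifnot(inherits(support, "od_support"), is.function(classifier))
  proposals <- tibble::as_tibble(proposals)
  if (nrow(proposals) == 0) return(empty_detections())
  w <- image_width(image); h <- image_height(image)
  classes <- support_classes(support)
  out <- purrr::map_dfr(seq_len(nrow(proposals)), function(i) {
    b <- proposals[i, ]
    padded <- pad_and_clip(b, pad = pad, width = w, height = h)
    crop <- crop_and_resize(image, padded, out_size = out_size)
    res <- classifier(crop, support)
    if (!res[[1]] %in% classes) {
      rlang::abort(paste0("classifier returned label outside the support ",
                          "classes: '", res[[1]], "'"))
    }
    conf <- as.numeric(res[[2]])
    if (is.na(conf) || conf < 0 || conf > 1) {
      rlang::abort("classifier confidence must lie in [0,1]")
    }
    tibble::tibble(image_id = image_id, class = as.character(res[[1]]),
                   score = conf, x_min = b$x_min, y_min = b$y_min,
                   x_max = b$x_max, y_max = b$y_max)
  })
  out
}

#' Nearest-centroid baseline crop classifier
#'
#' A deterministic, training-free stand-in for an external few-shot
#' classifier, usable wherever the cascade expects a
#' `(crop, support) -> (label, confidence)` function. Each crop is mapped to
#' a fixed feature vector — its grayscale intensities mean-pooled to an
#' 8 x 8 grid, plus the overall mean and standard deviation — and assigned
#' to the class whose support-crop centroid is nearest in Euclidean
#' distance. Confidence is the softmax of negative distances at the chosen
#' class. Ties break toward the lexicographically first class label.
#'
#' @param crop Square numeric raster (grayscale or multi-channel).
#' @param support An `od_support` set.
#' @return A list `(class_label, confidence)`.
#' @export
baseline_classifier <- function(crop, support) {
  stopifnot(inherits(support, "od_support"))
  f <- crop_features(crop)
  classes <- support_classes(support)
  centroids <- vapply(classes, function(cl) {
    feats <- vapply(support$crop[support$class == cl], crop_features,
                    numeric(length(f)))
    rowMeans(feats)
  }, numeric(length(f)))
  d <- sqrt(colSums((centroids - f)^2))
  best <- which(d <= min(d) + 1e-12)[1]  # lexicographic tie-break
  p <- exp(-(d - min(d)))
  list(class_label = classes[best],
       confidence = unname(p[best] / sum(p)))
}

# grayscale 8x8 bilinear thumbnail + global mean/sd
crop_features <- function(crop) {
  if (length(dim(crop)) == 3) crop <- apply(crop, c(1, 2), mean)
  thumb <- crop_and_resize(
    crop, list(x_min = 0, y_min = 0,
               x_max = image_width(crop), y_max = image_height(crop)),
    out_size = 8)
  c(as.vector(thumb), mean(crop), stats::sd(as.vector(crop)))
}
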