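#' Bounding-box dataset pools
#'
#' An `od_pool` bundles a table of images with a table of ground-truth
#' bounding boxes and an ordered class universe. It is the central container
#' for split optimization, split scoring, and evaluation.
#'
#' Boxes use continuous corner coordinates `(x_min, y_min, x_max, y_max)`
#' with x rightward and y downward, so `area = (x_max - x_min) * (y_max -
#' y_min)`. A box may touch an image border exactly; boxes extending past a
#' border are rejected at construction so data errors surface early, rather
#' than being clipped silently.
#'
#' @param images A data frame with columns `image_id` (character), `source`
#'   (character tag for the dataset of origin), `width` and `height`
#'   (positive integer pixels).
#' @param boxes A data frame with columns `image_id`, `class`, `x_min`,
#'   `y_min`, `x_max`, `y_max`. May have zero rows.
#' @param classes Optional character vector giving the ordered class
#'   universe. Defaults to the sorted set of labels present in `boxes`. Must
#'   contain every label that appears in `boxes`.
#'
#' @return An object of class `od_pool`: a list with tibbles `images` and
#'   `boxes` and the character vector `classes`.
#' @examples
#' imgs <- tibble::tibble(image_id = c("a", "b"), source = "demo",
#'                        width = 100L, height = 100L)
#' bxs <- tibble::tibble(image_id = c("a", "a", "b"),
#'                       class = c("round", "spindle", "round"),
#'                       x_min = c(10, 40, 5), y_min = c(10, 40, 5),
#'                       x_max = c(30, 60, 25), y_max = c(30, 60, 25))
#' od_pool(imgs, bxs)
#' @export
od_pool <- function(images, boxes, classes = NULL) {
  images <- tibble::as_tibble(images)
  boxes <- tibble::as_tibble(boxes)
  need_img <- c("image_id", "source", "width", "height")
  if (!all(need_img %in% names(images))) {
    rlang::abort(paste0("`images` must have columns ",
                        paste(need_img, collapse = ", ")))
  }
  need_box <- c("image_id", "class", "x_min", "y_min", "x_max", "y_max")
  if (!all(need_box %in% names(boxes))) {
    rlang::abort(paste0("`boxes` must have columns ",
                        paste(need_box, collapse = ", ")))
  }
  images$image_id <- as.character(images$image_id)
  images$source <- as.character(images$source)
  boxes$image_id <- as.character(boxes$image_id)
  boxes$class <- as.character(boxes$class)
  if (anyDuplicated(images$image_id)) {
    rlang::abort("duplicate image_id in `images`")
  }
  if (any(images$width <= 0) || any(images$height <= 0)) {
    rlang::abort("image width and height must be positive")
  }
  if (nrow(boxes) > 0) {
    unknown <- setdiff(boxes$image_id, images$image_id)
    if (length(unknown) > 0) {
      rlang::abort(paste0("boxes reference unknown image_id: ",
                          paste(utils::head(unknown, 5), collapse = ", ")))
    }
    validate_boxes(boxes, images)
  }
  if (is.null(classes)) {
    classes <- sort(unique(boxes$class))
  } else {
    classes <- as.character(classes)
    missing <- setdiff(unique(boxes$class), classes)
    if (length(missing) > 0) {
      rlang::abort(paste0("`classes` must contain every label in `boxes`; ",
                          "missing: ", paste(missing, collapse = ", ")))
    }
    if (anyDuplicated(classes)) rlang::abort("duplicate labels in `classes`")
  }
  structure(list(images = images, boxes = boxes[, need_box],
                 classes = classes),
            class = "od_pool")
}

# box validity incl. image-bound containment; `images` gives per-id bounds
validate_boxes <- function(boxes, images) {
  bad <- !(boxes$x_max > boxes$x_min & boxes$y_max > boxes$y_min &
             boxes$x_min >= 0 & boxes$y_min >= 0)
  if (any(bad)) {
    rlang::abort(paste0("degenerate or negative box(es) on image(s): ",
                        paste(unique(boxes$image_id[bad]), collapse = ", ")))
  }
  dims <- images[match(boxes$image_id, images$image_id), c("width", "height")]
  out <- boxes$x_max > dims$width + 1e-9 | boxes$y_max > dims$height + 1e-9
  if (any(out)) {
    rlang::abort(paste0("box outside image bounds on image(s): ",
                        paste(unique(boxes$image_id[out]), collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.od_pool <- function(x, ...) {
  srcs <- table(x$images$source)
  cat("<od_pool> ", nrow(x$images), " images, ", nrow(x$boxes),
      " boxes, ", length(x$classes), " classes\n", sep = "")
  cat("  sources: ",
      paste(sprintf("%s (%d)", names(srcs), as.integer(srcs)),
            collapse = ", "), "\n", sep = "")
  cat("  classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname od_pool
is_od_pool <- function(x) inherits(x, "od_pool")

#' Restrict a pool to a subset of images
#'
#' @param pool An [od_pool()].
#' @param image_ids Character vector of image ids to keep.
#' @param drop_classes If `TRUE`, restrict the class universe to labels still
#'   present; by default the universe is preserved (a subset of a pool keeps
#'   the frame of reference of the whole pool, which matters for
#'   entropy normalization).
#' @return An `od_pool`.
#' @export
pool_subset <- function(pool, image_ids, drop_classes = FALSE) {
  stopifnot(is_od_pool(pool))
  image_ids <- as.character(image_ids)
  unknown <- setdiff(image_ids, pool$images$image_id)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown image_id: ", paste(unknown, collapse = ", ")))
  }
  images <- pool$images[pool$images$image_id %in% image_ids, ]
  boxes <- pool$boxes[pool$boxes$image_id %in% image_ids, ]
  od_pool(images, boxes,
          classes = if (drop_classes) NULL else pool$classes)
}

#' Per-class box counts of (a subset of) a pool
#'
#' @inheritParams pool_subset
#' @param image_ids Optional image ids; defaults to the whole pool.
#' @return A tibble with columns `class` and `n_boxes`, one row per class in
#'   the pool's universe (zero counts included), in universe order.
#' @export
class_box_counts <- function(pool, image_ids = NULL) {
  stopifnot(is_od_pool(pool))
  boxes <- pool$boxes
  if (!is.null(image_ids)) boxes <- boxes[boxes$image_id %in% image_ids, ]
  tab <- table(factor(boxes$class, levels = pool$classes))
  tibble::tibble(class = pool$classes, n_boxes = as.integer(tab))
}

#' @export
tidy.od_pool <- function(x, ...) {
  dplyr::left_join(x$boxes, x$images, by = "image_id")
}

#' @export
glance.od_pool <- function(x, ...) {
  tibble::tibble(n_images = nrow(x$images), n_boxes = nrow(x$boxes),
                 n_classes = length(x$classes),
                 n_sources = length(unique(x$images$source)))
}
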