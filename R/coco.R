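#' Read COCO-style annotations into a pool
#'
#' Parses a COCO-dialect JSON file (top-level `images`, `annotations` and
#' `categories` arrays, with `bbox` stored as `[x, y, width, height]`) and
#' converts boxes to the internal corner convention: `x_max = x + w`,
#' `y_max = y + h`. A non-standard per-image `source` field, if present, is
#' preserved as the dataset-of-origin tag; otherwise every image is tagged
#' `"default"`.
#'
#' Boxes that extend beyond their image bounds are a validation error (they
#' are never clipped), as are annotations referencing unknown images or
#' categories.
#'
#' @param path Path to a COCO JSON file.
#' @return An [od_pool()]. The class universe is ordered by category id.
#' @seealso [write_coco_annotations()], [read_coco_detections()]
#' @export
read_coco_annotations <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    rlang::abort(paste0("failed to parse '", path, "': ",
                                        conditionMessage(e)))
                  })
  for (key in c("images", "annotations", "categories")) {
    if (is.null(doc[[key]])) {
      rlang::abort(paste0("malformed COCO file: missing '", key, "' array"))
    }
  }
  cats <- purrr::map_dfr(doc$categories, function(x) {
    if (is.null(x$id) || is.null(x$name)) {
      rlang::abort("malformed COCO category record (needs id, name)")
    }
    tibble::tibble(category_id = as.integer(x$id), name = as.character(x$name))
  })
  cats <- cats[order(cats$category_id), ]
  images <- purrr::map_dfr(doc$images, function(x) {
    if (is.null(x$id) || is.null(x$width) || is.null(x$height)) {
      rlang::abort("malformed COCO image record (needs id, width, height)")
    }
    tibble::tibble(image_id = as.character(x$id),
                   source = as.character(x$source %||% "default"),
                   width = as.integer(x$width),
                   height = as.integer(x$height))
  })
  if (nrow(images) == 0) {
    images <- tibble::tibble(image_id = character(), source = character(),
                             width = integer(), height = integer())
  }
  boxes <- purrr::map_dfr(doc$annotations, function(x) {
    if (is.null(x$image_id) || is.null(x$category_id) ||
        length(x$bbox) != 4) {
      rlang::abort(paste0("malformed COCO annotation record",
                          if (!is.null(x$id)) paste0(" (id ", x$id, ")")))
    }
    idx <- match(as.integer(x$category_id), cats$category_id)
    if (is.na(idx)) {
      rlang::abort(paste0("annotation references unknown category_id ",
                          x$category_id))
    }
    b <- as.numeric(x$bbox)
    tibble::tibble(image_id = as.character(x$image_id),
                   class = cats$name[idx],
                   x_min = b[1], y_min = b[2],
                   x_max = b[1] + b[3], y_max = b[2] + b[4])
  })
  if (nrow(boxes) == 0) {
    boxes <- tibble::tibble(image_id = character(), class = character(),
                            x_min = double(), y_min = double(),
                            x_max = double(), y_max = double())
  }
  od_pool(images, boxes, classes = cats$name)
}

#' Write a pool as COCO-style annotations
#'
#' Inverse of [read_coco_annotations()]: corner coordinates are converted
#' back to `bbox = [x_min, y_min, width, height]`, categories are numbered in
#' class-universe order, and the per-image `source` tag is written alongside
#' the standard fields so a round trip reproduces the pool field-for-field.
#'
#' @param pool An [od_pool()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coco_annotations <- function(pool, path) {
  stopifnot(is_od_pool(pool))
  cat_id <- seq_along(pool$classes)
  names(cat_id) <- pool$classes
  images <- purrr::pmap(pool$images, function(image_id, source, width, height) {
    list(id = coco_id(image_id), source = source,
         width = as.integer(width), height = as.integer(height),
         file_name = paste0(image_id, ".png"))
  })
  annotations <- purrr::pmap(
    cbind(pool$boxes, ann_id = seq_len(nrow(pool$boxes))),
    function(image_id, class, x_min, y_min, x_max, y_max, ann_id) {
      list(id = as.integer(ann_id), image_id = coco_id(image_id),
           category_id = unname(cat_id[class]),
           bbox = c(x_min, y_min, x_max - x_min, y_max - y_min),
           area = (x_max - x_min) * (y_max - y_min), iscrowd = 0L)
    })
  categories <- purrr::map2(unname(cat_id), pool$classes, function(id, name) {
    list(id = id, name = name)
  })
  doc <- list(images = images, annotations = annotations,
              categories = categories)
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) rlang::abort(paste0("could not write '", path, "'"))
  invisible(path)
}

# keep integer-looking ids as integers for interoperability, otherwise strings
coco_id <- function(x) {
  if (grepl("^[0-9]+$", x)) as.integer(x) else x
}

#' Read COCO-style detection results
#'
#' Parses a COCO results file (a bare JSON array of records with `image_id`,
#' `category_id`, `bbox` and `score`) into a detections tibble, converting
#' `bbox = [x, y, w, h]` to corner coordinates. Record order is preserved.
#'
#' @param path Path to a results JSON file.
#' @param categories Mapping from `category_id` to class label: either an
#'   [od_pool()] (categories numbered in class-universe order, as written by
#'   [write_coco_annotations()]) or a data frame with columns `category_id`
#'   and `name`. If `NULL`, category ids are used verbatim as labels.
#' @return A tibble with columns `image_id`, `class`, `score`, `x_min`,
#'   `y_min`, `x_max`, `y_max`.
#' @export
read_coco_detections <- function(path, categories = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  recs <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                   error = function(e) {
                     rlang::abort(paste0("failed to parse '", path, "': ",
                                         conditionMessage(e)))
                   })
  lookup <- NULL
  if (is_od_pool(categories)) {
    lookup <- tibble::tibble(category_id = seq_along(categories$classes),
                             name = categories$classes)
  } else if (is.data.frame(categories)) {
    lookup <- categories
  }
  out <- purrr::imap_dfr(recs, function(x, i) {
    if (is.null(x$score)) {
      rlang::abort(paste0("detection record ", i, " missing 'score'"))
    }
    s <- as.numeric(x$score)
    if (is.na(s) || s < 0 || s > 1) {
      rlang::abort(paste0("detection record ", i, " has score outside [0,1]"))
    }
    if (length(x$bbox) != 4 || is.null(x$image_id)) {
      rlang::abort(paste0("malformed detection record ", i))
    }
    cid <- as.integer(x$category_id)
    label <- if (is.null(lookup)) {
      as.character(cid)
    } else {
      j <- match(cid, lookup$category_id)
      if (is.na(j)) {
        rlang::abort(paste0("detection record ", i,
                            " references unknown category_id ", cid))
      }
      lookup$name[j]
    }
    b <- as.numeric(x$bbox)
    tibble::tibble(image_id = as.character(x$image_id), class = label,
                   score = s, x_min = b[1], y_min = b[2],
                   x_max = b[1] + b[3], y_max = b[2] + b[4])
  })
  if (nrow(out) == 0) {
    out <- empty_detections()
  }
  out
}

#' Write detections as a COCO results file
#'
#' @param detections A detections tibble (see [read_coco_detections()] for
#'   the columns).
#' @param path Output path.
#' @param categories Same mapping argument as in [read_coco_detections()];
#'   with an [od_pool()], labels are numbered in class-universe order.
#' @return `path`, invisibly.
#' @export
write_coco_detections <- function(detections, path, categories = NULL) {
  detections <- as_detections(detections)
  to_id <- function(label) {
    if (is_od_pool(categories)) {
      i <- match(label, categories$classes)
      if (is.na(i)) rlang::abort(paste0("label not in pool universe: ", label))
      i
    } else if (is.data.frame(categories)) {
      i <- match(label, categories$name)
      if (is.na(i)) rlang::abort(paste0("unknown label: ", label))
      as.integer(categories$category_id[i])
    } else {
      out <- suppressWarnings(as.integer(label))
      if (is.na(out)) rlang::abort("non-integer labels need `categories`")
      out
    }
  }
  recs <- purrr::pmap(detections, function(image_id, class, score,
                                           x_min, y_min, x_max, y_max, ...) {
    list(image_id = coco_id(image_id), category_id = to_id(class),
         bbox = c(x_min, y_min, x_max - x_min, y_max - y_min),
         score = score)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

empty_detections <- function() {
  tibble::tibble(image_id = character(), class = character(),
                 score = double(), x_min = double(), y_min = double(),
                 x_max = double(), y_max = double())
}

# coerce and check a detections data frame
as_detections <- function(detections) {
  detections <- tibble::as_tibble(detections)
  need <- c("image_id", "class", "score", "x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(detections))) {
    rlang::abort(paste0("detections must have columns ",
                        paste(need, collapse = ", ")))
  }
  detections$image_id <- as.character(detections$image_id)
  detections$class <- as.character(detections$class)
  if (nrow(detections) > 0) {
    if (any(detections$score < 0 | detections$score > 1)) {
      rlang::abort("detection scores must lie in [0,1]")
    }
    if (any(detections$x_max <= detections$x_min |
              detections$y_max <= detections$y_min)) {
      rlang::abort("degenerate detection box(es)")
    }
  }
  detections[, need]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
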