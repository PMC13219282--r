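#' Default class palette for synthetic microscopy fixtures
#'
#' Five cell morphologies with deliberately imbalanced abundances, so that
#' rare-class behaviour of the split optimizer and of the class-balance
#' entropy is exercised: an abundant small round type (red-blood-cell-like),
#' a rarer large round type, dark elongated spindles, mid-tone polygonal
#' cells, and a rare bright ring-like type.
#'
#' @return A tibble with columns `label`, `radius` (mean semi-major axis,
#'   px), `eccentricity` (minor/major axis ratio in (0, 1]), `intensity`
#'   (mean fill intensity on `[0, 1]`) and `weight` (relative abundance).
#' @export
default_classes <- function() {
  tibble::tibble(
    label = c("round_small", "round_large", "spindle", "polygonal", "ring"),
    radius = c(6, 14, 10, 12, 8),
    eccentricity = c(0.9, 0.85, 0.35, 0.7, 0.95),
    intensity = c(0.55, 0.85, 0.3, 0.65, 0.95),
    weight = c(0.45, 0.1, 0.2, 0.2, 0.05))
}

#' Configuration for the synthetic fixture generator
#'
#' Defaults emulate the benchmark's study conditions: four source pools of
#' 63 images each (so a 53/10 test/support split per source), dense fields
#' of small elliptical cells with imbalanced class abundances.
#'
#' @param n_images Images per source.
#' @param sources Character vector of source names.
#' @param classes Class palette tibble, see [default_classes()].
#' @param cells_per_image Length-2 integer range; each image draws its cell
#'   count uniformly from it.
#' @param image_size Side length of the square images, px.
#' @param background Mean background intensity.
#' @param noise_sd Gaussian background noise standard deviation.
#' @param seed Integer master seed; every random draw flows from it.
#' @return A list of class `od_fixture_config`.
#' @export
fixture_config <- function(n_images = 63,
                           sources = c("brightfield_a", "brightfield_b",
                                       "phasecontrast_a", "phasecontrast_b"),
                           classes = default_classes(),
                           cells_per_image = c(8, 30),
                           image_size = 384,
                           background = 0.15,
                           noise_sd = 0.03,
                           seed = 1) {
  classes <- tibble::as_tibble(classes)
  need <- c("label", "radius", "eccentricity", "intensity", "weight")
  if (!all(need %in% names(classes))) {
    rlang::abort(paste0("`classes` needs columns ",
                        paste(need, collapse = ", ")))
  }
  if (anyDuplicated(classes$label)) rlang::abort("duplicate class labels")
  stopifnot(all(classes$radius > 0), all(classes$weight > 0),
            all(classes$intensity >= 0), all(classes$intensity <= 1),
            all(classes$eccentricity > 0), all(classes$eccentricity <= 1),
            length(cells_per_image) == 2,
            cells_per_image[1] >= 0,
            cells_per_image[2] >= cells_per_image[1],
            image_size >= 8, n_images >= 0)
  if (any(2 * classes$radius * 1.2 >= image_size)) {
    rlang::abort("cells cannot fit: a class radius exceeds the image size")
  }
  structure(list(n_images = as.integer(n_images),
                 sources = as.character(sources),
                 classes = classes,
                 cells_per_image = as.integer(cells_per_image),
                 image_size = as.integer(image_size),
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "od_fixture_config")
}

#' Generate a synthetic annotated microscopy dataset
#'
#' Draws, for every image of every source, a set of elliptical cells with
#' class-dependent size, elongation and intensity (plus per-cell jitter and
#' random orientation), records each cell's tight bounding box and label,
#' and optionally renders anti-aliased rasters over a noisy background.
#' Cells may overlap, emulating dense microscopy fields. The annotation
#' stream and the pixel-noise stream are seeded separately from the master
#' seed, so the returned pool is bit-identical whether or not rasters are
#' rendered, and two calls with the same config are bit-identical
#' throughout.
#'
#' @param config An [fixture_config()].
#' @param render If `FALSE`, skip rasterization and return `images = NULL`
#'   (the pool alone is enough for split optimization and metric studies).
#' @return A list with `pool` (an [od_pool()]) and `images` (named list of
#'   `image_size x image_size` matrices, or `NULL`).
#' @examples
#' ds <- generate_dataset(fixture_config(n_images = 2, sources = "demo",
#'                                       image_size = 96, seed = 42))
#' ds$pool
#' @export
generate_dataset <- function(config = fixture_config(), render = TRUE) {
  stopifnot(inherits(config, "od_fixture_config"))
  size <- config$image_size
  cls <- config$classes
  cells <- withr::with_seed(config$seed, {
    purrr::map_dfr(config$sources, function(src) {
      purrr::map_dfr(seq_len(config$n_images), function(i) {
        id <- sprintf("%s_%03d", src, i)
        n_cells <- sample.int(config$cells_per_image[2] -
                                config$cells_per_image[1] + 1L, 1L) +
          config$cells_per_image[1] - 1L
        if (n_cells == 0) {
          return(tibble::tibble(image_id = character(), source = character()))
        }
        k <- sample.int(nrow(cls), n_cells, replace = TRUE,
                        prob = cls$weight)
        a <- cls$radius[k] * stats::runif(n_cells, 0.85, 1.15)
        b <- a * cls$eccentricity[k] * stats::runif(n_cells, 0.9, 1.1)
        theta <- stats::runif(n_cells, 0, pi)
        hx <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
        hy <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
        cx <- stats::runif(n_cells, hx, size - hx)
        cy <- stats::runif(n_cells, hy, size - hy)
        intensity <- pmin(1, pmax(0, cls$intensity[k] +
                                    stats::runif(n_cells, -0.08, 0.08)))
        tibble::tibble(image_id = id, source = src, class = cls$label[k],
                       cx = cx, cy = cy, a = a, b = b, theta = theta,
                       intensity = intensity,
                       x_min = cx - hx, y_min = cy - hy,
                       x_max = cx + hx, y_max = cy + hy)
      })
    })
  })
  images_tbl <- tibble::tibble(
    image_id = as.vector(vapply(config$sources, function(src) {
      sprintf("%s_%03d", src, seq_len(config$n_images))
    }, character(config$n_images))),
    source = rep(config$sources, each = config$n_images),
    width = size, height = size)
  boxes <- if (nrow(cells) > 0) {
    cells[, c("image_id", "class", "x_min", "y_min", "x_max", "y_max")]
  } else {
    tibble::tibble(image_id = character(), class = character(),
                   x_min = double(), y_min = double(),
                   x_max = double(), y_max = double())
  }
  pool <- od_pool(images_tbl, boxes, classes = cls$label)
  images <- NULL
  if (render && nrow(images_tbl) > 0) {
    images <- withr::with_seed(config$seed + 1L, {
      out <- lapply(images_tbl$image_id, function(id) {
        render_cells(cells[cells$image_id == id, ], size,
                     config$background, config$noise_sd)
      })
      names(out) <- images_tbl$image_id
      out
    })
  }
  list(pool = pool, images = images)
}

# paint anti-aliased filled ellipses over a noisy background
render_cells <- function(cells, size, background, noise_sd) {
  img <- matrix(background + stats::rnorm(size * size, 0, noise_sd),
                size, size)
  for (r in seq_len(nrow(cells))) {
    x0 <- max(1L, floor(cells$x_min[r])); x1 <- min(size, ceiling(cells$x_max[r]))
    y0 <- max(1L, floor(cells$y_min[r])); y1 <- min(size, ceiling(cells$y_max[r]))
    xs <- seq(x0, x1) - 0.5  # pixel centers
    ys <- seq(y0, y1) - 0.5
    dx <- outer(rep(1, length(ys)), xs - cells$cx[r])
    dy <- outer(ys - cells$cy[r], rep(1, length(xs)))
    ct <- cos(cells$theta[r]); st <- sin(cells$theta[r])
    u <- (dx * ct + dy * st) / cells$a[r]
    v <- (-dx * st + dy * ct) / cells$b[r]
    q <- sqrt(u^2 + v^2)
    # approximate signed distance (px) to the ellipse boundary; 1px feather
    sd_px <- (q - 1) * min(cells$a[r], cells$b[r])
    alpha <- pmin(pmax(0.5 - sd_px, 0), 1)
    block <- img[y0:y1, x0:x1, drop = FALSE]
    img[y0:y1, x0:x1] <- block * (1 - alpha) + cells$intensity[r] * alpha
  }
  pmin(pmax(img, 0), 1)  # pmin/pmax keep dim only from their first argument
}

#' Corrupt ground truth into synthetic detections
#'
#' Produces a detections tibble from a pool's ground truth under a
#' controllable noise model: each box is independently dropped with
#' probability `drop_rate`; surviving boxes get i.i.d. Gaussian jitter of sd
#' `jitter_sd` on each coordinate (clipped to the image, degenerate boxes
#' re-inflated to a minimum side of one pixel) and their label flipped to a
#' random other class with probability `label_flip_rate`; and each image
#' gains `Poisson(fp_rate)` spurious boxes with random geometry and class.
#' Surviving true boxes score in `[0.5, 1]`, spurious ones in `[0.05, 0.5]`.
#' Deterministic per `seed`. With all rates and jitter at 0 the output is
#' the ground truth itself (with scores attached).
#'
#' @param pool An [od_pool()].
#' @param jitter_sd Coordinate noise sd, px.
#' @param drop_rate,fp_rate,label_flip_rate Probabilities in `[0, 1]`
#'   (`fp_rate` is a per-image Poisson rate and may exceed 1).
#' @param seed Integer seed.
#' @return A detections tibble.
#' @export
perturb_detections <- function(pool, jitter_sd = 0, drop_rate = 0,
                               fp_rate = 0, label_flip_rate = 0, seed = 1) {
  stopifnot(is_od_pool(pool), jitter_sd >= 0, drop_rate >= 0, drop_rate <= 1,
            fp_rate >= 0, label_flip_rate >= 0, label_flip_rate <= 1)
  classes <- pool$classes
  withr::with_seed(seed, {
    boxes <- dplyr::left_join(pool$boxes, pool$images[, c("image_id", "width",
                                                          "height")],
                              by = "image_id")
    n <- nrow(boxes)
    kept <- if (n > 0) stats::runif(n) >= drop_rate else logical(0)
    boxes <- boxes[kept, ]
    n <- nrow(boxes)
    if (n > 0) {
      if (jitter_sd > 0) {
        boxes$x_min <- boxes$x_min + stats::rnorm(n, 0, jitter_sd)
        boxes$y_min <- boxes$y_min + stats::rnorm(n, 0, jitter_sd)
        boxes$x_max <- boxes$x_max + stats::rnorm(n, 0, jitter_sd)
        boxes$y_max <- boxes$y_max + stats::rnorm(n, 0, jitter_sd)
        boxes <- fix_boxes(boxes)
      }
      flip <- stats::runif(n) < label_flip_rate
      if (any(flip) && length(classes) > 1) {
        boxes$class[flip] <- vapply(boxes$class[flip], function(cl) {
          sample(setdiff(classes, cl), 1)
        }, character(1))
      }
      boxes$score <- stats::runif(n, 0.5, 1)
    }
    spurious <- purrr::map_dfr(seq_len(nrow(pool$images)), function(i) {
      img <- pool$images[i, ]
      m <- stats::rpois(1, fp_rate)
      if (m == 0) return(NULL)
      w <- stats::runif(m, 5, 30)
      h <- stats::runif(m, 5, 30)
      cx <- stats::runif(m, w / 2, img$width - w / 2)
      cy <- stats::runif(m, h / 2, img$height - h / 2)
      tibble::tibble(image_id = img$image_id,
                     class = sample(classes, m, replace = TRUE),
                     score = stats::runif(m, 0.05, 0.5),
                     x_min = cx - w / 2, y_min = cy - h / 2,
                     x_max = cx + w / 2, y_max = cy + h / 2)
    })
    keep_cols <- c("image_id", "class", "score",
                   "x_min", "y_min", "x_max", "y_max")
    out <- dplyr::bind_rows(
      if (n > 0) boxes[, keep_cols] else empty_detections(),
      spurious)
    if (nrow(out) == 0) empty_detections() else out
  })
}

# clip jittered boxes to the image and re-inflate degenerate ones
fix_boxes <- function(boxes) {
  boxes$x_min <- pmax(0, pmin(boxes$x_min, boxes$width - 1))
  boxes$y_min <- pmax(0, pmin(boxes$y_min, boxes$height - 1))
  boxes$x_max <- pmin(boxes$width, pmax(boxes$x_max, 1))
  boxes$y_max <- pmin(boxes$height, pmax(boxes$y_max, 1))
  bad <- boxes$x_max <= boxes$x_min
  if (any(bad)) {
    mid <- (boxes$x_min[bad] + boxes$x_max[bad]) / 2
    boxes$x_min[bad] <- pmax(0, mid - 0.5)
    boxes$x_max[bad] <- boxes$x_min[bad] + 1
  }
  bad <- boxes$y_max <= boxes$y_min
  if (any(bad)) {
    mid <- (boxes$y_min[bad] + boxes$y_max[bad]) / 2
    boxes$y_min[bad] <- pmax(0, mid - 0.5)
    boxes$y_max[bad] <- boxes$y_min[bad] + 1
  }
  boxes
}
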