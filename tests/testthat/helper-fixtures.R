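# Shared fixture builders and independent oracles.

# Build a pool from a compact spec: list(i1 = c(A = 1), i2 = c(A = 1, B = 2))
# gives image i1 with one box of class A, image i2 with one A and two B boxes.
# Boxes are laid out on a grid; geometry is irrelevant to split logic.
make_pool <- function(spec, source = "s", width = 1000L, height = 1000L,
                      classes = NULL) {
  images <- tibble::tibble(image_id = names(spec), source = source,
                           width = width, height = height)
  rows <- list()
  for (id in names(spec)) {
    counts <- spec[[id]]
    k <- 0
    for (cl in names(counts)) {
      for (j in seq_len(counts[[cl]])) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          image_id = id, class = cl,
          x_min = 10 * k, y_min = 0, x_max = 10 * k + 8, y_max = 8)
        k <- k + 1
      }
    }
  }
  boxes <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(image_id = character(), class = character(),
                   x_min = double(), y_min = double(),
                   x_max = double(), y_max = double())
  od_pool(images, boxes, classes = classes)
}

# Random multi-source pool spec for property tests.
random_pool <- function(n_images, n_classes = 3, sources = "s",
                        max_boxes = 4, seed = 1) {
  withr::with_seed(seed, {
    cls <- LETTERS[seq_len(n_classes)]
    pools <- lapply(sources, function(src) {
      spec <- lapply(seq_len(n_images), function(i) {
        present <- cls[stats::runif(n_classes) < 0.6]
        if (length(present) == 0) present <- sample(cls, 1)
        counts <- sample.int(max_boxes, length(present), replace = TRUE)
        names(counts) <- present
        counts
      })
      names(spec) <- sprintf("%s_i%02d", src, seq_len(n_images))
      make_pool(spec, source = src, classes = cls)
    })
    images <- dplyr::bind_rows(lapply(pools, function(p) p$images))
    boxes <- dplyr::bind_rows(lapply(pools, function(p) p$boxes))
    od_pool(images, boxes, classes = cls)
  })
}

# Independent brute-force maximum-total-IoU one-to-one matching: enumerate
# every injective assignment of the smaller side into the larger.
brute_force_match_total <- function(iou) {
  n <- nrow(iou); m <- ncol(iou)
  if (n == 0 || m == 0) return(0)
  if (n > m) return(brute_force_match_total(t(iou)))
  best <- 0
  cols <- utils::combn(m, n, simplify = FALSE)
  perms <- all_perms(n)
  for (cc in cols) {
    for (p in perms) {
      best <- max(best, sum(iou[cbind(seq_len(n), cc[p])]))
    }
  }
  best
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

random_boxes <- function(n, size = 100, seed = 1, classes = "c") {
  withr::with_seed(seed, {
    x <- stats::runif(n, 0, size - 20)
    y <- stats::runif(n, 0, size - 20)
    w <- stats::runif(n, 5, 20)
    h <- stats::runif(n, 5, 20)
    tibble::tibble(image_id = "img", class = sample(classes, n, TRUE),
                   score = stats::runif(n),
                   x_min = x, y_min = y, x_max = x + w, y_max = y + h)
  })
}

# Two visually separable morphologies for cascade tests: bright round cells
# vs dark elongated cells.
separable_classes <- function() {
  tibble::tibble(label = c("bright_round", "dark_elongated"),
                 radius = c(9, 11), eccentricity = c(0.95, 0.3),
                 intensity = c(0.9, 0.25), weight = c(0.5, 0.5))
}
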