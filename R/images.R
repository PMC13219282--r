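#' Read a raster image
#'
#' Reads PNG or TIFF (by extension) into a numeric array with intensities on
#' `[0, 1]`: a `height x width` matrix for grayscale, `height x width x
#' channels` otherwise. Integer-coded files are rescaled on load by the
#' underlying readers.
#'
#' @param path Image path ending in `.png`, `.tif` or `.tiff`.
#' @return A numeric matrix or array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                rlang::abort(paste0("unsupported image format: .", ext)))
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  img
}

#' Write a raster image
#'
#' @param image Numeric matrix or array with intensities on `[0, 1]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image[image < 0] <- 0
  image[image > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(image, path),
         tif = ,
         tiff = tiff::writeTIFF(image, path),
         rlang::abort(paste0("unsupported image format: .", ext)))
  invisible(path)
}

image_height <- function(image) dim(image)[1]
image_width <- function(image) dim(image)[2]

#' Display an image with overlaid boxes
#'
#' @param image Numeric raster on `[0, 1]`.
#' @param boxes Optional data frame of boxes (corner convention), with an
#'   optional `class` column used for the outline colour.
#' @return A ggplot object.
#' @export
plot_image <- function(image, boxes = NULL) {
  h <- image_height(image)
  w <- image_width(image)
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(grDevices::as.raster(pmin(pmax(image, 0), 1)),
                               xmin = 0, xmax = w, ymin = -h, ymax = 0) +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(-h, 0), expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL)
  if (!is.null(boxes) && nrow(boxes) > 0) {
    boxes <- tibble::as_tibble(boxes)
    if (!"class" %in% names(boxes)) boxes$class <- "box"
    p <- p + ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = -.data$y_max, ymax = -.data$y_min,
                   colour = .data$class),
      fill = NA, linewidth = 0.4)
  }
  p
}
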