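#' Micrograph objects
#'
#' A micrograph is a grayscale pixel grid in `[0, 1]` with an image id and an
#' optional [calibration()]. 8-bit input (0..255) is rescaled on construction;
#' RGB arrays are converted to luminance. Coordinates throughout the package
#' are 0-based with `x` the column and `y` the row, origin at the top-left
#' pixel center.
#'
#' @param pixels Numeric matrix (rows = y, columns = x) in `[0, 1]` or
#'   integers in 0..255, or an RGB array `h x w x 3`.
#' @param image_id Character scalar identifier.
#' @param calibration Optional [calibration()]; when present its pixel
#'   dimensions must match the pixel grid.
#' @return An object of class `"micrograph"` with elements `image_id`,
#'   `pixels` (matrix in `[0, 1]`), `calibration` (or `NULL`).
#' @export
micrograph <- function(pixels, image_id = "img", calibration = NULL) {
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    d3 <- dim(pixels)[3L]
    if (d3 < 3L) pixels <- pixels[, , 1L]
    else pixels <- 0.299 * pixels[, , 1L] + 0.587 * pixels[, , 2L] +
        0.114 * pixels[, , 3L]
  }
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix or an h x w x 3 array", call. = FALSE)
  }
  pixels <- unname(pixels)
  mx <- suppressWarnings(max(pixels))
  if (is.finite(mx) && mx > 1) pixels <- pixels / 255
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1 + 1e-9) {
    stop("pixel intensities must lie in [0, 255] (8-bit) or [0, 1]",
         call. = FALSE)
  }
  pixels[pixels > 1] <- 1
  if (!is.null(calibration)) {
    stopifnot_calibration(calibration)
    if (calibration$image_width_px != ncol(pixels) ||
        calibration$image_height_px != nrow(pixels)) {
      stop(sprintf(
        "calibration is %d x %d px but image is %d x %d px",
        calibration$image_width_px, calibration$image_height_px,
        ncol(pixels), nrow(pixels)), call. = FALSE)
    }
  }
  structure(list(image_id = as.character(image_id), pixels = pixels,
                 calibration = calibration),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("micrograph '%s': %d x %d px%s\n", x$image_id,
              ncol(x$pixels), nrow(x$pixels),
              if (is.null(x$calibration)) " (uncalibrated)" else
                sprintf(", %.4f um/px", um_per_px(x$calibration))))
  invisible(x)
}

micrograph_width <- function(m) ncol(m$pixels)
micrograph_height <- function(m) nrow(m$pixels)

#' Ground-truth stoma annotations
#'
#' Builds and validates a table of stoma center annotations. Each row marks
#' one stoma by its center (0-based pixel coordinates, x = column, y = row)
#' and the approximate extent of its major axis in pixels. `length_px`
#' defaults to 120 (the patch size) when unknown.
#'
#' @param image_id Character vector.
#' @param x_px,y_px Numeric center coordinates.
#' @param length_px Numeric major-axis extents; `NA` entries are replaced by
#'   the 120 px default.
#' @param width_px,height_px Optional image dimensions for bounds checking.
#' @return A `data.frame` of class `"stoma_annotations"` with columns
#'   `image_id`, `x_px`, `y_px`, `length_px`.
#' @export
stoma_annotations <- function(image_id = character(), x_px = numeric(),
                              y_px = numeric(), length_px = NULL,
                              width_px = NULL, height_px = NULL) {
  n <- length(x_px)
  if (length(y_px) != n) stop("x_px and y_px lengths differ", call. = FALSE)
  image_id <- rep_len(as.character(image_id), n)
  if (is.null(length_px)) length_px <- rep(120, n)
  length_px <- rep_len(as.numeric(length_px), n)
  length_px[is.na(length_px)] <- 120
  bad <- which(!is.finite(x_px) | !is.finite(y_px) | x_px < 0 | y_px < 0 |
                 length_px <= 0)
  if (!is.null(width_px)) bad <- union(bad, which(x_px >= width_px))
  if (!is.null(height_px)) bad <- union(bad, which(y_px >= height_px))
  if (length(bad)) {
    stop(sprintf(
      "invalid annotation row(s) %s: need 0 <= x < width, 0 <= y < height, length_px > 0",
      paste(sort(bad), collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(image_id = image_id, x_px = as.numeric(x_px),
                    y_px = as.numeric(y_px), length_px = length_px,
                    stringsAsFactors = FALSE)
  class(out) <- c("stoma_annotations", "data.frame")
  out
}
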