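#' Microscope calibration: pixels to micrometers
#'
#' A calibration ties the pixel grid of a micrograph to physical dimensions
#' of the microscope view field. The default values correspond to a digital
#' light microscope at 1000x magnification producing 1,600 x 1,200 px images
#' of a 344 x 258 um field (about 0.09 mm^2).
#'
#' The micrometer-per-pixel ratio is expected to be (nearly) identical along
#' both axes; a discrepancy above 2 percent triggers a warning because it
#' usually indicates mismatched image/field dimensions rather than true
#' anisotropic optics.
#'
#' @param image_width_px,image_height_px Image size in pixels.
#' @param field_width_um,field_height_um Physical view-field size in
#'   micrometers.
#' @return An object of class `"calibration"`.
#' @examples
#' cal <- calibration()
#' view_field_area_mm2(cal)
#' um_per_px(cal)
#' @export
calibration <- function(image_width_px = 1600L, image_height_px = 1200L,
                        field_width_um = 344, field_height_um = 258) {
  image_width_px <- as.integer(image_width_px)
  image_height_px <- as.integer(image_height_px)
  field_width_um <- as.numeric(field_width_um)
  field_height_um <- as.numeric(field_height_um)
  vals <- c(image_width_px, image_height_px, field_width_um, field_height_um)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid calibration: all dimensions must be strictly positive",
         call. = FALSE)
  }
  rx <- field_width_um / image_width_px
  ry <- field_height_um / image_height_px
  if (abs(rx - ry) / min(rx, ry) > 0.02) {
    warning(sprintf(
      "calibration is anisotropic: %.4f um/px (x) vs %.4f um/px (y) differ by more than 2%%",
      rx, ry), call. = FALSE)
  }
  structure(
    list(image_width_px = image_width_px, image_height_px = image_height_px,
         field_width_um = field_width_um, field_height_um = field_height_um),
    class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %d x %d px = %.1f x %.1f um (%.4f um/px, %.6f mm^2)\n",
              x$image_width_px, x$image_height_px,
              x$field_width_um, x$field_height_um,
              um_per_px(x), view_field_area_mm2(x)))
  invisible(x)
}

stopifnot_calibration <- function(cal) {
  if (!inherits(cal, "calibration")) {
    stop("expected a 'calibration' object; see ?calibration", call. = FALSE)
  }
  cal
}

#' View-field area in square millimeters
#'
#' Area of the calibrated microscope view field, unrounded
#' (`field_width_um * field_height_um / 1e6`). The default calibration gives
#' 0.088752 mm^2, i.e. 0.09 mm^2 at two decimals.
#'
#' @param cal A [calibration()] object.
#' @return Area in mm^2 (numeric scalar, unrounded).
#' @export
view_field_area_mm2 <- function(cal) {
  stopifnot_calibration(cal)
  cal$field_width_um * cal$field_height_um / 1e6
}

#' Mean micrometers per pixel
#'
#' Mean of the width and height um/px ratios. A warning about anisotropy is
#' emitted at [calibration()] construction time, not here.
#'
#' @param cal A [calibration()] object.
#' @return um per pixel (numeric scalar).
#' @export
um_per_px <- function(cal) {
  stopifnot_calibration(cal)
  (cal$field_width_um / cal$image_width_px +
     cal$field_height_um / cal$image_height_px) / 2
}

#' Stomatal density
#'
#' Converts a stomata count over a known leaf area into stomata per square
#' millimeter, the standard reporting unit for stomatal density.
#'
#' @param count Non-negative integer count of stomata.
#' @param area_mm2 Positive area in mm^2 (e.g. [view_field_area_mm2()]).
#' @return Density in stomata/mm^2.
#' @examples
#' density_per_mm2(62, view_field_area_mm2(calibration()))
#' @export
density_per_mm2 <- function(count, area_mm2) {
  if (length(count) != 1L || !is.finite(count) || count < 0 ||
      count != trunc(count)) {
    stop("count must be a single non-negative integer", call. = FALSE)
  }
  if (length(area_mm2) != 1L || !is.finite(area_mm2) || area_mm2 <= 0) {
    stop("area_mm2 must be a single positive number", call. = FALSE)
  }
  count / area_mm2
}

#' Per-image density results
#'
#' Bundles per-image stomata counts with the imaged area and the derived
#' density. `area_mm2` is kept unrounded; round only when reporting.
#'
#' @param image_id Character vector of image identifiers.
#' @param count Integer vector of stomata counts (same length).
#' @param area_mm2 Single area in mm^2 applying to every image, or a vector.
#' @return A `data.frame` with columns `image_id`, `count`, `area_mm2`,
#'   `density_per_mm2`.
#' @export
density_result <- function(image_id, count, area_mm2) {
  n <- length(image_id)
  if (length(count) != n) stop("image_id and count lengths differ", call. = FALSE)
  area_mm2 <- rep_len(as.numeric(area_mm2), n)
  dens <- mapply(density_per_mm2, as.numeric(count), area_mm2)
  data.frame(image_id = as.character(image_id), count = as.integer(count),
             area_mm2 = area_mm2, density_per_mm2 = as.numeric(dens),
             stringsAsFactors = FALSE)
}
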