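#' Sliding-window patch configuration
#'
#' Windows of `patch_size_px` are placed at offsets `0, s, 2s, ...` along
#' each axis. With `flush = TRUE` an extra window is placed flush against
#' each border whenever `(dim - size)` is not a multiple of the stride, so
#' that every pixel is covered.
#'
#' The 120 px default matches the average stoma size the workflow targets;
#' the 30 px stride (a quarter patch) trades localization granularity
#' against the number of windows to score.
#'
#' @param patch_size_px Window side length in px (default 120).
#' @param stride_px Step between window origins, `1 <= stride <= size`.
#' @param flush Add border-flush windows (default `FALSE`).
#' @return An object of class `"patch_config"`.
#' @export
patch_config <- function(patch_size_px = 120L, stride_px = 30L, flush = FALSE) {
  patch_size_px <- as.integer(patch_size_px)
  stride_px <- as.integer(stride_px)
  if (patch_size_px < 1L) stop("patch_size_px must be >= 1", call. = FALSE)
  if (stride_px < 1L || stride_px > patch_size_px) {
    stop("stride_px must satisfy 1 <= stride <= patch size", call. = FALSE)
  }
  structure(list(patch_size_px = patch_size_px, stride_px = stride_px,
                 flush = isTRUE(flush)),
            class = "patch_config")
}

window_offsets <- function(dim, size, stride, flush) {
  if (dim < size) {
    stop(sprintf("image dimension %d px is smaller than the %d px patch",
                 dim, size), call. = FALSE)
  }
  offs <- seq.int(0L, dim - size, by = stride)
  if (flush && (dim - size) %% stride != 0L) offs <- c(offs, dim - size)
  offs
}

## Row-major grid of window origins (x varies fastest).
window_grid <- function(width, height, cfg) {
  xo <- window_offsets(width, cfg$patch_size_px, cfg$stride_px, cfg$flush)
  yo <- window_offsets(height, cfg$patch_size_px, cfg$stride_px, cfg$flush)
  expand.grid(x0 = xo, y0 = yo, KEEP.OUT.ATTRS = FALSE)
}

new_patch <- function(image_id, x0, y0, size, pixels = NULL) {
  structure(list(image_id = image_id, x0 = as.integer(x0), y0 = as.integer(y0),
                 size = as.integer(size), pixels = pixels),
            class = "patch")
}

patch_pixels_at <- function(m, x0, y0, size) {
  m$pixels[(y0 + 1L):(y0 + size), (x0 + 1L):(x0 + size), drop = FALSE]
}

#' Extract sliding-window patches from a micrograph
#'
#' Returns the row-major grid of overlapping windows. With the default
#' configuration (no flush windows) the count is
#' `(floor((W - P) / s) + 1) * (floor((H - P) / s) + 1)`.
#'
#' @param m A [micrograph()].
#' @param cfg A [patch_config()].
#' @param pixels Materialize pixel grids (`TRUE`, default) or return
#'   coordinate-only patches (`FALSE`), useful for large scans.
#' @return A list of `"patch"` objects (`image_id`, `x0`, `y0`, `size`,
#'   `pixels`).
#' @export
extract_patches <- function(m, cfg = patch_config(), pixels = TRUE) {
  stopifnot(inherits(m, "micrograph"), inherits(cfg, "patch_config"))
  grid <- window_grid(micrograph_width(m), micrograph_height(m), cfg)
  P <- cfg$patch_size_px
  lapply(seq_len(nrow(grid)), function(i) {
    new_patch(m$image_id, grid$x0[i], grid$y0[i], P,
              if (pixels) patch_pixels_at(m, grid$x0[i], grid$y0[i], P))
  })
}

## Vectorized labeling of a window grid against annotations: a window is
## positive iff it fully contains the axis-aligned square of side length_px
## centered on at least one stoma.
label_window_grid <- function(grid, anns, size) {
  pos <- logical(nrow(grid))
  for (i in seq_len(nrow(anns))) {
    L2 <- anns$length_px[i] / 2
    pos <- pos | (grid$x0 <= anns$x_px[i] - L2 &
                    grid$x0 + size >= anns$x_px[i] + L2 &
                    grid$y0 <= anns$y_px[i] - L2 &
                    grid$y0 + size >= anns$y_px[i] + L2)
  }
  pos
}

#' Label a patch as positive or negative
#'
#' A patch is positive iff at least one stoma is fully contained in it:
#' the axis-aligned square of side `length_px` centered at the annotated
#' center must lie inside the window. Stomata that are only partially
#' visible in the window therefore label it negative, as do windows with no
#' stoma at all.
#'
#' @param p A `"patch"` (from [extract_patches()]).
#' @param anns [stoma_annotations()] for the same image.
#' @return `"positive"` or `"negative"`.
#' @export
label_patch <- function(p, anns) {
  stopifnot(inherits(p, "patch"))
  grid <- data.frame(x0 = p$x0, y0 = p$y0)
  if (label_window_grid(grid, anns, p$size)) "positive" else "negative"
}

#' Assemble a labeled training set from annotated scenes
#'
#' Extracts and labels every sliding window of every scene, keeps all
#' positive patches, and subsamples the (far more numerous and more
#' variable) negative patches uniformly at random down to
#' `neg_pos_ratio` negatives per positive — the 6:1 default mirrors a
#' training corpus of 12,000 positive and 72,000 negative patches.
#'
#' @param scenes A list of `synth_scene` objects, or of lists with elements
#'   `micrograph` and `annotations`.
#' @param cfg A [patch_config()].
#' @param neg_pos_ratio Target negatives per positive (default 6).
#' @param seed Seed for the negative subsample.
#' @return An object of class `"patch_dataset"`: `X` (matrix, one column
#'   per patch, pixels in column-major order), `label` (factor
#'   negative/positive), `meta` (data.frame `image_id`, `x0`, `y0`),
#'   `class_counts`, and `provenance`.
#' @export
build_training_set <- function(scenes, cfg = patch_config(),
                               neg_pos_ratio = 6, seed = 1L) {
  stopifnot(length(scenes) >= 1, inherits(cfg, "patch_config"))
  P <- cfg$patch_size_px
  metas <- list()
  for (s in scenes) {
    m <- s$micrograph
    grid <- window_grid(micrograph_width(m), micrograph_height(m), cfg)
    grid$positive <- label_window_grid(grid, s$annotations, P)
    grid$image_id <- m$image_id
    metas[[length(metas) + 1L]] <- grid
  }
  all <- do.call(rbind, metas)
  n_pos <- sum(all$positive)
  if (n_pos == 0L) {
    stop(paste("no positive patches: annotate more data (at least ~250",
               "stomata are recommended to train a usable classifier)"),
         call. = FALSE)
  }
  neg_idx <- which(!all$positive)
  n_neg_keep <- min(length(neg_idx), round(neg_pos_ratio * n_pos))
  keep_neg <- with_fixed_seed(seed, sort(sample(neg_idx, n_neg_keep)))
  keep <- sort(c(which(all$positive), keep_neg))
  sel <- all[keep, , drop = FALSE]

  mics <- stats::setNames(lapply(scenes, `[[`, "micrograph"),
                          vapply(scenes, function(s) s$micrograph$image_id, ""))
  X <- matrix(0, P * P, nrow(sel))
  for (i in seq_len(nrow(sel))) {
    X[, i] <- as.vector(patch_pixels_at(mics[[sel$image_id[i]]],
                                        sel$x0[i], sel$y0[i], P))
  }
  label <- factor(ifelse(sel$positive, "positive", "negative"),
                  levels = c("negative", "positive"))
  structure(list(
    X = X, label = label,
    meta = data.frame(image_id = sel$image_id, x0 = sel$x0, y0 = sel$y0,
                      stringsAsFactors = FALSE),
    class_counts = table(label),
    provenance = list(image_ids = names(mics), patch_config = cfg,
                      neg_pos_ratio = neg_pos_ratio, seed = seed)),
    class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("patch_dataset: %d patches (%d positive, %d negative; ratio %.2f)\n",
              length(x$label), x$class_counts[["positive"]],
              x$class_counts[["negative"]],
              x$class_counts[["negative"]] / x$class_counts[["positive"]]))
  invisible(x)
}

#' Dihedral transform of a square pixel grid
#'
#' Applies `rotation` quarter-turns (clockwise) followed by optional
#' horizontal and vertical flips. These transforms permute pixels without
#' interpolation, so intensities (and hence labels) are preserved exactly.
#'
#' @param pixels Square numeric matrix.
#' @param rotation Integer 0-3 quarter turns.
#' @param hflip,vflip Logical flips (applied after rotation).
#' @return Transformed matrix of the same size.
#' @export
dihedral_transform <- function(pixels, rotation = 0L, hflip = FALSE,
                               vflip = FALSE) {
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels)) {
    stop("dihedral transforms require a square patch", call. = FALSE)
  }
  rot_cw <- function(m) t(m[nrow(m):1L, , drop = FALSE])
  for (k in seq_len(as.integer(rotation) %% 4L)) pixels <- rot_cw(pixels)
  if (hflip) pixels <- pixels[, ncol(pixels):1L, drop = FALSE]
  if (vflip) pixels <- pixels[nrow(pixels):1L, , drop = FALSE]
  pixels
}

#' Randomly augment a patch
#'
#' Draws a seeded random element of the dihedral group (rotation by a
#' multiple of 90 degrees plus independent horizontal/vertical flips) and
#' applies it to the patch pixels. Label-preserving by construction.
#'
#' @param p A `"patch"` with pixels.
#' @param seed Integer seed.
#' @return The transformed `"patch"`.
#' @export
augment_patch <- function(p, seed = 1L) {
  stopifnot(inherits(p, "patch"))
  if (is.null(p$pixels)) stop("patch has no pixels to augment", call. = FALSE)
  with_fixed_seed(seed, {
    rotation <- sample(0:3, 1L)
    hflip <- stats::runif(1) < 0.5
    vflip <- stats::runif(1) < 0.5
    p$pixels <- dihedral_transform(p$pixels, rotation, hflip, vflip)
    p
  })
}
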