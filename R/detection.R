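#' Detection configuration
#'
#' `threshold` (tau) is the minimum presence confidence for a window to
#' count as positive — 0.7 is the precision/recall sweet spot the workflow
#' defaults to. `bandwidth_px` is the flat-kernel mean-shift radius used to
#' merge overlapping positive windows into one stoma coordinate (default
#' 60 px, half a patch, roughly the stoma radius scale).
#'
#' @param threshold Confidence threshold in (0, 1).
#' @param bandwidth_px Mean-shift bandwidth (> 0).
#' @param min_cluster_size Drop clusters with fewer member windows.
#' @return An object of class `"detection_config"`.
#' @export
detection_config <- function(threshold = 0.7, bandwidth_px = 60,
                             min_cluster_size = 1L) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  if (bandwidth_px <= 0) stop("bandwidth_px must be > 0", call. = FALSE)
  structure(list(threshold = threshold, bandwidth_px = bandwidth_px,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "detection_config")
}

#' Score every sliding window of a micrograph
#'
#' Runs the classifier over the full sliding-window grid and records one
#' confidence per window. Deterministic for fixed weights.
#'
#' @param clf A `"stoma_classifier"`, an [oracle_classifier()], or a plain
#'   function `f(x0, y0, size)` returning a confidence (useful for tests).
#' @param m A [micrograph()].
#' @param patch_cfg A [patch_config()].
#' @param batch Windows scored per backend call.
#' @return A `"score_map"`: data.frame with `x0`, `y0`, `x_center`,
#'   `y_center`, `confidence`, carrying the image id and configs as
#'   attributes.
#' @export
score_image <- function(clf, m, patch_cfg = patch_config(), batch = 256L) {
  stopifnot(inherits(m, "micrograph"), inherits(patch_cfg, "patch_config"))
  grid <- window_grid(micrograph_width(m), micrograph_height(m), patch_cfg)
  P <- patch_cfg$patch_size_px
  n <- nrow(grid)
  conf <- numeric(n)
  if (inherits(clf, "oracle_classifier")) {
    anns <- clf$anns[clf$anns$image_id == m$image_id, , drop = FALSE]
    conf <- as.numeric(label_window_grid(grid, anns, P))
  } else if (is.function(clf)) {
    conf <- vapply(seq_len(n),
                   function(i) clf(grid$x0[i], grid$y0[i], P), numeric(1))
  } else if (inherits(clf, "stoma_classifier")) {
    for (start in seq.int(1L, n, by = batch)) {
      stop_i <- min(start + batch - 1L, n)
      idx <- start:stop_i
      X <- matrix(0, P * P, length(idx))
      for (k in seq_along(idx)) {
        X[, k] <- as.vector(patch_pixels_at(m, grid$x0[idx[k]],
                                            grid$y0[idx[k]], P))
      }
      conf[idx] <- score_patch_matrix(clf, X)
    }
  } else {
    stop("unsupported classifier object", call. = FALSE)
  }
  out <- data.frame(x0 = grid$x0, y0 = grid$y0,
                    x_center = grid$x0 + P / 2, y_center = grid$y0 + P / 2,
                    confidence = conf)
  attr(out, "image_id") <- m$image_id
  attr(out, "patch_config") <- patch_cfg
  class(out) <- c("score_map", "data.frame")
  out
}

#' Flat-kernel mean-shift clustering
#'
#' Iterates every point to the mean of all original points within
#' `bandwidth` of its current position until the largest displacement falls
#' below `tol` (or `max_iter` is reached). Converged positions closer than
#' `merge_dist` are merged into one mode by single linkage; each input
#' point is assigned to exactly one mode, and the mode coordinate is the
#' mean of its members' converged positions.
#'
#' @param points Numeric matrix (n x 2) of `(x, y)` positions; empty input
#'   yields an empty result.
#' @param bandwidth Flat-kernel radius (> 0).
#' @param tol Convergence tolerance in px.
#' @param max_iter Iteration cap.
#' @param merge_dist Mode-merging distance (default `bandwidth / 2`).
#' @return List with `centers` (k x 2 matrix), `assignment` (length-n mode
#'   index), `sizes` (members per mode).
#' @export
mean_shift <- function(points, bandwidth, tol = 1e-3, max_iter = 300L,
                       merge_dist = bandwidth / 2) {
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  points <- matrix(as.numeric(points), ncol = 2L)
  n <- nrow(points)
  if (n == 0L) {
    return(list(centers = matrix(numeric(0), 0L, 2L),
                assignment = integer(0), sizes = integer(0)))
  }
  pos <- points
  bw2 <- bandwidth^2
  for (it in seq_len(max_iter)) {
    d2 <- outer(pos[, 1L], points[, 1L], "-")^2 +
      outer(pos[, 2L], points[, 2L], "-")^2
    inb <- d2 <= bw2
    cnt <- rowSums(inb)
    newx <- (inb %*% points[, 1L]) / cnt
    newy <- (inb %*% points[, 2L]) / cnt
    disp <- pmax(abs(newx - pos[, 1L]), abs(newy - pos[, 2L]))
    pos <- cbind(as.numeric(newx), as.numeric(newy))
    if (max(disp) < tol) break
  }
  ## single-linkage merge of converged positions
  assignment <- integer(n)
  md2 <- merge_dist^2
  d2 <- outer(pos[, 1L], pos[, 1L], "-")^2 + outer(pos[, 2L], pos[, 2L], "-")^2
  link <- d2 <= md2
  comp <- 0L
  for (i in seq_len(n)) {
    if (assignment[i] > 0L) next
    comp <- comp + 1L
    frontier <- i
    assignment[i] <- comp
    while (length(frontier)) {
      nb <- which(link[frontier[1L], ] & assignment == 0L)
      assignment[nb] <- comp
      frontier <- c(frontier[-1L], nb)
    }
  }
  centers <- t(vapply(seq_len(comp), function(k) {
    colMeans(pos[assignment == k, , drop = FALSE])
  }, numeric(2)))
  list(centers = centers, assignment = assignment,
       sizes = as.integer(tabulate(assignment, comp)))
}

## Thresholds a score map and clusters surviving window centers into
## detections; shared by detect_stomata() and the threshold sweeps.
detections_from_scoremap <- function(sm, det_cfg) {
  keep <- sm$confidence >= det_cfg$threshold
  image_id <- attr(sm, "image_id")
  empty <- data.frame(image_id = character(0), x_px = numeric(0),
                      y_px = numeric(0), confidence = numeric(0),
                      cluster_size = integer(0), stringsAsFactors = FALSE)
  if (!any(keep)) {
    class(empty) <- c("detection_set", "data.frame")
    return(empty)
  }
  pts <- cbind(sm$x_center[keep], sm$y_center[keep])
  conf <- sm$confidence[keep]
  ms <- mean_shift(pts, det_cfg$bandwidth_px)
  k <- nrow(ms$centers)
  out <- data.frame(
    image_id = rep(image_id, k),
    x_px = ms$centers[, 1L], y_px = ms$centers[, 2L],
    confidence = vapply(seq_len(k),
                        function(j) max(conf[ms$assignment == j]), numeric(1)),
    cluster_size = ms$sizes, stringsAsFactors = FALSE)
  out <- out[out$cluster_size >= det_cfg$min_cluster_size, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("detection_set", "data.frame")
  out
}

#' Detect stomata in a micrograph
#'
#' The full leaf-to-coordinates step: score every sliding window, keep
#' windows at or above the confidence threshold, mean-shift their centers,
#' and report one detection per mode. Cluster confidence is the maximum
#' member score; clusters below `min_cluster_size` are dropped.
#'
#' @param clf Classifier (see [score_image()]).
#' @param m A [micrograph()].
#' @param patch_cfg A [patch_config()].
#' @param det_cfg A [detection_config()].
#' @param score_map Optional precomputed [score_image()] result.
#' @return A `"detection_set"` data.frame: `image_id`, `x_px`, `y_px`,
#'   `confidence`, `cluster_size`.
#' @export
detect_stomata <- function(clf, m, patch_cfg = patch_config(),
                           det_cfg = detection_config(), score_map = NULL) {
  if (is.null(score_map)) score_map <- score_image(clf, m, patch_cfg)
  detections_from_scoremap(score_map, det_cfg)
}

#' Detection counts across a threshold sweep
#'
#' Scores the image once, then re-thresholds and re-clusters for every
#' value of `tau_list` (ascending). Counts are non-increasing in the
#' threshold up to cluster-merge effects.
#'
#' @param clf,m,patch_cfg As in [detect_stomata()].
#' @param tau_list Ascending thresholds, default 0.05..0.95 step 0.05.
#' @param det_cfg Base [detection_config()] supplying bandwidth.
#' @return data.frame with `tau` and `n_detections`.
#' @export
detection_counts_vs_threshold <- function(clf, m, patch_cfg = patch_config(),
                                          tau_list = seq(0.05, 0.95, by = 0.05),
                                          det_cfg = detection_config()) {
  if (is.unsorted(tau_list)) stop("tau_list must be ascending", call. = FALSE)
  sm <- score_image(clf, m, patch_cfg)
  n <- vapply(tau_list, function(tau) {
    cfg <- det_cfg
    cfg$threshold <- tau
    nrow(detections_from_scoremap(sm, cfg))
  }, numeric(1))
  data.frame(tau = tau_list, n_detections = as.integer(n))
}
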