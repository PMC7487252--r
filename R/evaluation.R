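#' Match detections to ground-truth annotations
#'
#' Greedy one-to-one matching: candidate pairs within `radius_px` are
#' sorted by ascending distance and accepted whenever both the detection
#' and the truth are still unmatched. Matched pairs are true positives;
#' leftover detections are false positives and leftover truths false
#' negatives. The 60 px default radius is half a patch.
#'
#' @param dets A `"detection_set"` (or data.frame with `x_px`, `y_px`).
#' @param truth [stoma_annotations()] for the same image(s).
#' @param radius_px Maximum matching distance (>= 0).
#' @return An object of class `"match_result"`: list with `TP`, `FP`, `FN`
#'   and `pairs` (data.frame `det`, `truth`, `distance_px`).
#' @export
match_detections <- function(dets, truth, radius_px = 60) {
  if (radius_px < 0) stop("radius_px must be >= 0", call. = FALSE)
  nd <- nrow(dets)
  nt <- nrow(truth)
  pairs <- data.frame(det = integer(0), truth = integer(0),
                      distance_px = numeric(0))
  if (nd > 0 && nt > 0) {
    d <- sqrt(outer(dets$x_px, truth$x_px, "-")^2 +
                outer(dets$y_px, truth$y_px, "-")^2)
    cand <- which(d <= radius_px, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_d <- logical(nd)
      used_t <- logical(nt)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        if (used_d[i] || used_t[j]) next
        used_d[i] <- TRUE
        used_t[j] <- TRUE
        pairs <- rbind(pairs, data.frame(det = i, truth = j,
                                         distance_px = d[i, j]))
      }
    }
  }
  structure(list(TP = nrow(pairs), FP = nd - nrow(pairs),
                 FN = nt - nrow(pairs), pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: TP=%d FP=%d FN=%d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

#' Precision, recall and F-score from a confusion count
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)` and the harmonic mean
#' `F = 2PR/(P+R)`. A zero denominator yields 0 for the affected measure
#' and sets the `degenerate` flag.
#'
#' @param TP,FP,FN Non-negative integer counts.
#' @return List with `precision`, `recall`, `f_score`, `degenerate`.
#' @examples
#' precision_recall_f(9, 1, 3)
#' @export
precision_recall_f <- function(TP, FP, FN) {
  if (any(c(TP, FP, FN) < 0)) stop("counts must be non-negative", call. = FALSE)
  degenerate <- FALSE
  p <- if (TP + FP > 0) TP / (TP + FP) else { degenerate <- TRUE; 0 }
  r <- if (TP + FN > 0) TP / (TP + FN) else { degenerate <- TRUE; 0 }
  f <- if (p + r > 0) 2 * p * r / (p + r) else { degenerate <- TRUE; 0 }
  list(precision = p, recall = r, f_score = f, degenerate = degenerate)
}

#' Harmonic mean of precision and recall
#'
#' `F = 2PR/(P + R)`, the F-score given precision and recall directly
#' (0 when both are 0).
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The F-score.
#' @examples
#' f_score(0.84, 0.91)
#' @export
f_score <- function(precision, recall) {
  if (precision < 0 || precision > 1 || recall < 0 || recall > 1) {
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  }
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Micro-averaged precision-recall curve over a threshold sweep
#'
#' Scores each annotated scene once, then for every threshold of the grid
#' re-clusters detections, matches them against the ground truth, pools
#' TP/FP/FN across scenes (micro-averaging) and computes
#' precision/recall/F. F iso-line values are attached for plotting.
#'
#' @param clf Classifier (see [score_image()]).
#' @param scenes List of annotated scenes (`synth_scene` objects or lists
#'   with `micrograph` and `annotations`).
#' @param patch_cfg A [patch_config()].
#' @param det_cfg Base [detection_config()] (bandwidth, min cluster size).
#' @param tau_grid Thresholds; default the 19-point grid 0.05..0.95.
#' @param radius_px Matching radius for [match_detections()].
#' @return data.frame of class `"pr_curve"` with `tau`, `TP`, `FP`, `FN`,
#'   `precision`, `recall`, `f_score`; attribute `f_iso` holds the
#'   reference F values 0.1..0.9.
#' @export
pr_curve <- function(clf, scenes, patch_cfg = patch_config(),
                     det_cfg = detection_config(),
                     tau_grid = seq(0.05, 0.95, by = 0.05), radius_px = 60) {
  if (!length(scenes)) stop("pr_curve needs at least one scene", call. = FALSE)
  maps <- lapply(scenes, function(s) score_image(clf, s$micrograph, patch_cfg))
  rows <- lapply(tau_grid, function(tau) {
    cfg <- det_cfg
    cfg$threshold <- tau
    TP <- FP <- FN <- 0L
    for (k in seq_along(scenes)) {
      dets <- detections_from_scoremap(maps[[k]], cfg)
      mr <- match_detections(dets, scenes[[k]]$annotations, radius_px)
      TP <- TP + mr$TP; FP <- FP + mr$FP; FN <- FN + mr$FN
    }
    prf <- precision_recall_f(TP, FP, FN)
    data.frame(tau = tau, TP = TP, FP = FP, FN = FN,
               precision = prf$precision, recall = prf$recall,
               f_score = prf$f_score)
  })
  out <- do.call(rbind, rows)
  attr(out, "f_iso") <- seq(0.1, 0.9, by = 0.1)
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Stomatal count accuracy
#'
#' Per-image agreement between automated and manual counts:
#' `accuracy = 100 * (1 - |computed - manual| / manual)`, floored at 0.
#' Under this deviation convention a 36 percent count deviation reads as
#' 64 percent accuracy. Images with a zero manual count are skipped with a
#' warning.
#'
#' @param pairs data.frame with columns `computed` and `manual` (one row
#'   per image; an optional `image_id` column is carried through).
#' @return List of class `"count_accuracy"`: `per_image` data.frame with
#'   an `accuracy_pct` column, and `mean_accuracy_pct`.
#' @export
count_accuracy <- function(pairs) {
  stopifnot(all(c("computed", "manual") %in% names(pairs)))
  skip <- pairs$manual == 0
  if (any(skip)) {
    warning(sprintf("%d image(s) with manual count 0 skipped", sum(skip)),
            call. = FALSE)
    pairs <- pairs[!skip, , drop = FALSE]
  }
  acc <- pmax(0, 100 * (1 - abs(pairs$computed - pairs$manual) / pairs$manual))
  per_image <- cbind(pairs, accuracy_pct = acc)
  structure(list(per_image = per_image,
                 mean_accuracy_pct = mean(acc)),
            class = "count_accuracy")
}

#' @export
print.count_accuracy <- function(x, ...) {
  cat(sprintf("count_accuracy: mean %.1f%% over %d image(s)\n",
              x$mean_accuracy_pct, nrow(x$per_image)))
  invisible(x)
}

#' Regression of computed on manual counts
#'
#' Ordinary least squares of computed counts on manual counts, the standard
#' agreement summary alongside count accuracy: a perfect detector gives
#' slope 1, intercept 0, R-squared 1.
#'
#' @param pairs data.frame with `computed` and `manual` columns, `n >= 3`.
#' @return List of class `"regression_summary"`: `slope`, `intercept`,
#'   `r_squared`, `p_value` (slope t-test), `n`.
#' @export
fit_counts_regression <- function(pairs) {
  stopifnot(all(c("computed", "manual") %in% names(pairs)))
  if (nrow(pairs) < 3L) stop("need at least 3 images", call. = FALSE)
  if (stats::var(pairs$manual) == 0) {
    stop("manual counts have zero variance; regression undefined",
         call. = FALSE)
  }
  fit <- stats::lm(computed ~ manual, data = pairs)
  # summary.lm warns on exact fits ("essentially perfect fit"); those are
  # legitimate here (e.g. a perfect detector)
  s <- suppressWarnings(summary(fit))
  # R^2 = 1 - SSres/SStot; constant computed counts have no variance to
  # explain, which reads as 0 rather than the 0/0 indeterminate
  r2 <- if (stats::var(pairs$computed) == 0) 0 else s$r.squared
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 p_value = unname(s$coefficients["manual", "Pr(>|t|)"]),
                 n = nrow(pairs)),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf(
    "counts regression: slope %.3f, intercept %.2f, R^2 = %.3f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
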