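# Independent reference implementations used as oracles. These are written
# as plain per-point loops, deliberately sharing no code with the package's
# vectorized implementations.

# Flat-kernel mean-shift, one point at a time: iterate to the mean of all
# original points within the bandwidth, then merge converged positions by
# single linkage at merge_dist and average them per group.
brute_mean_shift <- function(points, bandwidth, tol = 1e-3, max_iter = 300,
                             merge_dist = bandwidth / 2) {
  n <- nrow(points)
  converged <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    p <- points[i, ]
    for (it in seq_len(max_iter)) {
      d <- sqrt((points[, 1] - p[1])^2 + (points[, 2] - p[2])^2)
      m <- colMeans(points[d <= bandwidth, , drop = FALSE])
      if (max(abs(m - p)) < tol) { p <- m; break }
      p <- m
    }
    converged[i, ] <- p
  }
  group <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (group[i] > 0L) next
    g <- g + 1L
    queue <- i
    group[i] <- g
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      for (k in seq_len(n)) {
        if (group[k] == 0L &&
            sqrt(sum((converged[j, ] - converged[k, ])^2)) <= merge_dist) {
          group[k] <- g
          queue <- c(queue, k)
        }
      }
    }
  }
  centers <- matrix(0, g, 2)
  for (k in seq_len(g)) {
    centers[k, ] <- colMeans(converged[group == k, , drop = FALSE])
  }
  list(centers = centers, assignment = group)
}

# Exhaustive maximum-cardinality, minimum-total-distance one-to-one
# matching within a radius; feasible only for tiny point sets.
brute_match <- function(dets, truth, radius) {
  nd <- nrow(dets)
  nt <- nrow(truth)
  if (nd == 0 || nt == 0) return(list(TP = 0L))
  d <- sqrt(outer(dets$x_px, truth$x_px, "-")^2 +
              outer(dets$y_px, truth$y_px, "-")^2)
  best <- list(TP = 0L, total = Inf)
  recurse <- function(i, used_t, tp, total) {
    if (i > nd) {
      if (tp > best$TP || (tp == best$TP && total < best$total)) {
        best <<- list(TP = tp, total = total)
      }
      return(invisible())
    }
    recurse(i + 1L, used_t, tp, total)  # leave detection i unmatched
    for (j in seq_len(nt)) {
      if (!used_t[j] && d[i, j] <= radius) {
        used_t[j] <- TRUE
        recurse(i + 1L, used_t, tp + 1L, total + d[i, j])
        used_t[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nt), 0L, 0)
  best
}

# Counts stomata fully inside exactly one tile of a non-overlapping
# patch-size tiling, by direct geometry.
brute_tiled_positives <- function(anns, width, height, size) {
  count <- 0L
  for (i in seq_len(nrow(anns))) {
    L2 <- anns$length_px[i] / 2
    hits <- 0L
    for (x0 in seq(0, width - size, by = size)) {
      for (y0 in seq(0, height - size, by = size)) {
        if (anns$x_px[i] - L2 >= x0 && anns$x_px[i] + L2 <= x0 + size &&
            anns$y_px[i] - L2 >= y0 && anns$y_px[i] + L2 <= y0 + size) {
          hits <- hits + 1L
        }
      }
    }
    if (hits == 1L) count <- count + 1L
  }
  count
}
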