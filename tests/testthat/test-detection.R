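test_that("mean-shift fixed points behave on canonical inputs", {
  one <- mean_shift(matrix(c(0, 0), 1, 2), bandwidth = 60)
  expect_equal(one$centers, matrix(c(0, 0), 1, 2))
  expect_equal(one$assignment, 1L)

  two <- mean_shift(matrix(c(0, 10, 0, 0), 2, 2), bandwidth = 60)
  expect_equal(nrow(two$centers), 1L)
  expect_equal(two$centers[1, ], c(5, 0), tolerance = 1e-6)

  far <- mean_shift(matrix(c(0, 1000, 0, 0), 2, 2), bandwidth = 60)
  expect_equal(nrow(far$centers), 2L)
  expect_equal(sort(far$centers[, 1]), c(0, 1000))

  empty <- mean_shift(matrix(numeric(0), 0, 2), bandwidth = 60)
  expect_equal(nrow(empty$centers), 0L)
  expect_length(empty$assignment, 0L)
  expect_error(mean_shift(matrix(0, 1, 2), bandwidth = 0), "bandwidth")
})

test_that("mean-shift agrees with an independent brute-force oracle", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(1:12, 1)
    pts <- cbind(runif(n, 0, 400), runif(n, 0, 300))
    bw <- sample(c(30, 60, 120), 1)
    got <- mean_shift(pts, bw)
    want <- brute_mean_shift(pts, bw)
    expect_equal(nrow(got$centers), nrow(want$centers))
    # centers agree as sets to 0.1 px
    ord_g <- order(got$centers[, 1], got$centers[, 2])
    ord_w <- order(want$centers[, 1], want$centers[, 2])
    expect_equal(got$centers[ord_g, , drop = FALSE],
                 want$centers[ord_w, , drop = FALSE], tolerance = 0.1,
                 ignore_attr = TRUE)
    # every update is a convex combination of the input points, so every
    # mode lies inside the bounding box of the full point set (a mode can
    # legitimately leave the box of its own members: converged positions
    # are dragged by in-bandwidth points of neighboring clusters)
    expect_true(all(got$centers[, 1] >= min(pts[, 1]) - 1e-6 &
                      got$centers[, 1] <= max(pts[, 1]) + 1e-6))
    expect_true(all(got$centers[, 2] >= min(pts[, 2]) - 1e-6 &
                      got$centers[, 2] <= max(pts[, 2]) + 1e-6))
  }
})

test_that("score maps cover the window grid", {
  m <- micrograph(matrix(0.5, 300, 400), "c")
  cfg <- patch_config(120L, 40L)
  constant <- function(x0, y0, size) 0.5
  sm <- score_image(constant, m, cfg)
  expect_equal(nrow(sm), length(extract_patches(m, cfg, pixels = FALSE)))
  expect_true(all(sm$confidence == 0.5))
  expect_equal(sm$x_center, sm$x0 + 60)
})

test_that("thresholding and clustering produce detections", {
  m <- micrograph(matrix(0.5, 360, 480), "d")
  cfg <- patch_config(120L, 40L)
  cold <- function(x0, y0, size) 0.1
  expect_equal(nrow(detect_stomata(cold, m, cfg, detection_config(0.7))), 0L)
  hot <- function(x0, y0, size) if (x0 == 160 && y0 == 120) 0.9 else 0.1
  dets <- detect_stomata(hot, m, cfg, detection_config(0.7))
  expect_equal(nrow(dets), 1L)
  expect_equal(c(dets$x_px, dets$y_px), c(160 + 60, 120 + 60))
  expect_equal(dets$confidence, 0.9)
  expect_equal(dets$cluster_size, 1L)
  # determinism
  expect_identical(dets, detect_stomata(hot, m, cfg, detection_config(0.7)))
})

test_that("the oracle detector recovers synthetic scenes exactly", {
  for (seed in c(31L, 32L)) {
    sc <- small_scene(seed, n_stomata = 3L)
    dets <- detect_stomata(oracle_classifier(sc$annotations), sc$micrograph,
                           patch_config(120L, 30L), detection_config())
    expect_equal(nrow(dets), nrow(sc$annotations))
    mr <- match_detections(dets, sc$annotations, radius_px = 60)
    expect_equal(mr$FP, 0L)
    expect_equal(mr$FN, 0L)
    expect_true(all(mr$pairs$distance_px <= 30))
  }
})

test_that("detection counts are non-increasing along the threshold sweep", {
  sc <- small_scene(35L, n_stomata = 3L)
  fx <- fixture_classifier()
  counts <- detection_counts_vs_threshold(fx$clf, sc$micrograph,
                                          patch_config(120L, 30L))
  expect_equal(nrow(counts), 19L)
  expect_equal(counts$tau, seq(0.05, 0.95, by = 0.05))
  expect_true(all(diff(counts$n_detections) <= 0))
  expect_lte(counts$n_detections[19], counts$n_detections[1])
  expect_error(
    detection_counts_vs_threshold(fx$clf, sc$micrograph,
                                  patch_config(120L, 30L),
                                  tau_list = c(0.9, 0.1)),
    "ascending")
})
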