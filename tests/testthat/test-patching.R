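blank_micrograph <- function(width, height, id = "img") {
  micrograph(matrix(0.5, height, width), id)
}

test_that("sliding-window grid counts follow the stride arithmetic", {
  m <- blank_micrograph(1600, 1200)
  patches <- extract_patches(m, patch_config(120L, 40L), pixels = FALSE)
  expect_length(patches, 38L * 28L)  # floor((1600-120)/40)+1 by floor((1200-120)/40)+1
  one <- extract_patches(blank_micrograph(120, 120), patch_config(120L, 40L))
  expect_length(one, 1L)
  expect_equal(c(one[[1]]$x0, one[[1]]$y0), c(0L, 0L))
  expect_error(extract_patches(blank_micrograph(119, 119),
                               patch_config(120L, 30L)), "smaller")
})

test_that("flush windows complete pixel coverage", {
  w <- 310L; h <- 250L; P <- 120L; s <- 50L
  cfg <- patch_config(P, s, flush = TRUE)
  patches <- extract_patches(blank_micrograph(w, h), cfg, pixels = FALSE)
  covered <- matrix(FALSE, h, w)
  for (p in patches) {
    covered[(p$y0 + 1):(p$y0 + P), (p$x0 + 1):(p$x0 + P)] <- TRUE
  }
  expect_true(all(covered))
  # without flush the trailing band is uncovered for these dimensions
  patches2 <- extract_patches(blank_micrograph(w, h), patch_config(P, s), pixels = FALSE)
  expect_lt(length(patches2), length(patches))
})

test_that("patch labeling follows the full-containment rule", {
  m <- blank_micrograph(240, 240)
  p <- extract_patches(m, patch_config(120L, 120L))[[1]]  # window (0,0)
  inside <- stoma_annotations("img", 60, 60, 80)
  expect_equal(label_patch(p, inside), "positive")
  crossing <- stoma_annotations("img", 10, 60, 80)
  expect_equal(label_patch(p, crossing), "negative")
  expect_equal(label_patch(p, stoma_annotations()), "negative")
  # exactly touching the window edge still counts as contained
  touching <- stoma_annotations("img", 60, 60, 120)
  expect_equal(label_patch(p, touching), "positive")
})

test_that("tiling positives equal the brute-force geometric count", {
  for (seed in c(4L, 9L)) {
    sc <- small_scene(seed, n_stomata = 3L)
    cfg <- patch_config(120L, 120L)  # non-overlapping tiling
    m <- sc$micrograph
    grid <- stomatadetect:::window_grid(480, 400, cfg)
    got <- sum(stomatadetect:::label_window_grid(grid, sc$annotations, 120L))
    want <- brute_tiled_positives(sc$annotations, 480, 400, 120L)
    expect_equal(got, want)
  }
})

test_that("training sets keep all positives and subsample negatives", {
  scenes <- lapply(1:2, function(i) small_scene(20L + i, n_stomata = 4L))
  cfg <- patch_config(120L, 30L)
  n_pos_all <- sum(vapply(scenes, function(s) {
    g <- stomatadetect:::window_grid(480, 400, cfg)
    sum(stomatadetect:::label_window_grid(g, s$annotations, 120L))
  }, integer(1)))
  ds <- build_training_set(scenes, cfg, neg_pos_ratio = 2, seed = 1L)
  expect_equal(unname(ds$class_counts[["positive"]]), n_pos_all)
  expect_equal(unname(ds$class_counts[["negative"]]), round(2 * n_pos_all))
  expect_equal(ncol(ds$X), length(ds$label))
  # ratio capped at the available negatives
  ds_all <- build_training_set(scenes, cfg, neg_pos_ratio = 1e6, seed = 1L)
  g <- stomatadetect:::window_grid(480, 400, cfg)
  expect_equal(length(ds_all$label), 2L * nrow(g))
  # the paper-scale imbalance: 72k negatives for 12k positives is ratio 6
  expect_equal(72000 / 12000, 6)
  expect_error(build_training_set(list(small_scene(33L, n_stomata = 0L)), cfg),
               "no positive")
})

test_that("dihedral transforms are exact pixel permutations", {
  marker <- matrix(1:9, 3, 3)  # no dihedral self-symmetry: orbit size 8
  # identity element
  expect_identical(dihedral_transform(marker, 0L, FALSE, FALSE), marker)
  # horizontal flip is an involution
  expect_identical(
    dihedral_transform(dihedral_transform(marker, 0L, TRUE), 0L, TRUE),
    marker)
  # the 8 dihedral transforms of an asymmetric patch are pairwise distinct
  orbit <- list()
  for (rot in 0:3) for (hf in c(FALSE, TRUE)) {
    orbit[[length(orbit) + 1L]] <- dihedral_transform(marker, rot, hf)
  }
  keys <- vapply(orbit, function(m) paste(m, collapse = ","), "")
  expect_length(unique(keys), 8L)
  # intensity histogram (hence any label) is preserved
  p <- extract_patches(blank_micrograph(120, 120), patch_config(120L, 30L))[[1]]
  p$pixels <- matrix(runif(120 * 120), 120, 120)
  q <- augment_patch(p, seed = 5L)
  expect_equal(dim(q$pixels), dim(p$pixels))
  expect_equal(sort(as.vector(q$pixels)), sort(as.vector(p$pixels)))
  expect_error(dihedral_transform(matrix(0, 2, 3)), "square")
})
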