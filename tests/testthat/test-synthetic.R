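test_that("empty scenes contain background only", {
  sc <- generate_micrograph(synth_config(width_px = 300L, height_px = 240L,
                                         n_stomata = 0L, artifact_rate = 0,
                                         seed = 3L))
  expect_equal(nrow(sc$annotations), 0L)
  expect_true(all(sc$micrograph$pixels >= 0 & sc$micrograph$pixels <= 1))
})

test_that("a fixed seed reproduces scenes exactly", {
  cfg <- small_scene_config(7L, n_stomata = 4L)
  a <- generate_micrograph(cfg, "x")
  b <- generate_micrograph(cfg, "x")
  expect_identical(a$micrograph$pixels, b$micrograph$pixels)
  expect_identical(as.data.frame(a$annotations), as.data.frame(b$annotations))
  expect_identical(a$artifacts, b$artifacts)
})

test_that("stoma placement honors separation and border margins", {
  for (seed in c(2L, 11L, 23L)) {
    sc <- small_scene(seed, n_stomata = 4L)
    a <- sc$annotations
    expect_equal(nrow(a), 4L)
    # brute-force pairwise distances
    for (i in seq_len(nrow(a) - 1)) {
      for (j in (i + 1):nrow(a)) {
        d <- sqrt((a$x_px[i] - a$x_px[j])^2 + (a$y_px[i] - a$y_px[j])^2)
        expect_gte(d, 140)
      }
    }
    # fully inside the view field with at least the major/2 margin
    expect_true(all(a$x_px >= a$length_px / 2 &
                      a$x_px <= 480 - a$length_px / 2))
    expect_true(all(a$y_px >= a$length_px / 2 &
                      a$y_px <= 400 - a$length_px / 2))
  }
})

test_that("infeasible packing fails with the achievable count", {
  cfg <- synth_config(width_px = 300L, height_px = 240L, n_stomata = 40L,
                      min_separation_px = 140, seed = 1L)
  expect_error(generate_micrograph(cfg), "packing error")
})

test_that("stomata render with a dark pore and lighter rim", {
  cfg <- synth_config(width_px = 300L, height_px = 240L, n_stomata = 1L,
                      stoma_major_axis_px = c(80, 80), artifact_rate = 0,
                      noise_level = 0, blur_sigma_px = 0, seed = 5L)
  sc <- generate_micrograph(cfg)
  a <- sc$annotations
  px <- sc$micrograph$pixels
  center <- px[round(a$y_px) + 1, round(a$x_px) + 1]
  bg <- median(px)
  expect_lt(center, bg)      # pore darker than background
  expect_gt(max(px), bg)     # rim brighter than background
})

test_that("generate_dataset writes images and one consistent CSV", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- small_scene_config(1L, n_stomata = 3L)
  scenes <- generate_dataset(2L, cfg, dir1)
  expect_length(scenes, 2L)
  pngs <- list.files(dir1, pattern = "\\.png$")
  expect_length(pngs, 2L)
  anns <- read_annotations(file.path(dir1, "annotations.csv"))
  expect_equal(nrow(anns), sum(vapply(scenes, function(s)
    nrow(s$annotations), integer(1))))
  expect_equal(nrow(anns), 6L)  # 3 stomata in each of 2 images
  # identical bytes on a second run
  generate_dataset(2L, cfg, dir2)
  expect_identical(readBin(file.path(dir1, "annotations.csv"), "raw", 1e6),
                   readBin(file.path(dir2, "annotations.csv"), "raw", 1e6))
  expect_identical(readBin(file.path(dir1, pngs[1]), "raw", 1e7),
                   readBin(file.path(dir2, pngs[1]), "raw", 1e7))
  # PNG round trip reproduces the scene pixels exactly (8-bit grid)
  m <- read_micrograph(file.path(dir1, pngs[1]))
  expect_equal(m$pixels, scenes[[1]]$micrograph$pixels, tolerance = 1e-12)
})
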