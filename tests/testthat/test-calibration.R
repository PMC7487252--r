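test_that("view-field area follows from the physical dimensions", {
  expect_equal(view_field_area_mm2(calibration(1600, 1200, 344, 258)),
               0.088752)
  expect_equal(round(view_field_area_mm2(calibration(1600, 1200, 344, 258)), 2),
               0.09)
  expect_equal(view_field_area_mm2(calibration(1000, 1000, 1000, 1000)), 1.0)
  expect_equal(view_field_area_mm2(calibration(100, 50, 100, 50)), 0.005)
  expect_error(calibration(1600, 1200, -344, 258), "strictly positive")
  expect_error(calibration(0, 1200, 344, 258), "strictly positive")
})

test_that("stomatal density is count over area", {
  expect_equal(density_per_mm2(0, 0.088752), 0)
  expect_equal(density_per_mm2(9, 0.09), 100)
  expect_equal(round(density_per_mm2(62, 0.088752), 2), 698.58)
  expect_error(density_per_mm2(5, 0), "positive")
  expect_error(density_per_mm2(-1, 0.09), "non-negative")
  expect_error(density_per_mm2(2.5, 0.09), "integer")
})

test_that("um-per-px is the mean axis ratio and anisotropy warns", {
  expect_equal(um_per_px(calibration(1600, 1200, 344, 258)), 0.215)
  expect_equal(um_per_px(calibration(100, 100, 100, 100)), 1.0)
  expect_warning(cal <- calibration(100, 100, 100, 95), "anisotropic")
  expect_equal(um_per_px(cal), (1 + 0.95) / 2)
})

test_that("density arithmetic properties hold", {
  area <- view_field_area_mm2(calibration())
  for (n in c(0L, 3L, 17L)) {
    for (k in c(0L, 2L, 5L)) {
      expect_equal(density_per_mm2(k * n, area), k * density_per_mm2(n, area))
    }
  }
  # symmetry in the two field dimensions
  expect_equal(view_field_area_mm2(calibration(1600, 1200, 344, 258)),
               view_field_area_mm2(calibration(1200, 1600, 258, 344)))
  # round trip density * area == count
  for (n in c(1L, 62L, 245L)) {
    expect_equal(density_per_mm2(n, area) * area, n, tolerance = 1e-9)
  }
})

test_that("density_result table is internally consistent", {
  dr <- density_result(c("a", "b"), c(10L, 0L), 0.088752)
  expect_equal(dr$density_per_mm2, dr$count / dr$area_mm2)
  expect_equal(nrow(dr), 2L)
})

test_that("micrograph construction rescales 8-bit input and checks bounds", {
  m8 <- micrograph(matrix(0:255, 16, 16), "a")
  expect_true(all(m8$pixels >= 0 & m8$pixels <= 1))
  expect_equal(max(m8$pixels), 1)
  rgb <- array(runif(12 * 10 * 3), dim = c(12, 10, 3))
  mg <- micrograph(rgb, "b")
  expect_equal(dim(mg$pixels), c(12, 10))
  expect_error(micrograph(matrix(-1, 4, 4)), "intensities")
  expect_error(micrograph(matrix(0.5, 4, 4), calibration = calibration()),
               "calibration")
})

test_that("annotation validation enforces coordinate bounds", {
  a <- stoma_annotations("img", c(10, 20), c(5, 6), c(80, NA))
  expect_equal(a$length_px, c(80, 120))
  expect_error(stoma_annotations("img", -5, 10), "invalid annotation")
  expect_error(stoma_annotations("img", 50, 10, width_px = 40),
               "invalid annotation")
  expect_error(stoma_annotations("img", 5, 10, length_px = 0),
               "invalid annotation")
})
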