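test_that("angiogram construction validates intensities and metadata", {
  px <- matrix(runif(64), 8)
  a <- enface_angiogram(px, fov_mm = 3, layer = "SRL")
  expect_s3_class(a, "enface_angiogram")
  expect_equal(pixel_size_mm(a), 3 / 8)
  expect_equal(dim(a), c(8, 8))

  expect_error(enface_angiogram(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(enface_angiogram(matrix(c(1, NA, 2, 3), 2)), "finite")
  expect_error(enface_angiogram(matrix(c(1, -1, 2, 3), 2)), "non-negative")
  expect_error(enface_angiogram(px, fov_mm = 0), "positive")
  expect_error(enface_angiogram(px, layer = "XXX"))
})

test_that("mask containers validate their input", {
  m <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2)
  expect_s3_class(binary_vessel_map(m, 0.5), "binary_vessel_map")
  expect_s3_class(skeleton_map(m), "skeleton_map")
  expect_error(binary_vessel_map(matrix(1:4, 2)), "logical")
  expect_error(skeleton_map(matrix(c(TRUE, NA), 1)), "NA")
})

test_that("16-bit TIFF write/read roundtrip is bit-identical", {
  set.seed(11)
  px <- matrix(sample(0:65535, 32 * 32, replace = TRUE), 32)
  a <- enface_angiogram(px + 0, layer = "DRL")
  f <- file.path(tempdir(), "S001_OD_DRL.tiff")
  write_angiogram(a, f)
  back <- read_angiogram(f)
  expect_identical(back$pixels, px + 0)
  expect_equal(back$layer, "DRL")
  unlink(f)
})

test_that("reader rejects multi-channel images and defaults the layer token", {
  f_rgb <- file.path(tempdir(), "rgb.png")
  png::writePNG(array(runif(16 * 16 * 3), c(16, 16, 3)), f_rgb)
  expect_error(read_angiogram(f_rgb), "multi-channel")
  unlink(f_rgb)

  f_nolayer <- file.path(tempdir(), "subjectx.png")
  png::writePNG(matrix(runif(16 * 16), 16), f_nolayer)
  expect_warning(a <- read_angiogram(f_nolayer), "defaulting to NS-RL")
  expect_equal(a$layer, "NS-RL")
  unlink(f_nolayer)
})

test_that("sidecar JSON overrides field of view and layer", {
  px <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16)
  stem <- file.path(tempdir(), "S002_OS_SRL")
  write_angiogram(enface_angiogram(px + 0, layer = "SRL"),
                  paste0(stem, ".tiff"), bits = 8)
  jsonlite::write_json(list(fov_mm = 6, layer = "DRL"),
                       paste0(stem, ".json"), auto_unbox = TRUE)
  a <- read_angiogram(paste0(stem, ".tiff"))
  expect_equal(a$fov_mm, 6)
  expect_equal(a$layer, "DRL")
  unlink(paste0(stem, c(".tiff", ".json")))
})
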