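test_that("16-bit TIFF round trip maps endpoints and preserves values to quantization", {
  img <- matrix(runif(64 * 64), 64, 64)
  img[1, 1] <- 0; img[1, 2] <- 1
  path <- withr::local_tempfile(fileext = ".tif")
  write_radiograph(img, path)
  back <- read_radiograph(path)
  expect_equal(dim(back), dim(img))
  expect_equal(back[1, 1], 0)
  expect_equal(back[1, 2], 1)
  expect_lt(max(abs(back - img)), 1 / 65535)
})

test_that("float TIFF in [0,1] reads back essentially unchanged", {
  img <- matrix(runif(32 * 32), 32, 32)
  img[1, 1] <- 0; img[2, 2] <- 1
  path <- withr::local_tempfile(fileext = ".tif")
  write_radiograph(img, path, float = TRUE)
  back <- read_radiograph(path)
  expect_lt(max(abs(back - img)), 1e-6)  # 32-bit quantization
})

test_that("constant image normalizes to zeros with a degenerate-range warning", {
  img <- matrix(17 / 255, 16, 16)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, path)
  expect_warning(back <- read_radiograph(path), "degenerate")
  expect_true(all(back == 0))
})

test_that("RGB input collapses to Rec. 601 luminance with a warning", {
  arr <- array(runif(16 * 16 * 3), c(16, 16, 3))
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr, path)
  expect_warning(back <- read_radiograph(path), "luminance")
  lum <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  expect_lt(max(abs(back - normalize_intensity(lum))), 0.01)  # 8-bit storage
})

test_that("normalization is idempotent and hits [0,1] endpoints", {
  x <- matrix(rnorm(400, 50, 10), 20, 20)
  n1 <- normalize_intensity(x)
  expect_equal(range(n1), c(0, 1))
  expect_equal(normalize_intensity(n1), n1)
})

test_that("missing and unsupported files raise I/O errors naming the path", {
  expect_error(read_radiograph("/nonexistent/img.tif"), "/nonexistent/img.tif")
  path <- withr::local_tempfile(fileext = ".bmp")
  writeLines("x", path)
  expect_error(read_radiograph(path), "unsupported")
})

test_that("default configuration carries the published parameter set", {
  cfg <- load_config(NULL)
  expect_s3_class(cfg, "fusion_config")
  expect_identical(cfg$wiener_window, c(5L, 5L))
  expect_identical(cfg$nsct_levels, c(4L, 4L, 4L, 4L))
  expect_equal(cfg$low_weight_a, 0.55)
  expect_equal(cfg$high_weights_bcd, c(0.41, 0.29, 0.30))
  expect_equal(cfg$high_threshold_Tth, 1)
  expect_equal(cfg$scm$f, 0.8)
  expect_equal(cfg$scm$g, 0.7)
  expect_equal(cfg$scm$h, 20)
  expect_equal(cfg$scm$k, 200L)
  expect_equal(cfg$scm$W[2, 2], 0)
  expect_equal(cfg$enhance$clahe_tiles, c(5L, 5L))
  expect_equal(cfg$enhance$clahe_clip, 0.00125)
  expect_equal(cfg$enhance$clahe_bins, 500L)
  expect_equal(cfg$enhance$sharpen_alpha, 3)
  expect_equal(cfg$enhance$lambda1, 4.8)
  expect_equal(cfg$enhance$lambda2, 0.49)
})

test_that("config file overrides merge with defaults and invalid values fail", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("low_weight_a: 0.7", "scm:", "  k: 50"), path)
  cfg <- load_config(path)
  expect_equal(cfg$low_weight_a, 0.7)
  expect_equal(cfg$scm$k, 50L)
  expect_equal(cfg$high_weights_bcd, c(0.41, 0.29, 0.30))

  writeLines("low_weight_a: 1.0", path)
  expect_error(load_config(path), "open interval")
  writeLines(c("high_weights_bcd: [0.5, 0.5, 0.5]"), path)
  expect_error(load_config(path), "sum to 1")
  writeLines("not_a_key: 1", path)
  expect_error(load_config(path), "unknown config keys")
  writeLines(c("scm:", "  bogus: 2"), path)
  expect_error(load_config(path), "scm")
})

test_that("tri_contrast enforces co-registration (equal shapes)", {
  a <- matrix(runif(64), 8, 8)
  b <- matrix(runif(80), 8, 10)
  expect_error(tri_contrast(a, a, b), "shape")
  expect_s3_class(tri_contrast(a, a, a), "tri_contrast")
})
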