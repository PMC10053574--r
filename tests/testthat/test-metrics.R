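test_that("spatial frequency vanishes on constants and matches the double loop", {
  expect_equal(spatial_frequency(matrix(0.7, 16, 16)), 0)
  Z <- random_image(20, 24, seed = 1)
  expect_equal(spatial_frequency(Z), sf_oracle(Z), tolerance = 1e-12)
  # vertical stripes: no variation along columns, so only RF contributes
  stripes <- matrix(rep(c(0, 1), length.out = 16), 16, 16, byrow = TRUE)
  M <- 16; N <- 16
  rf_only <- sqrt(sum((stripes[, 2:N] - stripes[, 1:(N - 1)])^2) / (M * N))
  expect_equal(spatial_frequency(stripes), rf_only)
})

test_that("standard deviation and entropy handle degenerate and two-level images", {
  const <- matrix(0.2, 16, 16)
  expect_equal(image_sd(const), 0)
  expect_equal(image_entropy(const), 0)
  two <- matrix(c(0, 1), 16, 16)   # equal areas
  expect_equal(image_entropy(two), 1)
  Z <- random_image(24, 24, seed = 2)
  expect_equal(image_sd(Z), sd_oracle(Z), tolerance = 1e-12)
  expect_equal(image_entropy(Z), entropy_oracle(Z), tolerance = 1e-9)
})

test_that("entropy of uniform noise approaches 8 bits from below", {
  Z <- random_image(256, 256, seed = 3)
  h <- image_entropy(Z)
  expect_lt(h, 8)
  expect_gt(h, 7.9)
})

test_that("mutual information satisfies its identities and the oracle", {
  A <- random_image(32, 32, seed = 4)
  expect_equal(mutual_information(A, A), image_entropy(A), tolerance = 1e-12)
  B <- random_image(32, 32, seed = 5)
  expect_equal(mutual_information(A, B), mi_oracle(A, B), tolerance = 1e-9)
  # independent images share almost no information at adequate sample size
  A2 <- random_image(256, 256, seed = 6)
  B2 <- random_image(256, 256, seed = 7)
  expect_lt(mutual_information(A2, B2, levels = 16), 0.05)
  tri <- tri_contrast(A, A, A)
  expect_equal(fusion_factor(tri, A), 3 * image_entropy(A), tolerance = 1e-12)
})

test_that("feature mutual information peaks on the identity triple", {
  ph <- small_phantom(seed = 8, shape = c(48, 48))
  A <- ph$clean$ac
  tri <- tri_contrast(A, A, A)
  feat_entropy <- image_entropy(suppressWarnings(normalize_intensity({
    g <- xgifuse:::sobel_gradients(A)
    sqrt(g$gx^2 + g$gy^2)
  })))
  expect_equal(feature_mutual_information(tri, A), 3 * feat_entropy,
               tolerance = 1e-12)
})

test_that("SSIM is 1 on identical images, symmetric, and matches the window loop", {
  A <- random_image(32, 32, seed = 9)
  B <- random_image(32, 32, seed = 10)
  expect_equal(image_ssim(A, A), 1)
  expect_equal(image_ssim(A, B), image_ssim(B, A), tolerance = 1e-12)
  expect_equal(image_ssim(A, B), ssim_oracle(A, B), tolerance = 1e-9)
  expect_lt(image_ssim(A, 1 - A), 1)
})

test_that("FSIM is 1 on identical images, symmetric, bounded, and pools correctly", {
  ph <- small_phantom(seed = 11, shape = c(32, 32))
  A <- ph$clean$ac
  B <- random_image(32, 32, seed = 12)
  expect_equal(image_fsim(A, A), 1)
  f <- image_fsim(A, B)
  expect_equal(f, image_fsim(B, A), tolerance = 1e-12)
  expect_gt(f, 0); expect_lte(f, 1)
  # pooling agrees with a scalar loop over the same feature maps
  pc_a <- xgifuse:::phase_congruency(A * 255)
  pc_b <- xgifuse:::phase_congruency(B * 255)
  ks <- matrix(c(3, 0, -3, 10, 0, -10, 3, 0, -3), 3, 3, byrow = TRUE) / 16
  gm <- function(x) {
    gx <- xgifuse:::conv3x3_replicate(x, ks)
    gy <- xgifuse:::conv3x3_replicate(x, t(ks))
    sqrt(gx^2 + gy^2)
  }
  g_a <- gm(A * 255); g_b <- gm(B * 255)
  num <- 0; den <- 0
  for (i in 1:32) for (j in 1:32) {
    spc <- (2 * pc_a[i, j] * pc_b[i, j] + 0.85) / (pc_a[i, j]^2 + pc_b[i, j]^2 + 0.85)
    sg <- (2 * g_a[i, j] * g_b[i, j] + 160) / (g_a[i, j]^2 + g_b[i, j]^2 + 160)
    w <- max(pc_a[i, j], pc_b[i, j])
    num <- num + spc * sg * w
    den <- den + w
  }
  expect_equal(f, num / den, tolerance = 1e-9)
})

test_that("edge strength is maximal for identity fusion and minimal for a flat fuse", {
  ph <- small_phantom(seed = 13, shape = c(32, 32))
  A <- ph$clean$ac
  tri <- tri_contrast(A, A, A)
  expect_equal(edge_strength(tri, A), edge_strength_max(), tolerance = 1e-12)
  flat <- matrix(0.5, 32, 32)
  expect_lt(edge_strength(tri, flat), 0.05)
  # brute-force per-pixel agreement on a genuine triple
  ph2 <- small_phantom(seed = 14, shape = c(32, 32))
  fused <- mean_fuse(ph2$clean)
  expect_equal(edge_strength(ph2$clean, fused), es_oracle(ph2$clean, fused),
               tolerance = 1e-9)
})

test_that("PSD concentrates DC, localizes sinusoids, and satisfies Parseval", {
  const <- matrix(0.3, 32, 32)
  p <- psd_curve(const)
  expect_equal(p$power[p$radius == 0], 0.3^2 * 32 * 32)
  expect_lt(max(p$power[p$radius > 0]), 1e-16)
  # horizontal sinusoid at radius 4 (varies along columns)
  Z <- matrix(sin(2 * pi * 4 * (0:31) / 32), 32, 32)
  ps <- psd_curve(Z)
  expect_equal(ps$radius[which.max(ps$power)], 4)
  # Parseval: total (pre-averaging) power equals the image energy
  R <- random_image(20, 28, seed = 15)
  pr <- psd_curve(R)
  expect_equal(sum(pr$power * pr$count), sum(R^2), tolerance = 1e-8)
  expect_equal(pr, psd_oracle(R), tolerance = 1e-10)
})

test_that("the report composes the suite and honors the ROI contract", {
  ph <- small_phantom(seed = 16, shape = c(48, 48))
  A <- ph$clean$ac
  tri <- tri_contrast(A, A, A)
  rep_id <- fusion_report(tri, A)
  expect_equal(rep_id$ssim, 1)
  expect_equal(rep_id$fsim, 1)
  expect_equal(rep_id$es, edge_strength_max(), tolerance = 1e-12)
  expect_equal(rep_id$ff, 3 * image_entropy(A), tolerance = 1e-12)
  # explicit full-frame ROI is the same as no ROI
  rep_full <- fusion_report(tri, A, roi = c(1, 1, 49, 49))
  for (nm in c("es", "sf", "sd", "entropy", "fmi", "fsim", "ff", "ssim")) {
    expect_equal(rep_full[[nm]], rep_id[[nm]], tolerance = 1e-12)
  }
  # ROI crop before vs after: metrics only see the cropped pixels
  fused <- mean_fuse(ph$clean)
  roi <- c(9, 9, 41, 41)
  rep_roi <- fusion_report(ph$clean, fused, roi)
  crop <- function(x) x[9:40, 9:40]
  ctri <- tri_contrast(crop(ph$clean$ac), crop(ph$clean$dpc), crop(ph$clean$dfc))
  rep_pre <- fusion_report(ctri, crop(fused))
  for (nm in c("es", "sf", "sd", "entropy", "fmi", "fsim", "ff", "ssim")) {
    expect_equal(rep_roi[[nm]], rep_pre[[nm]], tolerance = 1e-12)
  }
  expect_error(fusion_report(tri, A, roi = c(10, 10, 10, 20)), "empty|bounds")
  expect_error(fusion_report(tri, A, roi = c(1, 1, 60, 60)), "bounds")
})

test_that("report serialization writes valid JSON and CSV", {
  ph <- small_phantom(seed = 17, shape = c(32, 32))
  rep <- fusion_report(ph$clean, mean_fuse(ph$clean))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path, csv = TRUE)
  back <- jsonlite::read_json(path)
  expect_equal(back$ssim, rep$ssim, tolerance = 1e-9)
  tab <- read.csv(sub("\\.json$", ".csv", path))
  expect_identical(tab$measure, c("ES", "SF", "SD", "ENTROPY", "FMI", "FSIM", "FF", "SSIM"))
})
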