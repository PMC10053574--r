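make_bands <- function(M, N, seed) {
  set.seed(seed)
  list(ac = matrix(rnorm(M * N), M, N), dpc = matrix(rnorm(M * N), M, N),
       dfc = matrix(rnorm(M * N), M, N))
}

test_that("lowpass selection follows the weighted ignition comparison", {
  h <- make_bands(8, 8, 1)
  t_same <- matrix(5L, 8, 8)
  # identical ignition everywhere: a = 0.55 weights AC above the others
  expect_identical(
    fuse_lowpass(h$ac, h$dpc, h$dfc, t_same, t_same, t_same, a = 0.55), h$ac)
  # a -> 1 forces the AC coefficient whenever AC fires at all
  set.seed(2)
  t_ac <- matrix(sample(1:10, 64, TRUE), 8, 8)
  t_dpc <- matrix(sample(0:10, 64, TRUE), 8, 8)
  t_dfc <- matrix(sample(0:10, 64, TRUE), 8, 8)
  expect_identical(
    fuse_lowpass(h$ac, h$dpc, h$dfc, t_ac, t_dpc, t_dfc, a = 0.99), h$ac)
  # scalar check: ignitions (1,3,2) at a=0.55 give scores (0.55,1.35,0.90)
  out <- fuse_lowpass(h$ac, h$dpc, h$dfc,
                      matrix(1, 8, 8), matrix(3, 8, 8), matrix(2, 8, 8), a = 0.55)
  expect_identical(out, h$dpc)
})

test_that("highpass seven-case rule resolves the documented examples", {
  h <- make_bands(4, 4, 3)
  w <- c(0.41, 0.29, 0.30)
  const <- function(v) matrix(v, 4, 4)
  # one dominant channel
  expect_identical(
    fuse_highpass(h$ac, h$dpc, h$dfc, const(10), const(2), const(2), w, 1), h$ac)
  # no significant differences: published-weight blend
  expect_equal(
    fuse_highpass(h$ac, h$dpc, h$dfc, const(5), const(5), const(5), w, 1),
    0.41 * h$ac + 0.29 * h$dpc + 0.30 * h$dfc)
  # two channels beat the third, neither beats the other: average the pair
  expect_equal(
    fuse_highpass(h$ac, h$dpc, h$dfc, const(8), const(7), const(2), w, 1),
    (h$ac + h$dpc) / 2)
})

test_that("vectorized rules agree with scalar enumeration over all ignition triples", {
  grid <- as.matrix(expand.grid(0:10, 0:10, 0:10))
  n <- nrow(grid)  # 1331
  M <- 121; N <- 11
  t_ac <- matrix(grid[, 1], M, N)
  t_dpc <- matrix(grid[, 2], M, N)
  t_dfc <- matrix(grid[, 3], M, N)
  h <- make_bands(M, N, 4)
  w <- c(0.41, 0.29, 0.30)
  for (Tth in c(0, 1, 3)) {
    out_h <- fuse_highpass(h$ac, h$dpc, h$dfc, t_ac, t_dpc, t_dfc, w, Tth)
    out_l <- fuse_lowpass(h$ac, h$dpc, h$dfc, t_ac, t_dpc, t_dfc, a = 0.55)
    for (p in seq_len(n)) {
      expect_identical(out_h[p], fuse_high_scalar(
        c(h$ac[p], h$dpc[p], h$dfc[p]), grid[p, ], w, Tth))
      expect_identical(out_l[p], fuse_low_scalar(
        c(h$ac[p], h$dpc[p], h$dfc[p]), grid[p, ], 0.55))
    }
  }
})

test_that("fused highpass coefficients stay in the per-pixel convex hull", {
  h <- make_bands(16, 16, 5)
  set.seed(6)
  ts <- lapply(1:3, function(i) matrix(sample(0:10, 256, TRUE), 16, 16))
  out <- fuse_highpass(h$ac, h$dpc, h$dfc, ts[[1]], ts[[2]], ts[[3]],
                       c(0.41, 0.29, 0.30), 1)
  lo <- pmin(h$ac, h$dpc, h$dfc)
  hi <- pmax(h$ac, h$dpc, h$dfc)
  expect_true(all(out >= lo - 1e-12 & out <= hi + 1e-12))
})

test_that("fusing three identical images returns the input", {
  img <- random_image(64, 64, seed = 7)
  tri <- tri_contrast(img, img, img)
  fused <- fuse_tricontrast(tri, fast_config())
  expect_lt(max(abs(fused - img)), 1e-6)
})

test_that("the full fusion is deterministic and transfers exclusive features", {
  ph <- small_phantom(seed = 8, shape = c(64, 64), noise = c(0, 0, 0))
  cfg <- fast_config()
  f1 <- fuse_tricontrast(ph$tri, cfg)
  f2 <- fuse_tricontrast(ph$tri, cfg)
  expect_identical(f1, f2)
  lap <- function(img, m) mean(abs(laplacian4(img)[m]))
  expect_gt(lap(f1, ph$dfc_only_mask), lap(ph$tri$ac, ph$dfc_only_mask))
})

test_that("shape mismatches and bad weights are rejected", {
  h <- make_bands(8, 8, 9)
  expect_error(fuse_lowpass(h$ac, h$dpc, matrix(0, 4, 4),
                            h$ac, h$ac, h$ac, 0.55), "shape mismatch")
  expect_error(fuse_highpass(h$ac, h$dpc, h$dfc, h$ac, h$ac, h$ac,
                             weights = c(0.5, 0.5, 0.5), Tth = 1), "sum to 1")
})
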