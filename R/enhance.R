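#' Contrast-limited adaptive histogram equalization
#'
#' Classic tile-based CLAHE: the image is divided into a `tiles` grid, each
#' tile's histogram (over `bins` uniform bins of \[0, 1\]) is clipped at a
#' limit derived from the normalized clip parameter and the excess is
#' redistributed, each tile gets an equalization mapping from its clipped
#' CDF, and pixel values are bilinearly interpolated between the mappings
#' of the four surrounding tile centers to avoid block discontinuities.
#' The clip limit follows the MATLAB convention: actual limit =
#' `minClip + round(clip * (tile_pixels - minClip))` with
#' `minClip = ceiling(tile_pixels / bins)`, so `clip` near 0 suppresses
#' almost all redistribution and the output approaches the input.
#' A constant image is returned unchanged (degenerate histogram).
#'
#' @param image numeric matrix in \[0, 1\].
#' @param tiles integer (rows, cols) tile grid.
#' @param clip normalized clip limit in (0, 1).
#' @param bins histogram bin count.
#' @return equalized matrix in \[0, 1\].
#' @export
clahe <- function(image, tiles = c(5L, 5L), clip = 0.00125, bins = 500L) {
  assert_radiograph(image)
  tiles <- as.integer(tiles)
  M <- nrow(image); N <- ncol(image)
  nr <- tiles[1]; nc <- tiles[2]
  if (nr > M || nc > N) stop("more CLAHE tiles than pixels", call. = FALSE)
  if (diff(range(image)) <= 0) return(image)

  bins <- as.integer(bins)
  bin_idx <- quantize_levels(image, bins)
  row_edges <- floor(M * (0:nr) / nr)
  col_edges <- floor(N * (0:nc) / nc)
  row_ctr <- (row_edges[-1] + row_edges[-(nr + 1)] + 1) / 2
  col_ctr <- (col_edges[-1] + col_edges[-(nc + 1)] + 1) / 2

  # per-tile clipped equalization mappings (bin index -> value in (0, 1])
  maps <- vector("list", nr * nc)
  for (r in seq_len(nr)) {
    ri <- (row_edges[r] + 1):row_edges[r + 1]
    for (c in seq_len(nc)) {
      ci <- (col_edges[c] + 1):col_edges[c + 1]
      h <- tabulate(bin_idx[ri, ci], nbins = bins)
      npix <- length(ri) * length(ci)
      min_clip <- ceiling(npix / bins)
      limit <- min_clip + round(clip * (npix - min_clip))
      for (pass in 1:20) {
        excess <- sum(pmax(h - limit, 0))
        if (excess <= 0) break
        h <- pmin(h, limit)
        h <- h + excess / bins
      }
      maps[[(r - 1) * nc + c]] <- cumsum(h) / sum(h)
    }
  }

  # bilinear blend of the four surrounding tile mappings
  ri_all <- seq_len(M); ci_all <- seq_len(N)
  tr <- findInterval(ri_all, row_ctr)   # 0..nr
  tc <- findInterval(ci_all, col_ctr)
  r_lo <- pmax(tr, 1L); r_hi <- pmin(tr + 1L, nr)
  c_lo <- pmax(tc, 1L); c_hi <- pmin(tc + 1L, nc)
  wr <- ifelse(r_lo == r_hi, 0,
               (ri_all - row_ctr[r_lo]) / (row_ctr[r_hi] - row_ctr[r_lo]))
  wc <- ifelse(c_lo == c_hi, 0,
               (ci_all - col_ctr[c_lo]) / (col_ctr[c_hi] - col_ctr[c_lo]))
  out <- matrix(0, M, N)
  for (r in sort(unique(c(r_lo, r_hi)))) {
    rows_lo <- which(r_lo == r); rows_hi <- which(r_hi == r)
    for (c in sort(unique(c(c_lo, c_hi)))) {
      m <- maps[[(r - 1) * nc + c]]
      cols_lo <- which(c_lo == c); cols_hi <- which(c_hi == c)
      if (length(rows_lo) && length(cols_lo)) {
        out[rows_lo, cols_lo] <- out[rows_lo, cols_lo] +
          outer(1 - wr[rows_lo], 1 - wc[cols_lo]) * m[bin_idx[rows_lo, cols_lo]]
      }
      if (length(rows_lo) && length(cols_hi)) {
        out[rows_lo, cols_hi] <- out[rows_lo, cols_hi] +
          outer(1 - wr[rows_lo], wc[cols_hi]) * m[bin_idx[rows_lo, cols_hi]]
      }
      if (length(rows_hi) && length(cols_lo)) {
        out[rows_hi, cols_lo] <- out[rows_hi, cols_lo] +
          outer(wr[rows_hi], 1 - wc[cols_lo]) * m[bin_idx[rows_hi, cols_lo]]
      }
      if (length(rows_hi) && length(cols_hi)) {
        out[rows_hi, cols_hi] <- out[rows_hi, cols_hi] +
          outer(wr[rows_hi], wc[cols_hi]) * m[bin_idx[rows_hi, cols_hi]]
      }
    }
  }
  clip01(out)
}

#' Discrete Laplacian (4-neighbor, replicate boundary)
#'
#' Sum of second differences along rows and columns; an interior unit
#' impulse maps to -4 at its pixel and +1 at its four neighbors.
#'
#' @param image numeric matrix.
#' @return Laplacian matrix, same shape.
#' @export
laplacian4 <- function(image) {
  M <- nrow(image); N <- ncol(image)
  up <- image[c(1, 1:(M - 1)), , drop = FALSE]
  down <- image[c(2:M, M), , drop = FALSE]
  left <- image[, c(1, 1:(N - 1)), drop = FALSE]
  right <- image[, c(2:N, N), drop = FALSE]
  up + down + left + right - 4 * image
}

#' Entropy-adaptive unsharp sharpening
#'
#' Unsharp masking `I - C * Laplacian(I)` where the gain `C` is chosen
#' adaptively: the entropy of the clipped candidate image is evaluated over
#' a grid of gains, the entropy-maximizing gain is divided by `alpha`
#' (guarding against over-sharpening), and the damped gain is applied.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param alpha gain damping divisor (> 0).
#' @param C_grid numeric (min, max, step) search grid.
#' @param levels quantization levels for the entropy computation.
#' @return sharpened matrix in \[0, 1\], with the applied gain in attribute
#'   `C_final` and the entropy-maximizing gain in `C_max`.
#' @export
adaptive_sharpen <- function(image, alpha = 3, C_grid = c(0, 5, 0.05),
                             levels = 256L) {
  assert_radiograph(image)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  Cs <- seq(C_grid[1], C_grid[2], by = C_grid[3])
  if (!length(Cs)) stop("empty sharpening gain grid", call. = FALSE)
  lap <- laplacian4(image)
  ent <- vapply(Cs, function(C) shannon_entropy(clip01(image - C * lap), levels),
                numeric(1))
  C_max <- Cs[which.max(ent)]
  C_final <- C_max / alpha
  out <- clip01(image - C_final * lap)
  attr(out, "C_final") <- C_final
  attr(out, "C_max") <- C_max
  out
}

#' Sigmoid tone (gamma-style) correction
#'
#' Pixelwise logistic mapping `1 / (1 + exp(lambda1 * (lambda2 - v)))` —
#' strictly order-preserving for `lambda1 > 0`, with midpoint value 0.5 at
#' `v = lambda2` — followed by a min-max rescale to \[0, 1\].
#'
#' @param image numeric matrix in \[0, 1\].
#' @param lambda1 slope of the sigmoid.
#' @param lambda2 midpoint of the sigmoid.
#' @param rescale min-max rescale the result (default `TRUE`).
#' @return tone-corrected matrix.
#' @export
gamma_sigmoid <- function(image, lambda1 = 4.8, lambda2 = 0.49,
                          rescale = TRUE) {
  assert_radiograph(image)
  g <- 1 / (1 + exp(lambda1 * (lambda2 - image)))
  if (rescale) g <- suppressWarnings(normalize_intensity(g))
  g
}

#' Full enhancement stage
#'
#' Min-max normalizes the fused image (the fusion operator does not
#' rescale), then applies [clahe()], [adaptive_sharpen()] and
#' [gamma_sigmoid()] in order. Enhancement is a function of the fused image
#' alone; it cannot add information from the source channels.
#'
#' @param image fused image matrix.
#' @param params an [enhance_params()] list.
#' @return enhanced matrix in \[0, 1\].
#' @export
enhance_image <- function(image, params = enhance_params()) {
  img <- suppressWarnings(normalize_intensity(image))
  img <- clahe(img, params$clahe_tiles, params$clahe_clip, params$clahe_bins)
  img <- adaptive_sharpen(img, params$sharpen_alpha, params$sharpen_C_grid)
  gamma_sigmoid(img, params$lambda1, params$lambda2)
}
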