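#' @name fusion-metrics
#' @title Fusion quality measures
#' @description
#' The evaluation suite used to compare fusion schemes: spatial frequency,
#' standard deviation, entropy, mutual information / fusion factor, feature
#' mutual information, SSIM, FSIM, edge-preservation strength, and the
#' radially averaged power spectral density. All measures operate on
#' \[0, 1\] grayscale matrices; histogram-based measures quantize to 256
#' uniform levels (the 8-bit convention) unless stated otherwise.
NULL

# 3x3 correlation with replicate boundary (shared by Sobel/Scharr operators)
conv3x3_replicate <- function(x, k) {
  M <- nrow(x); N <- ncol(x)
  p <- x[c(1, 1:M, M), c(1, 1:N, N)]
  out <- matrix(0, M, N)
  for (di in -1:1) for (dj in -1:1) {
    out <- out + k[di + 2, dj + 2] * p[(2 + di):(M + 1 + di), (2 + dj):(N + 1 + dj)]
  }
  out
}

sobel_gradients <- function(x) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)  # d/dcol
  ky <- t(kx)                                                        # d/drow
  list(gx = conv3x3_replicate(x, kx), gy = conv3x3_replicate(x, ky))
}

#' Spatial frequency
#'
#' `SF = sqrt(RF^2 + CF^2)` with the row frequency `RF` the RMS of
#' horizontal first differences and the column frequency `CF` the RMS of
#' vertical first differences, both normalized by the full pixel count.
#' Higher values mean more local detail.
#'
#' @param image numeric matrix.
#' @return nonnegative scalar.
#' @export
spatial_frequency <- function(image) {
  stopifnot(is.matrix(image))
  M <- nrow(image); N <- ncol(image)
  rf2 <- sum((image[, 2:N, drop = FALSE] - image[, 1:(N - 1), drop = FALSE])^2) / (M * N)
  cf2 <- sum((image[2:M, , drop = FALSE] - image[1:(M - 1), , drop = FALSE])^2) / (M * N)
  sqrt(rf2 + cf2)
}

#' Image standard deviation (population) — the contrast measure
#' @param image numeric matrix.
#' @return nonnegative scalar.
#' @export
image_sd <- function(image) {
  stopifnot(is.matrix(image))
  sqrt(mean((image - mean(image))^2))
}

#' Image entropy in bits
#'
#' Shannon entropy of the `levels`-level uniform quantization of \[0, 1\].
#'
#' @param image numeric matrix in \[0, 1\].
#' @param levels number of gray levels.
#' @return entropy in `[0, log2(levels)]` bits.
#' @export
image_entropy <- function(image, levels = 256L) {
  stopifnot(is.matrix(image))
  shannon_entropy(image, levels)
}

#' Mutual information between two images (bits)
#'
#' Computed from the `levels x levels` joint histogram of the uniform
#' quantizations; `mutual_information(a, a)` equals `image_entropy(a)`.
#'
#' @param a,b numeric matrices in \[0, 1\], one shape.
#' @param levels quantization levels.
#' @return nonnegative scalar (bits).
#' @export
mutual_information <- function(a, b, levels = 256L) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  ia <- quantize_levels(a, levels)
  ib <- quantize_levels(b, levels)
  joint <- tabulate((ia - 1L) * levels + ib, nbins = levels * levels)
  p <- joint / length(ia)
  pa <- tabulate(ia, nbins = levels) / length(ia)
  pb <- tabulate(ib, nbins = levels) / length(ib)
  pm <- matrix(p, levels, levels)        # [b, a] layout
  denom <- outer(pb, pa)
  nz <- pm > 0
  sum(pm[nz] * log2(pm[nz] / denom[nz]))
}

#' Fusion factor
#'
#' Sum of the mutual information between each source channel and the fused
#' image; larger values mean more source information retained.
#'
#' @param tri a [tri_contrast()] set.
#' @param fused fused image matrix.
#' @param levels quantization levels.
#' @return nonnegative scalar (bits).
#' @export
fusion_factor <- function(tri, fused, levels = 256L) {
  tri <- as_tri_contrast(tri)
  mutual_information(tri$ac, fused, levels) +
    mutual_information(tri$dpc, fused, levels) +
    mutual_information(tri$dfc, fused, levels)
}

#' Feature mutual information
#'
#' Mutual information computed between gradient-magnitude feature images
#' (Sobel magnitude, min-max normalized per image), summed over the three
#' source channels versus the fused image. Measures how much *feature*
#' content survived fusion rather than raw intensity agreement.
#'
#' @inheritParams fusion_factor
#' @return nonnegative scalar (bits).
#' @export
feature_mutual_information <- function(tri, fused, levels = 256L) {
  tri <- as_tri_contrast(tri)
  feat <- function(x) {
    g <- sobel_gradients(x)
    suppressWarnings(normalize_intensity(sqrt(g$gx^2 + g$gy^2)))
  }
  ff <- feat(fused)
  mutual_information(feat(tri$ac), ff, levels) +
    mutual_information(feat(tri$dpc), ff, levels) +
    mutual_information(feat(tri$dfc), ff, levels)
}

#' Structural similarity index (mean SSIM)
#'
#' Sliding-window SSIM with the standard dialect: 11 x 11 Gaussian window
#' (sigma 1.5), `k1 = 0.01`, `k2 = 0.03`, dynamic range `L = 1`. Windows
#' are "valid" (fully inside the image); the map is averaged.
#'
#' @param a,b numeric matrices in \[0, 1\], one shape, at least 16 x 16.
#' @return scalar in \[-1, 1\] (1 for identical images).
#' @export
image_ssim <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  if (min(dim(a)) < 16) stop("images must be at least 16 x 16 for SSIM", call. = FALSE)
  win <- 11L; sigma <- 1.5; r <- (win - 1L) %/% 2L
  g <- exp(-((-r:r)^2) / (2 * sigma^2)); g <- g / sum(g)
  G <- outer(g, g)
  M <- nrow(a); N <- ncol(a)
  vi <- (r + 1):(M - r); vj <- (r + 1):(N - r)
  f <- function(x) conv2_circular(x, G)[vi, vj, drop = FALSE]
  mu_a <- f(a); mu_b <- f(b)
  va <- f(a^2) - mu_a^2
  vb <- f(b^2) - mu_b^2
  vab <- f(a * b) - mu_a * mu_b
  C1 <- (0.01)^2; C2 <- (0.03)^2   # (k L)^2 with L = 1
  smap <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
          ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(smap)
}

#' Overall SSIM of a fusion result
#'
#' Mean of the three channel-versus-fused SSIM values.
#' @inheritParams fusion_factor
#' @return scalar.
#' @export
overall_ssim <- function(tri, fused) {
  tri <- as_tri_contrast(tri)
  (image_ssim(tri$ac, fused) + image_ssim(tri$dpc, fused) +
     image_ssim(tri$dfc, fused)) / 3
}

# Local-energy phase congruency over a log-Gabor quadrature filter bank.
# Returns a map in [0, 1]; dimensionless and contrast-invariant (up to eps).
phase_congruency <- function(image, nscale = 4L, norient = 4L,
                             min_wavelength = 6, mult = 2, sigma_onf = 0.55) {
  M <- nrow(image); N <- ncol(image)
  fx <- ifelse(seq_len(N) - 1 < N / 2, seq_len(N) - 1, seq_len(N) - 1 - N) / N
  fy <- ifelse(seq_len(M) - 1 < M / 2, seq_len(M) - 1, seq_len(M) - 1 - M) / M
  X <- matrix(fx, M, N, byrow = TRUE)
  Y <- matrix(fy, M, N)
  radius <- sqrt(X^2 + Y^2); radius[1, 1] <- 1
  theta <- atan2(Y, X)
  IM <- fft(image)
  sin_t <- sin(theta); cos_t <- cos(theta)
  sigma_theta <- pi / norient / 1.5
  E_total <- matrix(0, M, N)
  A_total <- matrix(0, M, N)
  for (o in seq_len(norient) - 1L) {
    ang <- o * pi / norient
    ds <- sin_t * cos(ang) - cos_t * sin(ang)
    dc <- cos_t * cos(ang) + sin_t * sin(ang)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * sigma_theta^2))
    sumE <- matrix(0, M, N); sumO <- matrix(0, M, N); sumAn <- matrix(0, M, N)
    for (s in seq_len(nscale) - 1L) {
      f0 <- 1 / (min_wavelength * mult^s)
      logg <- exp(-(log(radius / f0))^2 / (2 * log(sigma_onf)^2))
      logg[1, 1] <- 0
      EO <- fft(IM * (logg * spread), inverse = TRUE) / (M * N)
      sumE <- sumE + Re(EO)
      sumO <- sumO + Im(EO)
      sumAn <- sumAn + Mod(EO)
    }
    E_total <- E_total + sqrt(sumE^2 + sumO^2)
    A_total <- A_total + sumAn
  }
  E_total / (A_total + 1e-4)
}

#' Feature similarity index (FSIM)
#'
#' Similarity of two images from two low-level feature maps: phase
#' congruency (log-Gabor local energy, 4 scales x 4 orientations) and
#' gradient magnitude (Scharr operator). Local similarities are combined
#' multiplicatively and pooled with the pointwise maximum phase congruency
#' as weight; constants `T1 = 0.85`, `T2 = 160` on the 0-255 gradient
#' scale (images are rescaled to 0-255 internally for this metric only).
#'
#' @param a,b numeric matrices in \[0, 1\], one shape, at least 16 x 16.
#' @return scalar in \[0, 1\] (1 for identical images).
#' @export
image_fsim <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  if (min(dim(a)) < 16) stop("images must be at least 16 x 16 for FSIM", call. = FALSE)
  a255 <- a * 255; b255 <- b * 255
  pc_a <- phase_congruency(a255)
  pc_b <- phase_congruency(b255)
  ks <- matrix(c(3, 0, -3, 10, 0, -10, 3, 0, -3), 3, 3, byrow = TRUE) / 16
  gm <- function(x) {
    gx <- conv3x3_replicate(x, ks)
    gy <- conv3x3_replicate(x, t(ks))
    sqrt(gx^2 + gy^2)
  }
  g_a <- gm(a255); g_b <- gm(b255)
  T1 <- 0.85; T2 <- 160
  s_pc <- (2 * pc_a * pc_b + T1) / (pc_a^2 + pc_b^2 + T1)
  s_g <- (2 * g_a * g_b + T2) / (g_a^2 + g_b^2 + T2)
  pcm <- pmax(pc_a, pc_b)
  sum(s_pc * s_g * pcm) / sum(pcm)
}

#' Overall FSIM of a fusion result
#'
#' Mean of the three channel-versus-fused FSIM values.
#' @inheritParams fusion_factor
#' @return scalar in \[0, 1\].
#' @export
overall_fsim <- function(tri, fused) {
  tri <- as_tri_contrast(tri)
  (image_fsim(tri$ac, fused) + image_fsim(tri$dpc, fused) +
     image_fsim(tri$dfc, fused)) / 3
}

# Per-pixel edge-preservation factor between one source and the fused image
# (Sobel strength + orientation, each passed through the published sigmoids).
edge_preservation_map <- function(src, fused,
                                  Gamma_g = 0.9994, kappa_g = -15, sigma_g = 0.5,
                                  Gamma_a = 0.9879, kappa_a = -22, sigma_a = 0.8) {
  gs <- sobel_gradients(src)
  gf <- sobel_gradients(fused)
  g_s <- sqrt(gs$gx^2 + gs$gy^2)
  g_f <- sqrt(gf$gx^2 + gf$gy^2)
  a_s <- ifelse(gs$gx == 0, pi / 2 * sign(gs$gy), atan(gs$gy / gs$gx))
  a_f <- ifelse(gf$gx == 0, pi / 2 * sign(gf$gy), atan(gf$gy / gf$gx))
  G <- ifelse(g_s == g_f, 1, ifelse(g_s > g_f, g_f / pmax(g_s, .Machine$double.xmin),
                                    g_s / pmax(g_f, .Machine$double.xmin)))
  dA <- abs(a_s - a_f)
  dA <- ifelse(dA > pi / 2, pi - dA, dA)
  A <- 1 - dA / (pi / 2)
  Qg <- Gamma_g / (1 + exp(kappa_g * (G - sigma_g)))
  Qa <- Gamma_a / (1 + exp(kappa_a * (A - sigma_a)))
  list(Q = Qg * Qa, w = g_s)
}

#' Maximum attainable edge-strength value
#'
#' Value of the edge-preservation sigmoids at perfect strength and
#' orientation agreement; [edge_strength()] equals this when the fused
#' image reproduces identical inputs exactly.
#'
#' @return scalar slightly below 1.
#' @export
edge_strength_max <- function() {
  (0.9994 / (1 + exp(-15 * (1 - 0.5)))) * (0.9879 / (1 + exp(-22 * (1 - 0.8))))
}

#' Edge strength of a fusion result
#'
#' Relative amount of edge information transferred from the three source
#' channels into the fused image: per-pixel edge-preservation factors
#' (gradient strength and orientation agreement, each mapped through the
#' published sigmoid constants) are averaged with the source gradient
#' magnitudes as weights.
#'
#' @inheritParams fusion_factor
#' @return scalar in \[0, 1\] (up to the sigmoid ceilings).
#' @export
edge_strength <- function(tri, fused) {
  tri <- as_tri_contrast(tri)
  if (!all(dim(tri$ac) == dim(fused))) stop("shape mismatch", call. = FALSE)
  m_ac <- edge_preservation_map(tri$ac, fused)
  m_dpc <- edge_preservation_map(tri$dpc, fused)
  m_dfc <- edge_preservation_map(tri$dfc, fused)
  wsum <- sum(m_ac$w) + sum(m_dpc$w) + sum(m_dfc$w)
  if (wsum == 0) return(edge_strength_max())  # edge-free degenerate inputs
  (sum(m_ac$Q * m_ac$w) + sum(m_dpc$Q * m_dpc$w) + sum(m_dfc$Q * m_dfc$w)) / wsum
}

#' Radially averaged power spectral density
#'
#' 2-D periodogram `|C|^2 / n` (`n = M * N`, unnormalized DFT coefficients
#' `C`) averaged over integer-radius frequency annuli. The sum of `power *
#' count` over all bins equals `sum(image^2)` (Parseval). For curve
#' comparisons use radii up to the Nyquist ring `floor(min(M, N) / 2)`.
#'
#' @param image numeric matrix.
#' @return data frame with columns `radius` (integer), `power` (mean power
#'   in the annulus), `count` (number of frequency samples).
#' @export
psd_curve <- function(image) {
  stopifnot(is.matrix(image))
  M <- nrow(image); N <- ncol(image)
  P <- Mod(fft(image))^2 / (M * N)
  fu <- ifelse(seq_len(M) - 1 < M / 2, seq_len(M) - 1, seq_len(M) - 1 - M)
  fv <- ifelse(seq_len(N) - 1 < N / 2, seq_len(N) - 1, seq_len(N) - 1 - N)
  R <- round(sqrt(outer(fu^2, fv^2, `+`)))
  radii <- sort(unique(as.vector(R)))
  power <- vapply(radii, function(r) mean(P[R == r]), numeric(1))
  count <- vapply(radii, function(r) sum(R == r), numeric(1))
  data.frame(radius = radii, power = power, count = count)
}

#' Metric report for one fusion result
#'
#' Computes the full measure suite on the (optionally ROI-cropped) images.
#' The ROI rectangle is half-open: rows `row0 .. row1 - 1`, columns
#' `col0 .. col1 - 1`, 1-based.
#'
#' @param tri a [tri_contrast()] source set.
#' @param fused fused image matrix (same shape, values in \[0, 1\]).
#' @param roi optional integer (row0, col0, row1, col1); `NULL` for the
#'   full frame.
#' @param levels quantization levels for histogram-based measures.
#' @return a list of class `metric_report`.
#' @export
fusion_report <- function(tri, fused, roi = NULL, levels = 256L) {
  tri <- as_tri_contrast(tri)
  if (!all(dim(tri$ac) == dim(fused))) stop("shape mismatch", call. = FALSE)
  crop <- function(x) x
  if (!is.null(roi)) {
    roi <- as.integer(roi)
    if (length(roi) != 4) stop("roi must be (row0, col0, row1, col1)", call. = FALSE)
    if (roi[1] < 1 || roi[2] < 1 || roi[3] > nrow(fused) + 1L ||
        roi[4] > ncol(fused) + 1L || roi[3] <= roi[1] || roi[4] <= roi[2]) {
      stop("roi is empty or out of bounds", call. = FALSE)
    }
    crop <- function(x) x[roi[1]:(roi[3] - 1L), roi[2]:(roi[4] - 1L), drop = FALSE]
  }
  ctri <- tri_contrast(crop(tri$ac), crop(tri$dpc), crop(tri$dfc))
  cf <- crop(fused)
  structure(list(
    es = edge_strength(ctri, cf),
    sf = spatial_frequency(cf),
    sd = image_sd(cf),
    entropy = image_entropy(cf, levels),
    fmi = feature_mutual_information(ctri, cf, levels),
    fsim = overall_fsim(ctri, cf),
    ff = fusion_factor(ctri, cf, levels),
    ssim = overall_ssim(ctri, cf),
    psd = psd_curve(cf),
    roi = roi
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Fusion quality report",
      if (!is.null(x$roi)) sprintf(" (ROI %s)", paste(x$roi, collapse = ",")),
      "\n", sep = "")
  for (nm in c("es", "sf", "sd", "entropy", "fmi", "fsim", "ff", "ssim")) {
    cat(sprintf("  %-8s %.4f\n", toupper(nm), x[[nm]]))
  }
  cat(sprintf("  PSD      %d radial bins (Nyquist ring %d)\n",
              nrow(x$psd), max(x$psd$radius)))
  invisible(x)
}

#' Write a metric report as JSON (and optionally CSV)
#'
#' @param report a `metric_report`.
#' @param path output `.json` path; a sibling `.csv` of the scalar
#'   measures is written when `csv = TRUE`.
#' @param csv also write the CSV table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv = FALSE) {
  stopifnot(inherits(report, "metric_report"))
  scalars <- report[c("es", "sf", "sd", "entropy", "fmi", "fsim", "ff", "ssim")]
  payload <- c(scalars, list(roi = report$roi, psd = report$psd))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  if (csv) {
    utils::write.csv(data.frame(measure = toupper(names(scalars)),
                                value = unlist(scalars)),
                     sub("\\.json$", ".csv", path), row.names = FALSE)
  }
  invisible(path)
}
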