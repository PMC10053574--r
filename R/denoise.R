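#' Adaptive Wiener filter
#'
#' Pixelwise adaptive (locally linear minimum-MSE) smoothing: with local
#' mean `m` and local variance `s2` over an `X x Y` window, the output is
#' `m + max(s2 - v2, 0) / s2 * (I - m)`, where `v2` is the noise variance.
#' If `noise_variance` is not supplied it is estimated as the mean of all
#' local variances. Flat neighborhoods (`s2 = 0`) return the local mean.
#' Local moments use symmetric (mirror) boundary padding; the result is
#' clipped to \[0, 1\].
#'
#' @param image numeric matrix in \[0, 1\].
#' @param window integer (X, Y) window size; both odd and >= 3.
#' @param noise_variance optional known noise variance (>= 0); `NULL` to
#'   estimate from the image.
#' @return filtered matrix, same shape, in \[0, 1\].
#' @export
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' out <- wiener_filter(img, c(5, 5))
wiener_filter <- function(image, window = c(5L, 5L), noise_variance = NULL) {
  assert_radiograph(image)
  window <- as.integer(window)
  if (length(window) != 2 || any(window < 3) || any(window %% 2 == 0)) {
    stop("wiener window dimensions must be odd and >= 3", call. = FALSE)
  }
  if (any(window > dim(image))) {
    stop("wiener window does not fit the image", call. = FALSE)
  }
  m <- local_box_mean(image, window)
  s2 <- local_box_mean(image^2, window) - m^2
  s2 <- pmax(s2, 0)  # guard against negative round-off
  if (is.null(noise_variance)) {
    v2 <- mean(s2)
  } else {
    if (noise_variance < 0) stop("noise_variance must be >= 0", call. = FALSE)
    v2 <- noise_variance
  }
  gain <- ifelse(s2 > 0, pmax(s2 - v2, 0) / s2, 0)
  out <- m + gain * (image - m)
  # zero-noise limit: unit gain wherever there is any local variation
  if (v2 == 0) out <- ifelse(s2 > 0, image, m)
  clip01(out)
}

#' Denoise all three contrast channels
#'
#' Applies [wiener_filter()] with the configured window to AC, DPC and DFC.
#'
#' @param tri a [tri_contrast()] set.
#' @param config a [fusion_config()].
#' @return a denoised `tri_contrast` set.
#' @export
denoise_tricontrast <- function(tri, config = fusion_config()) {
  tri <- as_tri_contrast(tri)
  w <- config$wiener_window
  tri_contrast(wiener_filter(tri$ac, w), wiener_filter(tri$dpc, w),
               wiener_filter(tri$dfc, w))
}
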