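#' Per-pixel mean baseline fuser
#'
#' Arithmetic mean of the three channels; the simplest possible comparison
#' arm for the evaluation harness.
#'
#' @param tri a [tri_contrast()] set.
#' @return fused matrix in \[0, 1\].
#' @export
mean_fuse <- function(tri) {
  tri <- as_tri_contrast(tri)
  (tri$ac + tri$dpc + tri$dfc) / 3
}

#' Transform-domain max-|coefficient| baseline fuser
#'
#' Generic multiscale baseline: decompose each channel with
#' [nsct_forward()], take the per-pixel coefficient of largest absolute
#' value in every detail band, average the lowpass bands, reconstruct.
#'
#' @param tri a [tri_contrast()] set.
#' @param levels NSCT directional levels per scale.
#' @return fused matrix (reconstruction-exact up to transform round-off).
#' @export
max_abs_highpass_fuse <- function(tri, levels = c(4L, 4L, 4L, 4L)) {
  tri <- as_tri_contrast(tri)
  co <- lapply(tri[c("ac", "dpc", "dfc")], nsct_forward, levels = levels)
  low <- (co$ac$lowpass + co$dpc$lowpass + co$dfc$lowpass) / 3
  high <- lapply(seq_along(levels), function(j) {
    lapply(seq_len(2^levels[j]), function(t) {
      h1 <- co$ac$highpass[[j]][[t]]
      h2 <- co$dpc$highpass[[j]][[t]]
      h3 <- co$dfc$highpass[[j]][[t]]
      out <- h1
      m2 <- abs(h2) > abs(out); out[m2] <- h2[m2]
      m3 <- abs(h3) > abs(out); out[m3] <- h3[m3]
      out
    })
  })
  nsct_inverse(structure(list(lowpass = low, highpass = high,
                              levels = as.integer(levels), shape = dim(low)),
                         class = "nsct_coeffs"))
}
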