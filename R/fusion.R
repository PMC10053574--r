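#' Low-frequency coefficient selection
#'
#' Pixelwise competitive selection among the three channels' lowpass
#' coefficients, driven by their SCM ignition counts. The AC channel's
#' count is weighted by `a`, the DPC and DFC counts by `1 - a`; the channel
#' with the strictly greatest score wins. Larger `a` therefore pulls the
#' fused base image toward the attenuation channel, which is what
#' radiologists are used to reading. Ties resolve by priority
#' AC > DPC > DFC.
#'
#' @param L_ac,L_dpc,L_dfc lowpass bands (matrices, one shape).
#' @param T_ac,T_dpc,T_dfc ignition matrices for those bands.
#' @param a AC affinity weight in (0, 1).
#' @return fused lowpass band.
#' @export
fuse_lowpass <- function(L_ac, L_dpc, L_dfc, T_ac, T_dpc, T_dfc, a = 0.55) {
  dims <- dim(L_ac)
  for (m in list(L_dpc, L_dfc, T_ac, T_dpc, T_dfc)) {
    if (!all(dim(m) == dims)) stop("lowpass fusion: shape mismatch", call. = FALSE)
  }
  if (a <= 0 || a >= 1) stop("a must lie in (0, 1)", call. = FALSE)
  s_ac <- a * T_ac
  s_dpc <- (1 - a) * T_dpc
  s_dfc <- (1 - a) * T_dfc
  out <- L_ac  # AC wins outright and on any tie
  dpc_wins <- s_dpc > s_ac & s_dpc > s_dfc
  dfc_wins <- s_dfc > s_ac & s_dfc > s_dpc
  out[dpc_wins] <- L_dpc[dpc_wins]
  out[dfc_wins] <- L_dfc[dfc_wins]
  out
}

#' High-frequency coefficient selection (seven-case rule)
#'
#' Channel X is "significantly more active" than channel Z at a pixel when
#' its ignition count exceeds Z's by more than `Tth`. The fused coefficient
#' is then, per pixel:
#' * exactly one channel significantly more active than both others — that
#'   channel's coefficient (3 cases);
#' * exactly two channels each significantly more active than the third —
#'   the average of those two (3 cases);
#' * otherwise — the weighted blend `b*H_ac + c*H_dpc + d*H_dfc` (1 case).
#'
#' The three situations are tested in that order, which makes the seven
#' cases a total, unambiguous partition for every ignition triple.
#'
#' @param H_ac,H_dpc,H_dfc one highpass band per channel (one shape).
#' @param T_ac,T_dpc,T_dfc ignition matrices for those bands.
#' @param weights numeric (b, c, d), summing to 1.
#' @param Tth significance margin (>= 0) on ignition-count differences.
#' @return fused highpass band.
#' @export
fuse_highpass <- function(H_ac, H_dpc, H_dfc, T_ac, T_dpc, T_dfc,
                          weights = c(0.41, 0.29, 0.30), Tth = 1) {
  dims <- dim(H_ac)
  for (m in list(H_dpc, H_dfc, T_ac, T_dpc, T_dfc)) {
    if (!all(dim(m) == dims)) stop("highpass fusion: shape mismatch", call. = FALSE)
  }
  if (length(weights) != 3 || abs(sum(weights) - 1) > 1e-9) {
    stop("highpass weights (b, c, d) must sum to 1", call. = FALSE)
  }
  if (Tth < 0) stop("Tth must be >= 0", call. = FALSE)

  ac_gt_dpc <- T_ac - T_dpc > Tth
  ac_gt_dfc <- T_ac - T_dfc > Tth
  dpc_gt_ac <- T_dpc - T_ac > Tth
  dpc_gt_dfc <- T_dpc - T_dfc > Tth
  dfc_gt_ac <- T_dfc - T_ac > Tth
  dfc_gt_dpc <- T_dfc - T_dpc > Tth

  sel_ac <- ac_gt_dpc & ac_gt_dfc
  sel_dpc <- dpc_gt_ac & dpc_gt_dfc
  sel_dfc <- dfc_gt_ac & dfc_gt_dpc
  single <- sel_ac | sel_dpc | sel_dfc

  # pairs both significantly beating the remaining channel
  pair_ac_dpc <- !single & ac_gt_dfc & dpc_gt_dfc
  pair_ac_dfc <- !single & ac_gt_dpc & dfc_gt_dpc
  pair_dpc_dfc <- !single & dpc_gt_ac & dfc_gt_ac

  blend <- !(single | pair_ac_dpc | pair_ac_dfc | pair_dpc_dfc)

  out <- weights[1] * H_ac + weights[2] * H_dpc + weights[3] * H_dfc
  out[!blend] <- 0
  out[sel_ac] <- H_ac[sel_ac]
  out[sel_dpc] <- H_dpc[sel_dpc]
  out[sel_dfc] <- H_dfc[sel_dfc]
  out[pair_ac_dpc] <- (H_ac[pair_ac_dpc] + H_dpc[pair_ac_dpc]) / 2
  out[pair_ac_dfc] <- (H_ac[pair_ac_dfc] + H_dfc[pair_ac_dfc]) / 2
  out[pair_dpc_dfc] <- (H_dpc[pair_dpc_dfc] + H_dfc[pair_dpc_dfc]) / 2
  out
}

#' Fuse a tri-contrast set in the transform domain
#'
#' The core fusion operator: decompose each (already denoised) channel with
#' [nsct_forward()], run [scm_ignition()] on every sub-band (stimulus =
#' max-normalized absolute coefficients), select/blend coefficients with
#' [fuse_lowpass()] and [fuse_highpass()] band by band (bands matched by
#' scale and direction index), and reconstruct with [nsct_inverse()]. The
#' result is *not* rescaled; tone handling belongs to the enhancement step.
#'
#' @param tri a [tri_contrast()] set (denoise first; see
#'   [denoise_tricontrast()]).
#' @param config a [fusion_config()].
#' @return fused image matrix (same shape; range may slightly exceed
#'   \[0, 1\] before enhancement).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(64, 64)))
#' cfg <- fusion_config(nsct_levels = c(2, 2), scm = scm_params(k = 30))
#' fused <- fuse_tricontrast(ph$clean, cfg)
fuse_tricontrast <- function(tri, config = fusion_config()) {
  tri <- as_tri_contrast(tri)
  co <- lapply(tri[c("ac", "dpc", "dfc")], nsct_forward,
               levels = config$nsct_levels)
  ign <- lapply(co, function(ch) {
    list(lowpass = scm_ignition(band_stimulus(ch$lowpass), config$scm),
         highpass = lapply(ch$highpass, function(scale) {
           lapply(scale, function(b) scm_ignition(band_stimulus(b), config$scm))
         }))
  })
  fused_low <- fuse_lowpass(
    co$ac$lowpass, co$dpc$lowpass, co$dfc$lowpass,
    ign$ac$lowpass, ign$dpc$lowpass, ign$dfc$lowpass,
    a = config$low_weight_a)
  fused_high <- lapply(seq_along(config$nsct_levels), function(j) {
    lapply(seq_len(2^config$nsct_levels[j]), function(t) {
      fuse_highpass(
        co$ac$highpass[[j]][[t]], co$dpc$highpass[[j]][[t]],
        co$dfc$highpass[[j]][[t]],
        ign$ac$highpass[[j]][[t]], ign$dpc$highpass[[j]][[t]],
        ign$dfc$highpass[[j]][[t]],
        weights = config$high_weights_bcd, Tth = config$high_threshold_Tth)
    })
  })
  nsct_inverse(structure(list(lowpass = fused_low, highpass = fused_high,
                              levels = config$nsct_levels,
                              shape = dim(fused_low)),
                         class = "nsct_coeffs"))
}
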