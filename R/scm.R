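#' Spiking cortical model ignition matrix
#'
#' Runs the simplified Eckhorn-type spiking cortical model on a stimulus
#' grid and returns the per-pixel total spike count over `k` iterations
#' (the "ignition matrix"), a measure of local stimulus salience used to
#' drive coefficient selection. Dynamics per iteration:
#' membrane `U <- f*U + S*(1 + beta*(W %*% Y))` (3 x 3 zero-padded
#' neighborhood convolution), spike `Y <- U > Theta`, threshold
#' `Theta <- g*Theta + h*Y`. The sigmoid spike generator of the model
#' exceeds one half exactly when `U > Theta`, so the comparison is used
#' directly. Initial state: `U = Y = 0`, `Theta = theta0` (default 1,
#' keeping zero-stimulus pixels silent and avoiding a spurious all-fire
#' first step).
#'
#' @param stimulus numeric matrix of nonnegative values in \[0, 1\].
#' @param params an [scm_params()] list.
#' @return integer matrix of spike counts in `[0, k]`.
#' @export
#' @examples
#' counts <- scm_ignition(matrix(0.5, 16, 16), scm_params(k = 50))
#' range(counts)
scm_ignition <- function(stimulus, params = scm_params()) {
  stopifnot(is.matrix(stimulus), is.numeric(stimulus))
  if (!all(is.finite(stimulus))) stop("stimulus must be finite", call. = FALSE)
  if (min(stimulus) < 0) {
    stop("stimulus must be nonnegative (take |coefficients| upstream)",
         call. = FALSE)
  }
  if (max(stimulus) > 1 + 1e-12) stop("stimulus must lie in [0, 1]", call. = FALSE)
  if (!inherits(params, "scm_params")) params <- do.call(scm_params, params)
  .scm_ignition_cpp(stimulus, params$f, params$g, params$h, params$beta,
                    params$W, params$k, params$theta0)
}

#' Prepare a sub-band as SCM stimulus
#'
#' Transform coefficients are signed; the model's drive is nonnegative.
#' Each band is mapped to \[0, 1\] by absolute value and per-band maximum
#' normalization (an all-zero band stays zero).
#'
#' @param band numeric matrix of coefficients.
#' @return nonnegative matrix in \[0, 1\].
#' @export
band_stimulus <- function(band) {
  a <- abs(band)
  m <- max(a)
  if (m > 0) a / m else a
}
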