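#' Non-subsampled contourlet-style decomposition
#'
#' Shift-invariant multiscale, multidirectional analysis. Two stages, both
#' undecimated so every sub-band keeps the input's shape:
#'
#' 1. *Non-subsampled pyramid*: an a-trous additive pyramid. At scale `j`
#'    the running approximation is smoothed by a separable binomial lowpass
#'    kernel upsampled by `2^(j-1)` (zeros inserted between taps, periodic
#'    extension); the detail band is the difference before/after smoothing.
#' 2. *Non-subsampled directional filter bank*: each detail band is split
#'    into `2^(l_j)` orientation bands by an exact angular-wedge partition
#'    of the frequency plane (wedge masks are 0/1, point-symmetric, and sum
#'    to one, so the split is invertible by plain summation).
#'
#' The transform is exactly linear, exactly shift-invariant under circular
#' shifts, and perfectly reconstructed by [nsct_inverse()]. Redundancy is
#' `sum(2^levels)` detail bands plus one lowpass.
#'
#' @param image numeric matrix; rows and columns must be at least
#'   `2^(J + 2)` for `J = length(levels)` pyramid scales.
#' @param levels integer vector `l_j` of directional levels per scale;
#'   scale 1 is the finest.
#' @return an object of class `nsct_coeffs`: list with `lowpass` (matrix),
#'   `highpass` (list over scales of lists of `2^(l_j)` matrices), `levels`
#'   and `shape`.
#' @export
#' @examples
#' co <- nsct_forward(matrix(runif(64 * 64), 64, 64), c(2, 3))
#' length(unlist(co$highpass, recursive = FALSE))
nsct_forward <- function(image, levels = c(4L, 4L, 4L, 4L)) {
  stopifnot(is.matrix(image), is.numeric(image), all(is.finite(image)))
  levels <- as.integer(levels)
  if (length(levels) < 1 || any(levels < 1)) {
    stop("levels must be a non-empty vector of integers >= 1", call. = FALSE)
  }
  M <- nrow(image); N <- ncol(image)
  J <- length(levels)
  max_J <- floor(log2(min(M, N))) - 2L
  if (min(M, N) < 2^(J + 2)) {
    stop(sprintf("image %d x %d supports at most J = %d pyramid scales (requested %d)",
                 M, N, max_J, J), call. = FALSE)
  }
  approx <- image
  highpass <- vector("list", J)
  for (j in seq_len(J)) {
    kern <- atrous_kernel(j)
    smooth <- conv2_circular(approx, kern)
    detail <- approx - smooth
    approx <- smooth
    masks <- wedge_masks(M, N, levels[j])
    Fd <- fft(detail)
    highpass[[j]] <- lapply(masks, function(m) Re(fft(Fd * m, inverse = TRUE)) / (M * N))
  }
  structure(list(lowpass = approx, highpass = highpass,
                 levels = levels, shape = c(M, N)),
            class = "nsct_coeffs")
}

#' Inverse non-subsampled contourlet-style transform
#'
#' Exact synthesis: directional bands of each scale sum to that scale's
#' detail band, and the details plus the lowpass sum to the input
#' (`nsct_inverse(nsct_forward(x)) == x` to machine precision).
#'
#' @param coeffs an `nsct_coeffs` object (see [nsct_forward()]).
#' @return the reconstructed matrix.
#' @export
nsct_inverse <- function(coeffs) {
  validate_nsct_coeffs(coeffs)
  out <- coeffs$lowpass
  for (scale in coeffs$highpass) {
    for (band in scale) out <- out + band
  }
  out
}

validate_nsct_coeffs <- function(coeffs) {
  if (!inherits(coeffs, "nsct_coeffs")) stop("not an nsct_coeffs object", call. = FALSE)
  shp <- dim(coeffs$lowpass)
  if (!all(shp == coeffs$shape)) stop("lowpass band shape mismatch", call. = FALSE)
  if (length(coeffs$highpass) != length(coeffs$levels)) {
    stop("highpass scale count does not match levels", call. = FALSE)
  }
  for (j in seq_along(coeffs$highpass)) {
    bands <- coeffs$highpass[[j]]
    if (length(bands) != 2^coeffs$levels[j]) {
      stop(sprintf("scale %d must have %d directional bands (got %d)",
                   j, 2^coeffs$levels[j], length(bands)), call. = FALSE)
    }
    for (b in bands) {
      if (!all(dim(b) == shp)) stop("directional band shape mismatch", call. = FALSE)
    }
  }
  invisible(coeffs)
}

#' Redundancy of a level configuration
#'
#' Number of detail bands, `sum(2^levels)`; the transform stores that many
#' input-sized bands plus one lowpass.
#'
#' @param levels integer vector of per-scale directional levels.
#' @return integer redundancy.
#' @export
nsct_redundancy <- function(levels) sum(2^as.integer(levels))

# Binomial lowpass [1,4,6,4,1]/16 upsampled a-trous by 2^(j-1): dyadic taps,
# unit DC gain, so detail bands carry exactly zero mean.
atrous_kernel <- function(j) {
  base <- c(1, 4, 6, 4, 1) / 16
  if (j > 1) {
    step <- 2^(j - 1)
    up <- numeric(4 * step + 1)
    up[seq(1, length(up), by = step)] <- base
    base <- up
  }
  outer(base, base)
}

# 0/1 angular-wedge masks over the DFT grid for 2^l orientations in [0, pi).
# Frequencies are canonicalized to the upper half-plane before the angle is
# taken, so mask[u, v] == mask[-u, -v] exactly and every band is real.
wedge_masks <- function(M, N, l, cache = TRUE) {
  key <- sprintf("%d_%d_%d", M, N, l)
  if (cache && !is.null(.wedge_cache[[key]])) return(.wedge_cache[[key]])
  n_dir <- 2^l
  fu <- ifelse(seq_len(M) - 1 < M / 2, seq_len(M) - 1, seq_len(M) - 1 - M)
  fv <- ifelse(seq_len(N) - 1 < N / 2, seq_len(N) - 1, seq_len(N) - 1 - N)
  U <- matrix(fu, M, N)
  V <- matrix(fv, M, N, byrow = TRUE)
  flip <- V < 0 | (V == 0 & U < 0)
  Uc <- ifelse(flip, -U, U)
  Vc <- ifelse(flip, -V, V)
  theta <- atan2(Vc, Uc)            # in [0, pi]
  bin <- pmin(floor(theta * n_dir / pi), n_dir - 1)
  masks <- lapply(seq_len(n_dir) - 1L, function(t) (bin == t) * 1)
  if (cache) .wedge_cache[[key]] <- masks
  masks
}

.wedge_cache <- new.env(parent = emptyenv())
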