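clip01 <- function(x) pmin(pmax(x, 0), 1)

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never disturb user RNG.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# 2-D FFT convolution with circular (periodic) boundary. `kernel` is given
# as a small matrix centered at its middle element; it is embedded at the
# origin of an M x N grid so the convolution introduces no shift.
conv2_circular <- function(x, kernel) {
  M <- nrow(x); N <- ncol(x)
  km <- nrow(kernel); kn <- ncol(kernel)
  stopifnot(km <= M, kn <= N)
  big <- matrix(0, M, N)
  ci <- (km + 1L) %/% 2L; cj <- (kn + 1L) %/% 2L
  ri <- ((seq_len(km) - ci) %% M) + 1L
  rj <- ((seq_len(kn) - cj) %% N) + 1L
  big[ri, rj] <- kernel
  Re(fft(fft(x) * fft(big), inverse = TRUE)) / (M * N)
}

# Periodic Gaussian blur used by the phantom texture synthesis.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  conv2_circular(x, outer(g, g))
}

# Symmetric (mirror) padding by (pr, pc) pixels on every side.
pad_symmetric <- function(x, pr, pc) {
  M <- nrow(x); N <- ncol(x)
  stopifnot(pr < M, pc < N)
  ri <- c(rev(seq_len(pr)), seq_len(M), M - seq_len(pr) + 1L)
  rj <- c(rev(seq_len(pc)), seq_len(N), N - seq_len(pc) + 1L)
  x[ri, rj]
}

# Local box mean over an (X x Y) window via integral images, with symmetric
# padding so every pixel sees a full window.
local_box_mean <- function(x, win) {
  X <- win[1]; Y <- win[2]
  pr <- (X - 1L) %/% 2L; pc <- (Y - 1L) %/% 2L
  p <- pad_symmetric(x, pr, pc)
  M <- nrow(p); N <- ncol(p)
  s <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  i1 <- seq_len(nrow(x)); j1 <- seq_len(ncol(x))
  sums <- s[i1 + X, j1 + Y, drop = FALSE] - s[i1, j1 + Y, drop = FALSE] -
          s[i1 + X, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
  sums / (X * Y)
}

# Shannon entropy (bits) of an image quantized to `levels` uniform bins of
# [0, 1]; shared by the metrics suite and the adaptive-sharpening gain search.
quantize_levels <- function(x, levels = 256L) {
  pmin(floor(pmin(pmax(x, 0), 1) * levels), levels - 1L) + 1L
}

shannon_entropy <- function(x, levels = 256L) {
  idx <- quantize_levels(x, levels)
  p <- tabulate(idx, nbins = levels) / length(idx)
  p <- p[p > 0]
  -sum(p * log2(p))
}
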