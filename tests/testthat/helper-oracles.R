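# Independent reference implementations (plain scalar loops) used as
# oracles against the vectorized/compiled package code, plus small fixture
# builders. Everything here is deliberately naive and slow.

random_image <- function(M, N, seed) {
  set.seed(seed)
  matrix(runif(M * N), M, N)
}

circ_shift <- function(m, s) {
  M <- nrow(m); N <- ncol(m)
  si <- ((seq_len(M) - 1 + s[1]) %% M) + 1
  sj <- ((seq_len(N) - 1 + s[2]) %% N) + 1
  m[si, sj]
}

small_phantom <- function(seed = 1, shape = c(64, 64), noise = c(0, 0, 0)) {
  generate_phantom(phantom_spec(shape = shape, noise_sigma = noise, seed = seed))
}

fast_config <- function(...) {
  fusion_config(nsct_levels = c(2L, 2L), scm = scm_params(k = 30L), ...)
}

# --- spiking cortical model: scalar reference iteration -------------------
# Neighbor accumulation follows column-major order (left column, center,
# right column) like a literal reading of the convolution sum.
scm_oracle <- function(S, params) {
  M <- nrow(S); N <- ncol(S)
  U <- matrix(0, M, N); Y <- matrix(0, M, N)
  Theta <- matrix(params$theta0, M, N)
  counts <- matrix(0L, M, N)
  W <- params$W
  for (n in seq_len(params$k)) {
    conv <- matrix(0, M, N)
    for (j in seq_len(N)) for (i in seq_len(M)) {
      acc <- 0
      for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= M && jj >= 1 && jj <= N) {
          acc <- acc + W[di + 2, dj + 2] * Y[ii, jj]
        }
      }
      conv[i, j] <- acc
    }
    U <- params$f * U + S * (1 + params$beta * conv)
    Y <- (U > Theta) * 1
    Theta <- params$g * Theta + params$h * Y
    counts <- counts + (Y > 0)
  }
  counts
}

# --- fusion rules: scalar case enumeration --------------------------------
fuse_low_scalar <- function(l, t, a) {
  s <- c(a * t[1], (1 - a) * t[2], (1 - a) * t[3])
  if (s[2] > s[1] && s[2] > s[3]) return(l[2])
  if (s[3] > s[1] && s[3] > s[2]) return(l[3])
  l[1]  # AC wins outright or on any tie (priority AC > DPC > DFC)
}

fuse_high_scalar <- function(h, t, w, Tth) {
  gt <- function(x, z) t[x] - t[z] > Tth
  dom <- c(gt(1, 2) && gt(1, 3), gt(2, 1) && gt(2, 3), gt(3, 1) && gt(3, 2))
  if (sum(dom) == 1) return(h[which(dom)])
  stopifnot(sum(dom) == 0)  # two simultaneous dominators are impossible
  if (gt(1, 3) && gt(2, 3)) return((h[1] + h[2]) / 2)
  if (gt(1, 2) && gt(3, 2)) return((h[1] + h[3]) / 2)
  if (gt(2, 1) && gt(3, 1)) return((h[2] + h[3]) / 2)
  w[1] * h[1] + w[2] * h[2] + w[3] * h[3]
}

# --- metrics: double-loop references --------------------------------------
sf_oracle <- function(Z) {
  M <- nrow(Z); N <- ncol(Z)
  rf <- 0; cf <- 0
  for (i in 1:M) for (j in 2:N) rf <- rf + (Z[i, j] - Z[i, j - 1])^2
  for (i in 2:M) for (j in 1:N) cf <- cf + (Z[i, j] - Z[i - 1, j])^2
  sqrt(rf / (M * N) + cf / (M * N))
}

sd_oracle <- function(Z) {
  mu <- sum(Z) / length(Z)
  acc <- 0
  for (v in Z) acc <- acc + (v - mu)^2
  sqrt(acc / length(Z))
}

entropy_oracle <- function(Z, levels = 256L) {
  idx <- pmin(floor(Z * levels), levels - 1L)
  h <- 0
  for (l in 0:(levels - 1L)) {
    p <- sum(idx == l) / length(Z)
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

mi_oracle <- function(A, B, levels = 256L) {
  ia <- pmin(floor(A * levels), levels - 1L)
  ib <- pmin(floor(B * levels), levels - 1L)
  n <- length(A)
  mi <- 0
  for (la in unique(as.vector(ia))) for (lb in unique(as.vector(ib))) {
    pab <- sum(ia == la & ib == lb) / n
    if (pab > 0) {
      pa <- sum(ia == la) / n
      pb <- sum(ib == lb) / n
      mi <- mi + pab * log2(pab / (pa * pb))
    }
  }
  mi
}

ssim_oracle <- function(A, B) {
  r <- 5L
  g <- exp(-((-r:r)^2) / (2 * 1.5^2)); g <- g / sum(g)
  G <- outer(g, g)
  C1 <- 0.01^2; C2 <- 0.03^2
  M <- nrow(A); N <- ncol(A)
  vals <- c()
  for (i in (r + 1):(M - r)) for (j in (r + 1):(N - r)) {
    wa <- A[(i - r):(i + r), (j - r):(j + r)]
    wb <- B[(i - r):(i + r), (j - r):(j + r)]
    mua <- sum(G * wa); mub <- sum(G * wb)
    va <- sum(G * wa^2) - mua^2
    vb <- sum(G * wb^2) - mub^2
    vab <- sum(G * wa * wb) - mua * mub
    vals <- c(vals, ((2 * mua * mub + C1) * (2 * vab + C2)) /
                     ((mua^2 + mub^2 + C1) * (va + vb + C2)))
  }
  mean(vals)
}

psd_oracle <- function(Z) {
  M <- nrow(Z); N <- ncol(Z)
  P <- Mod(stats::fft(Z))^2 / (M * N)
  fu <- ifelse(seq_len(M) - 1 < M / 2, seq_len(M) - 1, seq_len(M) - 1 - M)
  fv <- ifelse(seq_len(N) - 1 < N / 2, seq_len(N) - 1, seq_len(N) - 1 - N)
  acc <- list()
  for (i in 1:M) for (j in 1:N) {
    r <- as.character(round(sqrt(fu[i]^2 + fv[j]^2)))
    acc[[r]] <- c(acc[[r]], P[i, j])
  }
  radii <- sort(as.integer(names(acc)))
  data.frame(radius = radii,
             power = unname(vapply(as.character(radii), function(r) mean(acc[[r]]), 1)),
             count = unname(vapply(as.character(radii), function(r) length(acc[[r]]), 1)))
}

# Edge-preservation reference: per-pixel scalar evaluation sharing only the
# published constants with the implementation.
es_oracle <- function(tri, fused) {
  sobel_pair <- function(x) {
    M <- nrow(x); N <- ncol(x)
    p <- x[c(1, 1:M, M), c(1, 1:N, N)]
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
    ky <- t(kx)
    gx <- matrix(0, M, N); gy <- matrix(0, M, N)
    for (i in 1:M) for (j in 1:N) {
      win <- p[i:(i + 2), j:(j + 2)]
      gx[i, j] <- sum(kx * win)
      gy[i, j] <- sum(ky * win)
    }
    list(g = sqrt(gx^2 + gy^2), a = ifelse(gx == 0, pi / 2 * sign(gy), atan(gy / gx)))
  }
  q_map <- function(src, fus) {
    s <- sobel_pair(src); f <- sobel_pair(fus)
    M <- nrow(src); N <- ncol(src)
    Q <- matrix(0, M, N)
    for (i in 1:M) for (j in 1:N) {
      gs <- s$g[i, j]; gf <- f$g[i, j]
      G <- if (gs == gf) 1 else if (gs > gf) gf / gs else gs / gf
      dA <- abs(s$a[i, j] - f$a[i, j])
      if (dA > pi / 2) dA <- pi - dA
      A <- 1 - dA / (pi / 2)
      Q[i, j] <- (0.9994 / (1 + exp(-15 * (G - 0.5)))) *
                 (0.9879 / (1 + exp(-22 * (A - 0.8))))
    }
    list(Q = Q, w = s$g)
  }
  ms <- lapply(tri[c("ac", "dpc", "dfc")], q_map, fus = fused)
  num <- 0; den <- 0
  for (m in ms) { num <- num + sum(m$Q * m$w); den <- den + sum(m$w) }
  num / den
}
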