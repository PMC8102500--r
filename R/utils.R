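# Internal helpers shared across modules.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Standard error of the mean; NA for a single value.
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Exact 90-degree clockwise rotation of a matrix (pure index permutation,
# no interpolation).
rot90_cw <- function(m) {
  t(m[nrow(m):1, , drop = FALSE])
}

# Integer-shift a matrix by (dy, dx), filling vacated pixels with `fill`.
shift_matrix <- function(m, dy, dx, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  ys <- seq_len(nrow(m)); xs <- seq_len(ncol(m))
  ysrc <- ys - dy; xsrc <- xs - dx
  yok <- ysrc >= 1 & ysrc <= nrow(m)
  xok <- xsrc >= 1 & xsrc <= ncol(m)
  out[ys[yok], xs[xok]] <- m[ysrc[yok], xsrc[xok], drop = FALSE]
  out
}

# Separable Gaussian smoothing of a matrix with per-axis sigmas, used by
# the synthetic generator to create spatially correlated (optionally
# anisotropic) intensity fields. Circular boundary via FFT convolution.
gauss_smooth <- function(m, sigma_y, sigma_x) {
  smooth_1d <- function(mat, sigma, along_rows) {
    if (sigma <= 0) return(mat)
    n <- if (along_rows) nrow(mat) else ncol(mat)
    r <- min(ceiling(4 * sigma), floor((n - 1) / 2))
    k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    k <- k / sum(k)
    kv <- numeric(n)
    kv[((seq(-r, r)) %% n) + 1] <- k
    if (along_rows) {
      Re(stats::mvfft(stats::mvfft(mat) * stats::fft(kv), inverse = TRUE)) / n
    } else {
      t(Re(stats::mvfft(stats::mvfft(t(mat)) * stats::fft(kv), inverse = TRUE)) / n)
    }
  }
  smooth_1d(smooth_1d(m, sigma_y, TRUE), sigma_x, FALSE)
}

# Euclidean distance-to-background transform of a binary mask (2D matrix),
# with the image border treated as background: the mask is zero-padded by
# one pixel before EBImage's distance map and cropped back, so a foreground
# pixel touching the border gets distance 1.
distance_to_background <- function(mask) {
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- (mask != 0) * 1
  d <- EBImage::distmap(m, metric = "euclidean")
  as.matrix(d)[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
}

# Significance stars: *P<0.05, **P<0.01, ***P<0.001.
signif_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}
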