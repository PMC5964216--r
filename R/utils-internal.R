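# Internal helpers: frequency-domain filtering, RNG stream splitting,
# small geometry utilities. Not exported.

# Squared angular-frequency grid |w|^2 for an nr x nc image, cycles mapped to
# radians/pixel. Cached per dimension within a call chain by the caller.
freq_grid_sq <- function(nr, nc) {
  wy <- 2 * pi * c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[seq_len(nr)] / nr
  wx <- 2 * pi * c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[seq_len(nc)] / nc
  outer(wy^2, wx^2, "+")
}

# Gaussian blur with standard deviation sigma_px (pixels), computed in the
# frequency domain with the exact continuous transfer function
# exp(-sigma^2 |w|^2 / 2). Circular boundary; callers keep content away from
# the edges.
fft_gaussian_blur <- function(img, sigma_px, w2 = NULL) {
  if (sigma_px <= 0) return(img)
  d <- dim(img)
  if (is.null(w2)) w2 <- freq_grid_sq(d[1], d[2])
  Re(stats::fft(stats::fft(img) * exp(-sigma_px^2 * w2 / 2), inverse = TRUE)) / length(img)
}

# Scale-normalized Laplacian-of-Gaussian responses (sign-flipped so bright
# blobs give positive peaks) for a vector of sigmas, sharing one forward FFT.
# Returns a list of matrices.
fft_log_stack <- function(img, sigmas_px, w2 = NULL) {
  d <- dim(img)
  if (is.null(w2)) w2 <- freq_grid_sq(d[1], d[2])
  F <- stats::fft(img)
  n <- length(img)
  lapply(sigmas_px, function(s) {
    Re(stats::fft(F * (s^2 * w2 * exp(-s^2 * w2 / 2)), inverse = TRUE)) / n
  })
}

# Deterministic per-field RNG stream: a field's seed is derived from the base
# seed and the 1-based field index by a fixed affine rule modulo 2^31 - 1.
# The rule is recorded in field provenance.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 99991 * as.numeric(index)) %% 2147483647)
}

# Local maxima of a matrix over its 8-neighbourhood (strictly greater than or
# equal to neighbours, strictly greater than at least one). Returns a logical
# matrix; border pixels are excluded.
local_maxima_8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  if (nr < 3 || nc < 3) return(out)
  ci <- 2:(nr - 1); cj <- 2:(nc - 1)
  x <- m[ci, cj]
  ok <- x >= m[ci - 1, cj] & x >= m[ci + 1, cj] &
    x >= m[ci, cj - 1] & x >= m[ci, cj + 1] &
    x >= m[ci - 1, cj - 1] & x >= m[ci - 1, cj + 1] &
    x >= m[ci + 1, cj - 1] & x >= m[ci + 1, cj + 1]
  out[ci, cj] <- ok
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
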