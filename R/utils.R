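#' @keywords internal
"_PACKAGE"

# Shared internal helpers: seeded evaluation, centered orthonormal FFTs,
# separable Gaussian smoothing.

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive n child seeds from a master seed, all < 2^31.
derive_seeds <- function(master_seed, n, stream = "") {
  offset <- if (nzchar(stream)) sum(utf8ToInt(stream)) else 0L
  with_seed(as.integer(master_seed) %% 2147483647L + offset,
            sample.int(2147483646L, n))
}

# -- Centered orthonormal Fourier transforms --------------------------------
# k-space is stored DC-centered; shifts are applied symmetrically so that
# ft2c/ift2c are exact inverses and Parseval holds (1/sqrt(N) both ways).

fftshift_idx <- function(n) {
  h <- floor(n / 2)
  if (h == 0L) return(1L)
  c((h + 1L):n, seq_len(h))
}

ifftshift_idx <- function(n) {
  h <- ceiling(n / 2)
  if (h == n) return(seq_len(n))
  c((h + 1L):n, seq_len(h))
}

fftshift2 <- function(x) x[fftshift_idx(nrow(x)), fftshift_idx(ncol(x)), drop = FALSE]
ifftshift2 <- function(x) x[ifftshift_idx(nrow(x)), ifftshift_idx(ncol(x)), drop = FALSE]

ft2c <- function(x) fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
ift2c <- function(k) fftshift2(stats::fft(ifftshift2(k), inverse = TRUE)) / sqrt(length(k))

ft1c <- function(v) {
  n <- length(v)
  stats::fft(v[ifftshift_idx(n)])[order(fftshift_idx(n))] / sqrt(n)
}

ift1c <- function(v) {
  n <- length(v)
  stats::fft(v[ifftshift_idx(n)], inverse = TRUE)[order(fftshift_idx(n))] / sqrt(n)
}

# Reflect-padding index vector: length n + 2*pad mapping into 1..n.
reflect_idx <- function(n, pad) {
  if (pad == 0L) return(seq_len(n))
  stopifnot(pad < n)
  c(rev(seq_len(pad) + 1L), seq_len(n), n - seq_len(pad))
}

# Separable convolution with reflect boundary (used for phantom smoothing).
sep_conv2_reflect <- function(img, kernel) {
  k <- length(kernel)
  pad <- (k - 1L) %/% 2L
  ri <- reflect_idx(nrow(img), pad)
  ci <- reflect_idx(ncol(img), pad)
  x <- img[ri, , drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (t in seq_len(k)) out <- out + kernel[t] * x[seq_len(nrow(img)) + t - 1L, , drop = FALSE]
  x <- out[, ci, drop = FALSE]
  out2 <- matrix(0, nrow(img), ncol(img))
  for (t in seq_len(k)) out2 <- out2 + kernel[t] * x[, seq_len(ncol(img)) + t - 1L, drop = FALSE]
  out2
}

gaussian_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
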