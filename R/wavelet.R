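# Periodized orthogonal Daubechies-4 (4-tap) wavelet transform and the
# soft-thresholding shrinkage operator used inside the POCS reconstruction.
#
# Filters have closed form; the transform is orthonormal, so perfect
# reconstruction and energy preservation hold to machine precision.

daub4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)  # quadrature mirror: g_n = (-1)^n h_{L-1-n}
  list(h = h, g = g)
}

# One periodized analysis step along rows of a matrix (each column is a
# signal). Returns approximation and detail halves, each nrow/2 x ncol.
dwt_step_cols <- function(x, filt) {
  n <- nrow(x)
  stopifnot(n %% 2L == 0L)
  half <- n %/% 2L
  a <- matrix(0 + 0i * x[1], half, ncol(x))
  d <- a
  for (t in 1:4) {
    idx <- ((2L * seq_len(half) - 2L + (t - 1L)) %% n) + 1L
    xs <- x[idx, , drop = FALSE]
    a <- a + filt$h[t] * xs
    d <- d + filt$g[t] * xs
  }
  if (is.double(x)) { a <- Re(a); d <- Re(d) }
  list(a = a, d = d)
}

idwt_step_cols <- function(a, d, filt) {
  half <- nrow(a)
  n <- 2L * half
  x <- matrix(0 + 0i * a[1], n, ncol(a))
  for (t in 1:4) {
    idx <- ((2L * seq_len(half) - 2L + (t - 1L)) %% n) + 1L
    x[idx, ] <- x[idx, , drop = FALSE] + filt$h[t] * a + filt$g[t] * d
  }
  if (is.double(a)) x <- Re(x)
  x
}

dwt2_step <- function(x, filt) {
  cc <- dwt_step_cols(x, filt)                       # along rows (columns as signals)
  ll_lh <- dwt_step_cols(t(cc$a), filt)              # along the other axis
  hl_hh <- dwt_step_cols(t(cc$d), filt)
  list(LL = t(ll_lh$a), LH = t(ll_lh$d), HL = t(hl_hh$a), HH = t(hl_hh$d))
}

idwt2_step <- function(b, filt) {
  ca <- t(idwt_step_cols(t(b$LL), t(b$LH), filt))
  cd <- t(idwt_step_cols(t(b$HL), t(b$HH), filt))
  idwt_step_cols(ca, cd, filt)
}

#' Multi-level 2D Daubechies-4 wavelet decomposition
#'
#' Periodized orthonormal transform; both dimensions must be divisible by
#' `2^levels`. Works on real or complex matrices (filters are real).
#'
#' @param x numeric or complex matrix.
#' @param levels number of decomposition levels.
#' @return list with `levels` (each holding detail bands `LH`, `HL`, `HH`,
#'   finest first), the final approximation `LL`, and the level count.
#' @export
dwt2 <- function(x, levels = 3L) {
  stopifnot(is.matrix(x), levels >= 1L)
  if (nrow(x) %% (2^levels) != 0L || ncol(x) %% (2^levels) != 0L)
    stop("matrix dimensions must be divisible by 2^levels")
  filt <- daub4_filters()
  out <- vector("list", levels)
  cur <- x
  for (l in seq_len(levels)) {
    b <- dwt2_step(cur, filt)
    out[[l]] <- list(LH = b$LH, HL = b$HL, HH = b$HH)
    cur <- b$LL
  }
  structure(list(levels = out, LL = cur, n_levels = levels), class = "dwt2")
}

#' Inverse of [dwt2()]
#' @param w a `dwt2` decomposition.
#' @return matrix of the original size.
#' @export
idwt2 <- function(w) {
  stopifnot(inherits(w, "dwt2"))
  filt <- daub4_filters()
  cur <- w$LL
  for (l in rev(seq_len(w$n_levels))) {
    b <- w$levels[[l]]
    cur <- idwt2_step(list(LL = cur, LH = b$LH, HL = b$HL, HH = b$HH), filt)
  }
  cur
}

#' Soft-thresholding (magnitude shrinkage)
#'
#' Shrinks magnitudes by `lambda` and zeroes values at or below it, preserving
#' sign (real input) or phase (complex input):
#' `y = x * max(|x| - lambda, 0) / |x|`.
#'
#' @param x real or complex values (any shape).
#' @param lambda threshold, `>= 0`.
#' @return values of the same shape and type.
#' @export
soft_threshold <- function(x, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("lambda must be a single non-negative number")
  m <- Mod(x)
  scale <- ifelse(m > lambda, (m - lambda) / m, 0)
  y <- x * scale
  y
}

# Threshold the detail bands of a decomposition; the approximation band is
# left untouched (standard wavelet denoising practice).
threshold_details <- function(w, lambda) {
  for (l in seq_len(w$n_levels)) {
    w$levels[[l]]$LH <- soft_threshold(w$levels[[l]]$LH, lambda)
    w$levels[[l]]$HL <- soft_threshold(w$levels[[l]]$HL, lambda)
    w$levels[[l]]$HH <- soft_threshold(w$levels[[l]]$HH, lambda)
  }
  w
}

# Robust noise-level estimate from the finest diagonal detail band
# (median absolute deviation of the real/imaginary parts, scaled to a
# Gaussian standard deviation).
estimate_noise_sigma <- function(w) {
  hh <- w$levels[[1]]$HH
  v <- if (is.complex(hh)) c(Re(hh), Im(hh)) else as.vector(hh)
  stats::median(abs(v - stats::median(v))) / 0.6745
}
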