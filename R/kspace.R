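# Multi-coil k-space simulation and retrospective equidistant undersampling.
#
# Conventions: k-space is stored DC-centered; the Fourier transform is
# orthonormal (1/sqrt(N) both directions) so Parseval holds exactly and
# noise bookkeeping carries between domains. The phase-encode axis is the
# second (column) axis.

#' Equidistant phase-encode sampling mask
#'
#' Keeps every `af`-th phase-encode line starting at `offset` (0-based line
#' indices, matching the usual k-space line numbering).
#'
#' @param n_lines total number of phase-encode lines.
#' @param af integer acceleration factor (>= 1).
#' @param offset first sampled line index, `0 <= offset < af`.
#' @return object of class `sampling_mask`: `n_lines`, `af`, `offset`,
#'   `sampled` (0-based line indices).
#' @export
make_equidistant_mask <- function(n_lines, af, offset = 0L) {
  n_lines <- as.integer(n_lines); af <- as.integer(af); offset <- as.integer(offset)
  if (af < 1L) stop("invalid mask specification: af must be >= 1")
  if (offset < 0L || offset >= af) stop("invalid mask specification: need 0 <= offset < af")
  if (n_lines < 1L) stop("invalid mask specification: n_lines must be >= 1")
  sampled <- seq.int(offset, n_lines - 1L, by = af)
  structure(list(n_lines = n_lines, af = af, offset = offset,
                 sampled = as.integer(sampled)),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> %d/%d lines, AF %d, offset %d\n",
              length(x$sampled), x$n_lines, x$af, x$offset))
  invisible(x)
}

# logical vector over lines (1-based positions)
mask_logical <- function(mask) {
  v <- rep(FALSE, mask$n_lines)
  v[mask$sampled + 1L] <- TRUE
  v
}

#' Simulate multi-coil complex k-space from a phantom
#'
#' Per channel `c`, `data_c = F(S_c * image) + eps_c` with `F` the centered
#' orthonormal 2D Fourier transform and `eps_c` i.i.d. complex Gaussian noise
#' (standard deviation `noise_std` in each of the real and imaginary parts).
#'
#' @param case a `phantom_case` (or a plain matrix image).
#' @param coils `coil_sensitivities` matching the image shape.
#' @param noise_std per-sample complex Gaussian noise sd (>= 0).
#' @param seed integer seed for the noise.
#' @return object of class `kspace_data`: `data` (complex array
#'   rows x cols x channels), `mask` (`"full"`), `noise_std`, `seed`.
#' @export
simulate_multicoil_kspace <- function(case, coils, noise_std = 0, seed = 1L) {
  img <- if (inherits(case, "phantom_case")) case$image else case
  stopifnot(is.matrix(img))
  if (!all(dim(img) == coils$shape))
    stop("incompatible inputs: coil maps do not match the phantom shape")
  if (noise_std < 0) stop("incompatible inputs: noise_std must be >= 0")
  nr <- nrow(img); nc <- ncol(img); nch <- coils$n_channels
  data <- array(0 + 0i, dim = c(nr, nc, nch))
  with_seed(seed, {
    for (ch in seq_len(nch)) {
      k <- ft2c(coils$maps[, , ch] * img)
      if (noise_std > 0)
        k <- k + complex(real = stats::rnorm(nr * nc, 0, noise_std),
                         imaginary = stats::rnorm(nr * nc, 0, noise_std))
      data[, , ch] <- k
    }
  })
  structure(list(data = data, mask = "full", noise_std = noise_std,
                 seed = as.integer(seed), shape = c(nr, nc), n_channels = nch),
            class = "kspace_data")
}

#' Apply an equidistant sampling mask to k-space
#'
#' Sampled phase-encode lines (columns) are copied verbatim; all other lines
#' are set exactly to zero. Idempotent.
#'
#' @param ks `kspace_data`.
#' @param mask `sampling_mask` with `n_lines` equal to the phase-encode
#'   (column) dimension of `ks`.
#' @return `kspace_data` with the mask attached.
#' @export
apply_mask <- function(ks, mask) {
  stopifnot(inherits(ks, "kspace_data"), inherits(mask, "sampling_mask"))
  if (mask$n_lines != ks$shape[2])
    stop("dimension mismatch: mask length does not match the phase-encode axis")
  keep <- mask_logical(mask)
  out <- ks
  out$data[, !keep, ] <- 0 + 0i
  out$mask <- mask
  out
}

#' Estimated scan time under acceleration
#'
#' The fully sampled scan time divided by the acceleration factor.
#'
#' @param full_time_s full-sampling scan time in seconds (> 0).
#' @param af integer acceleration factor (>= 1).
#' @return accelerated scan time in seconds.
#' @export
estimate_scan_time <- function(full_time_s, af) {
  if (!is.numeric(full_time_s) || full_time_s <= 0) stop("full_time_s must be positive")
  if (af < 1) stop("af must be >= 1")
  full_time_s / af
}

#' Render seconds as minutes and seconds
#' @param seconds non-negative duration.
#' @return string like `"1 min 32 s"` (rounded to the nearest second).
#' @export
format_scan_time <- function(seconds) {
  s <- round(seconds)
  sprintf("%d min %d s", s %/% 60, s %% 60)
}
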