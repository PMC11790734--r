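# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small phantom + coils used by many recon tests (48 is divisible by 3 and 8)
small_phantom <- function() cached("small_phantom",
  generate_phantom(shape = c(48L, 48L), n_lesions = 2L,
                   diameter_range_mm = c(15, 30), seed = 11L))

small_coils <- function() cached("small_coils",
  generate_coil_sensitivities(c(48L, 48L), n_channels = 8L, seed = 5L))

small_mask <- function() cached("small_mask", make_equidistant_mask(48L, 3L, 0L))

# coils object with a single channel of exactly unit sensitivity
unit_coils <- function(shape) {
  structure(list(maps = array(1 + 0i, dim = c(shape, 1L)),
                 n_channels = 1L, shape = as.integer(shape), seed = 0L),
            class = "coil_sensitivities")
}

# tiny end-to-end experiment configuration (fast; used by pipeline tests)
tiny_config <- function(master_seed = 3L, ...) {
  experiment_config(
    n_cases = 3L, n_train_cases = 2L, shape = c(48L, 48L),
    n_lesions = 2L, diameter_range_mm = c(15, 30),
    pocs = pocs_config(max_iters = 40L),
    denoiser = list(n_patches = 48L, patch_size = 24L, epochs = 3L,
                    lr = 1e-3, batch_size = 16L, val_frac = 0.5),
    master_seed = master_seed, ...)
}

# independent per-window SSIM oracle: explicit loops over every window,
# uniform weighting, straight transcription of the SSIM formula
ssim_loop_oracle <- function(ref, test, win = 3L, k1 = 0.01, k2 = 0.03, L = NULL) {
  if (is.null(L)) L <- max(ref, test) - min(ref, test)
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  vals <- c()
  for (i in 1:(nrow(ref) - win + 1)) {
    for (j in 1:(ncol(ref) - win + 1)) {
      x <- as.vector(ref[i:(i + win - 1), j:(j + win - 1)])
      y <- as.vector(test[i:(i + win - 1), j:(j + win - 1)])
      mx <- sum(x) / length(x); my <- sum(y) / length(y)
      vx <- sum((x - mx)^2) / length(x)
      vy <- sum((y - my)^2) / length(y)
      cxy <- sum((x - mx) * (y - my)) / length(x)
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}

# independent whole-system SENSE oracle: build the full forward operator
# (image -> stacked masked k-space over channels) column by column and solve
# the joint least-squares problem
sense_full_system_oracle <- function(ks_masked, coils, mask) {
  nr <- coils$shape[1]; nc <- coils$shape[2]; nch <- coils$n_channels
  keep <- rep(FALSE, nc); keep[mask$sampled + 1L] <- TRUE
  n_pix <- nr * nc
  n_obs <- nr * sum(keep) * nch
  A <- matrix(0 + 0i, n_obs, n_pix)
  ftc <- function(x) {
    sh <- function(n) { h <- floor(n / 2); c((h + 1):n, 1:h) }
    ish <- function(n) { h <- ceiling(n / 2); c((h + 1):n, 1:h) }
    y <- x[ish(nr), ish(nc)]
    y <- stats::fft(y) / sqrt(length(x))
    y[sh(nr), sh(nc)]
  }
  for (p in seq_len(n_pix)) {
    e <- matrix(0, nr, nc); e[p] <- 1
    col <- c()
    for (ch in seq_len(nch)) {
      k <- ftc(coils$maps[, , ch] * e)
      col <- c(col, as.vector(k[, keep]))
    }
    A[, p] <- col
  }
  y <- c()
  for (ch in seq_len(nch)) y <- c(y, as.vector(ks_masked$data[, keep, ch]))
  x <- qr.solve(A, y)
  matrix(Mod(x), nr, nc)
}

# independent Wilcoxon oracle: full enumeration of all 2^n sign assignments,
# own ranking of |d| (zeros ranked then dropped, Pratt)
wilcoxon_enum_oracle <- function(a, b) {
  d <- a - b
  r_all <- rank(abs(d))
  r <- r_all[d != 0]
  s <- sign(d[d != 0])
  tobs <- sum(s * r)
  n <- length(r)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tall <- signs %*% r
  mean(abs(tall) >= abs(tobs) - 1e-9)
}

# independent ICC(2,1) oracle: explicit double sums for the ANOVA mean
# squares, no shared code with icc_2_1
icc_sums_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (sum(m[i, ]) / k - grand)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (sum(m[, j]) / n - grand)^2
  sst <- 0
  for (i in 1:n) for (j in 1:k) sst <- sst + (m[i, j] - grand)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  as.numeric((msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}
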