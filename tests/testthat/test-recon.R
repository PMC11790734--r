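# recon fixtures shared within this file
rec_ks_clean <- function() cached("rec_ks_clean",
  simulate_multicoil_kspace(small_phantom(), small_coils(), 0, seed = 1L))
rec_ks_noisy <- function() cached("rec_ks_noisy",
  simulate_multicoil_kspace(small_phantom(), small_coils(), 0.012, seed = 2L))

test_that("reference recon recovers the phantom from noiseless data", {
  p <- small_phantom()
  # single unit-sensitivity channel: exact equality up to fft rounding
  ks1 <- simulate_multicoil_kspace(p, unit_coils(c(48L, 48L)), 0, 1L)
  r1 <- reference_recon(ks1, unit_coils(c(48L, 48L)))
  expect_lt(max(abs(r1$image - p$image)), 1e-12)
  expect_identical(r1$method, "std")
  # 8-channel: relative RMS error below 1e-6
  r8 <- reference_recon(rec_ks_clean(), small_coils())
  expect_lt(sqrt(sum((r8$image - p$image)^2) / sum(p$image^2)), 1e-6)
})

test_that("noise strictly degrades the reconstruction", {
  p <- small_phantom()
  rn <- reference_recon(rec_ks_noisy(), small_coils())
  expect_false(isTRUE(all.equal(rn$image, p$image)))
  expect_lt(compute_ssim(p$image, rn$image), 1)
})

test_that("SENSE at AF = 1 equals the reference reconstruction", {
  co <- small_coils()
  m1 <- make_equidistant_mask(48L, 1L, 0L)
  s <- sense_recon(rec_ks_noisy(), co, m1)
  r <- reference_recon(rec_ks_noisy(), co)
  expect_lt(max(abs(s$image - r$image)), 1e-10)
})

test_that("noiseless well-conditioned AF = 3 SENSE recovers the phantom", {
  p <- small_phantom()
  co <- small_coils()
  m <- small_mask()
  s <- sense_recon(apply_mask(rec_ks_clean(), m), co, m)
  expect_lt(sqrt(sum((s$image - p$image)^2) / sum(p$image^2)), 1e-6)
  expect_identical(s$method, "acc_sense")
  expect_identical(s$af, 3L)
})

test_that("toy 2-pixel 2-channel R=2 system is solved exactly", {
  # sensitivities S = [[1, 0.5], [0.4, 1]] along the phase encode, true
  # pixel values (a, b) per row; R = 2 folds the two columns together
  img <- matrix(c(0.83, 0.27, 0.31, 0.65), 2L, 2L)
  S <- array(0 + 0i, c(2L, 2L, 2L))
  S[, , 1] <- matrix(c(1, 0.5), 2L, 2L, byrow = TRUE)
  S[, , 2] <- matrix(c(0.4, 1), 2L, 2L, byrow = TRUE)
  coils <- structure(list(maps = S, n_channels = 2L, shape = c(2L, 2L), seed = 0L),
                     class = "coil_sensitivities")
  ks <- simulate_multicoil_kspace(img, coils, 0, 1L)
  m <- make_equidistant_mask(2L, 2L, 0L)
  out <- sense_recon(apply_mask(ks, m), coils, m)
  # oracle: the 2x2 linear system has a unique solution, the true pixels
  expect_equal(out$image, img, tolerance = 1e-10)
})

test_that("single-channel R > 1 aliasing is reported as unresolvable", {
  co <- unit_coils(c(48L, 48L))
  ks <- simulate_multicoil_kspace(small_phantom(), co, 0, 1L)
  m <- make_equidistant_mask(48L, 2L, 0L)
  expect_error(sense_recon(apply_mask(ks, m), co, m), "unresolvable aliasing")
})

test_that("SENSE matches the joint whole-system least-squares oracle", {
  set.seed(4)
  img <- matrix(runif(12 * 12, 0.2, 1), 12, 12)
  co <- generate_coil_sensitivities(c(12L, 12L), 6L, seed = 6L)
  m <- make_equidistant_mask(12L, 3L, 0L)
  ks <- apply_mask(simulate_multicoil_kspace(img, co, 0.01, seed = 7L), m)
  ours <- sense_recon(ks, co, m)
  oracle <- sense_full_system_oracle(ks, co, m)
  expect_lt(max(abs(ours$image - oracle)), 1e-8)
})

test_that("POCS with lambda 0 and AF 1 reproduces the reference recon", {
  co <- small_coils()
  m1 <- make_equidistant_mask(48L, 1L, 0L)
  pc <- pocs_wavelet_recon(rec_ks_noisy(), co, m1,
                           pocs_config(lambda = 0, max_iters = 5L))
  r <- reference_recon(rec_ks_noisy(), co)
  expect_lt(max(abs(pc$image - r$image)), 1e-8)
})

test_that("POCS sampled-line residual is non-increasing (lambda = 0)", {
  co <- small_coils()
  m <- small_mask()
  pc <- pocs_wavelet_recon(apply_mask(rec_ks_clean(), m), co, m,
                           pocs_config(lambda = 0, max_iters = 40L, tol = 1e-12,
                                       init = "zero_filled"))
  res <- pc$meta$residuals
  expect_gte(length(res), 10L)
  expect_true(all(diff(res) <= 1e-12))
  expect_lt(res[length(res)], res[1])
})

test_that("POCS with lambda 0 drives the sampled-line mismatch toward zero", {
  co <- small_coils()
  m <- small_mask()
  ksm <- apply_mask(rec_ks_clean(), m)
  pc <- pocs_wavelet_recon(ksm, co, m,
                           pocs_config(lambda = 0, max_iters = 80L, tol = 1e-12,
                                       init = "zero_filled"))
  res <- pc$meta$residuals
  # consistent (noiseless) data: the residual shrinks monotonically and ends
  # well below its starting value
  expect_true(all(diff(res) <= 1e-12))
  expect_lt(res[length(res)], res[1] / 3)
})

test_that("wavelet thresholding reduces noise relative to zero-filled recon", {
  p <- small_phantom()
  co <- small_coils()
  m <- small_mask()
  ksm <- apply_mask(rec_ks_noisy(), m)
  zf <- flairacc:::zero_filled_recon(ksm, co)
  pc <- pocs_wavelet_recon(ksm, co, m, pocs_config(lambda = 0.5, max_iters = 60L))
  p0 <- pocs_wavelet_recon(ksm, co, m, pocs_config(lambda = 0, max_iters = 60L))
  # uniform white-matter region away from lesions
  wm <- p$labels == 3L
  err_sd <- function(img) stats::sd(img[wm] - p$image[wm])
  expect_lt(err_sd(pc$image), err_sd(zf$image))
  expect_lte(err_sd(pc$image), err_sd(p0$image))
})

test_that("Monte-Carlo noise maps behave physically", {
  p <- small_phantom()
  co <- small_coils()
  m <- small_mask()
  # zero input noise -> zero map
  map0 <- noise_uniformity_map(function(ks) reference_recon(ks, co),
                               p, co, mask = NULL, noise_std = 0,
                               n_reps = 3L, seed = 1L)
  expect_lt(max(map0), 1e-6)   # identical realizations, up to fft rounding

  reps <- 60L
  brain <- p$labels > 0L
  map_r1 <- noise_uniformity_map(function(ks) reference_recon(ks, co),
                                 p, co, mask = NULL, noise_std = 0.012,
                                 n_reps = reps, seed = 2L)
  map_r3 <- noise_uniformity_map(sense_reconstructor(co, m),
                                 p, co, mask = m, noise_std = 0.012,
                                 n_reps = reps, seed = 2L)
  cv <- function(mp) stats::sd(mp[brain]) / mean(mp[brain])
  # parallel imaging at R=3 amplifies noise non-uniformly (g-factor)
  expect_gt(cv(map_r3), cv(map_r1))
  expect_gt(mean(map_r3[brain]), mean(map_r1[brain]))

  # map scales linearly with the input noise level. Magnitude images are
  # Rician, so linearity is checked in the high-SNR regime (bright tissue,
  # small sigma) where |signal + noise| is effectively linear in the noise.
  hi <- p$labels %in% c(2L, 3L)
  map_a <- noise_uniformity_map(sense_reconstructor(co, m),
                                p, co, mask = m, noise_std = 0.002,
                                n_reps = reps, seed = 2L)
  map_b <- noise_uniformity_map(sense_reconstructor(co, m),
                                p, co, mask = m, noise_std = 0.004,
                                n_reps = reps, seed = 2L)
  ratio <- mean(map_b[hi]) / mean(map_a[hi])
  expect_equal(ratio, 2, tolerance = 0.1)
})
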