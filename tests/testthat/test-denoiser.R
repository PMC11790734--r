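test_that("architecture is frozen: kernels 9/5/5, channels 64/32/1, 57281 params", {
  m <- init_model(seed = 1L)
  kernels <- vapply(m$arch, function(a) a$kernel, integer(1))
  chans <- vapply(m$arch, function(a) a$n_out, integer(1))
  expect_equal(kernels, c(9L, 5L, 5L))
  expect_equal(chans, c(64L, 32L, 1L))
  expect_equal(dim(m$W[[1]]), c(9 * 9 * 1, 64))
  expect_equal(dim(m$W[[2]]), c(5 * 5 * 64, 32))
  expect_equal(dim(m$W[[3]]), c(5 * 5 * 32, 1))
  expect_equal(n_parameters(m),
               (9 * 9 * 1 * 64 + 64) + (5 * 5 * 64 * 32 + 32) + (5 * 5 * 32 * 1 + 1))
  expect_equal(n_parameters(m), 57281)
  expect_true(m$residual)
})

test_that("initialization is seeded and the forward pass preserves shape", {
  expect_identical(init_model(7L), init_model(7L))
  expect_false(identical(init_model(7L)$W[[1]], init_model(8L)$W[[1]]))
  m <- init_model(1L)
  x <- matrix(runif(32 * 32), 32, 32)
  y <- flairacc:::denoiser_forward(m, x)
  expect_identical(dim(y), c(32L, 32L))
  y2 <- flairacc:::denoiser_forward(m, matrix(0, 20, 24))
  expect_identical(dim(y2), c(20L, 24L))
  expect_true(all(is.finite(y2)))
})

test_that("a 1x1-kernel convolution reduces to a hand-computed affine map", {
  x <- array(matrix(c(1, -2, 3, 0.5), 2, 2), c(2L, 2L, 1L))
  W <- matrix(c(2, -1), 1, 2)     # 1x1 kernel, 1 input, 2 output channels
  b <- c(0.25, 1)
  out <- flairacc:::conv_forward(x, W, b, 1L)
  expect_equal(array(out$out, c(2, 2, 2))[, , 1], 2 * x[, , 1] + 0.25)
  expect_equal(array(out$out, c(2, 2, 2))[, , 2], -1 * x[, , 1] + 1)
})

test_that("convolution gradients match numerical differentiation", {
  set.seed(10)
  m <- init_model(2L)
  x <- matrix(runif(16 * 16), 16, 16)
  ref <- matrix(runif(16 * 16), 16, 16)
  fw <- flairacc:::denoiser_forward(m, x, keep = TRUE)
  gr <- flairacc:::denoiser_backward(m, fw, 2 * (fw$y - ref) / length(ref))
  loss <- function(mod) mean((flairacc:::denoiser_forward(mod, x) - ref)^2)
  eps <- 1e-6
  for (l in 1:3) {
    m2 <- m
    m2$W[[l]][3, 1] <- m2$W[[l]][3, 1] + eps
    expect_equal(gr[[l]]$gW[3, 1], (loss(m2) - loss(m)) / eps, tolerance = 1e-4)
  }
})

test_that("patch pairs are co-located, normalized, and reproducible", {
  set.seed(11)
  refs <- list(matrix(runif(48 * 48, 0, 2), 48, 48))
  nois <- list(refs[[1]] + matrix(rnorm(48 * 48, sd = 0.1), 48, 48))
  msk <- list(matrix(TRUE, 48, 48))
  p1 <- sample_patch_pairs(refs, nois, msk, n_patches = 30L, patch_size = 16L, seed = 3L)
  p2 <- sample_patch_pairs(refs, nois, msk, n_patches = 30L, patch_size = 16L, seed = 3L)
  expect_identical(p1, p2)
  expect_length(p1$ref, 30L)
  # patches co-located: difference equals the (normalized) noise field patch
  mse <- mean(vapply(seq_len(30L), function(i)
    mean((p1$ref[[i]] - p1$noisy[[i]])^2), numeric(1)))
  expect_gt(mse, 0)
  expect_error(sample_patch_pairs(refs, nois, msk, 5L, patch_size = 64L), "patch larger")
  # degenerate pairs: identical ref and noisy arms
  pd <- sample_patch_pairs(refs, refs, msk, 10L, 16L, seed = 4L)
  expect_equal(mean(vapply(seq_len(10L), function(i)
    mean((pd$ref[[i]] - pd$noisy[[i]])^2), numeric(1))), 0)
})

test_that("training reduces the loss and is invariant to pair order", {
  set.seed(12)
  base <- matrix(runif(40 * 40), 40, 40)
  refs <- list(base, base * 0.8 + 0.1)
  nois <- lapply(refs, function(r) r + matrix(rnorm(1600, sd = 0.08), 40, 40))
  msk <- list(matrix(TRUE, 40, 40), matrix(TRUE, 40, 40))
  pairs <- sample_patch_pairs(refs, nois, msk, 24L, 16L, seed = 5L)

  m0 <- init_model(3L)
  m1 <- train_denoiser(m0, pairs, epochs = 4L, lr = 1e-3, seed = 6L,
                       batch_size = 8L, val_frac = 0.5)
  lh <- m1$train_meta$loss_history
  expect_lt(lh[length(lh)], lh[1])

  # permuting the supplied pair order leaves the trained weights identical
  perm <- sample(length(pairs$id))
  shuffled <- pairs
  shuffled$ref <- pairs$ref[perm]; shuffled$noisy <- pairs$noisy[perm]
  shuffled$id <- pairs$id[perm]; shuffled$case <- pairs$case[perm]
  m2 <- train_denoiser(m0, shuffled, epochs = 4L, lr = 1e-3, seed = 6L,
                       batch_size = 8L, val_frac = 0.5)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
})

test_that("training on identical pairs drives the loss toward zero", {
  set.seed(13)
  refs <- list(matrix(runif(40 * 40), 40, 40))
  msk <- list(matrix(TRUE, 40, 40))
  pairs <- sample_patch_pairs(refs, refs, msk, 16L, 16L, seed = 7L)
  m <- train_denoiser(init_model(4L), pairs, epochs = 6L, lr = 1e-3,
                      seed = 8L, batch_size = 8L, val_frac = 0)
  lh <- m$train_meta$loss_history
  # the zero-initialized residual network starts exactly at the optimum for
  # identical pairs (loss 0, zero gradient) and must stay there
  expect_lte(lh[length(lh)], lh[1] + 1e-12)
  expect_lt(lh[length(lh)], 1e-3)
})

test_that("divergent training is reported as an error", {
  set.seed(14)
  refs <- list(matrix(runif(40 * 40), 40, 40))
  nois <- list(refs[[1]] + matrix(rnorm(1600, sd = 0.1), 40, 40))
  msk <- list(matrix(TRUE, 40, 40))
  pairs <- sample_patch_pairs(refs, nois, msk, 16L, 16L, seed = 9L)
  expect_error(
    train_denoiser(init_model(5L), pairs, epochs = 5L, lr = 1e200,
                   seed = 10L, batch_size = 8L, val_frac = 0),
    "diverged")
})

test_that("applying the denoiser preserves shape, clamps, and is bounded", {
  m <- init_model(6L)
  img <- new_recon <- matrix(runif(48 * 48, 0, 1.5), 48, 48)
  out <- apply_denoiser(m, img)
  expect_s3_class(out, "recon_image")
  expect_identical(out$method, "dlr")
  expect_identical(dim(out$image), dim(img))
  expect_true(all(out$image >= 0))
  expect_true(all(is.finite(out$image)))
  # second application changes the output by a finite, bounded amount
  out2 <- apply_denoiser(m, out)
  expect_true(is.finite(sqrt(sum((out2$image - out$image)^2))))
  # determinism
  expect_identical(apply_denoiser(m, img)$image, out$image)
})
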