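test_that("SSIM is 1 for identical images and symmetric in its arguments", {
  set.seed(1)
  x <- matrix(runif(20 * 20), 20, 20)
  y <- x + matrix(rnorm(400, sd = 0.05), 20, 20)
  expect_equal(compute_ssim(x, x), 1)
  expect_equal(compute_ssim(x, y), compute_ssim(y, x), tolerance = 1e-14)
  expect_lt(compute_ssim(x, y), 1)
  expect_error(compute_ssim(x, y[1:10, 1:10]), "shape")
  expect_error(compute_ssim(x * 0, x * 0), "dynamic range")
})

test_that("SSIM matches the per-window loop oracle on small images", {
  set.seed(2)
  params <- ssim_params(window_size = 3L, window = "uniform")
  for (n in c(8L, 12L, 16L)) {
    ref <- matrix(runif(n * n), n, n)
    test <- ref + matrix(rnorm(n * n, sd = 0.1), n, n)
    expect_equal(compute_ssim(ref, test, params),
                 ssim_loop_oracle(ref, test, win = 3L),
                 tolerance = 1e-10)
  }
})

test_that("NRMSE matches hand arithmetic and is scale invariant", {
  expect_equal(as.numeric(compute_nrmse(matrix(c(0, 2)), matrix(c(0, 1)))),
               sqrt(0.5) / 2, tolerance = 1e-12)
  set.seed(3)
  x <- matrix(runif(64), 8, 8); y <- matrix(runif(64), 8, 8)
  expect_equal(as.numeric(compute_nrmse(x, x)), 0)
  expect_equal(as.numeric(compute_nrmse(3.7 * x, 3.7 * y)),
               as.numeric(compute_nrmse(x, y)), tolerance = 1e-12)
  expect_equal(attr(compute_nrmse(x, y, "mean"), "normalization"), "mean")
  expect_error(compute_nrmse(matrix(1, 4, 4), matrix(0, 4, 4), "range"), "zero normalizer")
  # euclidean mode: rmse / rms(ref)
  expect_equal(as.numeric(compute_nrmse(x, y, "euclidean")),
               sqrt(mean((x - y)^2)) / sqrt(mean(x^2)), tolerance = 1e-12)
})

test_that("region extraction centers and clamps windows deterministically", {
  img <- matrix(seq_len(128 * 128), 128, 128)
  ctr <- extract_region(img, c(64L, 64L), 25L)
  expect_identical(dim(ctr), c(25L, 25L))
  expect_equal(attr(ctr, "coords"), c(52, 52))
  corner <- extract_region(img, c(1L, 1L), 25L)
  expect_equal(attr(corner, "coords"), c(1, 1))
  expect_identical(corner[, ], img[1:25, 1:25])
  far <- extract_region(img, c(128L, 128L), 25L)
  expect_equal(attr(far, "coords"), c(104, 104))
  expect_error(extract_region(img, c(0L, 5L)), "outside")
  expect_error(extract_region(matrix(0, 10, 10), c(5L, 5L), 25L), "smaller")
  # identical centers give byte-identical coordinates on any arm
  other <- matrix(rnorm(128 * 128), 128, 128)
  expect_identical(attr(extract_region(other, c(3L, 90L)), "coords"),
                   attr(extract_region(img, c(3L, 90L)), "coords"))
})

test_that("regional metrics yield one record per lesion; identical arms are perfect", {
  set.seed(4)
  img <- matrix(runif(128 * 128), 128, 128)
  lesions <- data.frame(id = 1:7,
                        row = sample(5:120, 7), col = sample(5:120, 7))
  out <- regional_metrics(img, img, lesions)
  expect_equal(nrow(out), 7L)
  expect_true(all(out$regional_ssim == 1))
  expect_true(all(out$regional_nrmse == 0))
  expect_error(regional_metrics(img, img, lesions[0, ]), "no lesions")
})

test_that("regional equals whole-image metrics on an exactly 25x25 image", {
  set.seed(5)
  ref <- matrix(runif(625), 25, 25)
  test <- ref + matrix(rnorm(625, sd = 0.05), 25, 25)
  les <- data.frame(id = 1L, row = 13L, col = 13L)
  reg <- regional_metrics(ref, test, les)
  expect_equal(reg$regional_ssim, compute_ssim(ref, test), tolerance = 1e-12)
  expect_equal(reg$regional_nrmse, as.numeric(compute_nrmse(ref, test)),
               tolerance = 1e-12)
})

test_that("metric summaries use the population SD and align paired vectors", {
  set.seed(6)
  img <- matrix(runif(64 * 64), 64, 64)
  noisy <- img + matrix(rnorm(64 * 64, sd = 0.03), 64, 64)
  les <- data.frame(id = 1:2, row = c(20L, 44L), col = c(20L, 44L))
  r1 <- metric_record(1L, "acc", img, noisy, les)
  single <- summarize_metrics(list(r1))
  # single-value metrics report SD 0 by the population convention
  whole <- single$table$metric %in% c("ssim", "nrmse")
  expect_true(all(single$table$sd[whole] == 0))
  # identical records in two arms produce identical rows
  r2 <- metric_record(1L, "dlr", img, noisy, les)
  both <- summarize_metrics(list(r1, r2))
  acc_rows <- both$table[both$table$arm == "acc", c("metric", "mean", "sd")]
  dlr_rows <- both$table[both$table$arm == "dlr", c("metric", "mean", "sd")]
  rownames(acc_rows) <- rownames(dlr_rows) <- NULL
  expect_identical(acc_rows, dlr_rows)
  expect_equal(both$paired$acc$ssim, both$paired$dlr$ssim)
  expect_error(summarize_metrics(list()), "no metric records")
})
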