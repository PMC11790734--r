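test_that("identical paired samples give a degenerate Wilcoxon result", {
  a <- c(3, 2, 4, 4, 1)
  w <- wilcoxon_signed_rank(a, a)
  expect_true(w$degenerate)
  expect_equal(w$p_value, 1)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "paired")
})

test_that("five uniformly positive differences give exact p = 0.0625", {
  w <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5), mode = "exact")
  expect_equal(w$p_value, 2 / 32)
  expect_equal(w$statistic, 15)
})

test_that("exact mode equals full 2^n enumeration for n <= 10, with ties and zeros", {
  set.seed(7)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    if (all(a == b)) a[1] <- a[1] %% 4 + 1
    w <- wilcoxon_signed_rank(a, b, mode = "exact")
    expect_equal(w$p_value, wilcoxon_enum_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("approximate mode is sane and close to exact for moderate n", {
  set.seed(8)
  a <- rnorm(12, mean = 0.8); b <- rnorm(12)
  pe <- wilcoxon_signed_rank(a, b, mode = "exact")$p_value
  pa <- wilcoxon_signed_rank(a, b, mode = "approx")$p_value
  expect_lt(abs(pe - pa), 0.05)
  # auto switches to the approximation above the exact limit
  a30 <- rnorm(30, 0.5); b30 <- rnorm(30)
  w <- wilcoxon_signed_rank(a30, b30)
  expect_match(w$method, "approximation")
  expect_true(w$p_value >= 0 && w$p_value <= 1)
})

test_that("Bonferroni multiplies, caps at one, preserves order, validates", {
  expect_equal(bonferroni_adjust(0.01, m = 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, m = 3), 1)
  expect_equal(bonferroni_adjust(c(0.04, 0.001, 0.3), m = 3),
               c(0.12, 0.003, 0.9))
  p <- c(0.2, 0.01)
  expect_true(all(bonferroni_adjust(p, m = 2) >= p))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "at least")
})

test_that("ICC(2,1) is 1 under perfect agreement and penalizes rater offsets", {
  items <- c(1, 2, 3, 4, 2, 3, 1, 4)
  perfect <- cbind(items, items, items)
  r <- icc_2_1(perfect)
  expect_equal(r$estimate, 1)
  expect_identical(r$category, "excellent")

  offset <- cbind(items, pmin(items + 1, 9))  # systematic +1 on every item
  r2 <- icc_2_1(offset)
  expect_lt(r2$estimate, 1)
  expect_equal(r2$estimate, icc_sums_oracle(offset), tolerance = 1e-12)

  flat <- matrix(2, 5, 3)
  expect_true(icc_2_1(flat)$degenerate)
  expect_error(icc_2_1(matrix(1:3, 3, 1)), "2 items")
})

test_that("ICC estimate matches the independent mean-squares oracle", {
  set.seed(9)
  m <- matrix(sample(1:4, 200, replace = TRUE), 100, 2)
  m[, 2] <- pmin(pmax(m[, 1] + sample(-1:1, 100, TRUE), 1), 4)  # correlated raters
  r <- icc_2_1(m)
  expect_equal(r$estimate, icc_sums_oracle(m), tolerance = 1e-10)
  expect_lte(r$ci_low, r$estimate)
  expect_gte(r$ci_high, r$estimate)
  expect_lte(r$estimate, 1)
  # invariant under relabeling of items and raters
  perm <- sample(100)
  expect_equal(icc_2_1(m[perm, c(2, 1)])$estimate, r$estimate, tolerance = 1e-12)
})

test_that("ICC categories follow the documented boundaries", {
  expect_identical(classify_icc(0.798), "good")
  expect_identical(classify_icc(0.462), "poor")
  expect_identical(classify_icc(0.50), "moderate")
  expect_identical(classify_icc(0.75), "moderate")
  expect_identical(classify_icc(0.90), "good")
  expect_identical(classify_icc(0.91), "excellent")
  expect_identical(classify_icc(-0.2), "poor")
  expect_error(classify_icc(1.2), "exceed")
})

test_that("score distributions count the fraction of ratings at 3 or above", {
  all4 <- rating_table(matrix(4, 10, 3))
  expect_equal(score_distribution(all4), 100)
  half <- rating_table(matrix(c(rep(2, 15), rep(3, 15)), 10, 3))
  expect_equal(score_distribution(half), 50)
  tab <- rating_table(matrix(c(rep(4, 97), rep(1, 3)), 100, 1))
  expect_equal(score_distribution(tab), 97)
  arms <- list(acc = half, dlr = all4)
  expect_equal(score_distribution(arms), c(acc = 50, dlr = 100))
  expect_error(rating_table(matrix(5, 3, 3)), "scale")
  expect_error(rating_table(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})
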