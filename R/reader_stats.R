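# Statistics layer: Wilcoxon signed-rank with Pratt zero handling (exact
# enumeration for small samples, tie-corrected normal approximation
# otherwise), Bonferroni correction, two-way random-effects absolute-agreement
# single-measure ICC(2,1) with an F-based 95% CI, and ordinal rating-table
# helpers.

#' Rating table (items x readers, ordinal 1-4)
#'
#' @param scores numeric matrix or data.frame, one row per item, one column
#'   per reader; complete design, entries in `scale`.
#' @param scale permitted score values.
#' @return integer matrix of class `rating_table` with dimnames kept.
#' @export
rating_table <- function(scores, scale = 1:4) {
  m <- as.matrix(scores)
  storage.mode(m) <- "integer"
  if (anyNA(m)) stop("rating table must be complete (no missing cells)")
  if (!all(m %in% scale)) stop("rating table entries must be in the scale")
  structure(m, class = c("rating_table", "matrix"))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Signed ranks of the paired differences, zeros handled by the Pratt method
#' (zeros participate in the ranking and are then dropped) or discarded
#' first. Two-sided p value: exact by enumeration over all sign assignments
#' when the number of non-zero differences is at most `exact_limit`,
#' otherwise a tie-corrected normal approximation with continuity correction.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param zero_policy `"pratt"` (default) or `"discard"`.
#' @param mode `"auto"`, `"exact"`, or `"approx"`.
#' @param exact_limit largest number of non-zero differences for which
#'   `"auto"` uses exact enumeration.
#' @return list: `statistic` (sum of positive ranks `V`), `signed_rank_sum`
#'   (`T = V+ - V-`), `p_value`, `n_effective`, `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(a, b, zero_policy = c("pratt", "discard"),
                                 mode = c("auto", "exact", "approx"),
                                 exact_limit = 12L) {
  zero_policy <- match.arg(zero_policy)
  mode <- match.arg(mode)
  if (length(a) != length(b) || length(a) < 1L) stop("a and b must be paired, length >= 1")
  d <- a - b
  if (zero_policy == "discard") d <- d[d != 0]
  if (length(d) == 0L || all(d == 0)) {
    return(list(statistic = 0, signed_rank_sum = 0, p_value = 1,
                n_effective = 0L, method = "degenerate", degenerate = TRUE))
  }
  r_all <- rank(abs(d))           # zeros (if kept) share in the ranking
  nz <- d != 0
  r <- r_all[nz]
  s <- sign(d[nz])
  Tobs <- sum(s * r)
  V <- sum(r[s > 0])
  m <- length(r)
  use_exact <- mode == "exact" || (mode == "auto" && m <= exact_limit)
  if (use_exact) {
    # enumerate all 2^m sign assignments of the non-zero ranks
    tvals <- as.vector(as.matrix(expand.grid(rep(list(c(-1, 1)), m))) %*% r)
    p <- mean(abs(tvals) >= abs(Tobs) - 1e-9)
    method <- "exact"
  } else {
    vr <- sum(r^2)
    z <- (abs(Tobs) - 1) / sqrt(vr)   # T moves in steps of ~2: cc = 1
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  list(statistic = V, signed_rank_sum = Tobs, p_value = min(p, 1),
       n_effective = m, method = method, degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' Each p value is multiplied by the number of comparisons `m` and capped at
#' 1; order is preserved.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param m number of comparisons, at least `length(p_values)`.
#' @return adjusted p values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  if (m < length(p_values)) stop("m must be at least the number of tests")
  pmin(1, m * p_values)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Estimated from the two-way ANOVA mean squares as
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`, with the F-based
#' 95% confidence interval for this form; the point estimate is labeled with
#' the conventional qualitative category (see [classify_icc()]).
#'
#' @param table items x raters numeric matrix (or `rating_table`); at least 2
#'   items and 2 raters, complete.
#' @param conf_level confidence level for the interval.
#' @return list of class `icc_result`: `estimate`, `ci_low`, `ci_high`,
#'   `category`, `n_items`, `n_raters`, `ms` (mean squares), `degenerate`.
#' @export
icc_2_1 <- function(table, conf_level = 0.95) {
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 items and 2 raters")
  if (anyNA(m)) stop("complete design required")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SST < .Machine$double.eps) {
    return(structure(list(estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, category = NA_character_,
                          n_items = n, n_raters = k,
                          ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                          degenerate = TRUE),
                     class = "icc_result"))
  }
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  # F-based CI (two-way random, absolute agreement, single measure)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  ci_high <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  structure(list(estimate = icc, ci_low = ci_low, ci_high = ci_high,
                 category = classify_icc(icc), n_items = n, n_raters = k,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE), degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$degenerate) cat("<icc_result> degenerate (zero variance)\n")
  else cat(sprintf("<icc_result> ICC(2,1) = %.3f [%.3f, %.3f] (%s), %d items x %d raters\n",
                   x$estimate, x$ci_low, x$ci_high, x$category, x$n_items, x$n_raters))
  invisible(x)
}

#' Qualitative ICC category
#'
#' `< 0.50` poor; `[0.50, 0.75]` moderate; `(0.75, 0.90]` good; `> 0.90`
#' excellent. The shared endpoints 0.75 and 0.90 are assigned to the lower
#' band (closed upper ends).
#'
#' @param value ICC estimate (`<= 1`).
#' @return character label.
#' @export
classify_icc <- function(value) {
  if (is.na(value)) return(NA_character_)
  if (value > 1) stop("ICC cannot exceed 1")
  if (value < 0.50) "poor"
  else if (value <= 0.75) "moderate"
  else if (value <= 0.90) "good"
  else "excellent"
}

#' Fraction of scores rated 3 or 4
#'
#' Proportion of all (item, reader) scores at or above 3, as a percentage;
#' accepts a single table or a named list of per-arm tables.
#'
#' @param table `rating_table` (or list of them).
#' @return percentage (or named vector of percentages).
#' @export
score_distribution <- function(table) {
  one <- function(t) 100 * mean(as.matrix(t) >= 3)
  if (is.list(table) && !is.matrix(table)) vapply(table, one, numeric(1)) else one(table)
}
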