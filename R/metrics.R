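# Quantitative image comparison: whole-image SSIM and NRMSE, plus regional
# variants on fixed-size windows centered on lesions (same coordinates in
# every arm).

#' SSIM parameters
#'
#' @param window_size odd window side length.
#' @param window `"gaussian"` (sd `sigma`) or `"uniform"` weighting.
#' @param sigma Gaussian window standard deviation in pixels.
#' @param k1,k2 stability constants.
#' @param dynamic_range intensity span `L`; `NULL` (default) uses the range
#'   of the two compared images combined, keeping the measure symmetric in
#'   its arguments.
#' @return list of class `ssim_params`.
#' @export
ssim_params <- function(window_size = 11L, window = c("gaussian", "uniform"),
                        sigma = 1.5, k1 = 0.01, k2 = 0.03, dynamic_range = NULL) {
  window <- match.arg(window)
  window_size <- as.integer(window_size)
  if (window_size %% 2L != 1L) stop("window size must be odd")
  if (k1 <= 0 || k2 <= 0) stop("k1 and k2 must be positive")
  structure(list(window_size = window_size, window = window, sigma = sigma,
                 k1 = k1, k2 = k2, dynamic_range = dynamic_range),
            class = "ssim_params")
}

ssim_window_weights <- function(params) {
  s <- params$window_size
  if (params$window == "uniform") {
    w <- matrix(1 / s^2, s, s)
  } else {
    half <- (s - 1) / 2
    g <- exp(-((-half):half)^2 / (2 * params$sigma^2))
    w <- outer(g, g)
    w <- w / sum(w)
  }
  w
}

# Weighted local mean over all fully interior windows ("valid" mode):
# out[i,j] = sum_w W[a,b] * img[i+a-1, j+b-1].
conv_valid <- function(img, w) {
  s <- nrow(w)
  nr <- nrow(img) - s + 1L
  nc <- ncol(img) - s + 1L
  out <- matrix(0, nr, nc)
  for (a in seq_len(s)) for (b in seq_len(s))
    out <- out + w[a, b] * img[a:(a + nr - 1L), b:(b + nc - 1L)]
  out
}

#' Structural similarity index (SSIM)
#'
#' Mean over local windows of
#' `[(2 mu_x mu_y + C1)(2 sigma_xy + C2)] / [(mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2)]`
#' with `C1 = (k1 L)^2`, `C2 = (k2 L)^2`. Windows fully inside the image are
#' used; the measure is symmetric in its arguments.
#'
#' @param ref,test same-shape numeric matrices.
#' @param params [ssim_params()].
#' @return scalar SSIM.
#' @export
compute_ssim <- function(ref, test, params = ssim_params()) {
  if (!all(dim(ref) == dim(test))) stop("shape mismatch")
  if (min(dim(ref)) < params$window_size)
    stop("image smaller than the SSIM window")
  L <- params$dynamic_range %||% (max(ref, test) - min(ref, test))
  if (L <= 0) stop("zero dynamic range")
  C1 <- (params$k1 * L)^2
  C2 <- (params$k2 * L)^2
  w <- ssim_window_weights(params)
  mux <- conv_valid(ref, w)
  muy <- conv_valid(test, w)
  sxx <- conv_valid(ref^2, w) - mux^2
  syy <- conv_valid(test^2, w) - muy^2
  sxy <- conv_valid(ref * test, w) - mux * muy
  num <- (2 * mux * muy + C1) * (2 * sxy + C2)
  den <- (mux^2 + muy^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

#' Normalized root-mean-square error (NRMSE)
#'
#' RMSE divided by a normalizer of the reference image: its intensity range
#' (default), mean, or root-mean-square (`"euclidean"`). The mode is recorded
#' as an attribute of the result.
#'
#' @param ref,test same-shape numeric matrices.
#' @param normalization `"range"`, `"mean"`, or `"euclidean"`.
#' @return scalar NRMSE with attribute `normalization`.
#' @export
compute_nrmse <- function(ref, test, normalization = c("range", "mean", "euclidean")) {
  normalization <- match.arg(normalization)
  if (!all(dim(ref) == dim(test))) stop("shape mismatch")
  rmse <- sqrt(mean((ref - test)^2))
  norm <- switch(normalization,
                 range = max(ref) - min(ref),
                 mean = mean(ref),
                 euclidean = sqrt(mean(ref^2)))
  if (norm == 0) stop("zero normalizer for NRMSE")
  structure(rmse / norm, normalization = normalization)
}

#' Extract a square region around a center pixel
#'
#' The window is centered at `center_rc` (1-based row, col); near borders it
#' is shifted just enough to stay inside the grid, so the same center always
#' yields the same coordinates regardless of image content — apply it with
#' identical centers to every arm.
#'
#' @param image numeric matrix.
#' @param center_rc integer pair (row, col), inside the image.
#' @param size odd window side length (default 25).
#' @return `size x size` matrix with attribute `coords = c(row0, col0)`
#'   (1-based top-left corner).
#' @export
extract_region <- function(image, center_rc, size = 25L) {
  size <- as.integer(size)
  if (size %% 2L != 1L) stop("window size must be odd")
  nr <- nrow(image); nc <- ncol(image)
  if (nr < size || nc < size) stop("image smaller than the window")
  cr <- as.integer(center_rc[1]); cc <- as.integer(center_rc[2])
  if (cr < 1L || cr > nr || cc < 1L || cc > nc) stop("center outside the image")
  half <- (size - 1L) %/% 2L
  r0 <- min(max(cr - half, 1L), nr - size + 1L)
  c0 <- min(max(cc - half, 1L), nc - size + 1L)
  structure(image[r0:(r0 + size - 1L), c0:(c0 + size - 1L)],
            coords = c(r0, c0))
}

#' Regional SSIM/NRMSE on lesion-centered windows
#'
#' For each lesion, extracts the same window from both images and computes
#' SSIM and NRMSE on the patches.
#'
#' @param ref,test same-shape numeric matrices.
#' @param lesions data.frame with columns `id`, `row`, `col` (1-based).
#' @param size window side length (default 25).
#' @param params [ssim_params()] for the patch SSIM (the window must fit the
#'   patch; the default 11x11 window fits 25x25).
#' @param nrmse_normalization normalizer mode for the patch NRMSE.
#' @return data.frame with columns `lesion_id`, `regional_ssim`,
#'   `regional_nrmse`.
#' @export
regional_metrics <- function(ref, test, lesions, size = 25L,
                             params = ssim_params(),
                             nrmse_normalization = "range") {
  if (nrow(lesions) == 0L) stop("no lesions supplied")
  out <- lapply(seq_len(nrow(lesions)), function(i) {
    center <- c(lesions$row[i], lesions$col[i])
    pr <- tryCatch(extract_region(ref, center, size),
                   error = function(e) stop(sprintf("lesion %s: %s",
                                                    lesions$id[i], conditionMessage(e))))
    pt <- extract_region(test, center, size)
    data.frame(lesion_id = lesions$id[i],
               regional_ssim = compute_ssim(pr, pt, params),
               regional_nrmse = as.numeric(compute_nrmse(pr, pt, nrmse_normalization)))
  })
  do.call(rbind, out)
}

#' Whole-image + regional metric record for one case/arm
#'
#' @param case_id identifier.
#' @param arm arm tag (e.g. `"acc"`, `"dlr"`).
#' @param ref,test reference and test images (matrices or `recon_image`s).
#' @param lesions lesion table (may have zero rows: regional part empty).
#' @param params,size,nrmse_normalization see [regional_metrics()].
#' @return list of class `metric_record`.
#' @export
metric_record <- function(case_id, arm, ref, test, lesions = NULL,
                          params = ssim_params(), size = 25L,
                          nrmse_normalization = "range") {
  ref <- as_image(ref); test <- as_image(test)
  regional <- if (!is.null(lesions) && nrow(lesions) > 0L)
    regional_metrics(ref, test, lesions, size, params, nrmse_normalization)
  else data.frame(lesion_id = integer(), regional_ssim = numeric(),
                  regional_nrmse = numeric())
  structure(list(case_id = case_id, arm = arm,
                 ssim = compute_ssim(ref, test, params),
                 nrmse = as.numeric(compute_nrmse(ref, test, nrmse_normalization)),
                 regional = regional),
            class = "metric_record")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarize metric records into a mean +/- SD table
#'
#' One row per arm and metric, with the population standard deviation (a
#' single record reports SD 0) and a formatted `mean ± SD` string.
#'
#' @param records list of [metric_record()]s.
#' @return list with `table` (data.frame: arm, metric, mean, sd, formatted)
#'   and `paired` (named list of per-arm value vectors for downstream paired
#'   tests, aligned by case then lesion order).
#' @export
summarize_metrics <- function(records) {
  if (length(records) == 0L) stop("no metric records")
  arms <- unique(vapply(records, function(r) r$arm, character(1)))
  collect <- function(arm) {
    rs <- Filter(function(r) r$arm == arm, records)
    list(ssim = vapply(rs, function(r) r$ssim, numeric(1)),
         nrmse = vapply(rs, function(r) r$nrmse, numeric(1)),
         regional_ssim = unlist(lapply(rs, function(r) r$regional$regional_ssim)),
         regional_nrmse = unlist(lapply(rs, function(r) r$regional$regional_nrmse)))
  }
  paired <- lapply(stats::setNames(arms, arms), collect)
  rows <- list()
  for (arm in arms) {
    for (metric in c("ssim", "nrmse", "regional_ssim", "regional_nrmse")) {
      v <- paired[[arm]][[metric]]
      if (length(v) == 0L) next
      rows[[length(rows) + 1L]] <-
        data.frame(arm = arm, metric = metric, n = length(v),
                   mean = mean(v), sd = pop_sd(v),
                   formatted = sprintf("%.4g ± %.3g", mean(v), pop_sd(v)))
    }
  }
  list(table = do.call(rbind, rows), paired = paired)
}
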