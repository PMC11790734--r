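# File interfaces: NIfTI / PNG export of phantoms and reconstructions,
# lesion and rating-table CSVs, YAML config round-trip, and the report
# writer (summary CSVs, JSON manifest, example PNG panel).

#' Write a 2D image as a single-slice NIfTI volume
#'
#' @param image matrix, `recon_image`, or `phantom_case` (its `image`).
#' @param path output file (`.nii` or `.nii.gz`).
#' @param pixel_mm pixel spacing in mm (taken from a `phantom_case` if given).
#' @return the path, invisibly.
#' @export
write_image_nifti <- function(image, path, pixel_mm = c(1, 1)) {
  if (inherits(image, "phantom_case")) {
    pixel_mm <- image$pixel_mm
    image <- image$image
  }
  img <- as_image(image)
  RNifti::writeNifti(RNifti::asNifti(array(img, c(dim(img), 1L)),
                                     pixdim = c(pixel_mm, 1)), path)
  invisible(path)
}

#' Read a 2D magnitude image (NIfTI or PNG)
#'
#' User-supplied images enter the metrics layer through this reader: NIfTI
#' volumes are reduced to their first slice; PNGs are converted to grayscale
#' by channel averaging.
#'
#' @param path input file (`.nii`, `.nii.gz`, or `.png`).
#' @return numeric matrix.
#' @export
read_magnitude_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE],
                                         c(1, 2), mean)
    return(a)
  }
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) > 2L) a <- a[, , 1L]
  matrix(as.numeric(a), nrow(a), ncol(a))
}

#' Write a magnitude image as a window-scaled PNG
#' @param image matrix or `recon_image`.
#' @param path output `.png`.
#' @param window intensity window (default full range).
#' @return the path, invisibly.
#' @export
write_image_png <- function(image, path, window = NULL) {
  img <- as_image(image)
  w <- window %||% range(img)
  x <- (img - w[1]) / max(w[2] - w[1], 1e-12)
  x[x < 0] <- 0; x[x > 1] <- 1
  png::writePNG(x, path)
  invisible(path)
}

#' Write / read a lesion table as CSV
#'
#' Columns `id, row, col, diameter_mm` with 0-based pixel indices on disk
#' (row-major convention); converted to the package's 1-based indexing on
#' read.
#'
#' @param lesions data.frame with 1-based `row`, `col`.
#' @param path CSV file.
#' @return the path (write) or the lesion data.frame (read).
#' @export
write_lesions_csv <- function(lesions, path) {
  out <- data.frame(id = lesions$id, row = lesions$row - 1L,
                    col = lesions$col - 1L, diameter_mm = lesions$diameter_mm)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lesions_csv
#' @export
read_lesions_csv <- function(path) {
  d <- utils::read.csv(path)
  data.frame(id = d$id, row = d$row + 1L, col = d$col + 1L,
             diameter_mm = d$diameter_mm)
}

#' Write coil sensitivity maps as real/imaginary NIfTI volumes
#'
#' Two files (`*_real.nii.gz`, `*_imag.nii.gz`), channels along the third
#' dimension.
#'
#' @param coils `coil_sensitivities`.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_coils_nifti <- function(coils, prefix) {
  re_path <- paste0(prefix, "_real.nii.gz")
  im_path <- paste0(prefix, "_imag.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(Re(coils$maps)), re_path)
  RNifti::writeNifti(RNifti::asNifti(Im(coils$maps)), im_path)
  invisible(c(re_path, im_path))
}

#' Read a rating table CSV (items x readers)
#'
#' First column may be an item id (non-numeric or named `item`); remaining
#' columns are reader scores.
#'
#' @param path CSV file.
#' @param scale permitted scores.
#' @return `rating_table`.
#' @export
read_rating_csv <- function(path, scale = 1:4) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (tolower(names(d)[1]) %in% c("item", "id") || !is.numeric(d[[1]])) {
    rn <- as.character(d[[1]])
    d <- d[, -1, drop = FALSE]
    rownames(d) <- rn
  }
  rating_table(d, scale = scale)
}

#' Serialize / restore an experiment configuration as YAML
#'
#' The configuration round-trips unchanged (up to numeric representation).
#'
#' @param config an [experiment_config()].
#' @param path YAML file.
#' @return the path (write) or the `experiment_config` (read).
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  plain <- unclass(config)
  plain$pocs <- unclass(plain$pocs)
  plain$ssim <- unclass(plain$ssim)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  p <- yaml::read_yaml(path)
  experiment_config(
    n_cases = p$n_cases, n_train_cases = p$n_train_cases, shape = p$shape,
    fov_mm = p$fov_mm, n_channels = p$n_channels, noise_std = p$noise_std,
    af = p$af, offset = p$offset, n_lesions = p$n_lesions,
    diameter_range_mm = p$diameter_range_mm, lesion_contrast = p$lesion_contrast,
    pocs = do.call(pocs_config, p$pocs),
    acc_method = p$acc_method, denoise = p$denoise, denoiser = p$denoiser,
    ssim = do.call(ssim_params, p$ssim[!vapply(p$ssim, is.null, logical(1))]),
    nrmse_mode = p$nrmse_mode, region_size = p$region_size,
    full_scan_time_s = p$full_scan_time_s, master_seed = p$master_seed)
}

#' Write an experiment report to disk
#'
#' Produces `summary.csv` (the quantitative-table analogue), per-case and
#' per-lesion metric CSVs, `tests.csv`, a JSON `manifest.json` (config echo,
#' seeds, train/eval split, scan-time strings, package version), and a PNG
#' panel of the std/acc/dlr example images with a lesion inset row.
#'
#' @param report an `experiment_report`.
#' @param outdir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "experiment_report"))
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("unwritable output directory")
  paths <- character(0)
  add <- function(p) { paths <<- c(paths, p); p }

  utils::write.csv(report$summary$table, add(file.path(outdir, "summary.csv")),
                   row.names = FALSE)

  per_case <- do.call(rbind, lapply(report$records, function(r)
    data.frame(case_id = r$case_id, arm = r$arm, ssim = r$ssim, nrmse = r$nrmse)))
  utils::write.csv(per_case, add(file.path(outdir, "per_case_metrics.csv")),
                   row.names = FALSE)

  per_lesion <- do.call(rbind, lapply(report$records, function(r) {
    if (nrow(r$regional) == 0L) return(NULL)
    cbind(data.frame(case_id = r$case_id, arm = r$arm), r$regional)
  }))
  regional_present <- !is.null(per_lesion) && nrow(per_lesion) > 0L
  if (regional_present)
    utils::write.csv(per_lesion, add(file.path(outdir, "per_lesion_metrics.csv")),
                     row.names = FALSE)

  utils::write.csv(report$tests, add(file.path(outdir, "tests.csv")),
                   row.names = FALSE)

  manifest <- list(
    config = unclass_deep(report$config),
    seeds = report$manifest$seeds,
    train_cases = report$manifest$train_cases,
    eval_cases = report$manifest$eval_cases,
    denoiser_val_cases = report$manifest$denoiser_val_cases,
    scan_time = report$scan_time,
    regional_rows = if (regional_present) nrow(per_lesion) else 0L,
    regional_omitted = !regional_present,
    package_version = report$manifest$package_version)
  jsonlite::write_json(manifest, add(file.path(outdir, "manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  # example panel: std | acc | dlr, plus lesion insets when lesions exist
  ex <- report$example
  w <- range(ex$std)
  scale01 <- function(img) {
    x <- (img - w[1]) / max(w[2] - w[1], 1e-12); x[x < 0] <- 0; x[x > 1] <- 1; x
  }
  gap <- matrix(1, nrow(ex$std), 2L)
  panel <- cbind(scale01(ex$std), gap, scale01(ex$acc), gap, scale01(ex$dlr))
  if (nrow(ex$lesions) > 0L) {
    ctr <- c(ex$lesions$row[1], ex$lesions$col[1])
    inset <- function(img) {
      patch <- extract_region(img, ctr, 25L)
      patch[rep(seq_len(25L), each = 2L), rep(seq_len(25L), each = 2L)]
    }
    irow <- cbind(scale01(inset(ex$std)), matrix(1, 50L, 2L),
                  scale01(inset(ex$acc)), matrix(1, 50L, 2L),
                  scale01(inset(ex$dlr)))
    width <- max(ncol(panel), ncol(irow))
    widen <- function(m) {
      out <- matrix(1, nrow(m), width)
      out[, seq_len(ncol(m))] <- m
      out
    }
    panel <- rbind(widen(panel), matrix(1, 2L, width), widen(irow))
  }
  png::writePNG(panel, add(file.path(outdir, "example_panel.png")))
  invisible(paths)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
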