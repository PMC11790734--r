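# Experiment orchestration: cohort -> k-space -> std / acc arms -> denoiser
# training on a disjoint training cohort -> dlr arm -> whole-image and
# regional metrics -> paired Wilcoxon tests with Bonferroni correction.

#' Experiment configuration
#'
#' Defaults mirror the study conditions at desk scale: a 30-case evaluation
#' cohort with at least 100 white-matter lesions in total, acceleration
#' factor 3 along the phase encode, 8 receive channels, and POCS with wavelet
#' soft-thresholding as the accelerated arm. The denoiser is trained on a
#' disjoint synthetic training cohort (`n_train_cases`), so every evaluation
#' case is held out from training.
#'
#' @param n_cases evaluation cohort size.
#' @param n_train_cases training cohort size (disjoint seeds).
#' @param shape grid rows x columns; the phase-encode length must be
#'   divisible by `af` and by `2^levels` of the wavelet.
#' @param fov_mm field of view in mm.
#' @param n_channels receive channels.
#' @param noise_std complex k-space noise sd per sample (relative to tissue
#'   signal ~0.55 for white matter).
#' @param af,offset equidistant undersampling factor and first sampled line.
#' @param n_lesions,diameter_range_mm,lesion_contrast lesion settings per case.
#' @param pocs [pocs_config()].
#' @param acc_method accelerated arm: `"pocs"` (default) or `"sense"`.
#' @param denoise apply the denoiser (if `FALSE` the dlr arm equals acc).
#' @param denoiser list: `n_patches`, `patch_size`, `epochs`, `lr`,
#'   `batch_size`, `val_frac`.
#' @param ssim [ssim_params()].
#' @param nrmse_mode NRMSE normalizer mode.
#' @param region_size regional analysis window (pixels).
#' @param full_scan_time_s fully sampled scan time for the scan-time estimate.
#' @param master_seed master seed; the whole experiment is a pure function of
#'   the configuration.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_cases = 30L, n_train_cases = 12L,
                              shape = c(120L, 120L), fov_mm = c(240, 240),
                              n_channels = 8L, noise_std = 0.002,
                              af = 3L, offset = 0L,
                              n_lesions = 4L, diameter_range_mm = c(3, 10),
                              lesion_contrast = 1.4,
                              pocs = pocs_config(),
                              acc_method = c("pocs", "sense"),
                              denoise = TRUE,
                              denoiser = list(n_patches = 288L, patch_size = 32L,
                                              epochs = 18L, lr = 3e-4,
                                              batch_size = 32L, val_frac = 0.2),
                              ssim = ssim_params(), nrmse_mode = "range",
                              region_size = 25L, full_scan_time_s = 277,
                              master_seed = 42L) {
  acc_method <- match.arg(acc_method)
  shape <- as.integer(rep(shape, length.out = 2L))
  if (n_cases < 1L || n_train_cases < 1L) stop("invalid config: cohort sizes must be >= 1")
  if (af >= 2L && shape[2] %% af != 0L)
    stop("invalid config: phase-encode length must be divisible by af for SENSE-style unfolding")
  if (shape[1] %% 2L^pocs$levels != 0L || shape[2] %% 2L^pocs$levels != 0L)
    stop("invalid config: grid must be divisible by 2^wavelet levels")
  if (noise_std < 0) stop("invalid config: negative noise_std")
  cfg <- list(n_cases = as.integer(n_cases), n_train_cases = as.integer(n_train_cases),
              shape = shape, fov_mm = rep(as.numeric(fov_mm), length.out = 2L),
              n_channels = as.integer(n_channels), noise_std = noise_std,
              af = as.integer(af), offset = as.integer(offset),
              n_lesions = as.integer(n_lesions),
              diameter_range_mm = as.numeric(diameter_range_mm),
              lesion_contrast = lesion_contrast, pocs = pocs,
              acc_method = acc_method, denoise = isTRUE(denoise),
              denoiser = denoiser, ssim = ssim, nrmse_mode = nrmse_mode,
              region_size = as.integer(region_size),
              full_scan_time_s = full_scan_time_s,
              master_seed = as.integer(master_seed))
  structure(cfg, class = "experiment_config")
}

# Simulate and reconstruct one case: fully sampled noisy k-space -> std;
# equidistant mask -> acc (POCS or SENSE). With `clean_ref = TRUE` a
# low-noise reference (reconstruction of the noiseless full k-space) is also
# produced — the training target for the denoiser, which must not share a
# noise realization with its input. Shared by the training-pair builder and
# the experiment driver.
reconstruct_case <- function(case, coil_seed, noise_seed, sim, clean_ref = FALSE) {
  coils <- generate_coil_sensitivities(case$shape, sim$n_channels, coil_seed)
  ks <- simulate_multicoil_kspace(case, coils, sim$noise_std, noise_seed)
  std <- reference_recon(ks, coils)
  mask <- make_equidistant_mask(case$shape[2], sim$af, sim$offset %||% 0L)
  ksm <- apply_mask(ks, mask)
  acc <- if ((sim$acc_method %||% "pocs") == "sense")
    sense_recon(ksm, coils, mask)
  else pocs_wavelet_recon(ksm, coils, mask, sim$pocs %||% pocs_config())
  ref <- if (clean_ref)
    reference_recon(simulate_multicoil_kspace(case, coils, 0, noise_seed), coils)
  else NULL
  list(std = std, acc = acc, ref_clean = ref, coils = coils, mask = mask)
}

sim_settings <- function(cfg) {
  list(n_channels = cfg$n_channels, noise_std = cfg$noise_std, af = cfg$af,
       offset = cfg$offset, pocs = cfg$pocs, acc_method = cfg$acc_method)
}

#' Run the full experiment
#'
#' Generates the training and evaluation cohorts, simulates multi-coil
#' k-space, reconstructs the std and acc arms, trains the denoiser on patch
#' pairs from the training cohort only, produces the dlr arm on the
#' evaluation cohort, computes whole-image and regional SSIM/NRMSE against
#' the std arm, and runs paired Wilcoxon signed-rank tests (acc vs dlr) with
#' Bonferroni correction across the four metric comparisons. Fully
#' reproducible from the master seed.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-stage progress lines.
#' @return list of class `experiment_report`: `config`, `records`, `summary`,
#'   `tests`, `scan_time`, `model_meta`, `manifest` (seeds + split), and the
#'   per-case images of the first evaluation case for figures.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  say <- function(...) if (verbose) message(sprintf(...))

  seeds <- list(
    eval_cohort = derive_seeds(cfg$master_seed, 1L, "eval-cohort"),
    train_cohort = derive_seeds(cfg$master_seed, 1L, "train-cohort"),
    eval_coils = derive_seeds(cfg$master_seed, cfg$n_cases, "eval-coils"),
    eval_noise = derive_seeds(cfg$master_seed, cfg$n_cases, "eval-noise"),
    train_coils = derive_seeds(cfg$master_seed, cfg$n_train_cases, "train-coils"),
    train_noise = derive_seeds(cfg$master_seed, cfg$n_train_cases, "train-noise"),
    patches = derive_seeds(cfg$master_seed, 1L, "patches"),
    denoiser = derive_seeds(cfg$master_seed, 1L, "denoiser")
  )

  say("stage=cohort n_eval=%d n_train=%d", cfg$n_cases, cfg$n_train_cases)
  gen <- function(n, master) generate_cohort(
    n, shape = cfg$shape, fov_mm = cfg$fov_mm, n_lesions = cfg$n_lesions,
    diameter_range_mm = cfg$diameter_range_mm,
    lesion_contrast = cfg$lesion_contrast, master_seed = master)
  eval_cohort <- gen(cfg$n_cases, seeds$eval_cohort)
  train_cohort <- gen(cfg$n_train_cases, seeds$train_cohort)

  sim <- sim_settings(cfg)
  recon_one <- function(cohort, i, cs, ns, label, clean_ref = FALSE) {
    say("stage=recon cohort=%s case=%d", label, i)
    tryCatch(reconstruct_case(cohort[[i]], cs[i], ns[i], sim, clean_ref),
             error = function(e) stop(sprintf("stage recon, %s case %d: %s",
                                              label, i, conditionMessage(e))))
  }
  train_arms <- if (cfg$denoise)
    lapply(seq_len(cfg$n_train_cases), function(i)
      recon_one(train_cohort, i, seeds$train_coils, seeds$train_noise, "train",
                clean_ref = TRUE))
  else list()
  eval_arms <- lapply(seq_len(cfg$n_cases), function(i)
    recon_one(eval_cohort, i, seeds$eval_coils, seeds$eval_noise, "eval"))

  model_meta <- NULL
  model <- NULL
  if (cfg$denoise) {
    say("stage=pairs n_patches=%d", cfg$denoiser$n_patches)
    pairs <- sample_patch_pairs(lapply(train_arms, `[[`, "ref_clean"),
                                lapply(train_arms, `[[`, "acc"),
                                lapply(train_cohort, function(cs) cs$labels > 0),
                                cfg$denoiser$n_patches, cfg$denoiser$patch_size,
                                seeds$patches)
    say("stage=train epochs=%d", cfg$denoiser$epochs)
    model <- train_denoiser(init_model(seeds$denoiser), pairs,
                            epochs = cfg$denoiser$epochs, lr = cfg$denoiser$lr,
                            seed = seeds$denoiser,
                            batch_size = cfg$denoiser$batch_size,
                            val_frac = cfg$denoiser$val_frac)
    model_meta <- model$train_meta
  }

  say("stage=metrics")
  records <- list()
  for (i in seq_len(cfg$n_cases)) {
    std <- eval_arms[[i]]$std
    acc <- eval_arms[[i]]$acc
    dlr <- if (cfg$denoise) apply_denoiser(model, acc) else
      new_recon_image(acc$image, "dlr", af = acc$af)
    lesions <- eval_cohort[[i]]$lesions
    records[[length(records) + 1L]] <-
      metric_record(i, "acc", std, acc, lesions, cfg$ssim, cfg$region_size, cfg$nrmse_mode)
    records[[length(records) + 1L]] <-
      metric_record(i, "dlr", std, dlr, lesions, cfg$ssim, cfg$region_size, cfg$nrmse_mode)
  }
  summary <- summarize_metrics(records)

  say("stage=stats")
  tests <- compare_arms(summary$paired, arm_a = "acc", arm_b = "dlr")

  acc_time <- estimate_scan_time(cfg$full_scan_time_s, cfg$af)
  report <- structure(list(
    config = cfg,
    records = records,
    summary = summary,
    tests = tests,
    scan_time = list(full_s = cfg$full_scan_time_s,
                     accelerated_s = acc_time,
                     full_rendered = format_scan_time(cfg$full_scan_time_s),
                     accelerated_rendered = format_scan_time(acc_time)),
    model_meta = model_meta,
    manifest = list(seeds = seeds,
                    train_cases = paste0("train-", seq_len(cfg$n_train_cases)),
                    eval_cases = paste0("eval-", seq_len(cfg$n_cases)),
                    denoiser_val_cases = model_meta$val_cases,
                    package_version = as.character(utils::packageVersion("flairacc"))),
    example = list(case = 1L,
                   std = eval_arms[[1]]$std$image,
                   acc = eval_arms[[1]]$acc$image,
                   dlr = if (cfg$denoise) apply_denoiser(model, eval_arms[[1]]$acc)$image
                         else eval_arms[[1]]$acc$image,
                   lesions = eval_cohort[[1]]$lesions)
  ), class = "experiment_report")
  report
}

#' Paired arm comparison with Bonferroni correction
#'
#' Wilcoxon signed-rank tests on the paired per-case (whole-image) and
#' per-lesion (regional) metric values of two arms; the four p values are
#' Bonferroni-adjusted as a family.
#'
#' @param paired the `paired` element of [summarize_metrics()].
#' @param arm_a,arm_b arm tags to compare.
#' @return data.frame: metric, mean_a, mean_b, n, statistic, p_raw,
#'   p_bonferroni.
#' @export
compare_arms <- function(paired, arm_a = "acc", arm_b = "dlr") {
  metrics <- c("ssim", "nrmse", "regional_ssim", "regional_nrmse")
  rows <- lapply(metrics, function(mt) {
    a <- paired[[arm_a]][[mt]]
    b <- paired[[arm_b]][[mt]]
    if (length(a) == 0L || length(a) != length(b)) return(NULL)
    w <- wilcoxon_signed_rank(a, b)
    data.frame(metric = mt, mean_a = mean(a), mean_b = mean(b), n = length(a),
               statistic = w$statistic, p_raw = w$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni_adjust(out$p_raw, m = nrow(out))
  attr(out, "arms") <- c(arm_a, arm_b)
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d eval cases, AF %d, acc arm = %s\n",
              x$config$n_cases, x$config$af, x$config$acc_method))
  cat(sprintf("  scan time: full %s, accelerated %s\n",
              x$scan_time$full_rendered, x$scan_time$accelerated_rendered))
  print(x$summary$table[, c("arm", "metric", "n", "formatted")], row.names = FALSE)
  cat("  paired tests (acc vs dlr, Bonferroni-adjusted):\n")
  print(x$tests[, c("metric", "mean_a", "mean_b", "p_bonferroni")], row.names = FALSE)
  invisible(x)
}
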