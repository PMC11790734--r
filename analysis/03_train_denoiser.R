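#!/usr/bin/env Rscript
# Train the 3-layer residual convolutional denoiser on reference/noisy patch
# pairs from a synthetic training cohort (disjoint from the evaluation
# cohort used in 04_evaluate.R).
#
# Outputs under results/denoiser/:
#   loss_history.csv     training and validation MSE per epoch
#   model.rds            trained weights (regenerable; binary, not tracked)

library(flairacc)

outdir <- file.path("results", "denoiser")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- experiment_config()
train_cohort <- generate_cohort(cfg$n_train_cases, shape = cfg$shape,
                                fov_mm = cfg$fov_mm, n_lesions = cfg$n_lesions,
                                diameter_range_mm = cfg$diameter_range_mm,
                                master_seed = cfg$master_seed + 1L)
pairs <- make_training_pairs(
  train_cohort,
  sim = list(n_channels = cfg$n_channels, noise_std = cfg$noise_std,
             af = cfg$af, offset = cfg$offset, pocs = cfg$pocs,
             acc_method = cfg$acc_method),
  n_patches = cfg$denoiser$n_patches, patch_size = cfg$denoiser$patch_size,
  seed = cfg$master_seed + 2L)

model <- train_denoiser(init_model(cfg$master_seed + 3L), pairs,
                        epochs = cfg$denoiser$epochs, lr = cfg$denoiser$lr,
                        seed = cfg$master_seed + 3L,
                        batch_size = cfg$denoiser$batch_size,
                        val_frac = cfg$denoiser$val_frac)

tm <- model$train_meta
write.csv(data.frame(epoch = seq_along(tm$loss_history),
                     train_mse = tm$loss_history, val_mse = tm$val_history),
          file.path(outdir, "loss_history.csv"), row.names = FALSE)
saveRDS(model, file.path(outdir, "model.rds"))

cat(sprintf("Model: %d parameters; trained %d epochs on %d patch pairs (%d training cases)\n",
            n_parameters(model), tm$epochs, length(pairs$id), cfg$n_train_cases))
cat(sprintf("Training MSE %.3g -> %.3g; validation MSE %.3g (noisy-input baseline %.3g)\n",
            tm$loss_history[1], tm$final_loss,
            tm$val_history[length(tm$val_history)], tm$val_mse_noisy))
if (is.finite(tm$val_mse_noisy) &&
    tm$val_history[length(tm$val_history)] < tm$val_mse_noisy)
  cat("Denoiser beats the noisy-input baseline on held-out validation patches.\n")
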