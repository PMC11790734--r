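# Three-layer residual convolutional denoiser (SRCNN-style):
#   layer 1: 9x9 kernels, 64 channels, ReLU
#   layer 2: 5x5 kernels, 32 channels, ReLU
#   layer 3: 5x5 kernels,  1 channel, linear
# with a global skip connection (output = input + correction). Convolutions
# use same-padding with reflect boundary; training is Adam on MSE over
# reference/noisy patch pairs. Implemented with im2col + BLAS matmul.

denoiser_arch <- function() list(
  list(kernel = 9L, n_in = 1L, n_out = 64L, act = "relu"),
  list(kernel = 5L, n_in = 64L, n_out = 32L, act = "relu"),
  list(kernel = 5L, n_in = 32L, n_out = 1L, act = "linear")
)

# -- im2col machinery (cached per image/kernel geometry) ---------------------

.conv_cache <- new.env(parent = emptyenv())

conv_geometry <- function(n, m, k) {
  key <- paste(n, m, k, sep = "x")
  g <- .conv_cache[[key]]
  if (!is.null(g)) return(g)
  pad <- (k - 1L) %/% 2L
  np <- n + 2L * pad; mp <- m + 2L * pad
  ri <- reflect_idx(n, pad); ci <- reflect_idx(m, pad)
  # linear indices into the padded image for each (output pixel, offset)
  base_r <- rep(seq_len(n), times = m)
  base_c <- rep(seq_len(m), each = n)
  IDX <- matrix(0L, n * m, k * k)
  o <- 0L
  for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    o <- o + 1L
    IDX[, o] <- (base_r + dr) + (base_c + dc - 1L) * np
  }
  idx_vec <- as.vector(IDX)
  # fold map: padded linear index -> unpadded linear index (reflect adjoint)
  map <- rep(ri, times = mp) + (rep(ci, each = np) - 1L) * n
  # adjoint of im2col + padding as one sparse scatter matrix:
  # gx = t(S) %*% gcol-reshaped, S[(p,o), map(idx)] = 1
  scatter <- Matrix::sparseMatrix(i = seq_along(idx_vec), j = map[idx_vec],
                                  x = 1, dims = c(length(idx_vec), n * m))
  g <- list(pad = pad, np = np, mp = mp, ri = ri, ci = ci,
            idx_vec = idx_vec, scatter_t = Matrix::t(scatter),
            n = n, m = m, k = k)
  .conv_cache[[key]] <- g
  g
}

# x: array (n, m, cin); W: matrix (k*k*cin, cout); b: length cout.
conv_forward <- function(x, W, b, k) {
  d <- dim(x)
  n <- d[1]; m <- d[2]; cin <- d[3]
  g <- conv_geometry(n, m, k)
  xp <- x[g$ri, g$ci, , drop = FALSE]
  dim(xp) <- c(g$np * g$mp, cin)
  colmat <- xp[g$idx_vec, , drop = FALSE]
  dim(colmat) <- c(n * m, k * k * cin)
  out <- colmat %*% W
  out <- out + rep(b, each = n * m)
  list(out = out, colmat = colmat, geom = g, cin = cin)
}

# gout: matrix (n*m, cout). Returns grads and the gradient wrt the input.
conv_backward <- function(fwd, W, gout) {
  g <- fwd$geom
  gW <- crossprod(fwd$colmat, gout)
  gb <- colSums(gout)
  gcol <- tcrossprod(gout, W)                            # (n*m, k2*cin)
  dim(gcol) <- c(g$n * g$m * g$k * g$k, fwd$cin)
  gx <- as.matrix(g$scatter_t %*% gcol)                  # (n*m, cin)
  list(gW = gW, gb = gb, gx = array(gx, c(g$n, g$m, fwd$cin)))
}

# -- model -------------------------------------------------------------------

#' Initialize the 3-layer residual denoiser
#'
#' Seeded He-scaled Gaussian initialization for the ReLU layers; the final
#' layer starts at exactly zero, so with the global skip connection the
#' untrained network is the identity — the standard initialization for a
#' residual correction, and the one that avoids the early-training collapse
#' in which the optimizer silences the random initial correction by killing
#' activations.
#'
#' @param seed integer seed.
#' @return object of class `denoiser_model` with weight matrices, biases,
#'   the architecture description, normalization settings, and (after
#'   training) `train_meta`.
#' @export
init_model <- function(seed = 1L) {
  arch <- denoiser_arch()
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_along(arch)) {
      a <- arch[[l]]
      fan_in <- a$kernel^2 * a$n_in
      W[[l]] <- if (a$act == "relu")
        matrix(stats::rnorm(fan_in * a$n_out, 0, sqrt(2 / fan_in)), fan_in, a$n_out)
      else matrix(0, fan_in, a$n_out)   # zero final layer: start at identity
      b[[l]] <- rep(0, a$n_out)
    }
    structure(list(arch = arch, W = W, b = b, residual = TRUE,
                   norm = list(probs = c(0.01, 0.99)),
                   train_meta = NULL, seed = as.integer(seed)),
              class = "denoiser_model")
  })
}

#' Number of trainable parameters
#' @param model `denoiser_model`.
#' @return integer count (weights + biases).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$W, length, numeric(1))) + sum(vapply(model$b, length, numeric(1)))
}

#' @export
print.denoiser_model <- function(x, ...) {
  layers <- vapply(x$arch, function(a)
    sprintf("%dx%d/%d", a$kernel, a$kernel, a$n_out), character(1))
  trained <- if (is.null(x$train_meta)) "untrained" else
    sprintf("trained %d epochs, final loss %.3g", x$train_meta$epochs, x$train_meta$final_loss)
  cat(sprintf("<denoiser_model> %s + skip, %d parameters, %s\n",
              paste(layers, collapse = " -> "), n_parameters(x), trained))
  invisible(x)
}

# Forward pass on a single-channel matrix (already normalized).
denoiser_forward <- function(model, x, keep = FALSE) {
  n <- nrow(x); m <- ncol(x)
  cur <- array(x, c(n, m, 1L))
  cache <- list()
  for (l in seq_along(model$arch)) {
    a <- model$arch[[l]]
    fwd <- conv_forward(cur, model$W[[l]], model$b[[l]], a$kernel)
    pre <- fwd$out
    act <- if (a$act == "relu") pmax(pre, 0) else pre
    if (keep) cache[[l]] <- list(fwd = fwd, pre = pre)
    cur <- array(act, c(n, m, a$n_out))
  }
  y <- x + matrix(cur, n, m)          # global skip connection
  if (keep) list(y = y, cache = cache) else y
}

# Backward pass; gy is dLoss/dy (matrix). Returns per-layer gW, gb.
denoiser_backward <- function(model, fw, gy) {
  nlay <- length(model$arch)
  g <- matrix(gy, length(gy), 1L)     # grad wrt layer-3 activation
  grads <- vector("list", nlay)
  for (l in rev(seq_len(nlay))) {
    a <- model$arch[[l]]
    cc <- fw$cache[[l]]
    gpre <- if (a$act == "relu") g * (cc$pre > 0) else g
    bk <- conv_backward(cc$fwd, model$W[[l]], gpre)
    grads[[l]] <- list(gW = bk$gW, gb = bk$gb)
    if (l > 1L) g <- matrix(bk$gx, prod(dim(bk$gx)[1:2]), dim(bk$gx)[3])
  }
  grads
}

# -- training pairs ----------------------------------------------------------

# Normalize an image linearly so its [p1, p99] quantile span maps to [0, 1].
norm_params <- function(img, probs = c(0.01, 0.99)) {
  q <- stats::quantile(img, probs, names = FALSE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1e-6
  list(lo = q[1], hi = q[2])
}
norm_apply <- function(img, p) (img - p$lo) / (p$hi - p$lo)
norm_invert <- function(img, p) img * (p$hi - p$lo) + p$lo

#' Sample aligned reference/noisy patch pairs from reconstructed images
#'
#' Patches are co-located crops of the reference (std-arm) and noisy
#' (acc-arm) reconstructions of the same case, with centers drawn from the
#' brain mask; both members of a pair are normalized by the noisy image's
#' percentile span (the same input-derived rule used at inference).
#'
#' @param refs,noisies lists of same-shape matrices (or `recon_image`s), one
#'   per case, aligned.
#' @param brain_masks list of logical matrices marking usable patch centers.
#' @param n_patches number of pairs to draw.
#' @param patch_size square patch side.
#' @param seed integer seed.
#' @param probs normalization percentiles.
#' @return object of class `training_pairs`.
#' @export
sample_patch_pairs <- function(refs, noisies, brain_masks, n_patches,
                               patch_size = 32L, seed = 1L,
                               probs = c(0.01, 0.99)) {
  stopifnot(length(refs) == length(noisies), length(refs) >= 1L, n_patches >= 1L)
  refs <- lapply(refs, as_image); noisies <- lapply(noisies, as_image)
  patch_size <- as.integer(patch_size)
  nr <- nrow(refs[[1]]); nc <- ncol(refs[[1]])
  if (patch_size > min(nr, nc)) stop("patch larger than image")
  half_lo <- (patch_size - 1L) %/% 2L
  half_hi <- patch_size - 1L - half_lo
  params <- lapply(noisies, norm_params, probs = probs)
  with_seed(seed, {
    case_of <- sample(rep_len(seq_along(refs), n_patches))
    ref_p <- vector("list", n_patches)
    noi_p <- vector("list", n_patches)
    for (i in seq_len(n_patches)) {
      ci <- case_of[i]
      msk <- brain_masks[[ci]]
      ok <- which(msk &
                    row(msk) > half_lo & row(msk) <= nr - half_hi &
                    col(msk) > half_lo & col(msk) <= nc - half_hi)
      if (length(ok) == 0L) stop("no valid patch centers inside the brain mask")
      pick <- ok[sample.int(length(ok), 1L)]
      r <- (pick - 1L) %% nr + 1L
      c <- (pick - 1L) %/% nr + 1L
      rows <- (r - half_lo):(r + half_hi)
      cols <- (c - half_lo):(c + half_hi)
      p <- params[[ci]]
      ref_p[[i]] <- norm_apply(refs[[ci]][rows, cols], p)
      noi_p[[i]] <- norm_apply(noisies[[ci]][rows, cols], p)
    }
    structure(list(ref = ref_p, noisy = noi_p, id = seq_len(n_patches),
                   case = case_of, patch_size = patch_size,
                   probs = probs, seed = as.integer(seed)),
              class = "training_pairs")
  })
}

#' Build training pairs from a phantom cohort
#'
#' Runs the simulation and both reconstruction arms for every case (fully
#' sampled -> std reference; undersampled -> acc), then samples co-located
#' patch pairs from the reconstructed images.
#'
#' @param cohort list of `phantom_case`s.
#' @param sim list of simulation/reconstruction settings: `n_channels`,
#'   `noise_std`, `af`, `offset`, `pocs` ([pocs_config()]), `acc_method`
#'   (`"pocs"` or `"sense"`).
#' @param n_patches,patch_size,seed see [sample_patch_pairs()].
#' @return `training_pairs`.
#' @export
make_training_pairs <- function(cohort, sim, n_patches, patch_size = 32L, seed = 1L) {
  stopifnot(length(cohort) >= 1L)
  coil_seeds <- derive_seeds(seed, length(cohort), "tp-coils")
  noise_seeds <- derive_seeds(seed, length(cohort), "tp-noise")
  arms <- lapply(seq_along(cohort), function(i)
    reconstruct_case(cohort[[i]], coil_seeds[i], noise_seeds[i], sim,
                     clean_ref = TRUE))
  sample_patch_pairs(lapply(arms, `[[`, "ref_clean"),
                     lapply(arms, `[[`, "acc"),
                     lapply(cohort, function(cs) cs$labels > 0),
                     n_patches, patch_size, seed)
}

#' @export
print.training_pairs <- function(x, ...) {
  cat(sprintf("<training_pairs> %d pairs of %dx%d patches from %d case(s)\n",
              length(x$id), x$patch_size, x$patch_size, length(unique(x$case))))
  invisible(x)
}

# -- training ----------------------------------------------------------------

#' Train the denoiser on reference/noisy patch pairs
#'
#' Adam on the mean-squared error between the network output and the
#' reference patch. Cases are split 80/20 into training and validation by
#' case (never by patch) from the seed; the validation loss is tracked per
#' epoch. Pairs are put into a canonical order by id before seeded
#' shuffling, so the result does not depend on the order the pairs are
#' supplied in.
#'
#' @param model `denoiser_model` (from [init_model()]).
#' @param pairs `training_pairs`.
#' @param epochs number of passes over the training pairs.
#' @param lr Adam learning rate.
#' @param seed integer seed (shuffling + split).
#' @param batch_size minibatch size.
#' @param val_frac fraction of cases held out for validation monitoring.
#' @return trained `denoiser_model` with `train_meta` (loss histories,
#'   validation case ids, epochs, lr, seed, final loss).
#' @export
train_denoiser <- function(model, pairs, epochs = 30L, lr = 1e-3, seed = 1L,
                           batch_size = 32L, val_frac = 0.2) {
  stopifnot(inherits(model, "denoiser_model"), inherits(pairs, "training_pairs"))
  if (length(pairs$id) == 0L) stop("no training pairs")
  ord <- order(pairs$id)
  refs <- pairs$ref[ord]; nois <- pairs$noisy[ord]; case <- pairs$case[ord]

  cases <- sort(unique(case))
  n_val <- if (length(cases) >= 2L) max(1L, round(val_frac * length(cases))) else 0L
  val_cases <- if (n_val > 0L)
    with_seed(seed + 1L, sort(sample(cases, n_val))) else integer(0)
  tr_idx <- which(!(case %in% val_cases))
  va_idx <- which(case %in% val_cases)
  if (length(tr_idx) == 0L) { tr_idx <- seq_along(refs); va_idx <- integer(0) }

  # Adam state
  mW <- lapply(model$W, function(w) w * 0); vW <- mW
  mb <- lapply(model$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_hist <- numeric(epochs); val_hist <- rep(NA_real_, epochs)

  mse_set <- function(idx) {
    if (length(idx) == 0L) return(NA_real_)
    mean(vapply(idx, function(i) {
      y <- denoiser_forward(model, nois[[i]])
      mean((y - refs[[i]])^2)
    }, numeric(1)))
  }

  shuffle_seeds <- derive_seeds(seed, epochs, "epoch-shuffle")
  for (ep in seq_len(epochs)) {
    perm <- with_seed(shuffle_seeds[ep], sample(tr_idx))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, length(perm), by = batch_size)) {
      batch <- perm[start:min(start + batch_size - 1L, length(perm))]
      gW <- lapply(model$W, function(w) w * 0)
      gb <- lapply(model$b, function(b) b * 0)
      bl <- 0
      for (i in batch) {
        fw <- denoiser_forward(model, nois[[i]], keep = TRUE)
        err <- fw$y - refs[[i]]
        bl <- bl + mean(err^2)
        gy <- 2 * err / length(err)
        gr <- denoiser_backward(model, fw, gy)
        for (l in seq_along(gW)) {
          gW[[l]] <- gW[[l]] + gr[[l]]$gW
          gb[[l]] <- gb[[l]] + gr[[l]]$gb
        }
      }
      nbatch <- length(batch)
      if (!is.finite(bl)) stop("training diverged: loss became non-finite (try a lower lr)")
      step <- step + 1L
      for (l in seq_along(model$W)) {
        gWl <- gW[[l]] / nbatch; gbl <- gb[[l]] / nbatch
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gWl
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gWl^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gbl
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gbl^2
        mhW <- mW[[l]] / (1 - beta1^step); vhW <- vW[[l]] / (1 - beta2^step)
        mhb <- mb[[l]] / (1 - beta1^step); vhb <- vb[[l]] / (1 - beta2^step)
        model$W[[l]] <- model$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        model$b[[l]] <- model$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
      ep_loss <- ep_loss + bl / nbatch
      nb <- nb + 1L
    }
    loss_hist[ep] <- ep_loss / nb
    val_hist[ep] <- mse_set(va_idx)
  }
  # baseline: MSE of the noisy validation patches themselves (no denoising)
  val_mse_noisy <- if (length(va_idx) > 0L)
    mean(vapply(va_idx, function(i) mean((nois[[i]] - refs[[i]])^2), numeric(1)))
  else NA_real_
  model$train_meta <- list(epochs = as.integer(epochs), lr = lr,
                           seed = as.integer(seed), batch_size = as.integer(batch_size),
                           loss_history = loss_hist, val_history = val_hist,
                           val_cases = val_cases, val_mse_noisy = val_mse_noisy,
                           final_loss = loss_hist[epochs])
  model
}

#' Apply the denoiser to a full image
#'
#' The image is normalized by its own percentile span (the probabilities
#' stored in the model), passed through the network as a whole (no tiling),
#' denormalized, and clamped to non-negative values.
#'
#' @param model trained `denoiser_model`.
#' @param image matrix or `recon_image` (the acc arm).
#' @return `recon_image` tagged `"dlr"` (acceleration factor inherited).
#' @export
apply_denoiser <- function(model, image) {
  stopifnot(inherits(model, "denoiser_model"))
  af <- if (inherits(image, "recon_image")) image$af else 1L
  x <- as_image(image)
  if (!is.matrix(x)) stop("image must be a 2D matrix")
  p <- norm_params(x, model$norm$probs)
  y <- norm_invert(denoiser_forward(model, norm_apply(x, p)), p)
  y[y < 0] <- 0
  new_recon_image(y, "dlr", af = af)
}
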